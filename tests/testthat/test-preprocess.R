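mk_toy <- function(t0, t1) {
  counts <- tibble::tibble(
    sgRNA = sprintf("s%02d", seq_along(t0)),
    gene = sprintf("g%02d", seq_along(t0)),
    A_T0 = t0, A_T1 = t1
  )
  sheet <- validate_sample_sheet(data.frame(
    sample = c("A_T0", "A_T1"), condition = c("a", "a"),
    replicate = 1L, timepoint = c("T0", "T1"),
    t0_partner = c(NA, "A_T0")), design = "independent")
  list(counts = counts, sheet = sheet)
}

test_that("fold changes follow the loss-proportion definition", {
  toy <- mk_toy(t0 = c(100, 100, 100), t1 = c(0, 100, 200))
  fc <- screen_fold_changes(toy$counts, toy$sheet, pseudocount = 0,
                            depth_normalize = FALSE)
  # complete lethality 1, no effect 0, proliferation negative
  expect_equal(fc$A_T1, c(1, 0, -1))
  expect_equal(attr(fc, "t0_partner"), c(A_T1 = "A_T0"))

  # zero T0 count: NA at pseudocount 0, finite with pseudocount 1
  toy0 <- mk_toy(t0 = c(0, 100), t1 = c(5, 50))
  fc0 <- screen_fold_changes(toy0$counts, toy0$sheet, pseudocount = 0,
                             depth_normalize = FALSE)
  expect_true(is.na(fc0$A_T1[1]))
  fc1 <- screen_fold_changes(toy0$counts, toy0$sheet, pseudocount = 1,
                             depth_normalize = FALSE)
  expect_true(is.finite(fc1$A_T1[1]))

  allzero <- mk_toy(t0 = c(0, 0), t1 = c(1, 2))
  expect_error(screen_fold_changes(allzero$counts, allzero$sheet),
               "all-zero")
})

test_that("lethality scores anchor control medians at 0 and 1 exactly", {
  scr <- small_screen()
  fc <- screen_fold_changes(scr$counts, scr$sheet)
  l <- screen_lethality(fc, scr$controls)
  m <- as.matrix(l[sample_columns(l)])
  pos <- l$gene %in% scr$controls$gene[scr$controls$class == "positive"]
  neg <- l$gene %in% scr$controls$gene[scr$controls$class == "negative"]
  for (j in seq_len(ncol(m))) {
    expect_equal(median(m[neg, j]), 0, tolerance = 1e-12)
    expect_equal(median(m[pos, j]), 1, tolerance = 1e-12)
  }

  # hand evaluation of the rescaling
  anc <- attr(l, "anchors")
  fcm <- as.matrix(fc[sample_columns(fc)])
  expect_equal(m[5, 2], (fcm[5, 2] - anc$fc_neg[2]) /
                 (anc$fc_pos[2] - anc$fc_neg[2]))
})

test_that("lethality rescaling is affine-invariant and monotone", {
  scr <- small_screen()
  fc <- screen_fold_changes(scr$counts, scr$sheet)
  l1 <- screen_lethality(fc, scr$controls)
  set.seed(2)
  fc2 <- fc
  for (s in sample_columns(fc2)) {
    a <- runif(1, 0.2, 3); b <- runif(1, -1, 1)
    fc2[[s]] <- a * fc2[[s]] + b
  }
  l2 <- screen_lethality(fc2, scr$controls)
  expect_equal(as.matrix(l2[sample_columns(l2)]),
               as.matrix(l1[sample_columns(l1)]), tolerance = 1e-9)

  # strictly increasing in fold change within a sample
  s <- sample_columns(fc)[1]
  ord <- order(fc[[s]])
  expect_true(all(diff(l1[[s]][ord]) > -1e-12))

  # degenerate controls: identical medians
  fc3 <- fc
  pos <- fc3$gene %in% scr$controls$gene[scr$controls$class == "positive"]
  neg <- fc3$gene %in% scr$controls$gene[scr$controls$class == "negative"]
  for (s in sample_columns(fc3)) fc3[[s]][pos | neg] <- 0.3
  expect_error(screen_lethality(fc3, scr$controls), "degenerate")
})

test_that("quantile normalization averages ranks, is idempotent, and can
           be disabled", {
  l <- tibble::tibble(sgRNA = c("a", "b", "c"), gene = c("a", "b", "c"),
                      s1 = c(0, 1, 2), s2 = c(10, 11, 12))
  qn <- screen_quantile_normalize(l)
  expect_equal(qn$s1, c(5, 6, 7))
  expect_equal(qn$s2, c(5, 6, 7))

  # permutations of one multiset are a fixed point (up to order)
  lp <- tibble::tibble(sgRNA = letters[1:4], gene = letters[1:4],
                       s1 = c(4, 1, 3, 2), s2 = c(1, 2, 3, 4))
  qp <- screen_quantile_normalize(lp)
  expect_equal(qp$s1, lp$s1)
  expect_equal(qp$s2, lp$s2)

  expect_identical(screen_quantile_normalize(l, enabled = FALSE), l)

  set.seed(3)
  lr <- tibble::tibble(sgRNA = sprintf("s%d", 1:50),
                       gene = sprintf("g%d", 1:50),
                       s1 = rnorm(50), s2 = rnorm(50, 2, 3),
                       s3 = rexp(50))
  q1 <- screen_quantile_normalize(lr)
  q2 <- screen_quantile_normalize(q1)
  expect_equal(as.matrix(q2[3:5]), as.matrix(q1[3:5]), tolerance = 1e-12)
  # identical sorted multisets across samples
  expect_equal(sort(q1$s1), sort(q1$s2))

  single <- lr[c("sgRNA", "gene", "s1")]
  expect_warning(qs <- screen_quantile_normalize(single), ">=2 samples")
  expect_identical(qs, single)
})
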