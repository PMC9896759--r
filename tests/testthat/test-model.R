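sim_gene_y <- function(S, R, beta, sigma = 0.1, alpha = 0.3,
                       tau_b = 0, tau_u = 0) {
  b <- rnorm(S, 0, tau_b)
  u0 <- rnorm(S, 0, tau_u); u1 <- rnorm(S, 0, tau_u)
  y <- numeric(S * 2 * R)
  k <- 0
  for (s in 1:S) for (x in 0:1) for (r in 1:R) {
    k <- k + 1
    y[k] <- alpha + beta * x + b[s] + (if (x == 1) u1[s] else u0[s]) +
      rnorm(1, 0, sigma)
  }
  y
}

test_that("gene specs stack observations and report exclusions", {
  scr <- small_screen()
  fc <- screen_fold_changes(scr$counts, scr$sheet)
  l <- screen_lethality(fc, scr$controls)
  gd <- screen_gene_data(l, scr$sheet, exclude_genes = scr$controls$gene)
  expect_equal(nrow(gd), 60L)
  expect_true(all(gd$n_obs == 24L))     # 4 guides x 3 replicates x 2 arms
  expect_true(all(gd$n_guides == 4L))

  # a gene whose guides are all missing in one condition is excluded
  l2 <- l
  gene1 <- l2$gene == l2$gene[1]
  cond2 <- scr$sheet$sample[scr$sheet$timepoint != "T0" &
                              scr$sheet$condition == "cond2"]
  for (s in cond2) l2[[s]][gene1] <- NA
  gd2 <- screen_gene_data(l2, scr$sheet, exclude_genes = scr$controls$gene)
  excl <- attr(gd2, "exclusions")
  expect_true(l$gene[1] %in% excl$gene)
  expect_equal(nrow(gd2), 59L)
})

test_that("balanced and dense likelihood paths agree", {
  set.seed(10)
  hp <- mk_hyper()
  for (i in 1:5) {
    S <- sample(2:4, 1); R <- sample(2:3, 1)
    sp <- mk_gene_spec(S, R, sim_gene_y(S, R, beta = 0.3))
    expect_true(sp$balanced)
    spd <- sp; spd$balanced <- FALSE
    phi <- rnorm(3, c(-4, -5, -5), 0.5)
    for (hyp in c("H0", "Ha")) {
      f1 <- ebcrispr:::make_neg_logpost(sp, hp, hyp, "condition")
      f2 <- ebcrispr:::make_neg_logpost(spd, hp, hyp, "condition")
      expect_equal(f1(phi), f2(phi), tolerance = 1e-10)
      expect_equal(f1(phi),
                   -ebcrispr:::phi_log_posterior(phi, sp, hp, hyp,
                                                 "condition"),
                   tolerance = 1e-10)
    }
  }
})

test_that("no condition signal gives a Bayes factor at most one", {
  set.seed(11)
  hp <- mk_hyper()
  for (i in 1:5) {
    S <- 3; R <- 2
    half <- rnorm(S * R, 0.4, 0.2)
    # identical responses in both conditions, guide-wise
    y <- as.vector(t(cbind(matrix(half, S, R), matrix(half, S, R))))
    sp <- mk_gene_spec(S, R, y)
    f <- fit_gene(sp, hp)
    expect_lt(f$log_bf, 0.05)
  }
})

test_that("rescaling the data and priors shifts the evidence by -n log k", {
  set.seed(12)
  y <- sim_gene_y(3, 3, beta = 0.4)
  sp <- mk_gene_spec(3, 3, y)
  k <- 2.5
  spk <- mk_gene_spec(3, 3, k * y)
  hp <- mk_hyper()
  hpk <- mk_hyper(v_beta = hp$v_beta * k^2, v_alpha = hp$v_alpha * k^2,
                  sigma2 = hp$sigma2 + c(2 * log(k), 0),
                  tau_b2 = hp$tau_b2 + c(2 * log(k), 0),
                  tau_u2 = hp$tau_u2 + c(2 * log(k), 0))
  n <- length(y)
  for (hyp in c("H0", "Ha")) {
    l1 <- as.numeric(gene_marginal_loglik(sp, hp, hyp))
    l2 <- as.numeric(gene_marginal_loglik(spk, hpk, hyp))
    expect_equal(l2, l1 - n * log(k), tolerance = 1e-6)
  }
})

test_that("swapping condition labels negates beta and preserves the BF", {
  set.seed(13)
  hp <- mk_hyper()
  for (i in 1:5) {
    S <- sample(2:4, 1); R <- sample(2:3, 1)
    y <- sim_gene_y(S, R, beta = runif(1, -0.5, 0.5))
    sp <- mk_gene_spec(S, R, y)
    # swapped labels: condition blocks exchanged within each guide
    yswap <- as.vector(apply(matrix(y, ncol = 2 * R, byrow = TRUE), 1,
                             function(r) c(r[(R + 1):(2 * R)], r[1:R])))
    sp2 <- mk_gene_spec(S, R, yswap)
    f1 <- fit_gene(sp, hp); f2 <- fit_gene(sp2, hp)
    expect_lt(abs(f1$log_bf - f2$log_bf), 1e-9)
    expect_lt(abs(f1$beta_hat + f2$beta_hat), 1e-9)
  }
})

test_that("fits are deterministic and degenerate genes raise errors", {
  set.seed(14)
  y <- sim_gene_y(2, 2, beta = 0.2)
  sp <- mk_gene_spec(2, 2, y)
  hp <- mk_hyper()
  f1 <- fit_gene(sp, hp); f2 <- fit_gene(sp, hp)
  expect_identical(f1, f2)

  flat <- mk_gene_spec(2, 2, rep(0.5, 8), gene = "flatgene")
  expect_error(fit_gene(flat, hp), "flatgene")
})

test_that("posterior condition effects are shrunk relative to least
           squares", {
  set.seed(15)
  hp <- mk_hyper(v_beta = 0.02)
  for (i in 1:10) {
    S <- 4; R <- 3
    y <- sim_gene_y(S, R, beta = runif(1, -0.6, 0.6))
    sp <- mk_gene_spec(S, R, y)
    f <- fit_gene(sp, hp)
    ols <- mean(y[sp$x == 1]) - mean(y[sp$x == 0])
    expect_lt(abs(f$beta_hat), abs(ols) + 1e-12)
  }
})

test_that("the posterior mean recovers the simulated condition effect", {
  set.seed(16)
  n_genes <- 200
  beta_true <- 0.5 / 0.7
  specs <- lapply(seq_len(n_genes), function(i) {
    mk_gene_spec(4, 3, sim_gene_y(4, 3, beta = beta_true, sigma = 0.1),
                 gene = sprintf("g%03d", i))
  })
  gd <- tibble::tibble(gene = vapply(specs, `[[`, "", "gene"),
                       n_guides = 4L, n_obs = 24L, spec = specs)
  hp <- screen_hyperparameters(gd)
  fits <- vapply(specs, function(s) fit_gene(s, hp)$beta_hat, 0)
  expect_lt(abs(mean(fits) - beta_true) / beta_true, 0.10)
})

test_that("median evidence increases strictly with the simulated effect", {
  set.seed(17)
  grid <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5)
  n_per <- 100
  specs <- list(); truth <- numeric(0)
  for (b in grid) for (i in 1:n_per) {
    specs[[length(specs) + 1]] <-
      mk_gene_spec(4, 3, sim_gene_y(4, 3, beta = b, sigma = 0.15),
                   gene = sprintf("g%.1f_%03d", b, i))
    truth <- c(truth, b)
  }
  gd <- tibble::tibble(gene = vapply(specs, `[[`, "", "gene"),
                       n_guides = 4L, n_obs = 24L, spec = specs)
  hp <- screen_hyperparameters(gd)
  med <- vapply(grid, function(b) {
    median(vapply(specs[truth == b], function(s) fit_gene(s, hp)$log_bf, 0))
  }, 0)
  expect_true(all(diff(med) > 0))
})

test_that("a longitudinal fit with a constant time covariate reduces to the
           single-timepoint model", {
  set.seed(18)
  y <- sim_gene_y(3, 3, beta = 0.4)
  sp1 <- mk_gene_spec(3, 3, y)
  spL <- mk_gene_spec(3, 3, y, design = "longitudinal", tv = 0)
  hp <- mk_hyper()
  f1 <- fit_gene(sp1, hp)
  fL <- fit_gene(spL, hp)
  expect_equal(fL$beta_hat, f1$beta_hat, tolerance = 1e-6)
  expect_equal(fL$log_bf, f1$log_bf, tolerance = 1e-6)
  expect_equal(fL$beta_time, 0, tolerance = 1e-10)
  expect_equal(fL$beta_interaction, 0, tolerance = 1e-10)
})

test_that("a genuine time trend is picked up by the longitudinal model", {
  set.seed(19)
  S <- 4; R <- 3
  rows <- expand.grid(r = 1:R, x = 0:1, t = c(0, 1), s = 1:S)
  y <- 0.2 + 0.5 * rows$x + 0.3 * rows$t + rnorm(nrow(rows), 0, 0.1)
  d <- data.frame(gene = "g", sgRNA = sprintf("s%d", rows$s), x = rows$x,
                  tv = rows$t, replicate = rows$r, l = y)
  sp <- ebcrispr:::new_gene_spec(d, "longitudinal")
  expect_equal(length(sp$y), S * R * 4)
  f <- fit_gene(sp, mk_hyper(v_beta = 0.5))
  expect_gt(f$log_bf, 3)
  expect_equal(f$beta_time, 0.3, tolerance = 0.15)
  expect_equal(f$beta_hat, 0.5, tolerance = 0.15)
})

test_that("hyperparameter pooling behaves under null, signal and scaling", {
  set.seed(20)
  mk_gd <- function(betas, sigma = 0.05, scale = 1) {
    specs <- lapply(seq_along(betas), function(i) {
      mk_gene_spec(4, 3,
                   scale * sim_gene_y(4, 3, beta = betas[i], sigma = sigma),
                   gene = sprintf("g%04d", i))
    })
    tibble::tibble(gene = vapply(specs, `[[`, "", "gene"),
                   n_guides = 4L, n_obs = 24L, spec = specs)
  }
  # all-null: prior variance of beta collapses to (near) the floor
  gd0 <- mk_gd(rep(0, 120))
  hp0 <- screen_hyperparameters(gd0)
  expect_gte(hp0$v_beta, 1e-4)
  expect_lt(hp0$v_beta, 3e-4)

  # beta ~ N(0, 0.04), low noise: recovered within 20%
  set.seed(21)
  betas <- rnorm(1000, 0, 0.2)
  gd1 <- mk_gd(betas, sigma = 0.02)
  hp1 <- screen_hyperparameters(gd1)
  expect_lt(abs(hp1$v_beta - 0.04) / 0.04, 0.20)

  # doubling every response quadruples v_beta
  set.seed(22); gd2 <- mk_gd(betas[1:200], sigma = 0.02)
  set.seed(22); gd4 <- mk_gd(betas[1:200], sigma = 0.02, scale = 2)
  expect_equal(screen_hyperparameters(gd4)$v_beta,
               4 * screen_hyperparameters(gd2)$v_beta, tolerance = 1e-8)

  expect_error(screen_hyperparameters(gd0[1:5, ]), "at least 10")
  expect_warning(screen_hyperparameters(gd0[1:20, ]), "fewer than 50")
})

test_that("the pooled unstructured covariance option runs and is more
           conservative for shared shifts", {
  set.seed(23)
  scr <- cached_screen("unstr", G = 80, n_effect = 15, delta = 0.3,
                       n_pos = 40, n_neg = 40, seed = 404)
  fc <- screen_fold_changes(scr$counts, scr$sheet)
  l <- screen_lethality(fc, scr$controls)
  gd <- screen_gene_data(l, scr$sheet, exclude_genes = scr$controls$gene)
  hp_d <- screen_hyperparameters(gd)
  hp_u <- screen_hyperparameters(gd, covariance = "unstructured")
  expect_true(is.matrix(hp_u$corr_b))
  expect_equal(dim(hp_u$corr_u), c(4L, 4L))
  eff <- gd$spec[[1]]                      # an effect gene
  f_d <- fit_gene(eff, hp_d)
  f_u <- fit_gene(eff, hp_u)
  expect_true(is.finite(f_u$log_bf))
  expect_lt(f_u$log_bf, f_d$log_bf)
})

test_that("selecting two timepoints doubles each spec's observations and
           switches to the longitudinal design", {
  scr <- small_screen()
  fc <- screen_fold_changes(scr$counts, scr$sheet)
  l1 <- screen_lethality(fc, scr$controls)
  # clone the endpoint as a second timepoint
  l2 <- l1
  sheet2 <- scr$sheet
  ep <- sheet2[sheet2$timepoint != "T0", ]
  for (k in seq_len(nrow(ep))) {
    nm <- paste0(ep$sample[k], "_T2")
    l2[[nm]] <- l1[[ep$sample[k]]] + rnorm(nrow(l1), 0, 0.01)
    sheet2 <- rbind(sheet2,
                    data.frame(sample = nm, condition = ep$condition[k],
                               replicate = ep$replicate[k],
                               timepoint = "T2",
                               t0_partner = ep$t0_partner[k]))
  }
  sheet2 <- validate_sample_sheet(sheet2, design = "independent",
                                  reference = "cond1")
  gd1 <- screen_gene_data(l1, scr$sheet, exclude_genes = scr$controls$gene)
  gdL <- screen_gene_data(l2, sheet2, timepoints = "all",
                          exclude_genes = scr$controls$gene)
  expect_equal(attr(gdL, "design"), "longitudinal")
  expect_equal(gdL$n_obs, 2L * gd1$n_obs)
  expect_equal(sort(unique(gdL$spec[[1]]$tv)), c(0, 1))
})

test_that("single-guide genes are excluded by default but can be retained", {
  scr <- small_screen()
  fc <- screen_fold_changes(scr$counts, scr$sheet)
  l <- screen_lethality(fc, scr$controls)
  # reduce one gene to a single guide
  g1 <- l$gene[1]
  keep <- !(l$gene == g1 & l$sgRNA != l$sgRNA[1])
  l1 <- l[keep, ]
  gd <- screen_gene_data(l1, scr$sheet, exclude_genes = scr$controls$gene)
  expect_true(g1 %in% attr(gd, "exclusions")$gene)
  gd2 <- screen_gene_data(l1, scr$sheet,
                          exclude_genes = scr$controls$gene,
                          allow_single_guide = TRUE)
  expect_false(g1 %in% attr(gd2, "exclusions")$gene)
  row <- gd2[gd2$gene == g1, ]
  expect_equal(row$n_guides, 1L)
  hp <- screen_hyperparameters(gd2)
  f <- fit_gene(row$spec[[1]], hp)
  expect_true(is.finite(f$log_bf))
})
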