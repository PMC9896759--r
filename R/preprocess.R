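#' Fold changes relative to the matched T=0 sample
#'
#' For every guide s and endpoint sample, computes
#' \deqn{fc_s = (C_{s0} - C_s) / C_{s0},}
#' the proportion of cells carrying the guide lost since T=0: 1 is complete
#' lethality, 0 no effect, negative values proliferation. Counts are
#' optionally depth-scaled to the mean library size across samples first, and
#' shifted by a pseudocount to bound the ratio when T=0 counts are low.
#'
#' @param counts Validated count tibble (see [read_screen_counts()]).
#' @param sheet Validated sample sheet; every non-T0 sample must name its
#'   T0 partner.
#' @param pseudocount Non-negative value added to every (scaled) count,
#'   default 1. With `pseudocount = 0` guides with zero T0 count get `NA`.
#' @param depth_normalize Scale each sample to the mean total count across
#'   all samples before forming ratios (default `TRUE`). The downstream
#'   control anchoring is invariant to this per-sample affine rescaling, so
#'   the toggle matters only for inspecting raw fold changes.
#' @return Tibble `sgRNA`, `gene`, plus one column per non-T0 sample.
#'   Attributes: `t0_partner` (named character), `pseudocount`.
#' @export
screen_fold_changes <- function(counts, sheet, pseudocount = 1,
                                depth_normalize = TRUE) {
  counts <- validate_counts(counts)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  smp <- sample_columns(counts)
  miss <- setdiff(sheet$sample, smp)
  if (length(miss)) {
    stop("sample(s) in sheet but not in counts: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(counts[smp])
  totals <- colSums(m)
  if (any(totals == 0)) {
    stop("all-zero sample column: ", paste(smp[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  if (depth_normalize) {
    m <- sweep(m, 2, mean(totals) / totals, `*`)
  }
  m <- m + pseudocount
  ep <- sheet[sheet$timepoint != "T0", , drop = FALSE]
  fc <- matrix(NA_real_, nrow(m), nrow(ep),
               dimnames = list(NULL, ep$sample))
  for (j in seq_len(nrow(ep))) {
    c0 <- m[, ep$t0_partner[j]]
    cs <- m[, ep$sample[j]]
    v <- (c0 - cs) / c0
    v[c0 == 0] <- NA_real_
    fc[, j] <- v
  }
  out <- dplyr::bind_cols(counts[c("sgRNA", "gene")],
                          tibble::as_tibble(fc))
  attr(out, "t0_partner") <- stats::setNames(ep$t0_partner, ep$sample)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Control-anchored lethality scores
#'
#' Rescales each sample's fold changes so that the median over
#' negative-control guides maps to 0 and the median over positive-control
#' guides maps to 1:
#' \deqn{l_s = (fc_s - fc_{neg}) / (fc_{pos} - fc_{neg}).}
#' The transform is affine per sample, so it cancels any per-sample affine
#' distortion of the fold changes (depth scaling included).
#'
#' @param fc Fold-change tibble from [screen_fold_changes()].
#' @param controls Control set from [control_set()].
#' @return Tibble of the same shape with lethality scores; attribute
#'   `anchors` is a tibble (`sample`, `fc_neg`, `fc_pos`).
#' @export
screen_lethality <- function(fc, controls) {
  smp <- sample_columns(fc)
  pos <- fc$gene %in% controls$gene[controls$class == "positive"]
  neg <- fc$gene %in% controls$gene[controls$class == "negative"]
  if (!any(pos) || !any(neg)) {
    stop("need >=1 positive-control and >=1 negative-control guide",
         call. = FALSE)
  }
  m <- as.matrix(fc[smp])
  fneg <- apply(m[neg, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  fpos <- apply(m[pos, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(fneg)) || any(!is.finite(fpos))) {
    stop("control fold-change medians are not finite", call. = FALSE)
  }
  if (any(abs(fpos - fneg) < 1e-12)) {
    stop("degenerate controls: positive and negative medians coincide",
         call. = FALSE)
  }
  l <- sweep(sweep(m, 2, fneg, `-`), 2, fpos - fneg, `/`)
  out <- dplyr::bind_cols(fc[c("sgRNA", "gene")], tibble::as_tibble(l))
  attr(out, "anchors") <- tibble::tibble(sample = smp, fc_neg = fneg,
                                         fc_pos = fpos)
  attr(out, "quantile_normalized") <- FALSE
  out
}

#' Quantile-normalize lethality scores across samples
#'
#' Standard rank-mean quantile normalization (via
#' [limma::normalizeQuantiles()], ties averaged): after normalization all
#' samples share the same sorted multiset of values. Only needed when
#' lethality-score distributions differ substantially between samples.
#' Rows with any missing value are carried through untouched.
#'
#' @param l Lethality tibble from [screen_lethality()].
#' @param enabled If `FALSE`, returns the input unchanged.
#' @return Tibble of the same shape.
#' @export
screen_quantile_normalize <- function(l, enabled = TRUE) {
  if (!enabled) return(l)
  smp <- sample_columns(l)
  if (length(smp) < 2) {
    warning("quantile normalization needs >=2 samples; returning input")
    return(l)
  }
  m <- as.matrix(l[smp])
  complete <- stats::complete.cases(m)
  m[complete, ] <- limma::normalizeQuantiles(m[complete, , drop = FALSE],
                                             ties = TRUE)
  out <- dplyr::bind_cols(l[c("sgRNA", "gene")], tibble::as_tibble(m))
  attr(out, "anchors") <- attr(l, "anchors")
  attr(out, "quantile_normalized") <- TRUE
  out
}
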