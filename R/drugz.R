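#' drugZ-style guide z-score baseline
#'
#' Reimplementation of the published drugZ algorithm for benchmark
#' comparison. Per replicate pair (reference arm vs non-reference arm at the
#' endpoint): samples are scaled to a common depth of 1e7 reads, a
#' pseudocount is added, and per-guide log2 fold changes treated-vs-control
#' are computed. Guide variance is estimated empirical-Bayes style against
#' read-count bins: guides are sorted by reference-arm reads (descending) and
#' the standard deviation for each half-bin of 400 guides is taken from the
#' 800-guide window starting there. Guide z-scores are summed per gene across
#' guides and replicates, `normZ = sumZ / sqrt(n)` re-standardized to zero
#' mean and unit variance across genes, with two-sided normal p-values and
#' BH-adjusted q-values.
#'
#' T=0 samples are ignored, as in drugZ. For the independent design,
#' replicate pairing between arms is positional (by replicate label), the way
#' such paired-design tools are applied to unpaired data.
#'
#' @param counts Count tibble.
#' @param sheet Validated sample sheet (reference condition is the first
#'   level unless set in the sheet's attributes).
#' @param pseudocount Added to depth-scaled reads, default 5 (drugZ default).
#' @return A tibble: `gene`, `n_obs`, `sumZ`, `normZ`, one-sided
#'   depletion/enrichment p-values (`pval_synth`, `pval_supp`), the
#'   two-sided `pval`, and BH q-values for each.
#' @export
drugz_scores <- function(counts, sheet, pseudocount = 5) {
  counts <- validate_counts(counts)
  reference <- attr(sheet, "reference")
  ep <- sheet[sheet$timepoint != "T0", , drop = FALSE]
  if (is.null(reference)) reference <- sort(unique(ep$condition))[1]
  ctrl <- ep[ep$condition == reference, , drop = FALSE]
  trt <- ep[ep$condition != reference, , drop = FALSE]
  if (!nrow(ctrl) || !nrow(trt)) {
    stop("need endpoint samples in both conditions", call. = FALSE)
  }
  ctrl <- ctrl[order(ctrl$replicate, ctrl$timepoint), , drop = FALSE]
  trt <- trt[order(trt$replicate, trt$timepoint), , drop = FALSE]
  if (nrow(ctrl) != nrow(trt)) {
    stop("cannot pair replicates: ", nrow(ctrl), " reference vs ",
         nrow(trt), " non-reference endpoint samples", call. = FALSE)
  }
  m <- as.matrix(counts[sample_columns(counts)])
  zs <- matrix(NA_real_, nrow(m), nrow(ctrl))
  for (j in seq_len(nrow(ctrl))) {
    c_reads <- m[, ctrl$sample[j]] * 1e7 / sum(m[, ctrl$sample[j]])
    t_reads <- m[, trt$sample[j]] * 1e7 / sum(m[, trt$sample[j]])
    fc <- log2((t_reads + pseudocount) / (c_reads + pseudocount))
    zs[, j] <- drugz_binned_zscores(fc, c_reads)
  }
  per_gene <- tibble::tibble(gene = counts$gene,
                             z = rowSums(zs), n = ncol(zs)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_obs = sum(.data$n),
                     sumZ = sum(.data$z), .groups = "drop")
  per_gene$normZ <- per_gene$sumZ / sqrt(per_gene$n_obs)
  # final re-standardization across genes, as in the published algorithm
  sdz <- stats::sd(per_gene$normZ)
  if (is.finite(sdz) && sdz > 0) {
    per_gene$normZ <- (per_gene$normZ - mean(per_gene$normZ)) / sdz
  }
  # like the published tool, report one-sided p-values for depletion
  # (synthetic-lethal) and enrichment (suppressor) separately, plus the
  # two-sided combination
  per_gene$pval_synth <- stats::pnorm(per_gene$normZ)
  per_gene$pval_supp <- stats::pnorm(-per_gene$normZ)
  per_gene$pval <- 2 * stats::pnorm(-abs(per_gene$normZ))
  per_gene$qval_synth <- stats::p.adjust(per_gene$pval_synth, method = "BH")
  per_gene$qval_supp <- stats::p.adjust(per_gene$pval_supp, method = "BH")
  per_gene$qval <- stats::p.adjust(per_gene$pval, method = "BH")
  per_gene[order(per_gene$pval, per_gene$gene), , drop = FALSE]
}

# Bin-wise empirical-Bayes variance: sort guides by reference reads
# (descending); each consecutive half-bin of 400 guides gets the sd of fold
# changes over the 800-guide window starting at the half-bin.
drugz_binned_zscores <- function(fc, ref_reads, bin_size = 800L,
                                 half = 400L) {
  n <- length(fc)
  ord <- order(ref_reads, decreasing = TRUE)
  fc_sorted <- fc[ord]
  sds <- numeric(n)
  starts <- seq(1L, n, by = half)
  for (s in starts) {
    win_end <- min(s + bin_size - 1L, n)
    win_start <- max(1L, min(s, n - bin_size + 1L))
    sd_bin <- stats::sd(fc_sorted[win_start:win_end])
    idx <- s:min(s + half - 1L, n)
    sds[idx] <- sd_bin
  }
  z_sorted <- ifelse(sds > 0, fc_sorted / sds, 0)
  z <- numeric(n)
  z[ord] <- z_sorted
  z
}

#' Call baseline hits at a significance level
#'
#' The published tool tests each direction (depletion / enrichment)
#' one-sided; `sided = "one"` (default) calls a gene when either direction
#' is significant at `level`, matching how its output is used in practice.
#' `sided = "two"` uses the two-sided p-value instead.
#'
#' @param result Output of [drugz_scores()].
#' @param level Significance level in (0, 1), default 0.05.
#' @param adjusted Use BH q-values instead of raw p-values.
#' @param sided `"one"` (either one-sided test) or `"two"` (two-sided).
#' @return Character vector of hit genes.
#' @export
call_baseline_hits <- function(result, level = 0.05, adjusted = FALSE,
                               sided = c("one", "two")) {
  stopifnot(level > 0, level <= 1)
  sided <- match.arg(sided)
  if (level >= 1) return(result$gene)
  p <- if (sided == "one") {
    if (adjusted) pmin(result$qval_synth, result$qval_supp)
    else pmin(result$pval_synth, result$pval_supp)
  } else {
    if (adjusted) result$qval else result$pval
  }
  result$gene[p < level]
}
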