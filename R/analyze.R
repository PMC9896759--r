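#' One-shot screen analysis
#'
#' Runs the full pipeline: fold changes relative to T=0, control-anchored
#' lethality scores, optional quantile normalization, per-gene
#' empirical-Bayes mixed-model fits, Bayes factors, lfdr and hit calls.
#' Control genes are used for anchoring and excluded from testing.
#'
#' @param counts Count tibble ([read_screen_counts()]).
#' @param sheet Validated sample sheet ([read_sample_sheet()]).
#' @param controls Control set ([control_set()]).
#' @param pseudocount Pseudocount for fold changes, default 1.
#' @param depth_normalize Depth-scale samples before fold changes.
#' @param quantile_normalize Quantile-normalize lethality scores across
#'   samples (default `FALSE`; control anchoring already aligns scales).
#' @param timepoints Timepoint selection for the model (`"last"`, `"all"`,
#'   or labels); more than one timepoint fits the longitudinal model.
#' @param allow_single_guide Retain single-guide genes (see
#'   [screen_gene_data()]).
#' @inheritParams eb_fit
#' @return An `eb_screen_fit` tibble (see [eb_fit()]).
#' @export
screen_analyze <- function(counts, sheet, controls,
                           pseudocount = 1, depth_normalize = TRUE,
                           quantile_normalize = FALSE,
                           timepoints = "last",
                           allow_single_guide = FALSE,
                           lfdr_threshold = 0.05, pi0 = "em",
                           theta_integration = c("laplace", "plugin"),
                           test = c("condition", "interaction"),
                           covariance = c("diagonal", "unstructured"),
                           v_floor = 1e-4) {
  fc <- screen_fold_changes(counts, sheet, pseudocount = pseudocount,
                            depth_normalize = depth_normalize)
  l <- screen_lethality(fc, controls)
  l <- screen_quantile_normalize(l, enabled = quantile_normalize)
  gd <- screen_gene_data(l, sheet, timepoints = timepoints,
                         exclude_genes = controls$gene,
                         allow_single_guide = allow_single_guide)
  eb_fit(gd, lfdr_threshold = lfdr_threshold, pi0 = pi0,
         theta_integration = theta_integration, test = test,
         covariance = covariance, v_floor = v_floor)
}

#' @export
print.eb_screen_fit <- function(x, ...) {
  opts <- attr(x, "options")
  cat("Per-gene empirical-Bayes screen fit\n")
  cat("  genes tested: ", nrow(x), "\n", sep = "")
  cat("  design: ", opts$design, ", test: ", opts$test, "\n", sep = "")
  cat("  pi0: ", signif(attr(x, "pi0"), 4),
      ", hits at lfdr < ", opts$lfdr_threshold, ": ", sum(x$hit),
      "\n\n", sep = "")
  NextMethod()
  invisible(x)
}

#' Tidy a screen fit into a per-gene tibble
#'
#' @param x An `eb_screen_fit`.
#' @param ... Unused.
#' @return A plain tibble with one row per gene.
#' @method tidy eb_screen_fit
#' @export
tidy.eb_screen_fit <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "eb_screen_fit")
  attr(out, "hyper") <- NULL
  attr(out, "pi0") <- NULL
  attr(out, "exclusions") <- NULL
  attr(out, "options") <- NULL
  tibble::as_tibble(out)
}

#' One-row summary of a screen fit
#'
#' @param x An `eb_screen_fit`.
#' @param ... Unused.
#' @return One-row tibble: genes tested, hits, pi0, v_beta, threshold.
#' @method glance eb_screen_fit
#' @export
glance.eb_screen_fit <- function(x, ...) {
  hp <- attr(x, "hyper")
  excl <- attr(x, "exclusions")
  tibble::tibble(
    n_genes = nrow(x),
    n_hits = sum(x$hit),
    pi0 = attr(x, "pi0"),
    v_beta = hp$v_beta,
    lfdr_threshold = attr(x, "options")$lfdr_threshold,
    n_excluded = if (is.null(excl)) 0L else nrow(excl)
  )
}
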