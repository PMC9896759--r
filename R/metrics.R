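#' Confusion counts of a hit call against simulation truth
#'
#' @param hits Character vector of genes called as hits.
#' @param truth Tibble `gene`, `is_effect` covering all tested genes.
#' @return One-row tibble `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(hits, truth) {
  unknown <- setdiff(hits, truth$gene)
  if (length(unknown)) {
    stop("hit gene(s) absent from truth: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  called <- truth$gene %in% hits
  tibble::tibble(
    tp = sum(called & truth$is_effect),
    fp = sum(called & !truth$is_effect),
    tn = sum(!called & !truth$is_effect),
    fn = sum(!called & truth$is_effect)
  )
}

#' Classification rates from confusion counts
#'
#' Conventions for empty cells: precision is 1 when nothing is called;
#' sensitivity is `NA` when no effect genes exist.
#'
#' @param cm One-row tibble from [confusion_counts()].
#' @return One-row tibble with `sensitivity`, `specificity`, `precision`,
#'   `recall`, `accuracy` appended.
#' @export
confusion_rates <- function(cm) {
  dplyr::mutate(
    cm,
    sensitivity = ifelse(.data$tp + .data$fn > 0,
                         .data$tp / (.data$tp + .data$fn), NA_real_),
    specificity = ifelse(.data$tn + .data$fp > 0,
                         .data$tn / (.data$tn + .data$fp), NA_real_),
    precision = ifelse(.data$tp + .data$fp > 0,
                       .data$tp / (.data$tp + .data$fp), 1),
    recall = .data$sensitivity,
    accuracy = (.data$tp + .data$tn) /
      (.data$tp + .data$fp + .data$tn + .data$fn)
  )
}

#' ROC points for a per-gene ordering statistic
#'
#' Sweeps the score threshold over its full range (smaller scores called
#' first: pass lfdr or p-values directly) and reports the curve evaluated by
#' vertical interpolation on a fixed FPR grid, so curves from different
#' datasets can be averaged pointwise.
#'
#' @param scores Named numeric vector (names = genes) or tibble
#'   `gene`, `score`; lower scores rank as stronger evidence.
#' @param truth Tibble `gene`, `is_effect`.
#' @param fpr_grid Grid of false-positive rates, default `seq(0, 1, 0.01)`.
#' @return Tibble `fpr`, `tpr`.
#' @export
roc_points <- function(scores, truth, fpr_grid = seq(0, 1, by = 0.01)) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$score, scores$gene)
  }
  truth <- truth[truth$gene %in% names(scores), , drop = FALSE]
  lab <- truth$is_effect[match(names(scores), truth$gene)]
  if (all(lab) || !any(lab)) {
    stop("ROC undefined: truth is all-effect or all-null", call. = FALSE)
  }
  ord <- order(scores)
  lab <- lab[ord]; sc <- scores[ord]
  # group ties: cumulative counts evaluated at the last index of each score
  last <- !duplicated(rev(sc)); last <- rev(last)
  tp <- cumsum(lab)[last]; fp <- cumsum(!lab)[last]
  tpr <- c(0, tp / sum(lab), 1)
  fpr <- c(0, fp / sum(!lab), 1)
  tpr_grid <- stats::approx(fpr, tpr, xout = fpr_grid, ties = max,
                            rule = 2)$y
  tibble::tibble(fpr = fpr_grid, tpr = tpr_grid)
}

#' Run the simulation benchmark grid
#'
#' For each (design, delta) scenario: simulate `n_datasets` screens, analyse
#' each with the requested methods, score hit calls against the truth, and
#' aggregate. The empirical-Bayes pipeline calls hits at `lfdr < 0.05`; the
#' drugZ-style baseline at raw `p < 0.05` (and BH-adjusted calls are
#' reported alongside). Per-dataset seeds are derived deterministically from
#' `seed`, so aggregates do not depend on dataset order.
#'
#' @param designs Character subset of `c("paired", "independent")`.
#' @param deltas Numeric vector of effect sizes.
#' @param n_datasets Simulated datasets per scenario.
#' @param methods Subset of `c("ebcrispr", "drugz")`.
#' @param seed Master seed.
#' @param lfdr_threshold Hit threshold for the empirical-Bayes pipeline.
#' @param level Raw-p level for the baseline.
#' @param config_args Extra arguments passed to [sim_config()].
#' @param roc Also compute averaged ROC curves (slower).
#' @return A tibble with one row per (design, delta, method): mean and sd of
#'   the confusion counts and rates across datasets. When `roc = TRUE` the
#'   attribute `roc` holds a tibble (design, delta, method, fpr, mean tpr).
#' @export
run_benchmark <- function(designs = c("independent"),
                          deltas = c(0, 0.2, 0.3),
                          n_datasets = 10, methods = c("ebcrispr", "drugz"),
                          seed = 1, lfdr_threshold = 0.05, level = 0.05,
                          config_args = list(), roc = FALSE) {
  stopifnot(all(methods %in% c("ebcrispr", "drugz")))
  rows <- list(); roc_rows <- list()
  for (design in designs) for (delta in deltas) {
    per_ds <- list(); per_roc <- list()
    for (i in seq_len(n_datasets)) {
      ds_seed <- (seed * 1000L + i * 37L +
                    round(delta * 1e4) + (design == "paired") * 101L) %%
        2147483647L
      cfg <- do.call(sim_config, c(list(delta = delta, design = design,
                                        seed = ds_seed), config_args))
      scr <- simulate_screen(cfg)
      for (method in methods) {
        out <- tryCatch(
          benchmark_one(scr, method, lfdr_threshold, level, roc),
          error = function(e) {
            warning("method ", method, " failed on dataset ", i, ": ",
                    conditionMessage(e))
            NULL
          })
        if (is.null(out)) next
        per_ds[[length(per_ds) + 1]] <- dplyr::mutate(out$row,
                                                      method = method)
        if (roc && !is.null(out$roc)) per_roc[[length(per_roc) + 1]] <-
            dplyr::mutate(out$roc, method = method)
      }
    }
    agg <- dplyr::bind_rows(per_ds) |>
      dplyr::group_by(.data$method) |>
      dplyr::summarise(dplyr::across(
        dplyr::where(is.numeric),
        list(mean = ~ mean(.x, na.rm = TRUE),
             sd = ~ stats::sd(.x, na.rm = TRUE))), .groups = "drop") |>
      dplyr::mutate(design = design, delta = delta,
                    n_datasets = n_datasets, .before = 1)
    rows[[length(rows) + 1]] <- agg
    if (roc && length(per_roc)) {
      roc_rows[[length(roc_rows) + 1]] <- dplyr::bind_rows(per_roc) |>
        dplyr::group_by(.data$method, .data$fpr) |>
        dplyr::summarise(tpr = mean(.data$tpr), .groups = "drop") |>
        dplyr::mutate(design = design, delta = delta, .before = 1)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (roc) attr(out, "roc") <- dplyr::bind_rows(roc_rows)
  out
}

# Analyse one simulated screen with one method and score it.
benchmark_one <- function(scr, method, lfdr_threshold, level, roc) {
  if (method == "ebcrispr") {
    res <- screen_analyze(scr$counts, scr$sheet, scr$controls,
                          lfdr_threshold = lfdr_threshold)
    hits <- res$gene[res$hit]
    score <- stats::setNames(res$lfdr, res$gene)
  } else {
    res <- drugz_scores(scr$counts, scr$sheet)
    res <- res[res$gene %in% scr$truth$gene, , drop = FALSE]
    hits <- intersect(call_baseline_hits(res, level = level),
                      scr$truth$gene)
    score <- stats::setNames(res$pval, res$gene)
  }
  truth <- scr$truth[scr$truth$gene %in% names(score), , drop = FALSE]
  cm <- confusion_rates(confusion_counts(hits, truth))
  rc <- NULL
  if (roc && any(truth$is_effect) && !all(truth$is_effect)) {
    rc <- roc_points(score, truth)
  }
  list(row = cm, roc = rc)
}
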