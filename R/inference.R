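#' Estimate the null proportion from Bayes factors
#'
#' Two-group EM on the mixture implied by
#' \eqn{lfdr_g = \pi_0 / (\pi_0 + (1-\pi_0) BF_g)}: iterate
#' \eqn{\pi_0 \leftarrow \mathrm{mean}_g(lfdr_g)} to convergence
#' (\eqn{|\Delta\pi_0| < 10^{-6}}). The result is clipped to `[0.5, 1]`,
#' which keeps the estimate conservative under dense signal.
#'
#' @param log_bfs Numeric vector of per-gene log Bayes factors.
#' @param pi0_init Starting value, default 0.9.
#' @return Estimated null proportion in `[0.5, 1]`.
#' @export
estimate_pi0 <- function(log_bfs, pi0_init = 0.9) {
  if (length(log_bfs) < 10) stop("need >= 10 genes", call. = FALSE)
  if (any(!is.finite(log_bfs))) {
    stop("non-finite log Bayes factor at position ",
         which(!is.finite(log_bfs))[1], call. = FALSE)
  }
  pi0 <- pi0_init
  for (i in 1:1000) {
    lf <- lfdr_from_logbf(log_bfs, pi0)
    new <- mean(lf)
    if (abs(new - pi0) < 1e-6) { pi0 <- new; break }
    pi0 <- new
  }
  pi0 <- min(max(pi0, 0.5), 1)
  # flat-likelihood tie-break: if the all-null model explains the Bayes
  # factors as well as the EM solution, prefer it (conservative)
  mix_ll <- function(p) {
    sum(log(p + (1 - p) * exp(pmin(log_bfs, 700))))
  }
  if (mix_ll(1) >= mix_ll(pi0) - 1e-8) pi0 <- 1
  pi0
}

# lfdr = pi0 / (pi0 + (1 - pi0) BF), evaluated in log space.
lfdr_from_logbf <- function(log_bfs, pi0) {
  if (pi0 >= 1) return(rep(1, length(log_bfs)))
  # 1 / (1 + exp(log((1-pi0)/pi0) + log_bf))
  stats::plogis(log(pi0 / (1 - pi0)) - log_bfs)
}

#' Local false discovery rates from Bayes factors
#'
#' @param log_bfs Numeric vector of per-gene log Bayes factors.
#' @param pi0 Null proportion in (0, 1].
#' @return A tibble with columns `log_bf`, `lfdr`, and attribute `pi0`.
#' @export
compute_lfdr <- function(log_bfs, pi0) {
  stopifnot(is.numeric(pi0), length(pi0) == 1, pi0 > 0, pi0 <= 1)
  if (anyNA(log_bfs)) stop("missing log Bayes factor", call. = FALSE)
  out <- tibble::tibble(log_bf = log_bfs,
                        lfdr = lfdr_from_logbf(log_bfs, pi0))
  attr(out, "pi0") <- pi0
  out
}

#' Call hits at an lfdr threshold
#'
#' A gene is a hit when its lfdr is strictly below the threshold.
#'
#' @param results A tibble with columns `gene` and `lfdr` (e.g. an
#'   [eb_fit()] result).
#' @param threshold Strict lfdr cutoff in (0, 1), default 0.05.
#' @return The input with its `hit` column set at the requested threshold.
#' @export
call_hits <- function(results, threshold = 0.05) {
  stopifnot(threshold > 0, threshold <= 1)
  results$hit <- results$lfdr < threshold
  results
}
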