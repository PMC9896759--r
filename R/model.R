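#' Assemble per-gene model data from lethality scores
#'
#' Stacks lethality scores into one record per (guide, replicate, condition
#' [, timepoint]) observation per gene, ready for the per-gene mixed model
#' \deqn{l = \alpha + \beta x + b_s + u_{sc} + \epsilon,}
#' where `x` is the condition indicator (0 = reference), `b_s` a random
#' per-guide effect and `u_{sc}` a random per-guide-by-condition interaction
#' effect (one draw per guide and condition, so condition labels enter the
#' covariance symmetrically). With several timepoints the fixed part extends
#' to \eqn{\alpha + \beta_1 x + \beta_2 t + \beta_3 x t}.
#'
#' A guide missing in more than half of the replicates of either condition is
#' dropped for that gene; genes left with fewer than 2 guides, or fewer than
#' 2 replicates in either condition, are excluded and reported.
#'
#' @param l Lethality tibble ([screen_lethality()]).
#' @param sheet Validated sample sheet.
#' @param timepoints `"last"` (default, single-timepoint model), `"all"`, or
#'   a character vector of timepoint labels to keep.
#' @param exclude_genes Genes to drop before modelling (e.g. control genes).
#' @param allow_single_guide Retain genes with a single guide. Their
#'   random effects are confounded with the residual and are constrained
#'   only by the pooled hyperpriors; such genes are recognizable by
#'   `n_guides == 1` in the output. Default `FALSE` (excluded).
#' @return A tibble with one row per retained gene (`gene`, `n_guides`,
#'   `n_obs`, `spec` list-column); attribute `exclusions` is a tibble of
#'   dropped genes with reasons, attribute `design` is `"single_timepoint"`
#'   or `"longitudinal"`.
#' @export
screen_gene_data <- function(l, sheet, timepoints = "last",
                             exclude_genes = character(),
                             allow_single_guide = FALSE) {
  smp <- sample_columns(l)
  ep <- sheet[sheet$timepoint != "T0" & sheet$sample %in% smp, , drop = FALSE]
  if (!nrow(ep)) stop("no endpoint samples shared by scores and sheet",
                      call. = FALSE)
  tps <- sort(unique(ep$timepoint))
  keep_tp <- if (identical(timepoints, "last")) {
    tps[length(tps)]
  } else if (identical(timepoints, "all")) {
    tps
  } else {
    missing_tp <- setdiff(timepoints, tps)
    if (length(missing_tp)) {
      stop("unknown timepoint(s): ", paste(missing_tp, collapse = ", "),
           call. = FALSE)
    }
    sort(unique(timepoints))
  }
  ep <- ep[ep$timepoint %in% keep_tp, , drop = FALSE]
  design <- if (length(keep_tp) > 1) "longitudinal" else "single_timepoint"
  reference <- attr(sheet, "reference")
  if (is.null(reference)) reference <- sort(unique(ep$condition))[1]

  long <- tidyr::pivot_longer(l[c("sgRNA", "gene", ep$sample)],
                              cols = dplyr::all_of(ep$sample),
                              names_to = "sample", values_to = "l")
  long <- dplyr::inner_join(long, ep[c("sample", "condition", "replicate",
                                       "timepoint")], by = "sample")
  long$x <- as.integer(long$condition != reference)
  tidx <- match(long$timepoint, keep_tp)
  long$tv <- if (length(keep_tp) > 1) (tidx - 1) / (length(keep_tp) - 1) else 0
  long <- long[!long$gene %in% exclude_genes, , drop = FALSE]

  # missing-value policy: drop a guide when >50% of either condition's
  # replicates are missing; then drop its remaining NA records.
  guide_ok <- long |>
    dplyr::group_by(.data$gene, .data$sgRNA, .data$x) |>
    dplyr::summarise(n_miss = sum(is.na(.data$l)), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::group_by(.data$gene, .data$sgRNA) |>
    dplyr::summarise(ok = all(.data$n_miss <= 0.5 * .data$n),
                     .groups = "drop")
  long <- long |>
    dplyr::inner_join(guide_ok, by = c("gene", "sgRNA")) |>
    dplyr::filter(.data$ok, !is.na(.data$l)) |>
    dplyr::select(-"ok")

  split_genes <- split(long, long$gene)
  all_genes <- unique(l$gene[!l$gene %in% exclude_genes])
  specs <- vector("list", length(split_genes))
  keep <- logical(length(split_genes))
  reasons <- character(0); dropped <- character(0)
  for (i in seq_along(split_genes)) {
    d <- split_genes[[i]]
    g <- d$gene[1]
    S <- length(unique(d$sgRNA))
    if (S < 2 && !allow_single_guide) {
      dropped <- c(dropped, g); reasons <- c(reasons, "fewer than 2 guides")
      next
    }
    n_rep <- vapply(split(d$replicate, d$x),
                    function(r) length(unique(r)), integer(1))
    if (length(n_rep) < 2 || any(n_rep < 2)) {
      dropped <- c(dropped, g)
      reasons <- c(reasons, "fewer than 2 replicates in a condition")
      next
    }
    specs[[i]] <- new_gene_spec(d, design)
    keep[i] <- TRUE
  }
  lost <- setdiff(all_genes, names(split_genes))
  if (length(lost)) {
    dropped <- c(dropped, lost)
    reasons <- c(reasons, rep("no usable observations", length(lost)))
  }
  specs <- specs[keep]
  out <- tibble::tibble(
    gene = purrr::map_chr(specs, "gene"),
    n_guides = purrr::map_int(specs, "S"),
    n_obs = purrr::map_int(specs, ~ length(.x$y)),
    spec = specs
  )
  attr(out, "exclusions") <- tibble::tibble(gene = dropped, reason = reasons)
  attr(out, "design") <- design
  attr(out, "timepoints") <- keep_tp
  out
}

# Build one gene's model spec: response, covariates, and the sufficient
# statistics for the fast (balanced) likelihood path.
new_gene_spec <- function(d, design) {
  # canonical condition-block order (label-free): the block with the larger
  # response total is placed second. Swapping the condition labels of the
  # input then produces a bitwise-identical spec, so Bayes factors are
  # exactly invariant; reported condition effects are sign-corrected via
  # `flip`.
  flip <- sum(d$l[d$x == 1]) < sum(d$l[d$x == 0])
  if (flip) d$x <- 1L - d$x
  ord <- order(d$sgRNA, d$x, d$tv, d$replicate)
  d <- d[ord, , drop = FALSE]
  guides <- unique(d$sgRNA)
  S <- length(guides)
  cell_id <- paste(d$x, d$tv, d$replicate)
  first <- !duplicated(cell_id)
  cells <- data.frame(x = d$x[first], tv = d$tv[first],
                      replicate = d$replicate[first], key = cell_id[first])
  cells <- cells[order(cells$x, cells$tv, cells$replicate), , drop = FALSE]
  m <- nrow(cells)
  gi <- match(d$sgRNA, guides)
  ci <- match(cell_id, cells$key)
  balanced <- nrow(d) == S * m && !anyDuplicated(gi + S * (ci - 1L))
  spec <- list(
    gene = d$gene[1], S = S, y = d$l,
    guide = gi,
    x = d$x, tv = d$tv, replicate = d$replicate,
    design = design, balanced = balanced, flip = flip
  )
  if (balanced) {
    Y <- matrix(NA_real_, S, m)          # rows guides, columns cells
    Y[cbind(gi, ci)] <- d$l
    ybar <- colMeans(Y)
    dev <- sweep(Y, 2, ybar)
    spec$ybar <- matrix(ybar, ncol = 1)
    spec$Wc <- crossprod(dev)          # sum over guides of outer(dev, dev)
    spec$cells <- cells[c("x", "tv", "replicate")]
    spec$m <- m
  }
  class(spec) <- "gene_spec"
  spec
}

# Fixed-effect design columns at cell level (fast path) or observation
# level. The condition covariate is centred to +-1/2 so that swapping the
# condition labels leaves the marginalized covariance exactly invariant
# (beta keeps its meaning as the between-condition difference; the
# intercept becomes the mid-point mean and is mapped back when reported).
fixed_effect_columns <- function(x, tv, design, hypothesis, test) {
  xc <- x - 0.5
  f <- list(intercept = rep(1, length(x)))
  if (design == "longitudinal") {
    f$condition <- xc
    f$time <- tv
    f$interaction <- xc * tv
    drop <- if (test == "interaction") "interaction" else "condition"
  } else {
    f$condition <- xc
    drop <- "condition"
  }
  if (hypothesis == "H0") f[[drop]] <- NULL
  f
}

# Prior covariance contribution of the fixed effects (their Gaussian priors
# marginalized into the response covariance).
fixed_prior_matrix <- function(fcols, hp) {
  v <- vapply(names(fcols), function(nm)
    if (nm == "intercept") hp$v_alpha else hp$v_beta, numeric(1))
  M <- matrix(0, length(fcols[[1]]), length(fcols[[1]]))
  for (k in seq_along(fcols)) {
    M <- M + v[k] * tcrossprod(fcols[[k]])
  }
  M
}

# Random-effect + noise covariance at observation level (dense path).
random_covariance <- function(spec, theta, hp) {
  n <- length(spec$y)
  Lb <- hp$corr_b; Lu <- hp$corr_u
  # pooled correlations only apply to genes with the modal guide count
  if (!is.null(Lb) && spec$S > nrow(Lb)) Lb <- NULL
  if (!is.null(Lu) && spec$S > nrow(Lu)) Lu <- NULL
  same_b <- if (is.null(Lb)) {
    outer(spec$guide, spec$guide, `==`) * 1
  } else {
    Lb[spec$guide, spec$guide]
  }
  same_u <- if (is.null(Lu)) {
    outer(spec$guide, spec$guide, `==`) * 1
  } else {
    Lu[spec$guide, spec$guide]
  }
  same_cond <- outer(spec$x, spec$x, `==`) * 1
  theta[1] * diag(n) + theta[2] * same_b +
    theta[3] * same_u * same_cond
}

# log N(y; 0, V) for the gene, exact in the Gaussian effects given theta.
# Fast path uses the guide-exchangeable structure V = I_S (x) A + J_S (x) C.
gene_loglik <- function(spec, theta, hp, hypothesis,
                        test = "condition") {
  if (spec$balanced && is.null(hp$corr_b) && is.null(hp$corr_u)) {
    m <- spec$m; S <- spec$S
    cx <- spec$cells$x; ct <- spec$cells$tv
    A <- theta[1] * diag(m) + theta[2] +
      theta[3] * (outer(cx, cx, `==`) * 1)
    fc <- fixed_effect_columns(cx, ct, spec$design, hypothesis, test)
    Cm <- fixed_prior_matrix(fc, hp)
    B <- A + S * Cm
    cA <- tryCatch(chol(A), error = function(e) NULL)
    cB <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(cA) || is.null(cB)) return(-Inf)
    ldA <- 2 * sum(log(diag(cA)))
    ldB <- 2 * sum(log(diag(cB)))
    qA <- sum(chol2inv(cA) * spec$Wc)
    z <- backsolve(cB, spec$ybar, transpose = TRUE)
    qB <- S * sum(z^2)
    n <- S * m
    -0.5 * (n * log(2 * pi) + (S - 1) * ldA + ldB + qA + qB)
  } else {
    V <- random_covariance(spec, theta, hp)
    fc <- fixed_effect_columns(spec$x, spec$tv, spec$design, hypothesis, test)
    V <- V + fixed_prior_matrix(fc, hp)
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(-Inf)
    z <- backsolve(cV, spec$y, transpose = TRUE)
    -0.5 * (length(spec$y) * log(2 * pi) + 2 * sum(log(diag(cV))) +
              sum(z^2))
  }
}

# Unnormalized log-posterior of phi = log(theta) under the log-normal
# hyperpriors (includes the Jacobian through the normal density in phi).
# Reference implementation; the optimizer uses the precomputed closure from
# make_neg_logpost(), which must agree with this.
phi_log_posterior <- function(phi, spec, hp, hypothesis, test) {
  if (any(phi < -40) || any(phi > 15)) return(-Inf)
  ll <- gene_loglik(spec, exp(phi), hp, hypothesis, test)
  if (!is.finite(ll)) return(-Inf)
  ll +
    stats::dnorm(phi[1], hp$sigma2[1], hp$sigma2[2], log = TRUE) +
    stats::dnorm(phi[2], hp$tau_b2[1], hp$tau_b2[2], log = TRUE) +
    stats::dnorm(phi[3], hp$tau_u2[1], hp$tau_u2[2], log = TRUE)
}

# Factory for the negative log-posterior of phi = log(theta): precomputes
# every matrix that does not depend on theta so the optimizer's objective is
# cheap. For positive theta the balanced-path matrices are always positive
# definite, so no factorization guard is needed there.
make_neg_logpost <- function(spec, hp, hypothesis, test) {
  mu <- c(hp$sigma2[1], hp$tau_b2[1], hp$tau_u2[1])
  sdv <- c(hp$sigma2[2], hp$tau_b2[2], hp$tau_u2[2])
  prior_cst <- sum(log(sdv)) + 1.5 * log(2 * pi)
  if (spec$balanced && is.null(hp$corr_b) && is.null(hp$corr_u)) {
    m <- spec$m; S <- spec$S; n <- S * m
    H <- outer(spec$cells$x, spec$cells$x, `==`) * 1
    fc <- fixed_effect_columns(spec$cells$x, spec$cells$tv, spec$design,
                               hypothesis, test)
    Cs <- S * fixed_prior_matrix(fc, hp)
    Wc <- spec$Wc; ybar <- spec$ybar
    didx <- seq(1L, m * m, by = m + 1L)
    cst <- 0.5 * n * log(2 * pi)
    function(phi) {
      if (any(phi < -40) || any(phi > 15)) return(1e10)
      th <- exp(phi)
      A <- th[2] + th[3] * H
      A[didx] <- A[didx] + th[1]
      B <- A + Cs
      cA <- chol(A)
      cB <- chol(B)
      qA <- sum(chol2inv(cA) * Wc)
      z <- backsolve(cB, ybar, transpose = TRUE)
      d <- (phi - mu) / sdv
      cst + (S - 1) * sum(log(diag(cA))) + sum(log(diag(cB))) +
        0.5 * (qA + S * sum(z * z)) + prior_cst + 0.5 * sum(d * d)
    }
  } else {
    cb <- hp$corr_b; cu <- hp$corr_u
    if (!is.null(cb) && spec$S > nrow(cb)) cb <- NULL
    if (!is.null(cu) && spec$S > nrow(cu)) cu <- NULL
    same_b <- if (is.null(cb)) {
      outer(spec$guide, spec$guide, `==`) * 1
    } else cb[spec$guide, spec$guide]
    same_u0 <- if (is.null(cu)) {
      outer(spec$guide, spec$guide, `==`) * 1
    } else cu[spec$guide, spec$guide]
    same_u <- same_u0 * (outer(spec$x, spec$x, `==`) * 1)
    fcols <- fixed_effect_columns(spec$x, spec$tv, spec$design, hypothesis,
                                  test)
    Cf <- fixed_prior_matrix(fcols, hp)
    y <- spec$y; n <- length(y)
    didx <- seq(1L, n * n, by = n + 1L)
    cst <- 0.5 * n * log(2 * pi)
    function(phi) {
      if (any(phi < -40) || any(phi > 15)) return(1e10)
      th <- exp(phi)
      V <- th[2] * same_b + th[3] * same_u + Cf
      V[didx] <- V[didx] + th[1]
      cV <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(cV)) return(1e10)
      z <- backsolve(cV, y, transpose = TRUE)
      d <- (phi - mu) / sdv
      cst + sum(log(diag(cV))) + 0.5 * sum(z * z) +
        prior_cst + 0.5 * sum(d * d)
    }
  }
}

# Central-difference gradient and Hessian. The step is taken fairly large
# (0.02 on the log-variance scale): second differences amplify rounding
# noise by 4*eps/h^2, which matters in nearly flat directions of the
# posterior, while the O(h^2) truncation bias stays well below the accuracy
# of the Laplace approximation itself.
fd_grad_hessian <- function(f, x, h = 2e-2) {
  d <- length(x)
  g <- numeric(d)
  H <- matrix(0, d, d)
  fp <- numeric(d); fm <- numeric(d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- h
    fp[i] <- f(x + ei); fm[i] <- f(x - ei)
    g[i] <- (fp[i] - fm[i]) / (2 * h)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
  }
  for (i in seq_len(d - 1)) for (j in (i + 1):d) {
    ei <- numeric(d); ei[i] <- h
    ej <- numeric(d); ej[j] <- h
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
         f(x - ei - ej)) / (4 * h^2)
  }
  list(value = f0, grad = g, hessian = H)
}

# Posterior mode of phi: Nelder-Mead from the hyperprior median, then a
# small Newton polish on the same objective. Returns the Hessian at the
# final point for reuse by the Laplace correction.
phi_posterior_mode <- function(neg, start, tol = 1e-8) {
  opt <- stats::optim(start, neg, method = "Nelder-Mead",
                      control = list(reltol = tol, maxit = 500))
  phi <- opt$par; val <- opt$value
  fd <- fd_grad_hessian(neg, phi)
  for (i in 1:3) {
    step <- tryCatch(solve(fd$hessian, fd$grad), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cand <- phi - step
    vc <- neg(cand)
    if (is.finite(vc) && vc < val) {
      phi <- cand; val <- vc
      # a sub-1e-6 step leaves the Hessian unchanged to working accuracy
      if (max(abs(step)) < 1e-6) break
      fd <- fd_grad_hessian(neg, phi)
    } else break
  }
  list(phi = phi, value = -val, hessian = fd$hessian)
}

#' Marginal log-likelihood of one gene under H0 or Ha
#'
#' Computes \eqn{\log \int p(y \mid \alpha,\beta,b,u,\theta)\,
#' p(\alpha)p(\beta)p(b,u\mid\theta)p(\theta)\, d(\cdot)}. The Gaussian
#' integrals over the intercept, the condition effect(s) and the random
#' effects are exact given the variance components \eqn{\theta = (\sigma^2,
#' \tau_b^2, \tau_u^2)}; the \eqn{\theta} integral uses a Laplace
#' approximation on \eqn{\log\theta} at its posterior mode (or a plug-in at
#' the mode with `theta_integration = "plugin"`). Under H0 the tested fixed
#' effect is removed. Deterministic: identical inputs give identical output.
#'
#' @param spec A gene spec from [screen_gene_data()]'s `spec` column.
#' @param hyper Hyperparameters from [screen_hyperparameters()].
#' @param hypothesis `"H0"` or `"Ha"`.
#' @param theta_integration `"laplace"` (default) or `"plugin"`.
#' @param test For the longitudinal model, which fixed effect is under test:
#'   `"condition"` (default) or `"interaction"`.
#' @param start Optional start value for the mode search (internal reuse).
#' @return A scalar log marginal likelihood; attribute `phi_mode` carries the
#'   posterior mode of \eqn{\log\theta}.
#' @export
gene_marginal_loglik <- function(spec, hyper,
                                 hypothesis = c("Ha", "H0"),
                                 theta_integration = c("laplace", "plugin"),
                                 test = c("condition", "interaction"),
                                 start = NULL) {
  hypothesis <- match.arg(hypothesis)
  theta_integration <- match.arg(theta_integration)
  test <- match.arg(test)
  if (stats::var(spec$y) < 1e-14) {
    stop("degenerate fit for gene ", spec$gene,
         ": all responses identical", call. = FALSE)
  }
  neg <- make_neg_logpost(spec, hyper, hypothesis, test)
  if (is.null(start)) {
    start <- c(hyper$sigma2[1], hyper$tau_b2[1], hyper$tau_u2[1])
  }
  mode <- phi_posterior_mode(neg, start, tol = hyper$laplace_tolerance)
  if (theta_integration == "plugin") {
    out <- gene_loglik(spec, exp(mode$phi), hyper, hypothesis, test)
  } else {
    ev <- eigen(mode$hessian, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 1e-8)   # guard against flat directions at the mode
    out <- mode$value + 1.5 * log(2 * pi) - 0.5 * sum(log(ev))
  }
  attr(out, "phi_mode") <- mode$phi
  out
}

#' Fit the mixed model for one gene under both hypotheses
#'
#' Returns the Bayes factor for the tested effect together with posterior
#' summaries of the fixed effects at the Ha variance-component mode.
#'
#' @inheritParams gene_marginal_loglik
#' @return A list of class `gene_fit`: `gene`, `n_guides`, `alpha_hat`,
#'   `beta_hat` (posterior mean of the tested effect; for the longitudinal
#'   model also `beta_time`, `beta_interaction`), `beta_se`, variance
#'   component posterior modes, `logml_h0`, `logml_ha`, `log_bf`.
#' @export
fit_gene <- function(spec, hyper,
                     theta_integration = c("laplace", "plugin"),
                     test = c("condition", "interaction")) {
  theta_integration <- match.arg(theta_integration)
  test <- match.arg(test)
  ml0 <- gene_marginal_loglik(spec, hyper, "H0",
                              theta_integration = theta_integration,
                              test = test)
  mla <- gene_marginal_loglik(spec, hyper, "Ha",
                              theta_integration = theta_integration,
                              test = test, start = attr(ml0, "phi_mode"))
  theta <- exp(attr(mla, "phi_mode"))
  post <- fixed_effect_posterior(spec, theta, hyper, test)
  sgn <- if (isTRUE(spec$flip)) -1 else 1   # undo canonical block order
  b_cond <- sgn * post$mean[[if (spec$design == "longitudinal") "condition"
                             else post$tested]]
  fit <- list(
    gene = spec$gene, n_guides = spec$S,
    # map the mid-point intercept back to the reference-condition mean
    alpha_hat = post$mean[["intercept"]] - 0.5 * b_cond,
    beta_hat = sgn * post$mean[[post$tested]],
    beta_se = post$se[[post$tested]],
    sigma2 = theta[1], tau_b2 = theta[2], tau_u2 = theta[3],
    logml_h0 = as.numeric(ml0), logml_ha = as.numeric(mla),
    log_bf = as.numeric(mla) - as.numeric(ml0)
  )
  if (spec$design == "longitudinal") {
    fit$beta_condition <- b_cond
    fit$beta_time <- post$mean[["time"]]
    fit$beta_interaction <- sgn * post$mean[["interaction"]]
  }
  class(fit) <- "gene_fit"
  fit
}

# Posterior of the fixed effects given theta (ridge-type GLS with the
# Gaussian priors as penalty).
fixed_effect_posterior <- function(spec, theta, hp, test = "condition") {
  Vre <- random_covariance(spec, theta, hp)
  fc <- fixed_effect_columns(spec$x, spec$tv, spec$design, "Ha", test)
  Fm <- do.call(cbind, fc)
  pv <- vapply(names(fc), function(nm)
    if (nm == "intercept") hp$v_alpha else hp$v_beta, numeric(1))
  cV <- chol(Vre)
  Wy <- backsolve(cV, spec$y, transpose = TRUE)
  WF <- backsolve(cV, Fm, transpose = TRUE)
  Prec <- crossprod(WF) + diag(1 / pv, ncol(Fm))
  Sig <- solve(Prec)
  mu <- drop(Sig %*% crossprod(WF, Wy))
  tested <- if (spec$design == "longitudinal" && test == "interaction")
    "interaction" else "condition"
  list(mean = stats::setNames(as.list(mu), names(fc)),
       se = stats::setNames(as.list(sqrt(diag(Sig))), names(fc)),
       tested = tested)
}

#' Estimate shrinkage hyperparameters across genes
#'
#' Two-stage empirical Bayes. Stage 1 computes, per gene, cheap moment-based
#' point estimates of the condition contrast, its standard error and the
#' variance components (these coincide with REML on the balanced designs the
#' simulator produces). Stage 2 pools them: the prior variance of the tested
#' effect is the uncentred second moment of the contrasts minus the mean
#' squared standard error (floored at `v_floor`), and each variance component
#' gets a log-normal hyperprior moment-matched to the across-gene
#' distribution of its log point estimate.
#'
#' @param gene_data Output of [screen_gene_data()].
#' @param v_floor Floor for the prior variance of the tested effect.
#' @param covariance `"diagonal"` (default): independent per-guide random
#'   effects. `"unstructured"`: a single correlation matrix per random
#'   effect, pooled across genes with the same guide count, with per-gene
#'   scale.
#' @return A list of class `eb_hyper`: `v_beta`, `v_alpha`, log-normal
#'   (meanlog, sdlog) pairs `sigma2`, `tau_b2`, `tau_u2`, `pi0_init`,
#'   `laplace_tolerance`, and optional pooled correlation matrices.
#' @export
screen_hyperparameters <- function(gene_data, v_floor = 1e-4,
                                   covariance = c("diagonal",
                                                  "unstructured")) {
  covariance <- match.arg(covariance)
  G <- nrow(gene_data)
  if (G < 10) stop("need at least 10 usable genes", call. = FALSE)
  if (G < 50) warning("fewer than 50 genes: hyperparameters may be unstable")
  st <- gene_moment_fits(gene_data$spec)
  beta <- st$beta_hat; se2 <- st$se2
  s2 <- st$sigma2; tb2 <- st$tau_b2; tu2 <- st$tau_u2
  ok <- is.finite(beta) & is.finite(se2)
  v_beta <- max(mean(beta[ok]^2) - mean(se2[ok]), v_floor)
  yvar <- stats::var(unlist(purrr::map(gene_data$spec, "y")))
  floor_c <- 0.01 * stats::median(s2, na.rm = TRUE)
  lognormal_fit <- function(v) {
    lv <- log(pmax(v[is.finite(v)], floor_c))
    c(mean(lv), max(stats::sd(lv), 0.25))
  }
  hp <- list(
    v_beta = v_beta,
    v_alpha = 1e3 * yvar,
    sigma2 = lognormal_fit(s2),
    tau_b2 = lognormal_fit(tb2),
    tau_u2 = lognormal_fit(tu2),
    pi0_init = 0.9,
    v_floor = v_floor,
    laplace_tolerance = 1e-8,
    corr_b = NULL, corr_u = NULL
  )
  if (covariance == "unstructured") {
    pooled <- pooled_guide_correlations(gene_data$spec)
    hp$corr_b <- pooled$corr_b
    hp$corr_u <- pooled$corr_u
  }
  class(hp) <- "eb_hyper"
  hp
}

# Moment-based point fits for all genes at once (stage 1 of the empirical
# Bayes). On the balanced designs produced by the generator these coincide
# with ANOVA/REML estimators.
gene_moment_fits <- function(specs) {
  long <- tibble::tibble(
    gene = rep(purrr::map_chr(specs, "gene"),
               purrr::map_int(specs, ~ length(.x$y))),
    guide = unlist(purrr::map(specs, "guide")),
    x = unlist(purrr::map(specs, "x")),
    tv = unlist(purrr::map(specs, "tv")),
    y = unlist(purrr::map(specs, "y"))
  )
  cellstats <- long |>
    dplyr::group_by(.data$gene, .data$guide, .data$x, .data$tv) |>
    dplyr::summarise(m = mean(.data$y), v = stats::var(.data$y),
                     n = dplyr::n(), .groups = "drop")
  per_guide <- cellstats |>
    dplyr::group_by(.data$gene, .data$guide) |>
    dplyr::summarise(
      d = mean(.data$m[.data$x == 1]) - mean(.data$m[.data$x == 0]),
      gm = mean(.data$m),
      n1 = sum(.data$n[.data$x == 1]), n0 = sum(.data$n[.data$x == 0]),
      .groups = "drop")
  sig <- cellstats |>
    dplyr::filter(.data$n > 1) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(sigma2 = sum(.data$v * (.data$n - 1)) /
                       sum(.data$n - 1), .groups = "drop")
  per_gene <- per_guide |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      beta_hat = mean(.data$d), var_d = stats::var(.data$d),
      S = dplyr::n(),
      inv_cond = mean(1 / .data$n1 + 1 / .data$n0),
      inv_tot = mean(1 / (.data$n1 + .data$n0)),
      w = mean(.data$n1 / (.data$n1 + .data$n0)),
      var_g = stats::var(.data$gm),
      .groups = "drop") |>
    dplyr::left_join(sig, by = "gene")
  per_gene$se2 <- per_gene$var_d / per_gene$S
  per_gene$tau_u2 <- pmax((per_gene$var_d -
                             per_gene$sigma2 * per_gene$inv_cond) / 2, 0)
  per_gene$tau_b2 <- pmax(per_gene$var_g - per_gene$tau_u2 / 2 -
                            per_gene$sigma2 * per_gene$inv_tot, 0)
  # restore spec order
  per_gene[match(purrr::map_chr(specs, "gene"), per_gene$gene), ,
           drop = FALSE]
}

# Pooled across-gene correlation of per-guide summaries, used by the
# unstructured covariance option. Guides are taken in their within-gene
# order; only genes with the modal guide count contribute.
pooled_guide_correlations <- function(specs) {
  Ss <- purrr::map_int(specs, "S")
  S <- as.integer(names(which.max(table(Ss))))
  use <- specs[Ss == S]
  gm <- matrix(NA_real_, length(use), S)
  dm <- matrix(NA_real_, length(use), S)
  for (i in seq_along(use)) {
    sp <- use[[i]]
    for (s in seq_len(S)) {
      ys <- sp$y[sp$guide == s]
      xs <- sp$x[sp$guide == s]
      gm[i, s] <- mean(ys)
      dm[i, s] <- mean(ys[xs == 1]) - mean(ys[xs == 0])
    }
  }
  shrink_corr <- function(M) {
    cc <- stats::cor(M, use = "pairwise.complete.obs")
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    # ridge toward identity to keep the matrix positive definite
    cc <- 0.9 * cc + 0.1 * diag(S)
    cc
  }
  list(corr_b = shrink_corr(gm), corr_u = shrink_corr(dm))
}

#' Fit the per-gene empirical-Bayes mixed model across a screen
#'
#' Runs [fit_gene()] for every retained gene, then converts Bayes factors to
#' local false discovery rates with the two-group model and calls hits.
#'
#' @param gene_data Output of [screen_gene_data()].
#' @param hyper Optional hyperparameters; estimated with
#'   [screen_hyperparameters()] when `NULL`.
#' @param lfdr_threshold Hit threshold on the lfdr (strict `<`), default 0.05.
#' @param pi0 `"em"` (two-group EM estimate) or a fixed value in (0, 1].
#' @inheritParams gene_marginal_loglik
#' @inheritParams screen_hyperparameters
#' @return A tibble of class `eb_screen_fit` with one row per gene: `gene`,
#'   `n_guides`, `beta_hat`, `beta_se`, `sigma2`, `tau_b2`, `tau_u2`,
#'   `logml_h0`, `logml_ha`, `log_bf`, `lfdr`, `hit`. Attributes: `hyper`,
#'   `pi0`, `exclusions`, `options`.
#' @export
eb_fit <- function(gene_data, hyper = NULL,
                   lfdr_threshold = 0.05, pi0 = "em",
                   theta_integration = c("laplace", "plugin"),
                   test = c("condition", "interaction"),
                   covariance = c("diagonal", "unstructured"),
                   v_floor = 1e-4) {
  theta_integration <- match.arg(theta_integration)
  test <- match.arg(test)
  covariance <- match.arg(covariance)
  if (is.null(hyper)) {
    hyper <- screen_hyperparameters(gene_data, v_floor = v_floor,
                                    covariance = covariance)
  }
  fits <- purrr::map(gene_data$spec, fit_gene, hyper = hyper,
                     theta_integration = theta_integration, test = test)
  res <- tibble::tibble(
    gene = purrr::map_chr(fits, "gene"),
    n_guides = purrr::map_int(fits, "n_guides"),
    alpha_hat = purrr::map_dbl(fits, "alpha_hat"),
    beta_hat = purrr::map_dbl(fits, "beta_hat"),
    beta_se = purrr::map_dbl(fits, "beta_se"),
    sigma2 = purrr::map_dbl(fits, "sigma2"),
    tau_b2 = purrr::map_dbl(fits, "tau_b2"),
    tau_u2 = purrr::map_dbl(fits, "tau_u2"),
    logml_h0 = purrr::map_dbl(fits, "logml_h0"),
    logml_ha = purrr::map_dbl(fits, "logml_ha"),
    log_bf = purrr::map_dbl(fits, "log_bf")
  )
  pi0_used <- if (identical(pi0, "em")) {
    estimate_pi0(res$log_bf, pi0_init = hyper$pi0_init)
  } else {
    stopifnot(is.numeric(pi0), pi0 > 0, pi0 <= 1)
    pi0
  }
  lf <- compute_lfdr(res$log_bf, pi0_used)
  res$lfdr <- lf$lfdr
  res$hit <- res$lfdr < lfdr_threshold
  res <- res[order(res$lfdr, res$gene), , drop = FALSE]
  class(res) <- c("eb_screen_fit", class(res))
  attr(res, "hyper") <- hyper
  attr(res, "pi0") <- pi0_used
  attr(res, "exclusions") <- attr(gene_data, "exclusions")
  attr(res, "options") <- list(lfdr_threshold = lfdr_threshold,
                               theta_integration = theta_integration,
                               test = test, covariance = covariance,
                               design = attr(gene_data, "design"))
  res
}
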