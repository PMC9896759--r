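# Shared fixtures and the independent brute-force oracle.

# Build a single-gene model spec directly from a response vector.
# Layout: guides x (condition 0 replicates, condition 1 replicates).
mk_gene_spec <- function(S, R, y, gene = "g", design = "single_timepoint",
                         tv = 0) {
  d <- data.frame(gene = gene,
                  sgRNA = rep(sprintf("s%02d", seq_len(S)), each = 2 * R),
                  x = rep(rep(0:1, each = R), S),
                  tv = tv,
                  replicate = rep(rep(seq_len(R), 2), S),
                  l = y)
  ebcrispr:::new_gene_spec(d, design)
}

# Hyperparameters constructed directly (log-normal (meanlog, sdlog) pairs).
mk_hyper <- function(v_beta = 0.05, v_alpha = 100,
                     sigma2 = c(log(0.02), 0.5),
                     tau_b2 = c(log(0.005), 0.5),
                     tau_u2 = c(log(0.005), 0.5)) {
  structure(list(v_beta = v_beta, v_alpha = v_alpha, sigma2 = sigma2,
                 tau_b2 = tau_b2, tau_u2 = tau_u2, pi0_init = 0.9,
                 v_floor = 1e-4, laplace_tolerance = 1e-8,
                 corr_b = NULL, corr_u = NULL),
            class = "eb_hyper")
}

# Independent oracle: log marginal likelihood by dense Simpson integration
# over the three log variance components. The covariance is assembled by
# naive elementwise loops, independently of the package's likelihood code.
oracle_logml <- function(spec, hp, hypothesis, npts = 25, span = 6) {
  n <- length(spec$y)
  Gb <- matrix(0, n, n); Gu <- matrix(0, n, n); Cf <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (spec$guide[i] == spec$guide[j]) Gb[i, j] <- 1
    if (spec$guide[i] == spec$guide[j] && spec$x[i] == spec$x[j]) {
      Gu[i, j] <- 1
    }
    Cf[i, j] <- hp$v_alpha
    if (hypothesis == "Ha") {
      Cf[i, j] <- Cf[i, j] +
        hp$v_beta * (spec$x[i] - 0.5) * (spec$x[j] - 0.5)
    }
  }
  I_n <- diag(n)
  mus <- c(hp$sigma2[1], hp$tau_b2[1], hp$tau_u2[1])
  sds <- c(hp$sigma2[2], hp$tau_b2[2], hp$tau_u2[2])
  gr <- lapply(1:3, function(k) {
    seq(mus[k] - span * sds[k], mus[k] + span * sds[k], length.out = npts)
  })
  sw <- c(1, rep(c(4, 2), length.out = npts - 2)[1:(npts - 2)], 1)
  h <- vapply(gr, function(g) g[2] - g[1], 0)
  lw3 <- log(outer(outer(sw, sw), sw)) + sum(log(h / 3))
  lv <- array(NA_real_, c(npts, npts, npts))
  for (a in 1:npts) for (b in 1:npts) for (cc in 1:npts) {
    phi <- c(gr[[1]][a], gr[[2]][b], gr[[3]][cc])
    th <- exp(phi)
    V <- th[1] * I_n + th[2] * Gb + th[3] * Gu + Cf
    cV <- chol(V)
    z <- backsolve(cV, spec$y, transpose = TRUE)
    lv[a, b, cc] <- -0.5 * n * log(2 * pi) - sum(log(diag(cV))) -
      0.5 * sum(z^2) + sum(stats::dnorm(phi, mus, sds, log = TRUE))
  }
  lv <- lv + lw3
  M <- max(lv)
  M + log(sum(exp(lv - M)))
}

# Memoized small simulated screens so several tests can share one.
.fixtures <- new.env(parent = emptyenv())
cached_screen <- function(key, ...) {
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- simulate_screen(sim_config(...))
  }
  .fixtures[[key]]
}
small_screen <- function() {
  cached_screen("small", G = 60, n_effect = 10, delta = 0.5,
                n_pos = 40, n_neg = 40, seed = 301)
}
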