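#' Configuration for the synthetic-screen generator
#'
#' Defaults reproduce the benchmark study conditions: 1000 library genes with
#' 4 guides each, 3 replicates per condition, the first 100 genes carrying a
#' condition effect of size `delta`, replicate noise `sigma = 0.1`, mean
#' transduction fold `f = 400`, and 400 positive plus 400 negative control
#' guides with mean lethality 0.8 and 0.1 and noise 0.05.
#'
#' @param G Number of library genes.
#' @param S_g Guides per gene.
#' @param R Replicates per condition.
#' @param n_effect Number of genes (the first ones) carrying the effect.
#' @param delta Mean difference in lethality between conditions for effect
#'   genes, on the fold-change scale.
#' @param sigma Between-replicate standard deviation of fold changes.
#' @param f Mean transduction fold (average initial cells per guide).
#' @param design `"independent"` (per-condition T0) or `"paired"` (shared T0).
#' @param n_pos,n_neg Number of positive / negative control guides.
#' @param control_means Mean lethality of positive and negative controls.
#' @param control_sigma Replicate noise of the control guides.
#' @param seed Master seed; each generator step draws from its own
#'   deterministic substream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(G = 1000, S_g = 4, R = 3, n_effect = 100, delta = 0,
                       sigma = 0.1, f = 400,
                       design = c("independent", "paired"),
                       n_pos = 400, n_neg = 400,
                       control_means = c(positive = 0.8, negative = 0.1),
                       control_sigma = 0.05, seed = 1) {
  design <- match.arg(design)
  stopifnot(G >= 1, S_g >= 1, R >= 1, n_effect <= G, n_effect >= 0,
            delta >= 0, sigma >= 0, f > 0, n_pos >= 0, n_neg >= 0,
            control_sigma >= 0)
  structure(list(G = G, S_g = S_g, R = R, n_effect = n_effect, delta = delta,
                 sigma = sigma, f = f, design = design, n_pos = n_pos,
                 n_neg = n_neg, control_means = control_means,
                 control_sigma = control_sigma, seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic per-step substreams: changing the number of draws in one
# step must not shift another step's draws.
with_step_seed <- function(seed, step, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) %% 2013265920L) + 7919L * step)
  force(code)
}

#' Per-gene mean lethality in both conditions
#'
#' Draws the reference-condition gene lethalities from a Gamma(shape 1,
#' scale 1) distribution and rescales them to `[0, 1]` by dividing by the
#' maximum; condition 2 adds `delta` for the first `n_effect` genes.
#'
#' @param config A [sim_config()].
#' @return Tibble `gene`, `z1`, `z2`, `is_effect`.
#' @export
simulate_gene_effects <- function(config) {
  z1 <- with_step_seed(config$seed, 1L, stats::rgamma(config$G, 1, 1))
  z1 <- z1 / max(z1)
  z2 <- z1
  if (config$n_effect > 0) {
    z2[seq_len(config$n_effect)] <- z1[seq_len(config$n_effect)] +
      config$delta
  }
  tibble::tibble(
    gene = sprintf("gene%04d", seq_len(config$G)),
    z1 = z1, z2 = z2,
    is_effect = seq_len(config$G) <= config$n_effect & config$delta > 0
  )
}

#' Guide-level true fold changes
#'
#' Every guide of a gene inherits the gene's mean lethality; observed fold
#' changes per replicate and condition are independent Gaussian draws around
#' it with standard deviation `sigma`.
#'
#' @param z Matrix (guides x 2) of per-guide mean lethality in condition 1/2.
#' @param config A [sim_config()].
#' @param R Replicates; defaults to `config$R`.
#' @param sigma Noise; defaults to `config$sigma`.
#' @param step Substream index (internal).
#' @return Matrix `L` of size guides x (2R); columns are condition 1
#'   replicates then condition 2 replicates.
#' @export
simulate_fold_changes <- function(z, config, R = config$R,
                                  sigma = config$sigma, step = 2L) {
  S <- nrow(z)
  with_step_seed(config$seed, step, {
    L <- matrix(NA_real_, S, 2 * R)
    for (c in 1:2) for (r in seq_len(R)) {
      L[, (c - 1) * R + r] <- stats::rnorm(S, z[, c], sigma)
    }
    colnames(L) <- paste0("c", rep(1:2, each = R), "_r", rep(seq_len(R), 2))
    L
  })
}

#' Initial (T=0) guide counts
#'
#' Counts are `trunc(f * lambda)` with transduction efficiency
#' `lambda ~ U(0.05, 1.95)`; under the paired design the two conditions of a
#' replicate share the same lambda (one transduction split into two arms).
#'
#' @param S Number of guides.
#' @inheritParams simulate_fold_changes
#' @return Integer matrix `C0` of size S x (2R), columns as in
#'   [simulate_fold_changes()].
#' @export
simulate_initial_counts <- function(S, config, R = config$R, step = 3L) {
  with_step_seed(config$seed, step, {
    if (config$design == "paired") {
      lam <- matrix(stats::runif(S * R, 0.05, 1.95), S, R)
      lam <- cbind(lam, lam)
    } else {
      lam <- matrix(stats::runif(S * 2 * R, 0.05, 1.95), S, 2 * R)
    }
    C0 <- trunc(config$f * lam)
    colnames(C0) <- paste0("c", rep(1:2, each = R), "_r", rep(seq_len(R), 2))
    C0
  })
}

#' Endpoint counts from initial counts and fold changes
#'
#' `M = C0 - C0 * L` elementwise, i.e. the initial population reduced by the
#' fraction lost. Entries are rounded to the nearest integer and clamped at
#' 0 (noise can push the simulated fold change above 1).
#'
#' @param C0 Initial count matrix.
#' @param L Fold-change matrix of the same shape.
#' @return Integer matrix `M`.
#' @export
compute_endpoint_counts <- function(C0, L) {
  stopifnot(all(dim(C0) == dim(L)))
  M <- round(C0 * (1 - L))
  M[M < 0] <- 0
  M
}

#' Simulate a complete synthetic screen
#'
#' Composes the generator steps (gene effects, guide fold changes, initial
#' counts, endpoint counts) for the library and for the control guides, and
#' packages the result as a count tibble plus sample sheet, control set and
#' per-gene truth labels. Control guides are grouped four per synthetic
#' control gene so they flow through gene-level code unchanged; their mean
#' lethality is identical in both conditions.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_screen`: `counts` (tibble, T0 and endpoint
#'   columns), `sheet` (sample sheet), `controls` (control set), `truth`
#'   (tibble `gene`, `is_effect` for library genes), and `latent` (the
#'   generator's intermediate matrices, for white-box checks).
#' @export
simulate_screen <- function(config = sim_config()) {
  eff <- simulate_gene_effects(config)
  S_lib <- config$G * config$S_g
  z_lib <- cbind(rep(eff$z1, each = config$S_g),
                 rep(eff$z2, each = config$S_g))
  L_lib <- simulate_fold_changes(z_lib, config, step = 2L)
  C0_lib <- simulate_initial_counts(S_lib, config, step = 3L)

  n_ctrl <- config$n_pos + config$n_neg
  z_ctrl <- cbind(rep(config$control_means[c("positive", "negative")],
                      c(config$n_pos, config$n_neg)))
  z_ctrl <- cbind(z_ctrl, z_ctrl)
  L_ctrl <- simulate_fold_changes(z_ctrl, config,
                                  sigma = config$control_sigma, step = 4L)
  C0_ctrl <- simulate_initial_counts(n_ctrl, config, step = 5L)

  L <- rbind(L_lib, L_ctrl)
  C0 <- rbind(C0_lib, C0_ctrl)
  M <- compute_endpoint_counts(C0, L)

  guides_per_ctrl_gene <- 4L
  pos_genes <- sprintf("pos_ctrl%03d",
                       ceiling(seq_len(config$n_pos) / guides_per_ctrl_gene))
  neg_genes <- sprintf("neg_ctrl%03d",
                       ceiling(seq_len(config$n_neg) / guides_per_ctrl_gene))
  gene <- c(rep(eff$gene, each = config$S_g), pos_genes, neg_genes)
  sgRNA <- paste0(gene, "_g",
                  c(rep(seq_len(config$S_g), config$G),
                    seq_len(config$n_pos) %% guides_per_ctrl_gene + 1L,
                    seq_len(config$n_neg) %% guides_per_ctrl_gene + 1L))
  sgRNA <- make.unique(sgRNA, sep = "_")

  R <- config$R
  arm <- paste0("c", rep(1:2, each = R), "_r", rep(seq_len(R), 2))
  t0_cols <- if (config$design == "paired") {
    paste0("r", seq_len(R), "_T0")[match(rep(seq_len(R), 2),
                                         seq_len(R))]
  } else {
    paste0(arm, "_T0")
  }
  ep_cols <- paste0(arm, "_T1")
  t0_unique <- unique(t0_cols)
  T0 <- C0[, !duplicated(t0_cols), drop = FALSE]
  colnames(T0) <- t0_unique
  colnames(M) <- ep_cols

  counts <- dplyr::bind_cols(
    tibble::tibble(sgRNA = sgRNA, gene = gene),
    tibble::as_tibble(T0), tibble::as_tibble(M)
  )
  sheet <- dplyr::bind_rows(
    tibble::tibble(sample = t0_unique,
                   condition = if (config$design == "paired") "shared"
                               else rep(c("cond1", "cond2"), each = R),
                   replicate = if (config$design == "paired") seq_len(R)
                               else rep(seq_len(R), 2),
                   timepoint = "T0", t0_partner = NA_character_),
    tibble::tibble(sample = ep_cols,
                   condition = rep(c("cond1", "cond2"), each = R),
                   replicate = rep(seq_len(R), 2),
                   timepoint = "T1", t0_partner = t0_cols)
  )
  sheet <- validate_sample_sheet(sheet, design = config$design,
                                 reference = "cond1")
  controls <- control_set(unique(pos_genes), unique(neg_genes))
  out <- list(
    counts = validate_counts(counts),
    sheet = sheet,
    controls = controls,
    truth = eff[c("gene", "is_effect")],
    latent = list(z = eff, L = L, C0 = C0, M = M),
    config = config
  )
  class(out) <- "sim_screen"
  out
}

#' Write a simulated screen to disk
#'
#' Writes the count TSV, sample sheet, positive/negative control gene lists
#' and the per-gene truth table into a directory.
#'
#' @param screen A `sim_screen` from [simulate_screen()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_screen <- function(screen, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_screen_counts(screen$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(screen$sheet, file.path(dir, "samples.tsv"),
                   progress = FALSE)
  ctrl <- screen$controls
  writeLines(ctrl$gene[ctrl$class == "positive"],
             file.path(dir, "positive_controls.txt"))
  writeLines(ctrl$gene[ctrl$class == "negative"],
             file.path(dir, "negative_controls.txt"))
  readr::write_tsv(screen$truth, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}
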