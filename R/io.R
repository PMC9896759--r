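#' Read a guide-level count matrix
#'
#' Reads a MAGeCK-style tab-delimited count file: a header row, a guide
#' identifier column, a gene column, and one numeric column per sample.
#' Comma-delimited files are tolerated via `delim = ","`.
#'
#' @param path Path to a delimited text file whose first two columns are the
#'   sgRNA identifier and the gene symbol, followed by one column of
#'   non-negative integer counts per sample.
#' @param delim Field delimiter, `"\t"` by default.
#' @return A tibble with columns `sgRNA`, `gene`, then one column per sample.
#' @export
read_screen_counts <- function(path, delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 3) {
    stop("count file must have at least 3 columns (sgRNA, gene, >=1 sample)",
         call. = FALSE)
  }
  nm <- names(raw)
  smp_nm <- nm[-(1:2)]
  if (any(nm == "") || any(grepl("^\\.\\.\\.[0-9]+$", nm)) ||
      all(!is.na(suppressWarnings(as.numeric(smp_nm))))) {
    stop("count file is missing a header row", call. = FALSE)
  }
  names(raw)[1:2] <- c("sgRNA", "gene")
  raw$sgRNA <- as.character(raw$sgRNA)
  raw$gene <- as.character(raw$gene)
  validate_counts(raw)
}

#' Validate a count tibble
#'
#' Checks the invariants of the guide-by-sample count table: unique guide
#' identifiers, a single gene per guide, and non-negative integral counts.
#'
#' @param counts A data frame with columns `sgRNA`, `gene` and sample columns.
#' @return The validated tibble (invisibly the same data).
#' @export
validate_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("sgRNA", "gene") %in% names(counts)))
  if (anyDuplicated(counts$sgRNA)) {
    dup <- counts$sgRNA[duplicated(counts$sgRNA)][1]
    stop("duplicate guide id in count table: ", dup, call. = FALSE)
  }
  smp <- sample_columns(counts)
  if (length(smp) < 1) stop("count table has no sample columns", call. = FALSE)
  m <- as.matrix(counts[smp])
  if (!is.numeric(m)) stop("sample columns must be numeric", call. = FALSE)
  if (anyNA(m)) stop("missing values in counts", call. = FALSE)
  if (any(m < 0)) stop("negative counts are not allowed", call. = FALSE)
  if (any(abs(m - round(m)) > 1e-8)) {
    stop("counts must be integral", call. = FALSE)
  }
  counts
}

#' Sample column names of a guide-level table
#'
#' @param x A counts / fold-change / lethality tibble.
#' @return Character vector of sample column names (everything except
#'   `sgRNA` and `gene`).
#' @export
sample_columns <- function(x) {
  setdiff(names(x), c("sgRNA", "gene"))
}

#' Write a count tibble to a MAGeCK-style TSV
#'
#' @param counts Validated count tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_screen_counts <- function(counts, path) {
  readr::write_tsv(validate_counts(counts), path, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' The sample sheet assigns each sequenced sample a condition, a replicate
#' label, a timepoint and (for non-T0 samples) the identifier of its matched
#' T=0 sample. Under the paired design the treated and untreated arms of a
#' replicate share one T0 sample; under the independent design each
#' condition/replicate pair has its own T0 sample.
#'
#' @param path Tab-delimited file with header
#'   `sample condition replicate timepoint t0_partner`.
#' @param design `"paired"` or `"independent"`.
#' @param reference Reference condition level; defaults to the first condition
#'   level appearing in the sheet.
#' @return A tibble with one row per sample; the design and the reference
#'   condition are stored in attributes `design` and `reference`.
#' @export
read_sample_sheet <- function(path, design = c("independent", "paired"),
                              reference = NULL) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                           show_col_types = FALSE)
  validate_sample_sheet(sheet, design = design, reference = reference)
}

#' Validate a sample sheet
#'
#' @param sheet Data frame with columns `sample`, `condition`, `replicate`,
#'   `timepoint`, `t0_partner`.
#' @inheritParams read_sample_sheet
#' @return The validated tibble with `design` and `reference` attributes.
#' @export
validate_sample_sheet <- function(sheet, design = c("independent", "paired"),
                                  reference = NULL) {
  design <- match.arg(design)
  sheet <- tibble::as_tibble(sheet)
  need <- c("sample", "condition", "replicate", "timepoint", "t0_partner")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) {
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sheet$sample <- as.character(sheet$sample)
  sheet$condition <- as.character(sheet$condition)
  sheet$timepoint <- as.character(sheet$timepoint)
  sheet$t0_partner <- as.character(sheet$t0_partner)
  if (anyDuplicated(sheet$sample)) {
    stop("duplicate sample id in sample sheet", call. = FALSE)
  }
  is_t0 <- sheet$timepoint == "T0"
  partner <- sheet$t0_partner[!is_t0]
  if (anyNA(partner) || any(partner == "")) {
    stop("every non-T0 sample must name a t0_partner", call. = FALSE)
  }
  dangling <- setdiff(partner, sheet$sample[is_t0])
  if (length(dangling)) {
    stop("t0_partner not present as a T0 sample: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  # paired: the two conditions of a replicate must share one T0 column;
  # independent: each condition/replicate has its own T0 column.
  ep <- sheet[!is_t0, , drop = FALSE]
  per_rep <- split(ep, list(ep$replicate, ep$timepoint), drop = TRUE)
  for (blk in per_rep) {
    if (length(unique(blk$condition)) < 2) next
    shared <- length(unique(blk$t0_partner)) == 1
    if (design == "paired" && !shared) {
      stop("paired design requires the conditions of a replicate to share ",
           "one T0 partner", call. = FALSE)
    }
    if (design == "independent" && shared) {
      stop("independent design requires per-condition T0 partners",
           call. = FALSE)
    }
  }
  lev <- unique(sheet$condition[!is_t0])
  if (is.null(reference)) reference <- lev[1]
  if (!reference %in% lev) {
    stop("reference condition '", reference, "' not found in sheet",
         call. = FALSE)
  }
  attr(sheet, "design") <- design
  attr(sheet, "reference") <- reference
  sheet
}

#' Read a control gene list
#'
#' @param path Text file with one gene symbol per line.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  unique(x[x != ""])
}

#' Assemble a control set
#'
#' Positive controls are guides targeting known essential genes (expected
#' lethal on knockout); negative controls target non-essential genes. The two
#' sets anchor the lethality-score scale at 1 and 0 respectively.
#'
#' @param positive,negative Character vectors of gene symbols.
#' @return A tibble with columns `gene` and `class` (`"positive"`/`"negative"`).
#' @export
control_set <- function(positive, negative) {
  positive <- unique(as.character(positive))
  negative <- unique(as.character(negative))
  both <- intersect(positive, negative)
  if (length(both)) {
    stop("gene(s) in both control sets: ", paste(both, collapse = ", "),
         call. = FALSE)
  }
  if (!length(positive) || !length(negative)) {
    stop("both control sets must be non-empty", call. = FALSE)
  }
  dplyr::bind_rows(
    tibble::tibble(gene = positive, class = "positive"),
    tibble::tibble(gene = negative, class = "negative")
  )
}

#' Write a per-gene results table
#'
#' Rows are ordered by ascending lfdr, ties broken alphabetically by gene;
#' numeric columns are written in scientific notation with 6 significant
#' digits.
#'
#' @param results Tibble with columns `gene`, `n_guides`, `beta_hat`,
#'   `log_bf`, `lfdr`, `hit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  need <- c("gene", "n_guides", "beta_hat", "log_bf", "lfdr", "hit")
  miss <- setdiff(need, names(results))
  if (length(miss)) {
    stop("results table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(results$lfdr < 0 | results$lfdr > 1, na.rm = TRUE)) {
    stop("lfdr must lie in [0, 1]", call. = FALSE)
  }
  out <- results[need]
  out <- out[order(out$lfdr, out$gene), , drop = FALSE]
  fmt <- function(v) formatC(v, format = "e", digits = 5)
  lines <- c(
    paste(need, collapse = "\t"),
    paste(out$gene, out$n_guides, fmt(out$beta_hat), fmt(out$log_bf),
          fmt(out$lfdr), as.integer(out$hit), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path Path to a results TSV.
#' @return Tibble with the standard results columns.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, col_types = "cidddl", progress = FALSE,
                  show_col_types = FALSE)
}
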