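#' Cycle-threshold tables
#'
#' A `ct_tbl` is a long-format tibble of raw qPCR cycle-threshold (Ct) values
#' with one row per (sample, gene) pair and columns `sample`, `gene`, `ct`,
#' plus any per-sample annotation columns (typically `group` for the treatment
#' arm and `location` for the tissue sampling site). Undetected reactions are
#' stored as `NA` — never imputed with the maximum cycle number, because
#' downstream stability statistics assume complete matrices and silently
#' inflated Ct values would bias every standard deviation they rest on.
#'
#' `as_ct_tbl()` coerces a data frame in either layout:
#' \describe{
#'   \item{wide}{one row per sample; a `sample` column (or the first column)
#'     holds identifiers and every other column is one gene.}
#'   \item{long}{columns `sample`, `gene`, `ct` and optionally `replicate`;
#'     technical replicates of the same (sample, gene) are collapsed to their
#'     arithmetic mean (Ct is already a log-scale quantity).}
#' }
#'
#' @param x A data frame in wide or long layout.
#' @param layout `"auto"` (default), `"wide"` or `"long"`. Auto-detection
#'   treats any table with both `gene` and `ct` columns as long.
#' @param annotations Optional data frame with columns `sample`, `group`,
#'   `location` (extra columns are carried along). Every sample in `x` must
#'   be annotated.
#' @return A `ct_tbl` tibble with columns `sample`, `gene`, `ct` and any
#'   annotation columns.
#' @examples
#' wide <- data.frame(sample = c("s1", "s2"), GAPDH = c(27.1, 27.5),
#'                    ACTB = c(26.0, 26.4))
#' as_ct_tbl(wide)
#' @export
as_ct_tbl <- function(x, layout = c("auto", "wide", "long"), annotations = NULL) {
  layout <- match.arg(layout)
  if (inherits(x, "ct_tbl") && is.null(annotations)) {
    return(validate_ct_tbl(x))
  }
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0 || ncol(x) == 0) {
    abort("Ct table is empty.")
  }
  if (layout == "auto") {
    layout <- if (all(c("gene", "ct") %in% names(x))) "long" else "wide"
  }

  if (layout == "wide") {
    nm <- names(x)
    if (!"sample" %in% nm) names(x)[1] <- "sample"
    gene_cols <- setdiff(names(x), "sample")
    if (length(gene_cols) == 0) abort("Wide Ct table has no gene columns.")
    if (anyDuplicated(x$sample)) {
      abort("Duplicate sample identifiers in wide Ct table.")
    }
    if (anyDuplicated(gene_cols)) {
      abort("Duplicate gene columns in wide Ct table.")
    }
    n_set_missing <- 0
    for (g in gene_cols) {
      parsed <- parse_ct_values(x[[g]])
      x[[g]] <- parsed$values
      n_set_missing <- n_set_missing + parsed$n_set_missing
    }
    warn_set_missing(n_set_missing)
    long <- tidyr::pivot_longer(x, -"sample", names_to = "gene",
                                values_to = "ct")
    long$sample <- as.character(long$sample)
  } else {
    missing_cols <- setdiff(c("sample", "gene", "ct"), names(x))
    if (length(missing_cols)) {
      abort(paste0("Long Ct table is missing column(s): ",
                   paste(missing_cols, collapse = ", "), "."))
    }
    parsed <- parse_ct_values(x$ct)
    x$ct <- parsed$values
    warn_set_missing(parsed$n_set_missing)
    x$sample <- as.character(x$sample)
    x$gene <- as.character(x$gene)
    # collapse technical replicates to their arithmetic mean
    long <- dplyr::summarise(
      dplyr::group_by(x, .data$sample, .data$gene),
      ct = if (all(is.na(.data$ct))) NA_real_ else mean(.data$ct, na.rm = TRUE),
      .groups = "drop"
    )
    # preserve first-appearance order of samples and genes
    long <- dplyr::arrange(long,
                           match(.data$sample, unique(x$sample)),
                           match(.data$gene, unique(x$gene)))
  }

  if (!is.null(annotations)) {
    long <- join_annotations(long, annotations)
  }
  out <- tibble::new_tibble(long, class = "ct_tbl")
  validate_ct_tbl(out)
}

parse_ct_values <- function(ct) {
  n_set_missing <- 0
  if (is.numeric(ct)) {
    vals <- as.numeric(ct)
  } else {
    raw <- trimws(as.character(ct))
    sentinel <- raw %in% c("", "NA", "N/A", "Undetermined", "undetermined") | is.na(raw)
    vals <- suppressWarnings(as.numeric(raw))
    n_set_missing <- sum(sentinel | (!sentinel & is.na(vals)))
  }
  if (any(!is.na(vals) & (!is.finite(vals) | vals <= 0))) {
    abort("Ct values must be finite and > 0 (undetected reactions go in as NA).")
  }
  list(values = vals, n_set_missing = n_set_missing)
}

warn_set_missing <- function(n) {
  if (n > 0) {
    warn(sprintf("%d non-numeric Ct entr%s set to missing.",
                 n, if (n == 1) "y" else "ies"))
  }
}

join_annotations <- function(long, annotations) {
  ann <- tibble::as_tibble(annotations)
  if (!"sample" %in% names(ann)) names(ann)[1] <- "sample"
  ann$sample <- as.character(ann$sample)
  if (anyDuplicated(ann$sample)) {
    abort("Annotation table has duplicated sample identifiers.")
  }
  unannotated <- setdiff(unique(long$sample), ann$sample)
  if (length(unannotated)) {
    abort(paste0("No annotation for sample(s): ",
                 paste(utils::head(unannotated, 5), collapse = ", "), "."))
  }
  dplyr::left_join(long, ann, by = "sample")
}

validate_ct_tbl <- function(ct) {
  stopifnot(is.data.frame(ct))
  if (!all(c("sample", "gene", "ct") %in% names(ct))) {
    abort("A ct_tbl needs columns sample, gene and ct.")
  }
  if (anyDuplicated(ct[c("sample", "gene")])) {
    abort("Duplicate (sample, gene) pairs in Ct table.")
  }
  if (any(!is.na(ct$ct) & (!is.finite(ct$ct) | ct$ct <= 0))) {
    abort("Ct values must be finite and > 0.")
  }
  if (!inherits(ct, "ct_tbl")) {
    ct <- tibble::new_tibble(tibble::as_tibble(ct), class = "ct_tbl")
  }
  ct
}

#' @export
print.ct_tbl <- function(x, ...) {
  cat(sprintf("# Ct table: %d samples x %d genes (%d missing values)\n",
              dplyr::n_distinct(x$sample), dplyr::n_distinct(x$gene),
              sum(is.na(x$ct))))
  NextMethod()
}

ct_samples <- function(ct) unique(ct$sample)
ct_genes <- function(ct) unique(ct$gene)

# samples x genes numeric matrix in first-appearance order
ct_matrix <- function(ct) {
  samples <- ct_samples(ct)
  genes <- ct_genes(ct)
  m <- matrix(NA_real_, length(samples), length(genes),
              dimnames = list(samples, genes))
  m[cbind(match(ct$sample, samples), match(ct$gene, genes))] <- ct$ct
  m
}

# per-sample annotation columns as a one-row-per-sample tibble
ct_annotations <- function(ct) {
  extra <- setdiff(names(ct), c("gene", "ct"))
  dplyr::distinct(tibble::as_tibble(ct)[extra])
}

#' Read a Ct table from delimited text
#'
#' Reads CSV (`.csv`) or TSV (`.tsv`/`.txt`) tables in wide or long layout;
#' the delimiter is chosen from the file extension. Sentinel entries
#' (`"Undetermined"`, `"NA"`, empty cells) become missing values with a
#' warning. An optional annotation file (columns `sample,group,location`) is
#' joined; every sample must then be annotated.
#'
#' @param path Path to the Ct table.
#' @param layout `"auto"`, `"wide"` or `"long"` (see [as_ct_tbl()]).
#' @param annotations Optional path to an annotation CSV/TSV, or a data frame.
#' @return A `ct_tbl`.
#' @export
read_ct_table <- function(path, layout = c("auto", "wide", "long"),
                          annotations = NULL) {
  layout <- match.arg(layout)
  x <- read_delimited(path)
  if (is.character(annotations)) annotations <- read_delimited(annotations)
  as_ct_tbl(x, layout = layout, annotations = annotations)
}

read_delimited <- function(path) {
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, col_types = readr::cols(),
                    progress = FALSE, show_col_types = FALSE)
}

#' Write a Ct table to CSV
#'
#' Non-missing Ct values survive a write/read round trip bit-exactly in both
#' layouts (values are written with full precision).
#'
#' @param ct A `ct_tbl`.
#' @param path Output path (`.csv` or `.tsv`).
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  ct <- validate_ct_tbl(ct)
  out <- if (layout == "wide") {
    tidyr::pivot_wider(tibble::as_tibble(ct)[c("sample", "gene", "ct")],
                       names_from = "gene", values_from = "ct")
  } else {
    tibble::as_tibble(ct)
  }
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Restrict a Ct table to complete cases
#'
#' Keeps the requested genes and drops every sample that has at least one
#' missing Ct among them. All four stability algorithms require a complete
#' samples-by-genes matrix, so this is the canonical preprocessing step.
#'
#' @param ct A `ct_tbl`.
#' @param genes Character vector of genes to keep (default: all).
#' @return A `ct_tbl` containing only complete samples; the identifiers of
#'   removed samples are attached as attribute `"removed_samples"`.
#' @export
complete_cases <- function(ct, genes = NULL) {
  ct <- validate_ct_tbl(ct)
  genes <- genes %||% ct_genes(ct)
  unknown <- setdiff(genes, ct_genes(ct))
  if (length(unknown)) {
    abort(paste0("Unknown gene(s): ", paste(unknown, collapse = ", "), "."))
  }
  sub <- dplyr::filter(ct, .data$gene %in% genes)
  incomplete <- unique(sub$sample[is.na(sub$ct)])
  # a sample missing a gene row entirely is also incomplete
  counts <- table(sub$sample)
  incomplete <- union(incomplete, names(counts)[counts < length(genes)])
  out <- dplyr::filter(sub, !.data$sample %in% incomplete)
  n_samples <- dplyr::n_distinct(out$sample)
  if (n_samples < 3 || length(genes) < 2) {
    abort(sprintf(
      "Complete-case matrix too small (%d samples x %d genes); stability statistics need >= 3 samples and >= 2 genes.",
      n_samples, length(genes)))
  }
  out <- tibble::new_tibble(out, class = "ct_tbl")
  attr(out, "removed_samples") <- incomplete
  out
}

#' Per-gene descriptive summaries of Ct values
#'
#' Computes, per gene (optionally stratified by an annotation column such as
#' `location`), the number of non-missing samples, mean Ct, sample standard
#' deviation (n - 1 denominator) and coefficient of variation
#' (CV\% = 100 * SD / mean).
#'
#' @param ct A `ct_tbl`.
#' @param by Optional name of an annotation column to stratify by.
#' @return A tibble with columns `gene` (and the stratifier), `n`, `mean_ct`,
#'   `sd_ct`, `cv_pct`. Strata with fewer than 2 observations get `NA` SD/CV
#'   with a warning.
#' @export
summarize_ct <- function(ct, by = NULL) {
  ct <- validate_ct_tbl(ct)
  if (!is.null(by) && !by %in% names(ct)) {
    abort(paste0("No annotation column called '", by, "'."))
  }
  grouping <- c("gene", by)
  out <- dplyr::summarise(
    dplyr::group_by(ct, dplyr::across(dplyr::all_of(grouping))),
    n = sum(!is.na(.data$ct)),
    mean_ct = mean(.data$ct, na.rm = TRUE),
    sd_ct = if (sum(!is.na(.data$ct)) >= 2) stats::sd(.data$ct, na.rm = TRUE) else NA_real_,
    .groups = "drop"
  )
  out$cv_pct <- 100 * out$sd_ct / out$mean_ct
  if (anyNA(out$sd_ct)) {
    warn("Some strata have fewer than 2 observations; SD and CV reported as NA.")
  }
  out
}
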