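#' Comprehensive ranking by geometric mean of method ranks
#'
#' Aggregates the four stability methods (comparative delta-Ct, geNorm,
#' NormFinder, BestKeeper) into one ordering: each gene's comprehensive value
#' is the geometric mean of its four dense method ranks,
#' \eqn{(\prod_{m=1}^{4} r_m)^{1/4}} — always >= 1, and exactly 1 only for a
#' gene ranked first by every method. Final ranks are assigned by ascending
#' geometric mean; exact ties are broken by the delta-Ct statistic (when
#' available) and then by gene id, so the output is deterministic.
#'
#' @param results Either a list of the four [stability_result] objects (one
#'   per method, identical gene sets), or a data frame with a `gene` column
#'   and integer rank columns `delta_ct`, `genorm`, `normfinder`,
#'   `bestkeeper` (useful for aggregating ranks published without the
#'   underlying Ct data).
#' @return A `comprehensive_ranking` object; [tidy()] returns one row per
#'   gene with the four method ranks, the full-precision geometric mean
#'   (`geomean`; display rounding to 2 decimals is applied only in
#'   [rank_table()]) and `final_rank`.
#' @examples
#' comprehensive_ranking(
#'   data.frame(gene = "TOP1", delta_ct = 3, genorm = 1,
#'              normfinder = 3, bestkeeper = 4))
#' @export
comprehensive_ranking <- function(results) {
  methods <- c("delta_ct", "genorm", "normfinder", "bestkeeper")
  if (is.data.frame(results)) {
    df <- tibble::as_tibble(results)
    missing_cols <- setdiff(c("gene", methods), names(df))
    if (length(missing_cols)) {
      abort(paste0("Rank table is missing column(s): ",
                   paste(missing_cols, collapse = ", "), "."))
    }
    ranks <- df[methods]
    genes <- as.character(df$gene)
    tiebreak <- rep(NA_real_, length(genes))
  } else {
    if (!is.list(results) || !all(vapply(results, inherits, logical(1),
                                         "stability_result"))) {
      abort("results must be a list of stability_result objects or a rank data frame.")
    }
    got <- vapply(results, `[[`, character(1), "method")
    if (!setequal(got, methods) || length(got) != 4) {
      abort(paste0("Need exactly one result per method (",
                   paste(methods, collapse = ", "), "); got: ",
                   paste(got, collapse = ", "), "."))
    }
    results <- stats::setNames(results, got)[methods]
    gene_sets <- lapply(results, function(r) sort(r$per_gene$gene))
    if (!all(vapply(gene_sets, identical, logical(1), gene_sets[[1]]))) {
      abort("All four methods must cover the identical gene set.")
    }
    genes <- results$delta_ct$per_gene$gene
    ranks <- as.data.frame(lapply(results, function(r) {
      r$per_gene$rank[match(genes, r$per_gene$gene)]
    }))
    dstat <- results$delta_ct$per_gene$statistic
    tiebreak <- dstat[match(genes, results$delta_ct$per_gene$gene)]
  }
  if (any(as.matrix(ranks) < 1)) abort("Method ranks must be >= 1.")

  geomean <- apply(as.matrix(ranks), 1, geometric_mean)
  ord <- order(geomean, tiebreak, genes)
  final_rank <- integer(length(genes))
  final_rank[ord] <- seq_along(genes)
  per_gene <- tibble::tibble(
    gene = genes,
    delta_ct_rank = as.integer(ranks$delta_ct),
    genorm_rank = as.integer(ranks$genorm),
    normfinder_rank = as.integer(ranks$normfinder),
    bestkeeper_rank = as.integer(ranks$bestkeeper),
    geomean = geomean,
    final_rank = final_rank
  )
  structure(list(per_gene = per_gene), class = "comprehensive_ranking")
}

#' @export
print.comprehensive_ranking <- function(x, ...) {
  cat("Comprehensive reference-gene ranking (geometric mean of method ranks)\n")
  out <- dplyr::arrange(x$per_gene, .data$final_rank)
  out$geomean <- round(out$geomean, 2)
  print(out)
  invisible(x)
}

#' @rdname comprehensive_ranking
#' @param x A `comprehensive_ranking`.
#' @param ... Unused.
#' @export
tidy.comprehensive_ranking <- function(x, ...) {
  dplyr::arrange(x$per_gene, .data$final_rank)
}

#' @rdname comprehensive_ranking
#' @export
glance.comprehensive_ranking <- function(x, ...) {
  best <- x$per_gene$gene[x$per_gene$final_rank == 1]
  tibble::tibble(n_genes = nrow(x$per_gene), most_stable = best,
                 least_stable = x$per_gene$gene[
                   x$per_gene$final_rank == nrow(x$per_gene)])
}

#' Full stability report table
#'
#' One row per gene with, in the conventional reporting order, the
#' comprehensive geometric mean and rank followed by statistic/rank pairs for
#' comparative delta-Ct, geNorm, NormFinder and BestKeeper. Geometric means
#' are rounded to 2 decimals for display; all statistics keep full precision.
#'
#' @param results A list of the four [stability_result] objects.
#' @return A tibble with 12 columns.
#' @export
rank_table <- function(results) {
  comp <- comprehensive_ranking(results)
  results <- stats::setNames(results,
                             vapply(results, `[[`, character(1), "method"))
  stat_of <- function(method, genes) {
    pg <- results[[method]]$per_gene
    pg$statistic[match(genes, pg$gene)]
  }
  out <- tidy.comprehensive_ranking(comp)
  tibble::tibble(
    gene = out$gene,
    geomean_rank_value = round(out$geomean, 2),
    comprehensive_rank = out$final_rank,
    delta_ct_avg_sd = stat_of("delta_ct", out$gene),
    delta_ct_rank = out$delta_ct_rank,
    genorm_m = stat_of("genorm", out$gene),
    genorm_rank = out$genorm_rank,
    normfinder_stability = stat_of("normfinder", out$gene),
    normfinder_rank = out$normfinder_rank,
    bestkeeper_sd = stat_of("bestkeeper", out$gene),
    bestkeeper_rank = out$bestkeeper_rank
  )
}

#' Run all four stability methods on one cohort
#'
#' Convenience wrapper: complete-cases the Ct table, runs comparative
#' delta-Ct, geNorm, NormFinder and BestKeeper, and aggregates them.
#'
#' @param ct A `ct_tbl` (missing values are removed via [complete_cases()]).
#' @param efficiencies Optional named amplification factors for geNorm.
#' @param normfinder_mode `"ungrouped"` (default) or `"grouped"`.
#' @return A list with elements `results` (named list of four
#'   [stability_result]s), `comprehensive` (a [comprehensive_ranking]) and
#'   `table` (the [rank_table()] output).
#' @export
stability_suite <- function(ct, efficiencies = NULL,
                            normfinder_mode = "ungrouped") {
  cc <- complete_cases(as_ct_tbl(ct))
  results <- list(
    delta_ct_stability(cc),
    genorm(cc, efficiencies = efficiencies),
    normfinder(cc, mode = normfinder_mode),
    bestkeeper(cc)
  )
  names(results) <- vapply(results, `[[`, character(1), "method")
  list(results = results,
       comprehensive = comprehensive_ranking(results),
       table = rank_table(results))
}
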