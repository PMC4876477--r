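#' Stability results
#'
#' All four stability algorithms return a `stability_result`: the method
#' name, a per-gene tibble with the method's statistic (lower = more stable)
#' and dense ascending ranks (ties share a rank; the set of rank values is
#' always 1..k), and a method-specific `aux` payload. Use [tidy()] to get the
#' per-gene table and [glance()] for a one-row summary.
#'
#' @name stability_result
NULL

new_stability_result <- function(method, gene, statistic, aux = list(),
                                 n_samples, ranks = NULL) {
  per_gene <- tibble::tibble(gene = gene, statistic = statistic,
                             rank = ranks %||% dense_ranks(statistic))
  structure(list(method = method, per_gene = per_gene, aux = aux,
                 n_samples = n_samples),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Reference-gene stability (%s), %d genes, %d samples\n",
              x$method, nrow(x$per_gene), x$n_samples))
  print(dplyr::arrange(x$per_gene, .data$rank, .data$gene))
  invisible(x)
}

#' @rdname stability_result
#' @param x A `stability_result`.
#' @param ... Unused.
#' @export
tidy.stability_result <- function(x, ...) {
  dplyr::mutate(x$per_gene, method = x$method, .before = 1)
}

#' @rdname stability_result
#' @export
glance.stability_result <- function(x, ...) {
  best <- x$per_gene$gene[x$per_gene$rank == 1]
  tibble::tibble(method = x$method, n_genes = nrow(x$per_gene),
                 n_samples = x$n_samples,
                 best_genes = paste(sort(best), collapse = ","),
                 min_statistic = min(x$per_gene$statistic),
                 max_statistic = max(x$per_gene$statistic))
}

# Coerce input to a complete samples x genes matrix; the stability algorithms
# are undefined on matrices with holes, so missingness is a hard error here.
stability_matrix <- function(ct, min_genes = 2) {
  m <- if (is.matrix(ct)) ct else ct_matrix(validate_ct_tbl(as_ct_tbl(ct)))
  if (anyNA(m)) {
    abort("Ct matrix contains missing values; run complete_cases() first.")
  }
  if (nrow(m) < 3) abort("Stability statistics need >= 3 samples.")
  if (ncol(m) < min_genes) {
    abort(sprintf("Need >= %d genes.", min_genes))
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("g", seq_len(ncol(m)))
  m
}

#' Pairwise delta-Ct standard deviations
#'
#' For every gene pair (j, k), the sample SD (n - 1 denominator) over samples
#' of the per-sample Ct difference \eqn{Ct_j - Ct_k}. This is the building
#' block of the comparative delta-Ct method: a per-sample global shift (e.g.
#' different RNA input) cancels in the differences, so only genuine relative
#' instability contributes.
#'
#' @param ct A complete-case `ct_tbl`, wide data frame, or samples-by-genes
#'   matrix.
#' @return A symmetric genes-by-genes matrix of SDs with zero diagonal.
#' @export
pairwise_delta_ct_sd <- function(ct) {
  m <- stability_matrix(ct)
  g <- ncol(m)
  out <- matrix(0, g, g, dimnames = list(colnames(m), colnames(m)))
  for (j in seq_len(g - 1)) {
    for (k in (j + 1):g) {
      s <- stats::sd(m[, j] - m[, k])
      out[j, k] <- s
      out[k, j] <- s
    }
  }
  out
}

#' Comparative delta-Ct stability
#'
#' Ranks genes by the mean of their pairwise delta-Ct SDs against every other
#' candidate (the "average of SD" statistic). Lower = more stable.
#'
#' @inheritParams pairwise_delta_ct_sd
#' @return A [stability_result] with the pairwise SD matrix in
#'   `aux$pairwise_sd`.
#' @export
delta_ct_stability <- function(ct) {
  m <- stability_matrix(ct)
  pw <- pairwise_delta_ct_sd(m)
  stat <- rowSums(pw) / (ncol(pw) - 1)
  new_stability_result("delta_ct", colnames(m), unname(stat),
                       aux = list(pairwise_sd = pw), n_samples = nrow(m))
}

#' geNorm stability (M value with stepwise exclusion)
#'
#' Transforms Ct to relative quantities
#' \eqn{q_{sj} = A_j^{\min_s Ct_{sj} - Ct_{sj}}} (with \eqn{A_j} the gene's
#' amplification factor, default 2), computes for each gene pair the SD over
#' samples of \eqn{\log_2(q_{sj}/q_{sk})}, and defines a gene's M value as
#' its mean pairwise variation. The gene with the highest M is removed and M
#' recomputed, iterating until two genes remain; because of this elimination
#' the method ends with a best *pair*, both reported at rank 1 with the
#' final-step M. Every other gene's reported statistic is its M at the step
#' of its elimination, ranked 2, 3, ... in reverse elimination order.
#' With all amplification factors equal to 2, the first-round M equals the
#' comparative delta-Ct statistic exactly.
#'
#' @inheritParams pairwise_delta_ct_sd
#' @param efficiencies Optional named vector of per-gene amplification
#'   factors (e.g. from [standard_curve_table()]); defaults to 2 for all
#'   genes.
#' @return A [stability_result]; `aux` carries the elimination order, the
#'   per-step M tables, and the pairwise-variation values
#'   \eqn{V_{n/n+1}} of successive normalization factors (reported, not
#'   thresholded).
#' @export
genorm <- function(ct, efficiencies = NULL) {
  m <- stability_matrix(ct)
  genes <- colnames(m)
  amp <- rep(2, length(genes))
  names(amp) <- genes
  if (!is.null(efficiencies)) {
    if (is.null(names(efficiencies))) {
      abort("efficiencies must be a named vector of amplification factors.")
    }
    if (any(efficiencies <= 1)) abort("Amplification factors must be > 1.")
    amp[names(efficiencies)] <- efficiencies
  }
  # log2 relative quantities; the per-gene max-expression anchor (min Ct) is a
  # constant per gene and cancels in every SD, but matches the conventional
  # q-scale definition
  logq <- sapply(genes, function(g) {
    (min(m[, g]) - m[, g]) * log2(amp[[g]])
  })

  pair_v <- function(cols) {
    g <- length(cols)
    vm <- matrix(0, g, g, dimnames = list(cols, cols))
    for (j in seq_len(g - 1)) {
      for (k in (j + 1):g) {
        v <- stats::sd(logq[, cols[j]] - logq[, cols[k]])
        vm[j, k] <- v
        vm[k, j] <- v
      }
    }
    vm
  }
  m_values <- function(cols) {
    vm <- pair_v(cols)
    rowSums(vm) / (length(cols) - 1)
  }

  if (length(genes) < 3) {
    warn("geNorm with only 2 genes: no stepwise exclusion possible.")
    mv <- m_values(genes)
    return(new_stability_result(
      "genorm", genes, unname(mv),
      aux = list(elimination_order = character(),
                 steps = list(tibble::tibble(gene = genes, m = unname(mv))),
                 v_pairwise = numeric()),
      n_samples = nrow(m), ranks = c(1L, 1L)))
  }

  active <- genes
  eliminated <- character()
  stat <- stats::setNames(numeric(length(genes)), genes)
  steps <- list()
  nf_log2 <- list()  # per-step log2 normalization factor (mean of logq)
  while (length(active) > 2) {
    mv <- m_values(active)
    steps[[length(steps) + 1]] <- tibble::tibble(
      gene = active, m = unname(mv))
    nf_log2[[length(nf_log2) + 1]] <- rowMeans(logq[, active, drop = FALSE])
    worst <- active[which.max(mv)]  # ties: first in current column order
    stat[worst] <- mv[[worst]]
    eliminated <- c(eliminated, worst)
    active <- setdiff(active, worst)
  }
  mv <- m_values(active)
  steps[[length(steps) + 1]] <- tibble::tibble(gene = active, m = unname(mv))
  nf_log2[[length(nf_log2) + 1]] <- rowMeans(logq[, active, drop = FALSE])
  stat[active] <- mv  # final pair shares an identical M

  # V_{n/n+1}: SD of the difference of successive log2 normalization factors,
  # indexed from the full panel down to the final pair
  v_pair <- if (length(nf_log2) > 1) {
    vapply(seq_len(length(nf_log2) - 1), function(i) {
      stats::sd(nf_log2[[i]] - nf_log2[[i + 1]])
    }, numeric(1))
  } else {
    numeric()
  }

  # rank 1 for the final pair, then reverse elimination order; exact
  # statistic ties share a rank
  ordered <- c(active, rev(eliminated))
  ranks <- stats::setNames(integer(length(genes)), ordered)
  ranks[active] <- 1L
  r <- 1L
  prev_stat <- stat[[active[1]]]
  for (g in rev(eliminated)) {
    if (stat[[g]] != prev_stat) r <- r + 1L
    ranks[g] <- r
    prev_stat <- stat[[g]]
  }
  new_stability_result(
    "genorm", genes, unname(stat[genes]),
    aux = list(elimination_order = eliminated, steps = steps,
               v_pairwise = v_pair),
    n_samples = nrow(m), ranks = unname(ranks[genes]))
}

#' NormFinder stability (variance decomposition)
#'
#' Treats Ct as log-scale expression. Each sample is centred across genes
#' (removing shared loading effects), giving \eqn{d_{sj} = y_{sj} -
#' \bar{y}_{s\cdot}}. Because the centring mixes every gene's noise into
#' every \eqn{d_{sj}}, the observed per-gene variance
#' \eqn{v_j = Var_s(d_{sj})} relates to the true per-gene variances via
#' \eqn{E[v_j] = \sigma^2_j (g-2)/g + \sum_k \sigma^2_k / g^2} (g genes);
#' solving with \eqn{\sum\sigma^2 = g/(g-1) \sum v} gives
#' \eqn{\hat\sigma^2_j = g/(g-2) [v_j - \sum v / (g(g-1))]}, truncated at 0.
#' The ungrouped stability value is \eqn{\hat\sigma_j}.
#'
#' In grouped mode the same decomposition is applied within each group, and
#' the stability value combines inter-group shifts with intra-group noise:
#' \eqn{mean_g(|\hat\gamma_{jg}| + \sqrt{\hat\sigma^2_{jg}/m_g})}, where
#' \eqn{\hat\gamma_{jg}} is the group's centred mean deviation from the grand
#' mean and \eqn{m_g} the group size.
#'
#' @inheritParams pairwise_delta_ct_sd
#' @param groups Per-sample group labels (required for `mode = "grouped"`;
#'   taken from a `group` column when `ct` is an annotated `ct_tbl`).
#' @param mode `"ungrouped"` (default) or `"grouped"`.
#' @return A [stability_result]; `aux` holds the per-gene variance estimates
#'   and, in grouped mode, the per-group intra/inter components.
#' @export
normfinder <- function(ct, groups = NULL, mode = c("ungrouped", "grouped")) {
  mode <- match.arg(mode)
  if (is.null(groups) && is.data.frame(ct) && "group" %in% names(ct) &&
      mode == "grouped") {
    ann <- ct_annotations(validate_ct_tbl(as_ct_tbl(ct)))
    groups <- stats::setNames(ann$group, ann$sample)
  }
  m <- stability_matrix(ct, min_genes = 3)
  genes <- colnames(m)
  g <- length(genes)

  decompose <- function(mm) {
    d <- mm - rowMeans(mm)
    v <- apply(d, 2, stats::var)
    sum_sigma2 <- g / (g - 1) * sum(v)
    sigma2 <- g / (g - 2) * (v - sum(v) / (g * (g - 1)))
    list(d = d, v = v, sigma2 = pmax(sigma2, 0), sum_sigma2 = sum_sigma2)
  }

  if (mode == "ungrouped") {
    dec <- decompose(m)
    stat <- sqrt(dec$sigma2)
    return(new_stability_result(
      "normfinder", genes, unname(stat),
      aux = list(mode = "ungrouped", variance = dec$sigma2,
                 observed_variance = dec$v),
      n_samples = nrow(m)))
  }

  if (is.null(groups)) abort("Grouped NormFinder needs per-sample group labels.")
  groups <- if (!is.null(names(groups))) {
    unname(groups[rownames(m)])
  } else {
    as.character(groups)
  }
  if (length(groups) != nrow(m) || anyNA(groups)) {
    abort("groups must label every sample in the Ct matrix.")
  }
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 3)) {
    abort("Grouped NormFinder needs >= 2 groups with >= 3 samples each.")
  }
  d_all <- m - rowMeans(m)
  per_group <- lapply(split(seq_len(nrow(m)), groups), function(idx) {
    dec <- decompose(m[idx, , drop = FALSE])
    list(sigma2 = dec$sigma2, dbar = colMeans(d_all[idx, , drop = FALSE]),
         n = length(idx))
  })
  dbar_mat <- do.call(rbind, lapply(per_group, `[[`, "dbar"))
  gamma <- sweep(dbar_mat, 2, colMeans(dbar_mat))
  sigma2_mat <- do.call(rbind, lapply(per_group, `[[`, "sigma2"))
  sizes_vec <- vapply(per_group, `[[`, numeric(1), "n")
  per_gene_terms <- abs(gamma) + sqrt(sigma2_mat / sizes_vec)
  stat <- colMeans(per_gene_terms)
  new_stability_result(
    "normfinder", genes, unname(stat),
    aux = list(mode = "grouped", intergroup = gamma,
               intragroup_variance = sigma2_mat, group_sizes = sizes_vec),
    n_samples = nrow(m))
}

#' BestKeeper descriptive stability
#'
#' Computes per-gene descriptive statistics of the raw Ct values (geometric
#' and arithmetic mean, min, max, dispersion, CV\%), the per-sample
#' BestKeeper index (geometric mean of all candidates' Ct in that sample),
#' and each gene's Pearson correlation with the index. Genes are ranked by
#' their Ct dispersion — the sample SD by default, or the original
#' mean-absolute-deviation variant with `sd_variant = "mean_abs_dev"`. A
#' dispersion >= 1 cycle conventionally flags a gene as unstable. Note that
#' unlike the other three methods, BestKeeper's dispersion responds to
#' per-sample global shifts (loading differences), since it works on raw Ct
#' rather than Ct differences.
#'
#' @inheritParams pairwise_delta_ct_sd
#' @param sd_variant `"sample_sd"` (n - 1 denominator, default) or
#'   `"mean_abs_dev"` (mean absolute deviation from the arithmetic mean).
#' @return A [stability_result]; `aux` holds the descriptive table
#'   (`descriptives`), the per-sample index, and the unstable flags.
#' @export
bestkeeper <- function(ct, sd_variant = c("sample_sd", "mean_abs_dev")) {
  sd_variant <- match.arg(sd_variant)
  m <- stability_matrix(ct)
  if (any(m <= 0)) abort("BestKeeper needs strictly positive Ct values.")
  genes <- colnames(m)
  index <- apply(m, 1, geometric_mean)
  desc <- lapply(genes, function(g) {
    x <- m[, g]
    disp <- if (sd_variant == "sample_sd") stats::sd(x) else mean(abs(x - mean(x)))
    if (stats::sd(x) == 0 || stats::sd(index) == 0) {
      r <- NA_real_  # correlation undefined for a constant gene or index
      p <- NA_real_
    } else {
      test <- stats::cor.test(x, index, method = "pearson")
      r <- unname(test$estimate)
      p <- test$p.value
    }
    tibble::tibble(
      gene = g, n = length(x), geo_mean = geometric_mean(x),
      ar_mean = mean(x), min = min(x), max = max(x),
      dispersion = disp, cv_pct = 100 * disp / mean(x),
      r = r, p_value = p
    )
  })
  desc <- dplyr::bind_rows(desc)
  new_stability_result(
    "bestkeeper", genes, desc$dispersion,
    aux = list(descriptives = desc, index = index,
               sd_variant = sd_variant,
               unstable = stats::setNames(desc$dispersion >= 1, genes)),
    n_samples = nrow(m))
}
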