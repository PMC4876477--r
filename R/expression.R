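#' Relative expression by the 2^-ddCt method
#'
#' Computes per-sample \eqn{\Delta Ct = Ct_{goi} - Ct_{ref}} (with several
#' reference genes, \eqn{Ct_{ref}} is their arithmetic mean, i.e.
#' geometric-mean normalization on the quantity scale), centres on the
#' arithmetic mean \eqn{\Delta Ct} of the control group
#' (\eqn{\Delta\Delta Ct}), and reports fold change \eqn{2^{-\Delta\Delta
#' Ct}}. With `efficiencies` supplied, the gene of interest and reference
#' amplification factors replace the 2s (efficiency-corrected variant).
#' Group summaries are mean +/- SEM of the per-sample fold changes. By
#' construction the *geometric* mean fold change of the control group is
#' exactly 1.
#'
#' @param ct A `ct_tbl` with a group annotation column.
#' @param goi Gene of interest.
#' @param refs One or more reference genes (must not include `goi`).
#' @param control_group Label of the control group (e.g. `"NI"`).
#' @param group_col Name of the annotation column holding group labels.
#' @param efficiencies Optional named amplification factors (gene -> fold per
#'   cycle) for efficiency-corrected fold changes; default 2 for all genes.
#' @return An `expression_result` with `per_sample` (sample, group,
#'   delta_ct, delta_delta_ct, fold) and `per_group` (group, n, mean_fold,
#'   sem_fold) tibbles. Samples missing the gene of interest or any
#'   reference are dropped.
#' @export
delta_delta_ct <- function(ct, goi, refs, control_group, group_col = "group",
                           efficiencies = NULL) {
  ct <- validate_ct_tbl(as_ct_tbl(ct))
  if (goi %in% refs) {
    abort("The gene of interest cannot be one of its own reference genes.")
  }
  missing_genes <- setdiff(c(goi, refs), ct_genes(ct))
  if (length(missing_genes)) {
    abort(paste0("Gene(s) not in the Ct table: ",
                 paste(missing_genes, collapse = ", "), "."))
  }
  if (!group_col %in% names(ct)) {
    abort(paste0("No annotation column called '", group_col, "'."))
  }
  cc <- complete_cases(ct, genes = c(goi, refs))
  m <- ct_matrix(cc)
  ann <- ct_annotations(cc)
  grp <- ann[[group_col]][match(rownames(m), ann$sample)]

  amp_of <- function(g) {
    if (!is.null(efficiencies) && g %in% names(efficiencies)) {
      efficiencies[[g]]
    } else {
      2
    }
  }
  # work on the log2 quantity scale so efficiency correction is a per-gene
  # rescaling of Ct: log2 amount ~ -Ct * log2(A)
  log2_goi <- -m[, goi] * log2(amp_of(goi))
  log2_ref <- rowMeans(sapply(refs, function(g) -m[, g] * log2(amp_of(g))))
  neg_delta <- log2_goi - log2_ref            # -dCt when all A = 2
  control <- grp == control_group
  if (!any(control)) {
    abort(paste0("No complete samples in control group '", control_group, "'."))
  }
  neg_ddct <- neg_delta - mean(neg_delta[control])
  per_sample <- tibble::tibble(
    sample = rownames(m),
    group = grp,
    delta_ct = unname(-neg_delta),
    delta_delta_ct = unname(-neg_ddct),
    fold = unname(2^neg_ddct)
  )
  per_group <- dplyr::summarise(
    dplyr::group_by(per_sample, .data$group),
    n = dplyr::n(),
    mean_fold = mean(.data$fold),
    sem_fold = stats::sd(.data$fold) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  structure(
    list(per_sample = per_sample, per_group = per_group, goi = goi,
         refs = refs, control_group = control_group,
         degenerate = stats::var(per_sample$fold) == 0),
    class = "expression_result"
  )
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("2^-ddCt expression of %s vs %s, control group %s\n",
              x$goi, paste(x$refs, collapse = "+"), x$control_group))
  print(x$per_group)
  invisible(x)
}

#' @rdname delta_delta_ct
#' @param x An `expression_result`.
#' @param ... Unused.
#' @export
tidy.expression_result <- function(x, ...) x$per_sample

#' @rdname delta_delta_ct
#' @export
glance.expression_result <- function(x, ...) {
  dplyr::mutate(x$per_group, goi = x$goi,
                reference = paste(x$refs, collapse = "+"),
                control_group = x$control_group)
}

#' One-way ANOVA and control comparisons on relative expression
#'
#' Runs a one-way ANOVA F-test across treatment groups and pairwise
#' each-group-vs-control Welch t-tests with Holm adjustment, with
#' significance tiers at 0.05 / 0.01 / 0.001 for report asterisks. By
#' default the tests run on the fold changes (matching the conventional
#' mean +/- SEM presentation); `scale = "log"` tests the ddCt values
#' instead, which is statistically preferable since fold changes are
#' log-normal.
#'
#' @param result An `expression_result` from [delta_delta_ct()].
#' @param scale `"fold"` (default) or `"log"` (tests -ddCt).
#' @return An `expression_anova` object with `$anova` (one-row tibble:
#'   `f_statistic`, `df1`, `df2`, `p_value`, `degenerate`) and
#'   `$comparisons` (group vs control: `p_value`, `p_adj`, `stars`). When
#'   every fold change is identical (e.g. a gene normalized against itself)
#'   the ANOVA is degenerate and flagged rather than run.
#' @export
group_anova <- function(result, scale = c("fold", "log")) {
  stopifnot(inherits(result, "expression_result"))
  scale <- match.arg(scale)
  d <- result$per_sample
  d$y <- if (scale == "fold") d$fold else -d$delta_delta_ct
  sizes <- table(d$group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn(paste0("Group(s) with n < 2 excluded from ANOVA: ",
                paste(small, collapse = ", "), "."))
    d <- d[!d$group %in% small, ]
  }
  if (dplyr::n_distinct(d$group) < 2) {
    abort("ANOVA needs at least 2 groups with n >= 2.")
  }
  degenerate <- stats::var(d$y) == 0
  if (degenerate) {
    warn("All responses identical; ANOVA is degenerate.")
    anova_row <- tibble::tibble(f_statistic = NA_real_, df1 = NA_real_,
                                df2 = NA_real_, p_value = NA_real_,
                                degenerate = TRUE)
  } else {
    fit <- stats::aov(y ~ group, data = d)
    tab <- summary(fit)[[1]]
    anova_row <- tibble::tibble(
      f_statistic = tab[1, "F value"], df1 = tab[1, "Df"],
      df2 = tab[2, "Df"], p_value = tab[1, "Pr(>F)"], degenerate = FALSE)
  }
  ctrl <- d$y[d$group == result$control_group]
  others <- setdiff(unique(d$group), result$control_group)
  comparisons <- dplyr::bind_rows(lapply(others, function(g) {
    y <- d$y[d$group == g]
    p <- if (degenerate || (stats::var(y) == 0 && stats::var(ctrl) == 0)) {
      NA_real_
    } else {
      stats::t.test(y, ctrl)$p.value
    }
    tibble::tibble(group = g, vs = result$control_group,
                   mean_diff = mean(y) - mean(ctrl), p_value = p)
  }))
  comparisons$p_adj <- stats::p.adjust(comparisons$p_value, method = "holm")
  comparisons$stars <- stars_for(comparisons$p_adj)
  structure(list(anova = anova_row, comparisons = comparisons,
                 scale = scale),
            class = "expression_anova")
}

#' @export
print.expression_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA (%s scale): F(%s, %s) = %s, p = %s\n",
              x$scale, format(x$anova$df1), format(x$anova$df2),
              format(x$anova$f_statistic, digits = 4),
              format(x$anova$p_value, digits = 3)))
  print(x$comparisons)
  invisible(x)
}

#' @rdname group_anova
#' @param x An `expression_anova`.
#' @param ... Unused.
#' @export
tidy.expression_anova <- function(x, ...) x$comparisons

#' @rdname group_anova
#' @export
glance.expression_anova <- function(x, ...) x$anova

#' Compare a gene's Ct between tissue locations within each group
#'
#' For each treatment group, a two-sided Welch t-test of the gene's Ct values
#' between the two sampling locations, plus five-number summaries per arm for
#' box-plot style reporting. Groups where either location arm has fewer than
#' 2 non-missing values are skipped with a warning.
#'
#' @param ct A `ct_tbl` with `group` and `location` annotation columns.
#' @param gene Gene to compare.
#' @param group_col,location_col Annotation column names.
#' @return A `location_comparison` with `$tests` (group, n per arm, mean
#'   difference, t statistic, df, p_value) and `$summaries` (group,
#'   location, n, min, q25, median, q75, max).
#' @export
location_compare <- function(ct, gene, group_col = "group",
                             location_col = "location") {
  ct <- validate_ct_tbl(as_ct_tbl(ct))
  for (col in c(group_col, location_col)) {
    if (!col %in% names(ct)) {
      abort(paste0("No annotation column called '", col, "'."))
    }
  }
  if (!gene %in% ct_genes(ct)) abort(paste0("Unknown gene '", gene, "'."))
  d <- ct[ct$gene == gene & !is.na(ct$ct), ]
  locs <- unique(d[[location_col]])
  if (length(locs) != 2) {
    abort("location_compare needs exactly 2 locations present.")
  }
  summaries <- dplyr::summarise(
    dplyr::group_by(d, group = .data[[group_col]],
                    location = .data[[location_col]]),
    n = dplyr::n(), min = min(.data$ct),
    q25 = unname(stats::quantile(.data$ct, 0.25)),
    median = stats::median(.data$ct),
    q75 = unname(stats::quantile(.data$ct, 0.75)),
    max = max(.data$ct), .groups = "drop")
  tests <- dplyr::bind_rows(lapply(unique(d[[group_col]]), function(g) {
    a <- d$ct[d[[group_col]] == g & d[[location_col]] == locs[1]]
    b <- d$ct[d[[group_col]] == g & d[[location_col]] == locs[2]]
    if (length(a) < 2 || length(b) < 2) {
      warn(paste0("Group '", g, "' skipped: a location arm has n < 2."))
      return(NULL)
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      return(tibble::tibble(group = g, n_1 = length(a), n_2 = length(b),
                            mean_diff = 0, t_statistic = 0, df = NA_real_,
                            p_value = 1))
    }
    tt <- stats::t.test(a, b)
    tibble::tibble(group = g, n_1 = length(a), n_2 = length(b),
                   mean_diff = mean(a) - mean(b),
                   t_statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value)
  }))
  structure(list(gene = gene, locations = locs, tests = tests,
                 summaries = summaries),
            class = "location_comparison")
}

#' @export
print.location_comparison <- function(x, ...) {
  cat(sprintf("Ct of %s: %s vs %s (Welch t per group)\n",
              x$gene, x$locations[1], x$locations[2]))
  print(x$tests)
  invisible(x)
}

#' @rdname location_compare
#' @param x A `location_comparison`.
#' @param ... Unused.
#' @export
tidy.location_comparison <- function(x, ...) x$tests
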