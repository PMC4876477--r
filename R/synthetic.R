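#' Specify a synthetic Ct-data design
#'
#' A simulation design describes the generative model for a synthetic qPCR
#' experiment:
#' \deqn{Ct_{sg} = baseline_g + u_s + \sum shifts + \epsilon_{sg}}
#' where \eqn{u_s \sim N(0, sample\_effect\_sd^2)} is a per-sample loading
#' effect shared by all genes (RNA input / reverse-transcription yield — the
#' co-variation that makes genuinely stable genes move together), and
#' \eqn{\epsilon_{sg} \sim N(0, noise\_sd_g^2)} is per-gene measurement and
#' biological noise on the Ct (log) scale. `effects` inject deterministic
#' shifts for matching (gene, group, location) combinations; `"*"` matches
#' any group or location.
#'
#' @param genes Data frame with columns `gene`, `baseline_ct`, `noise_sd`.
#' @param groups Data frame with columns `group`, `n_per_location`.
#' @param locations Character vector of tissue locations.
#' @param sample_effect_sd SD (cycles) of the shared per-sample effect.
#' @param effects Data frame with columns `gene`, `group`, `location`,
#'   `shift` (cycles); `"*"` wildcards allowed. May be `NULL`.
#' @param censor_at Optional Ct above which values are censored to missing
#'   (off by default; realism knob, e.g. 45 cycles).
#' @param seed Default seed used by [simulate_ct()] when none is given.
#' @return A `simulation_design` object.
#' @export
simulation_design <- function(genes, groups, locations, sample_effect_sd = 0.5,
                              effects = NULL, censor_at = NULL, seed = 1L) {
  genes <- tibble::as_tibble(genes)
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("gene", "baseline_ct", "noise_sd") %in% names(genes)),
            all(c("group", "n_per_location") %in% names(groups)))
  if (anyDuplicated(genes$gene)) abort("Duplicate gene ids in design.")
  if (anyDuplicated(groups$group)) abort("Duplicate group ids in design.")
  if (any(genes$noise_sd < 0) || sample_effect_sd < 0) {
    abort("Noise SDs must be >= 0.")
  }
  if (any(groups$n_per_location < 1)) abort("Group sizes must be >= 1.")
  if (length(locations) < 1 || anyDuplicated(locations)) {
    abort("locations must be a non-empty set of unique labels.")
  }
  if (!is.null(effects)) {
    effects <- tibble::as_tibble(effects)
    stopifnot(all(c("gene", "group", "location", "shift") %in% names(effects)))
    bad_gene <- setdiff(effects$gene, c("*", genes$gene))
    if (length(bad_gene)) {
      abort(paste0("Effect references unknown gene(s): ",
                   paste(bad_gene, collapse = ", "), "."))
    }
  } else {
    effects <- tibble::tibble(gene = character(), group = character(),
                              location = character(), shift = numeric())
  }
  structure(
    list(genes = genes, groups = groups, locations = as.character(locations),
         sample_effect_sd = sample_effect_sd, effects = effects,
         censor_at = censor_at, seed = as.integer(seed)),
    class = "simulation_design"
  )
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf(
    "Simulation design: %d genes, %d groups x %d locations (n = %s per cell), sample effect SD %.2f, %d effect shift(s)\n",
    nrow(x$genes), nrow(x$groups), length(x$locations),
    paste(unique(x$groups$n_per_location), collapse = "/"),
    x$sample_effect_sd, nrow(x$effects)))
  invisible(x)
}

#' Default preterm-lamb lung design
#'
#' Five candidate reference genes at the baselines and per-gene noise SDs
#' observed in non-dependent lung tissue of the preterm-lamb ventilation
#' study (18S rRNA 12.36 +/- 1.139, GAPDH 27.42 +/- 1.170, ACTB 26.12 +/-
#' 1.858, TOP1 27.86 +/- 1.366, RPS29 37.19 +/- 1.641 cycles), six treatment
#' groups (NI control plus ventilation strategies V1-V5) crossed with two
#' tissue locations at n = 10 samples per cell, a shared per-sample loading
#' effect of SD 0.5 cycles, and a +1.78-cycle shift of RPS29 in
#' gravity-dependent tissue (38.97 - 37.19).
#'
#' @return A `simulation_design`.
#' @export
default_design <- function() {
  simulation_design(
    genes = tibble::tibble(
      gene        = c("18S", "GAPDH", "ACTB", "TOP1", "RPS29"),
      baseline_ct = c(12.36, 27.42, 26.12, 27.86, 37.19),
      noise_sd    = c(1.139, 1.170, 1.858, 1.366, 1.641)
    ),
    groups = tibble::tibble(
      group = c("NI", "V1", "V2", "V3", "V4", "V5"),
      n_per_location = 10L
    ),
    locations = c("non-dependent", "gravity-dependent"),
    sample_effect_sd = 0.5,
    effects = tibble::tibble(
      gene = "RPS29", group = "*", location = "gravity-dependent",
      shift = 1.78
    ),
    seed = 1L
  )
}

#' Simulate a Ct table from a design
#'
#' Draws one dataset from the generative model described in
#' [simulation_design()]. Reproducible: the same seed yields a bit-identical
#' table. The design used (the simulation truth) is attached as attribute
#' `"design"` and retrievable with [design_of()].
#'
#' @param design A `simulation_design`.
#' @param seed Optional seed overriding `design$seed`.
#' @return A `ct_tbl` with annotation columns `group` and `location`.
#' @export
simulate_ct <- function(design, seed = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  seed <- seed %||% design$seed

  cells <- tidyr::expand_grid(
    group = design$groups$group,
    location = design$locations
  )
  cells <- dplyr::left_join(cells, design$groups, by = "group")
  samples <- dplyr::mutate(
    tidyr::uncount(cells, .data$n_per_location, .id = "idx"),
    sample = sprintf("%s_%s_%02d", .data$group,
                     gsub("[^A-Za-z0-9]+", "", substr(.data$location, 1, 4)),
                     .data$idx)
  )[c("sample", "group", "location")]

  genes <- design$genes
  n_s <- nrow(samples)
  n_g <- nrow(genes)

  long <- with_seed(seed, {
    u <- stats::rnorm(n_s, 0, design$sample_effect_sd)
    eps <- matrix(stats::rnorm(n_s * n_g), n_s, n_g) *
      rep(genes$noise_sd, each = n_s)
    ctm <- matrix(genes$baseline_ct, n_s, n_g, byrow = TRUE) + u + eps
    out <- tidyr::expand_grid(sample_row = seq_len(n_s), gene_col = seq_len(n_g))
    out$ct <- ctm[cbind(out$sample_row, out$gene_col)]
    out
  })

  res <- tibble::tibble(
    sample = samples$sample[long$sample_row],
    gene = genes$gene[long$gene_col],
    ct = long$ct,
    group = samples$group[long$sample_row],
    location = samples$location[long$sample_row]
  )

  if (nrow(design$effects)) {
    for (i in seq_len(nrow(design$effects))) {
      e <- design$effects[i, ]
      hit <- (e$gene == "*" | res$gene == e$gene) &
        (e$group == "*" | res$group == e$group) &
        (e$location == "*" | res$location == e$location)
      res$ct[hit] <- res$ct[hit] + e$shift
    }
  }
  if (!is.null(design$censor_at)) {
    res$ct[res$ct > design$censor_at] <- NA_real_
  }

  out <- tibble::new_tibble(res, class = "ct_tbl")
  attr(out, "design") <- design
  validate_ct_tbl(out)
}

#' Retrieve the simulation truth attached to a simulated Ct table
#' @param x A `ct_tbl` produced by [simulate_ct()].
#' @return The `simulation_design`, or `NULL` for real data.
#' @export
design_of <- function(x) attr(x, "design")

#' Simulate a dilution-series Ct table
#'
#' Generates duplicate (or `n_replicates`) Ct measurements per dilution point
#' under the standard-curve model
#' \deqn{Ct = intercept - \log_{10}(dilution) / \log_{10}(1 + E/100) + noise,}
#' i.e. a gene amplifying with efficiency E\% has slope
#' \eqn{-1/\log_{10}(1 + E/100)} against log10 dilution (exactly
#' \eqn{-1/\log_{10} 2 = -3.32193} at 100\%).
#'
#' @param true_efficiency_pct True amplification efficiency in percent
#'   (0 < E <= 150).
#' @param intercept_ct Ct at dilution 1 (log10 dilution 0).
#' @param dilution_log10_steps Numeric vector of log10 dilutions (>= 3
#'   distinct values), e.g. `c(0, -1, -2, -3)`.
#' @param replicate_sd SD (cycles) of replicate noise; 0 gives a noiseless
#'   series.
#' @param n_replicates Replicates per dilution point (default 2, duplicates).
#' @param seed Optional RNG seed.
#' @return A tibble with columns `log10_dilution`, `replicate`, `ct`.
#' @export
simulate_dilution_series <- function(true_efficiency_pct, intercept_ct,
                                     dilution_log10_steps = c(0, -1, -2, -3),
                                     replicate_sd = 0, n_replicates = 2,
                                     seed = NULL) {
  if (true_efficiency_pct <= 0 || true_efficiency_pct > 150) {
    abort("true_efficiency_pct must be in (0, 150].")
  }
  if (length(unique(dilution_log10_steps)) < 3) {
    abort("A standard curve needs at least 3 distinct dilution points.")
  }
  slope <- -1 / log10(1 + true_efficiency_pct / 100)
  pts <- tidyr::expand_grid(log10_dilution = dilution_log10_steps,
                            replicate = seq_len(n_replicates))
  pts$ct <- with_seed(seed, {
    intercept_ct + slope * pts$log10_dilution +
      stats::rnorm(nrow(pts), 0, replicate_sd)
  })
  pts
}

#' Write / read a simulation design as YAML
#'
#' @param design A `simulation_design`.
#' @param path File path.
#' @return `write_design()` returns `path` invisibly; `read_design()` returns
#'   the `simulation_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "simulation_design"))
  obj <- list(
    genes = as.data.frame(design$genes),
    groups = as.data.frame(design$groups),
    locations = design$locations,
    sample_effect_sd = design$sample_effect_sd,
    effects = if (nrow(design$effects)) as.data.frame(design$effects) else NULL,
    censor_at = design$censor_at,
    seed = design$seed
  )
  yaml::write_yaml(obj, path, column.major = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  obj <- yaml::read_yaml(path)
  to_tbl <- function(x) dplyr::bind_rows(lapply(x, tibble::as_tibble))
  simulation_design(
    genes = to_tbl(obj$genes),
    groups = to_tbl(obj$groups),
    locations = unlist(obj$locations),
    sample_effect_sd = obj$sample_effect_sd %||% 0.5,
    effects = if (!is.null(obj$effects)) to_tbl(obj$effects) else NULL,
    censor_at = obj$censor_at,
    seed = obj$seed %||% 1L
  )
}
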