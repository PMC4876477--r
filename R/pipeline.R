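#' Validate a pipeline configuration
#'
#' Reads a YAML configuration and returns either a validated config object or
#' the complete list of violations (validation never stops at the first
#' problem). A config describes the input (a Ct table on disk or a
#' simulation design), the cohorts to analyse (filters on group/location),
#' the stability methods to run, optional geNorm amplification factors,
#' optional expression analyses, the output directory and the seed.
#'
#' @param source Path to a YAML file, or an already-parsed list.
#' @return A `pipeline_config`, or an object of class `config_errors`
#'   (character vector of violations) when invalid.
#' @export
validate_config <- function(source) {
  cfg <- if (is.character(source)) yaml::read_yaml(source) else source
  errors <- character()
  note <- function(msg) errors <<- c(errors, msg)

  input <- cfg$input
  if (is.null(input)) {
    note("input: missing (need input.design or input.ct)")
  } else {
    if (is.null(input$design) && is.null(input$ct)) {
      note("input: need either input.design (simulation) or input.ct (table path)")
    }
    if (!is.null(input$ct) && !file.exists(input$ct)) {
      note(paste0("input.ct: file not found: ", input$ct))
    }
    if (!is.null(input$design) && !identical(input$design, "default") &&
        !file.exists(input$design)) {
      note(paste0("input.design: must be 'default' or an existing YAML path, got: ",
                  input$design))
    }
  }

  methods_allowed <- c("delta_ct", "genorm", "normfinder", "bestkeeper")
  methods <- cfg$methods %||% methods_allowed
  bad <- setdiff(methods, methods_allowed)
  if (length(bad)) {
    note(paste0("methods: unknown value(s) ", paste(bad, collapse = ", "),
                "; allowed: ", paste(methods_allowed, collapse = ", ")))
  }

  cohorts <- cfg$cohorts
  if (is.null(cohorts) || !length(cohorts)) {
    note("cohorts: at least one cohort is required")
  } else {
    nms <- vapply(cohorts, function(co) co$name %||% NA_character_,
                  character(1))
    if (anyNA(nms)) note("cohorts: every cohort needs a name")
    dup <- unique(nms[duplicated(nms)])
    if (length(dup)) {
      note(paste0("cohorts: duplicated name(s): ",
                  paste(stats::na.omit(dup), collapse = ", ")))
    }
  }

  expression <- cfg$expression
  if (!is.null(expression)) {
    for (field in c("goi", "refs", "control_group")) {
      if (is.null(expression[[field]])) {
        note(paste0("expression.", field, ": missing"))
      }
    }
    if (!is.null(expression$goi) &&
        any(unlist(expression$goi) %in% unlist(expression$refs))) {
      note("expression: goi must not appear among refs")
    }
  }

  seed <- cfg$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1) note("seed: must be one integer")

  if (length(errors)) {
    return(structure(errors, class = "config_errors"))
  }
  structure(
    list(input = input, cohorts = cohorts, methods = methods,
         genorm_efficiencies = cfg$genorm_efficiencies,
         expression = expression,
         output_dir = cfg$output_dir %||% "refstab-output",
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @export
print.config_errors <- function(x, ...) {
  cat("Invalid pipeline configuration:\n")
  cat(paste0("  - ", unclass(x), collapse = "\n"), "\n")
  invisible(x)
}

cohort_filter <- function(ct, cohort) {
  keep <- rep(TRUE, nrow(ct))
  if (!is.null(cohort$groups)) {
    if (!"group" %in% names(ct)) abort("Cohort filters on group but the Ct table has no group column.")
    unknown <- setdiff(unlist(cohort$groups), unique(ct$group))
    if (length(unknown)) {
      abort(paste0("Cohort '", cohort$name, "' references unknown group(s): ",
                   paste(unknown, collapse = ", "), "."))
    }
    keep <- keep & ct$group %in% unlist(cohort$groups)
  }
  if (!is.null(cohort$locations)) {
    if (!"location" %in% names(ct)) abort("Cohort filters on location but the Ct table has no location column.")
    unknown <- setdiff(unlist(cohort$locations), unique(ct$location))
    if (length(unknown)) {
      abort(paste0("Cohort '", cohort$name, "' references unknown location(s): ",
                   paste(unknown, collapse = ", "), "."))
    }
    keep <- keep & ct$location %in% unlist(cohort$locations)
  }
  out <- ct[keep, ]
  if (nrow(out) == 0) {
    abort(paste0("Cohort '", cohort$name, "' selects no samples."))
  }
  tibble::new_tibble(out, class = "ct_tbl")
}

#' Run the full reference-gene validation pipeline
#'
#' Loads or simulates the Ct data, then for every configured cohort runs the
#' requested stability methods, the comprehensive ranking and the gene
#' summaries, plus optional expression analyses, writing one CSV per report
#' and a JSON manifest (config hash, seed, package version, per-stage sample
#' and gene counts, complete-case removals, output files). Runs are
#' deterministic: re-running a simulation-backed config with the same seed
#' reproduces every output file byte for byte.
#'
#' @param config A `pipeline_config` from [validate_config()], or a path to
#'   a YAML config.
#' @return Invisibly, a list with the loaded `ct`, per-cohort results,
#'   expression results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) || !inherits(config, "pipeline_config")) {
    config <- validate_config(config)
  }
  if (inherits(config, "config_errors")) {
    abort(paste0("Invalid configuration:\n",
                 paste0("  - ", unclass(config), collapse = "\n")))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    inform(msg)
  }

  if (!is.null(config$input$design)) {
    design <- if (identical(config$input$design, "default")) {
      default_design()
    } else {
      read_design(config$input$design)
    }
    ct <- simulate_ct(design, seed = config$seed)
    say("Simulated %d samples x %d genes (seed %d)",
        length(ct_samples(ct)), length(ct_genes(ct)), config$seed)
  } else {
    ct <- read_ct_table(config$input$ct,
                        annotations = config$input$annotations)
    say("Loaded %d samples x %d genes from %s",
        length(ct_samples(ct)), length(ct_genes(ct)), config$input$ct)
  }

  efficiencies <- NULL
  if (!is.null(config$genorm_efficiencies)) {
    eff_tbl <- read_delimited(config$genorm_efficiencies)
    efficiencies <- stats::setNames(eff_tbl$amplification, eff_tbl$gene)
  }

  files <- character()
  emit <- function(df, name) {
    path <- file.path(config$output_dir, name)
    readr::write_csv(df, path)
    files <<- c(files, name)
    path
  }

  cohort_out <- list()
  for (cohort in config$cohorts) {
    sub <- cohort_filter(ct, cohort)
    cc <- complete_cases(sub)
    removed <- attr(cc, "removed_samples")
    say("Cohort '%s': %d samples, %d genes (%d removed as incomplete)",
        cohort$name, length(ct_samples(cc)), length(ct_genes(cc)),
        length(removed))
    emit(summarize_ct(sub, by = if ("location" %in% names(sub)) "location"),
         paste0(cohort$name, "_gene_summary.csv"))
    results <- list()
    for (method in config$methods) {
      res <- switch(method,
        delta_ct = delta_ct_stability(cc),
        genorm = genorm(cc, efficiencies = efficiencies),
        normfinder = normfinder(cc),
        bestkeeper = bestkeeper(cc))
      results[[method]] <- res
      emit(tidy.stability_result(res), paste0(cohort$name, "_", method, ".csv"))
      if (method == "bestkeeper") {
        emit(res$aux$descriptives,
             paste0(cohort$name, "_bestkeeper_descriptives.csv"))
      }
      if (method == "genorm") {
        elim <- dplyr::bind_rows(lapply(seq_along(res$aux$steps), function(i) {
          dplyr::mutate(res$aux$steps[[i]], step = i, .before = 1)
        }))
        emit(elim, paste0(cohort$name, "_genorm_steps.csv"))
      }
    }
    if (length(results) == 4) {
      emit(rank_table(unname(results)),
           paste0(cohort$name, "_comprehensive_ranking.csv"))
    }
    cohort_out[[cohort$name]] <- list(ct = cc, results = results,
                                      removed = removed)
  }

  expression_out <- NULL
  if (!is.null(config$expression)) {
    ex <- config$expression
    expression_out <- list()
    for (goi in unlist(ex$goi)) {
      res <- delta_delta_ct(ct, goi = goi, refs = unlist(ex$refs),
                            control_group = ex$control_group)
      cmp <- group_anova(res)
      report <- dplyr::left_join(glance.expression_result(res),
                                 tidy.expression_anova(cmp),
                                 by = "group")
      emit(report, paste0("expression_", goi, ".csv"))
      expression_out[[goi]] <- list(result = res, anova = cmp)
      say("Expression of %s vs %s: ANOVA p = %s", goi,
          paste(unlist(ex$refs), collapse = "+"),
          format(cmp$anova$p_value, digits = 3))
    }
  }

  manifest <- list(
    package = "refstab",
    version = as.character(utils::packageVersion("refstab")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
    files = files,
    log = log_lines
  )
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(ct = ct, cohorts = cohort_out,
                 expression = expression_out, manifest = manifest))
}
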