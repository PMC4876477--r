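#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats sd var cor.test t.test aov anova lm coef p.adjust quantile
NULL

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Dense ranks (ties share a rank, rank values are 1..k), ascending.
dense_ranks <- function(statistic) {
  vapply(statistic, function(s) sum(unique(statistic) < s), integer(1)) + 1L
}

geometric_mean <- function(x) exp(mean(log(x)))

stars_for <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}
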