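# Build a ct_tbl from a samples x genes matrix
ct_from_matrix <- function(m, annotations = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("g", seq_len(ncol(m)))
  wide <- data.frame(sample = rownames(m), m, check.names = FALSE)
  as_ct_tbl(wide, layout = "wide", annotations = annotations)
}

random_ct_matrix <- function(n_samples, n_genes, seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_samples * n_genes, mean = 25, sd = 2),
              n_samples, n_genes,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("g", seq_len(n_genes))))
  m
}

# 3-gene toy used across the delta-Ct / geNorm tests:
# B is A shifted by a constant (perfectly co-stable pair), C varies against both
toy3 <- function() {
  m <- cbind(A = c(20, 21, 22, 23),
             B = c(21, 22, 23, 24),
             C = c(20, 20, 24, 24))
  rownames(m) <- paste0("s", 1:4)
  m
}

# Brute-force oracle: SD over samples of Ct_j - Ct_k with explicit loops and
# an explicit n-1 variance formula (independent of the package's code path)
brute_pairwise_sd <- function(m) {
  g <- ncol(m)
  n <- nrow(m)
  out <- matrix(0, g, g, dimnames = list(colnames(m), colnames(m)))
  for (j in seq_len(g)) {
    for (k in seq_len(g)) {
      if (j == k) next
      d <- numeric(n)
      for (s in seq_len(n)) d[s] <- m[s, j] - m[s, k]
      mu <- sum(d) / n
      ss <- 0
      for (s in seq_len(n)) ss <- ss + (d[s] - mu)^2
      out[j, k] <- sqrt(ss / (n - 1))
    }
  }
  out
}

design_with_gene <- function(design, gene, baseline_ct, noise_sd,
                             effects = NULL) {
  design$genes <- dplyr::bind_rows(
    design$genes,
    tibble::tibble(gene = gene, baseline_ct = baseline_ct, noise_sd = noise_sd))
  if (!is.null(effects)) {
    design$effects <- dplyr::bind_rows(design$effects, effects)
  }
  design
}

# Default design plus an unstable gene whose expression depends strongly on
# treatment group: a 3-cycle shift of alternating sign per group, noise SD 0.5
design_with_unstable_gene <- function() {
  d <- default_design()
  shifts <- tibble::tibble(
    gene = "UNSTABLE",
    group = d$groups$group,
    location = "*",
    shift = 3 * (-1)^seq_len(nrow(d$groups))
  )
  design_with_gene(d, "UNSTABLE", baseline_ct = 28, noise_sd = 0.5,
                   effects = shifts)
}
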