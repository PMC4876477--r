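test_that("pairwise delta-Ct SDs match hand arithmetic and a brute-force oracle", {
  m <- toy3()
  pw <- pairwise_delta_ct_sd(m)
  expect_equal(pw["A", "B"], 0)                       # constant difference
  expect_equal(pw["A", "C"], 1.29099, tolerance = 1e-5)  # SD of {0,1,-2,-1}
  expect_equal(pw, t(pw))
  expect_equal(diag(pw), c(A = 0, B = 0, C = 0))

  r <- random_ct_matrix(12, 5, seed = 21)
  expect_equal(pairwise_delta_ct_sd(r), brute_pairwise_sd(r),
               tolerance = 1e-12)
})

test_that("per-sample global shifts cancel in pairwise delta-Ct SDs", {
  m <- random_ct_matrix(10, 4, seed = 8)
  m2 <- m
  m2[3, ] <- m2[3, ] + 5
  expect_equal(pairwise_delta_ct_sd(m2), pairwise_delta_ct_sd(m),
               tolerance = 1e-10)
})

test_that("comparative delta-Ct statistic is the mean pairwise SD, densely ranked", {
  res <- delta_ct_stability(toy3())
  pg <- res$per_gene
  expect_equal(pg$statistic[pg$gene == "A"], 1.29099 / 2, tolerance = 1e-5)
  expect_equal(pg$statistic[pg$gene == "B"], 1.29099 / 2, tolerance = 1e-5)
  expect_equal(pg$statistic[pg$gene == "C"], 1.29099, tolerance = 1e-5)
  expect_equal(pg$rank, c(1L, 1L, 2L))  # tie shares rank, ranks stay dense

  # genes identical up to constants: all statistics 0, all rank 1
  base <- c(20, 22, 21, 23, 25)
  m <- cbind(a = base, b = base + 1, c = base - 2)
  res0 <- delta_ct_stability(m)
  expect_equal(res0$per_gene$statistic, c(0, 0, 0))
  expect_equal(res0$per_gene$rank, c(1L, 1L, 1L))

  # independent oracle on a random matrix
  r <- random_ct_matrix(12, 5, seed = 33)
  bf <- brute_pairwise_sd(r)
  expect_equal(delta_ct_stability(r)$per_gene$statistic,
               unname(rowSums(bf) / (ncol(r) - 1)), tolerance = 1e-12)
})

test_that("missing values are a hard error for the stability methods", {
  m <- random_ct_matrix(6, 3, seed = 2)
  m[2, 2] <- NA
  ct <- ct_from_matrix(m)
  expect_error(delta_ct_stability(ct), "complete_cases")
  expect_error(genorm(ct), "complete_cases")
  expect_error(normfinder(ct), "complete_cases")
  expect_error(bestkeeper(ct), "complete_cases")
})

test_that("geNorm keeps the co-stable pair at rank 1 with identical M", {
  res <- genorm(toy3())
  pg <- res$per_gene
  expect_equal(pg$rank[pg$gene %in% c("A", "B")], c(1L, 1L))
  expect_equal(pg$statistic[pg$gene == "A"], 0)
  expect_equal(pg$statistic[pg$gene == "B"], 0)
  expect_equal(pg$rank[pg$gene == "C"], 2L)
  expect_equal(res$aux$elimination_order, "C")
  expect_equal(pg$statistic[pg$gene == "C"], 1.29099, tolerance = 1e-5)
})

test_that("geNorm first-round M equals the delta-Ct statistic at amplification 2", {
  for (seed in 1:10) {
    m <- random_ct_matrix(12, 5, seed = seed)
    first_round <- genorm(m)$aux$steps[[1]]
    dct <- delta_ct_stability(m)$per_gene
    expect_equal(first_round$m[match(dct$gene, first_round$gene)],
                 dct$statistic, tolerance = 1e-10)
  }
})

test_that("geNorm respects per-gene amplification factors and sample shifts", {
  m <- random_ct_matrix(10, 4, seed = 14)
  m2 <- m
  m2[5, ] <- m2[5, ] + 5   # per-sample global shift cancels in ratios
  expect_equal(genorm(m2)$per_gene, genorm(m)$per_gene, tolerance = 1e-10)

  # non-default efficiencies change the statistics
  eff <- c(g1 = 1.9, g2 = 2.1, g3 = 2.0, g4 = 1.95)
  expect_false(isTRUE(all.equal(genorm(m, efficiencies = eff)$per_gene$statistic,
                                genorm(m)$per_gene$statistic)))
  expect_error(genorm(m, efficiencies = c(g1 = 0.9)), "> 1")
})

test_that("geNorm final pair always shares an identical M value", {
  for (seed in 11:16) {
    res <- genorm(random_ct_matrix(9, 6, seed = seed))
    pair <- res$per_gene[res$per_gene$rank == 1, ]
    expect_equal(nrow(pair), 2)
    expect_equal(pair$statistic[1], pair$statistic[2])
  }
})

test_that("geNorm on 2 genes computes the pair without exclusion, with a warning", {
  m <- random_ct_matrix(8, 2, seed = 4)
  expect_warning(res <- genorm(m), "2 genes")
  expect_equal(res$per_gene$rank, c(1L, 1L))
  expect_equal(res$per_gene$statistic[1], res$per_gene$statistic[2])
})

test_that("NormFinder is zero under a pure loading effect and self-consistent", {
  set.seed(101)
  u <- stats::rnorm(10)
  m <- outer(u, rep(1, 4)) + matrix(rep(c(20, 25, 30, 35), each = 10), 10, 4)
  colnames(m) <- paste0("g", 1:4)
  rownames(m) <- paste0("s", 1:10)
  res <- normfinder(m)
  expect_equal(res$per_gene$statistic, rep(0, 4), tolerance = 1e-12)

  # algebraic self-consistency: plugging the estimates back into the
  # decomposition reproduces the observed variances of the centred data
  r <- random_ct_matrix(12, 4, seed = 19)
  rf <- normfinder(r)
  sigma2 <- rf$aux$variance
  v <- rf$aux$observed_variance
  g <- 4
  expect_true(all(sigma2 > 0))  # no truncation for this seed
  expect_equal(unname(sigma2 * (g - 2) / g + sum(sigma2) / g^2), unname(v),
               tolerance = 1e-9)
})

test_that("NormFinder enforces its minimum sizes", {
  expect_error(normfinder(random_ct_matrix(5, 2, seed = 1)), ">= 3")
  m <- random_ct_matrix(5, 3, seed = 1)
  expect_error(normfinder(m, groups = c("a", "a", "a", "b", "b"),
                          mode = "grouped"), ">= 3 samples")
})

test_that("grouped NormFinder flags a group-shifted gene as least stable", {
  d <- design_with_gene(
    default_design(), "SHIFTED", baseline_ct = 28, noise_sd = 0.5,
    effects = tibble::tibble(gene = "SHIFTED",
                             group = c("V3", "V4", "V5"),
                             location = "*", shift = 3))
  hits <- vapply(1:60, function(s) {
    ct <- simulate_ct(d, seed = s)
    res <- normfinder(ct, mode = "grouped")
    pg <- res$per_gene
    pg$gene[which.max(pg$statistic)] == "SHIFTED"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("BestKeeper descriptives, index, and correlations are as defined", {
  # two genes, constant difference; one sample with Ct (20, 30)
  m <- cbind(a = c(20, 22, 24), b = c(30, 32, 34))
  rownames(m) <- paste0("s", 1:3)
  res <- bestkeeper(m)
  expect_equal(unname(res$aux$index[1]), sqrt(600), tolerance = 1e-9)
  desc <- res$aux$descriptives
  expect_equal(desc$geo_mean[desc$gene == "a"], exp(mean(log(c(20, 22, 24)))))

  # a gene exactly equal to the index correlates perfectly with it
  twin <- cbind(a = c(20, 22, 24), b = c(20, 22, 24))
  expect_equal(bestkeeper(twin)$aux$descriptives$r, c(1, 1),
               tolerance = 1e-12)

  const <- cbind(k = c(20, 20, 20, 20), x = c(25, 26, 27, 28))
  resc <- bestkeeper(const)
  pg <- resc$per_gene
  expect_equal(pg$statistic[pg$gene == "k"], 0)
  expect_equal(pg$rank[pg$gene == "k"], 1L)
  expect_true(is.na(resc$aux$descriptives$r[resc$aux$descriptives$gene == "k"]))
})

test_that("BestKeeper dispersion variants and instability flag behave", {
  m <- random_ct_matrix(10, 3, seed = 77)
  sd_res <- bestkeeper(m)
  mad_res <- bestkeeper(m, sd_variant = "mean_abs_dev")
  expect_equal(sd_res$per_gene$statistic,
               apply(m, 2, stats::sd), ignore_attr = TRUE)
  expect_equal(mad_res$per_gene$statistic,
               apply(m, 2, function(x) mean(abs(x - mean(x)))),
               ignore_attr = TRUE)
  expect_true(all(mad_res$per_gene$statistic <= sd_res$per_gene$statistic))
  expect_identical(unname(sd_res$aux$unstable),
                   unname(sd_res$per_gene$statistic >= 1))
})

test_that("per-gene constant shifts leave all four methods' statistics unchanged", {
  m <- random_ct_matrix(10, 4, seed = 55)
  m2 <- m
  m2[, 2] <- m2[, 2] + 3
  for (f in list(delta_ct_stability, genorm, normfinder, bestkeeper)) {
    expect_equal(f(m2)$per_gene$statistic, f(m)$per_gene$statistic,
                 tolerance = 1e-10)
  }
})

test_that("all four methods are invariant to sample order", {
  m <- random_ct_matrix(10, 4, seed = 66)
  perm <- m[sample(nrow(m)), ]
  for (f in list(delta_ct_stability, genorm, normfinder, bestkeeper)) {
    a <- f(m)$per_gene
    b <- f(perm)$per_gene
    expect_equal(b$statistic[match(a$gene, b$gene)], a$statistic,
                 tolerance = 1e-10)
  }
})

test_that("tidy and glance expose the per-gene table and summary", {
  res <- delta_ct_stability(toy3())
  td <- tidy(res)
  expect_named(td, c("method", "gene", "statistic", "rank"))
  gl <- glance(res)
  expect_equal(gl$method, "delta_ct")
  expect_equal(gl$best_genes, "A,B")
})
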