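expr_toy <- function() {
  # 2 genes x 6 samples, two groups; hand-controlled dCt values
  m <- cbind(EGR1 = c(27, 27, 27, 25, 25, 25),
             REF = c(20, 20, 20, 20, 20, 20))
  rownames(m) <- paste0("s", 1:6)
  ann <- data.frame(sample = rownames(m),
                    group = rep(c("NI", "Vx"), each = 3),
                    location = "non-dependent")
  ct_from_matrix(m, annotations = ann)
}

test_that("ddCt arithmetic follows the definition", {
  ct <- expr_toy()
  res <- delta_delta_ct(ct, "EGR1", "REF", control_group = "NI")
  ps <- res$per_sample
  # control dCt = 7 for all controls -> control folds exactly 1
  expect_equal(ps$fold[ps$group == "NI"], c(1, 1, 1))
  # treated: dCt 5, ddCt -2, fold 4
  expect_equal(ps$delta_delta_ct[ps$group == "Vx"], c(-2, -2, -2))
  expect_equal(ps$fold[ps$group == "Vx"], c(4, 4, 4))
  pg <- res$per_group
  expect_equal(pg$mean_fold[pg$group == "Vx"], 4)
  expect_equal(pg$sem_fold[pg$group == "Vx"], 0)
})

test_that("control-group geometric mean fold is exactly 1", {
  d <- default_design()
  d <- design_with_gene(d, "EGR1", baseline_ct = 30, noise_sd = 0.4)
  ct <- simulate_ct(d, seed = 12)
  res <- delta_delta_ct(ct, "EGR1", "GAPDH", control_group = "NI")
  ctrl <- res$per_sample$fold[res$per_sample$group == "NI"]
  expect_equal(exp(mean(log(ctrl))), 1, tolerance = 1e-12)
})

test_that("fold changes are invariant to a constant shift of the reference", {
  d <- design_with_gene(default_design(), "EGR1", 30, 0.4)
  ct <- simulate_ct(d, seed = 13)
  shifted <- ct
  shifted$ct[shifted$gene == "GAPDH"] <- shifted$ct[shifted$gene == "GAPDH"] + 4
  a <- delta_delta_ct(ct, "EGR1", "GAPDH", "NI")
  b <- delta_delta_ct(validate_ct_tbl(shifted), "EGR1", "GAPDH", "NI")
  expect_equal(b$per_sample$fold, a$per_sample$fold, tolerance = 1e-12)
})

test_that("multiple references average on the log scale", {
  ct <- expr_toy()
  m2 <- cbind(ct_matrix(ct), REF2 = c(22, 22, 22, 22, 22, 22))
  ann <- ct_annotations(ct)
  ct2 <- ct_from_matrix(m2, annotations = ann)
  res <- delta_delta_ct(ct2, "EGR1", c("REF", "REF2"), "NI")
  # mean ref Ct = 21 -> same dCt pattern as single ref, folds unchanged
  expect_equal(res$per_sample$fold[res$per_sample$group == "Vx"], c(4, 4, 4))
})

test_that("a gene normalized against an identical profile is degenerate, not a crash", {
  ct <- expr_toy()
  m <- ct_matrix(ct)
  m <- cbind(m, TWIN = m[, "EGR1"])
  ct2 <- ct_from_matrix(m, annotations = ct_annotations(ct))
  res <- delta_delta_ct(ct2, "EGR1", "TWIN", "NI")
  expect_true(all(res$per_sample$fold == 1))
  expect_true(res$degenerate)
  expect_warning(cmp <- group_anova(res), "degenerate")
  expect_true(cmp$anova$degenerate)
  expect_true(is.na(cmp$anova$p_value))
  expect_error(delta_delta_ct(ct, "EGR1", "EGR1", "NI"), "own reference")
})

test_that("ANOVA F matches a hand-computed oracle on a 2x3 toy", {
  y <- c(1.0, 1.2, 0.8, 3.9, 4.2, 4.1)
  g <- rep(c("NI", "Vx"), each = 3)
  ybar <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - ybar)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ssb / 1) / (ssw / 4)
  m <- cbind(EGR1 = 20 - log2(y), REF = rep(20, 6))
  rownames(m) <- paste0("s", 1:6)
  ct2 <- ct_from_matrix(m, annotations = data.frame(
    sample = rownames(m), group = g, location = "x"))
  res2 <- delta_delta_ct(ct2, "EGR1", "REF", "NI")
  # re-centering on the control mean rescales all folds by a constant,
  # which leaves the one-way F statistic unchanged
  cmp2 <- group_anova(res2)
  expect_equal(cmp2$anova$f_statistic, f_oracle, tolerance = 1e-9)
  expect_equal(cmp2$anova$df1, 1)
  expect_equal(cmp2$anova$df2, 4)
})

test_that("Welch t in location_compare matches a closed-form oracle", {
  a <- c(20.1, 21.3, 19.8, 20.9)
  b <- c(22.0, 21.5, 23.1, 22.4)
  m <- cbind(G = c(a, b))
  rownames(m) <- paste0("s", 1:8)
  ann <- data.frame(sample = rownames(m), group = "NI",
                    location = rep(c("nd", "gd"), each = 4))
  # needs >= 2 genes for a valid table
  m <- cbind(m, OTHER = 25)
  lc <- location_compare(ct_from_matrix(m, annotations = ann), "G")
  se <- sqrt(var(a) / 4 + var(b) / 4)
  t_oracle <- (mean(a) - mean(b)) / se
  df_oracle <- se^4 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  p_oracle <- 2 * stats::pt(-abs(t_oracle), df_oracle)
  expect_equal(lc$tests$t_statistic, t_oracle, tolerance = 1e-9)
  expect_equal(lc$tests$df, df_oracle, tolerance = 1e-9)
  expect_equal(lc$tests$p_value, p_oracle, tolerance = 1e-9)
})

test_that("identical location arms give p = 1 and symmetric summaries", {
  m <- cbind(G = rep(c(20, 21, 22), 2), H = 25)
  rownames(m) <- paste0("s", 1:6)
  ann <- data.frame(sample = rownames(m), group = "NI",
                    location = rep(c("nd", "gd"), each = 3))
  lc <- location_compare(ct_from_matrix(m, annotations = ann), "G")
  expect_equal(lc$tests$p_value, 1, tolerance = 1e-12)
  s <- lc$summaries
  expect_equal(s$median[s$location == "nd"], s$median[s$location == "gd"])
})

test_that("location arms with n < 2 are skipped with a warning", {
  m <- cbind(G = c(20, 21, 22, 23, 24), H = 25)
  rownames(m) <- paste0("s", 1:5)
  ann <- data.frame(sample = rownames(m),
                    group = c("NI", "NI", "NI", "NI", "V1"),
                    location = c("nd", "nd", "gd", "gd", "nd"))
  expect_warning(lc <- location_compare(ct_from_matrix(m, annotations = ann), "G"),
                 "skipped")
  expect_equal(lc$tests$group, "NI")
})

test_that("the designed RPS29 location shift is detected; a stable gene is not", {
  d <- default_design()
  hits_rps29 <- logical(100)
  hits_gapdh <- logical(100)
  for (s in 1:100) {
    ct <- simulate_ct(d, seed = 3000 + s)
    pooled <- ct
    pooled$group <- "all"   # pool treatment groups; location is the contrast
    pr <- location_compare(validate_ct_tbl(pooled), "RPS29")
    pg <- location_compare(validate_ct_tbl(pooled), "GAPDH")
    hits_rps29[s] <- pr$tests$p_value < 0.05
    hits_gapdh[s] <- pg$tests$p_value < 0.05
  }
  expect_gte(mean(hits_rps29), 0.9)
  expect_lte(mean(hits_gapdh), 0.15)
})

test_that("SEM shrinks roughly as 1/sqrt(n) on synthetic data", {
  mk <- function(n) {
    d <- simulation_design(
      genes = data.frame(gene = c("EGR1", "REF"), baseline_ct = c(30, 20),
                         noise_sd = c(0.5, 0)),
      groups = data.frame(group = c("NI", "V1"), n_per_location = n),
      locations = "x", sample_effect_sd = 0.3)
    sems <- vapply(1:40, function(s) {
      ct <- simulate_ct(d, seed = s)
      res <- delta_delta_ct(ct, "EGR1", "REF", "NI")
      res$per_group$sem_fold[res$per_group$group == "V1"]
    }, numeric(1))
    mean(sems)
  }
  ratio <- mk(10) / mk(40)
  expect_gt(ratio, 1.6)  # ideal 2
  expect_lt(ratio, 2.4)
})
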