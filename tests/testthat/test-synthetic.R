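test_that("generated counts reproduce the negative-binomial mean-variance law", {
  # Poisson limit: dispersion 0, no extremes, equal size factors
  cm0 <- generate_counts(40, 5000, seed = 2, base_mean = 50, dispersion = 0,
                         extreme_value_rate = 0, size_factor_sdlog = 0,
                         block_rho = 0)
  ratio <- apply(cm0$counts, 1, var) / rowMeans(cm0$counts)
  expect_equal(mean(ratio), 1, tolerance = 0.05)

  # NB: variance ~ mu + alpha mu^2 = 5100 at mu = 100, alpha = 0.5;
  # cross-checked against directly sampled NB variates
  cm <- generate_counts(40, 5000, seed = 1, base_mean = 100, dispersion = 0.5,
                        extreme_value_rate = 0, size_factor_sdlog = 0,
                        block_rho = 0)
  v <- mean(apply(cm$counts, 1, var))
  expect_equal(v, 5100, tolerance = 0.10)
  set.seed(99)
  oracle <- var(rnbinom(2e5, size = 1 / 0.5, mu = 100))
  expect_equal(v, oracle, tolerance = 0.10)
})

test_that("count generation is deterministic in the seed and validates input", {
  a <- generate_counts(30, 10, seed = 7)
  b <- generate_counts(30, 10, seed = 7)
  expect_identical(a$counts, b$counts)
  expect_identical(a$genes, b$genes)
  c <- generate_counts(30, 10, seed = 8)
  expect_false(identical(a$counts, c$counts))
  expect_error(generate_counts(1, 10, seed = 1), "n_genes")
  expect_error(generate_counts(10, 10, seed = 1, extreme_value_rate = 0.5),
               "extreme_value_rate")
})

test_that("mean-variance dependency steepens beyond Poisson when dispersed", {
  cm <- generate_counts(400, 200, seed = 5, extreme_value_rate = 0)
  m <- rowMeans(cm$counts)
  v <- apply(cm$counts, 1, var)
  keep <- m > 0 & v > 0
  slope <- coef(lm(log(v[keep]) ~ log(m[keep])))[2]
  expect_gt(slope, 1)
})

test_that("extreme values inflate gene-gene correlations before truncation", {
  cm <- generate_counts(200, 150, seed = 21, extreme_value_rate = 0.005)
  norm <- normalize_counts(cm)
  trunc <- truncate_extremes(norm)
  # pairs sharing an inflated entry: compare correlation before/after
  raw_cor <- cor(t(norm))
  tr_cor <- cor(t(trunc))
  diffs <- raw_cor - tr_cor
  diag(diffs) <- 0
  expect_gt(max(diffs, na.rm = TRUE), 0.5)
})

test_that("informative genes are drawn one per gene-length bin", {
  # 20 genes, 10 bins: one of each consecutive pair in length order
  genes <- make_genes(lengths = sample(seq(100, 4000, by = 100), 20))
  picks <- choose_informative_genes(genes, 10, seed = 3)
  ord <- genes$gene_id[order(genes$length_bp, seq_len(20))]
  bins <- split(ord, rep(1:10, each = 2))
  expect_length(picks, 10)
  for (b in 1:10) expect_length(intersect(picks, bins[[b]]), 1)

  # n_informative = n_genes returns everything
  expect_setequal(choose_informative_genes(genes, 20, seed = 1),
                  genes$gene_id)

  # 21 genes in 10 bins: remainder rule gives sizes (3, 2, 2, ...)
  g21 <- make_genes(lengths = 100 * (21:1))
  set.seed(0)
  picks21 <- replicate(200, choose_informative_genes(
    g21, 10, seed = sample.int(1e6, 1)), simplify = FALSE)
  ord21 <- g21$gene_id[order(g21$length_bp, seq_len(21))]
  sizes <- c(3, rep(2, 9))
  stops <- cumsum(sizes)
  bins21 <- lapply(seq_along(sizes), function(b)
    ord21[(c(1, head(stops, -1) + 1)[b]):stops[b]])
  for (p in picks21)
    for (b in seq_along(bins21))
      expect_length(intersect(p, bins21[[b]]), 1)
  # every member of the 3-gene first bin is reachable
  first_picks <- vapply(picks21, function(p) intersect(p, bins21[[1]]), "")
  expect_setequal(unique(first_picks), bins21[[1]])

  expect_error(choose_informative_genes(genes, 21, seed = 1), "n_informative")
})

test_that("effect calibration hits the target SNR and scales correctly", {
  set.seed(4)
  x <- matrix(rnorm(400), 1, 400)
  rownames(x) <- "g001"

  # zero effect has zero SNR under both definitions
  expect_equal(countsig:::snr_latent(0, as.numeric(x)), 0)
  expect_equal(countsig:::snr_bernoulli(0, as.numeric(x)), 0)

  # grid-search oracle at a small target
  b <- calibrate_effects(x, snr_target = 0.1)
  grid <- seq(0, 5, length.out = 1e4)
  snrs <- vapply(grid, countsig:::snr_latent, numeric(1),
                 x_sum = as.numeric(x))
  b_oracle <- grid[which.min(abs(snrs - 0.1))]
  expect_equal(as.numeric(b), b_oracle, tolerance = 1e-2)
  expect_equal(attr(b, "snr"), 0.1, tolerance = 0.01)

  # doubling the covariate halves the calibrated effect
  b2 <- calibrate_effects(2 * x, snr_target = 0.1)
  expect_equal(as.numeric(b2), as.numeric(b) / 2, tolerance = 1e-3)
  bb <- calibrate_effects(x, 0.1, snr_def = "bernoulli")
  bb2 <- calibrate_effects(2 * x, 0.1, snr_def = "bernoulli")
  expect_equal(as.numeric(bb2), as.numeric(bb) / 2, tolerance = 1e-3)

  # achieved SNR within 1% of target at study-like settings
  xs <- make_expr(10, 200, seed = 6)
  bs <- calibrate_effects(xs, 2.5)
  expect_equal(attr(bs, "snr"), 2.5, tolerance = 0.01)

  expect_error(calibrate_effects(matrix(1, 1, 10), 1), "calibration")
})

test_that("binary outcomes follow the generating logistic model", {
  x <- make_expr(20, 2000, seed = 8)
  zero <- simulation_design(rownames(x)[1:5], rep(0, 5), "linear")
  out0 <- simulate_binary_outcome(x, zero, seed = 1)
  expect_true(all(out0$pi == 0.5))

  # strong single-gene effect: top covariate decile enriched for cases
  des <- simulation_design("g001", 2, "logarithmic")
  out <- simulate_binary_outcome(x, des, seed = 2)
  cov <- log(x["g001", ] + 1)
  hi <- out$y[cov >= quantile(cov, 0.9)]
  lo <- out$y[cov <= quantile(cov, 0.1)]
  expect_gt(mean(hi), mean(lo))

  expect_identical(out$y, simulate_binary_outcome(x, des, seed = 2)$y)
  bad <- simulation_design("nope", 1, "linear")
  expect_error(simulate_binary_outcome(x, bad, seed = 1), "not present")
})

test_that("survival outcomes follow the exponential Cox generating model", {
  x <- make_expr(10, 5000, seed = 9)
  null_des <- simulation_design("g001", 0, "linear")
  so <- simulate_survival_outcome(x, NULL, null_des, baseline_hazard = 0.2,
                                  censor_rate = 0, seed = 3)
  expect_true(all(so$event == 1L))
  expect_equal(median(so$time), log(2) / 0.2, tolerance = 0.05)

  # positive effect: higher expression, earlier events
  des <- simulation_design("g002", 1.2, "logarithmic")
  so2 <- simulate_survival_outcome(x, NULL, des, censor_rate = 0, seed = 4)
  tau <- cor(log(x["g002", ] + 1), so2$time, method = "kendall")
  expect_lt(tau, 0)

  # censoring rate is hit within the stated window
  so3 <- simulate_survival_outcome(x, NULL, des, censor_rate = 0.4, seed = 5)
  expect_lt(abs(mean(1 - so3$event) - 0.4), 0.05)
  expect_error(
    simulate_survival_outcome(x, NULL, des, censor_rate = 0.99, seed = 1),
    "censor_rate")
})
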