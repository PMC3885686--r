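test_that("unpenalized boosting on an orthonormal design is stagewise regression", {
  set.seed(42)
  X <- qr.Q(qr(matrix(rnorm(50 * 5), 50)))
  y <- rnorm(50)
  fit <- boost_fit(X, y, "gaussian", steps = 1, penalty = 0)
  score <- as.numeric(crossprod(X, y - mean(y)))
  expect_identical(fit$selected[1], which.max(abs(score)))
  expect_equal(fit$delta[1], score[which.max(abs(score))], tolerance = 1e-10)

  # zero steps leave every penalized coefficient at zero
  f0 <- boost_fit(X, y, "gaussian", steps = 0)
  expect_true(all(f0$beta == 0))
})

test_that("small-step boosting tracks the soft-thresholding path", {
  set.seed(42)
  X <- qr.Q(qr(matrix(rnorm(50 * 5), 50)))
  y <- rnorm(50)
  fit <- boost_fit(X, y, "gaussian", steps = 2000, nu = 0.01)
  bhat <- as.numeric(crossprod(X, y - mean(y)))   # OLS for orthonormal X
  soft <- function(L) {
    if (L >= sum(abs(bhat))) return(bhat)
    t <- uniroot(function(t) sum(pmax(abs(bhat) - t, 0)) - L,
                 c(0, max(abs(bhat))))$root
    sign(bhat) * pmax(abs(bhat) - t, 0)
  }
  for (m in seq(200, 2000, by = 200)) {
    bm <- boost_coef(fit, m)[1:5]
    expect_lt(max(abs(bm - soft(sum(abs(bm))))) / max(abs(bhat)), 0.05)
  }
})

test_that("penalized boosting preferentially selects the high-variance covariate", {
  # identical standardized association, variances 1 vs 4
  first_pick <- function(seed) {
    set.seed(seed)
    z1 <- rnorm(150); z2 <- rnorm(150)
    y <- rbinom(150, 1, plogis(0.5 * scale(z1) + 0.5 * scale(z2)))
    x <- cbind(z1, 2 * z2)
    boost_fit(x, y, "logistic", steps = 1, nu = 0.1)$selected[1]
  }
  picks <- vapply(1:60, first_pick, integer(1))
  expect_gt(mean(picks == 2), 0.5)

  # the score statistic itself explains the preference: direct evaluation
  set.seed(1)
  z <- matrix(rnorm(300), 150)
  y <- rbinom(150, 1, plogis(0.5 * scale(z[, 1]) + 0.5 * scale(z[, 2])))
  x <- cbind(z[, 1], 2 * z[, 2])
  p0 <- mean(y)                     # intercept-only fit
  w <- rep(p0 * (1 - p0), 150)
  U <- crossprod(x, y - p0)
  I <- crossprod(x^2, w)
  stat <- U^2 / (I + 9 * sum(w))    # nu = 0.1 penalty at the null fit
  f <- boost_fit(x, y, "logistic", steps = 1, nu = 0.1)
  expect_identical(f$selected[1], unname(which.max(stat)))
})

test_that("rescaling a null covariate raises its selection frequency", {
  sel_freq <- function(scale_factor) {
    mean(vapply(1:40, function(s) {
      set.seed(s + 500)
      x <- matrix(rnorm(100 * 10), 100)
      x[, 7] <- x[, 7] * scale_factor
      y <- rbinom(100, 1, 0.5)
      7L %in% selected_set(boost_fit(x, y, "logistic", steps = 5, nu = 0.1))
    }, logical(1)))
  }
  expect_gt(sel_freq(10), sel_freq(1))
})

test_that("the (partial) log-likelihood never decreases along the path", {
  set.seed(3)
  x <- matrix(rnorm(120 * 30), 120)
  y <- rbinom(120, 1, plogis(x[, 1] - x[, 2]))
  fl <- boost_fit(x, y, "logistic", steps = 60, nu = 0.1, mandatory = 5L)
  expect_true(all(diff(fl$loglik) > -1e-8))

  sv <- make_survival(n = 90, seed = 4)
  fc <- boost_fit(sv$x, survival::Surv(sv$time, sv$event), "cox",
                  steps = 60, nu = 0.1)
  expect_true(all(diff(fc$loglik) > -1e-8))
})

test_that("cox boosting agrees with the partial-likelihood oracle at zero penalty", {
  sv <- make_survival(n = 100, seed = 5)
  fit <- boost_fit(sv$x, survival::Surv(sv$time, sv$event), "cox",
                   steps = 500, penalty = 0)
  oracle <- survival::coxph(survival::Surv(sv$time, sv$event) ~ sv$x,
                            ties = "breslow")
  expect_equal(fit$beta, unname(coef(oracle)), tolerance = 1e-5)
})

test_that("mandatory covariates are refreshed unpenalized and stay in the model", {
  sv <- make_survival(n = 100, seed = 6)
  fit <- boost_fit(sv$x, survival::Surv(sv$time, sv$event), "cox",
                   mandatory = 1:2, steps = 5, nu = 0.1)
  # with only the mandatory block ever updated and no signal elsewhere
  # selected, the block converges to the unpenalized two-covariate fit
  # when boosting adds nothing
  fit2 <- boost_fit(sv$x[, 1:2], survival::Surv(sv$time, sv$event), "cox",
                    mandatory = 1:2, steps = 10, nu = 0.1)
  oracle <- survival::coxph(survival::Surv(sv$time, sv$event) ~ sv$x[, 1:2],
                            ties = "breslow")
  expect_equal(fit2$beta, unname(coef(oracle)), tolerance = 1e-8)
  # support of the penalized part never shrinks along the path
  sel <- fit$selected[fit$selected > 0]
  expect_true(all(!sel %in% 1:2))
})

test_that("ridge closed forms reproduce OLS, the scaling identity, and shrinkage", {
  set.seed(8)
  X <- scale(matrix(rnorm(20 * 5), 20), scale = FALSE)
  y <- rnorm(20)
  expect_equal(ridge_closed_form(X, y, 0),
               unname(coef(lm(y ~ X - 1))), tolerance = 1e-10)

  # common-penalty raw ridge = rescaled standardized ridge with
  # per-covariate penalties lambda / s_j^2
  lam <- 3.14
  s <- apply(X, 2, sd)
  expect_equal(ridge_closed_form(X, y, lam),
               ridge_standardized(X, y, lam / s^2)$coef_rescaled,
               tolerance = 1e-10)

  # norm shrinks monotonically in lambda
  norms <- vapply(c(0, 1, 10, 100, 1e4),
                  function(l) sqrt(sum(ridge_closed_form(X, y, l)^2)),
                  numeric(1))
  expect_true(all(diff(norms) < 0))

  # p > n at zero penalty is singular
  Xbig <- matrix(rnorm(5 * 10), 5)
  expect_error(ridge_closed_form(Xbig, rnorm(5), 0), "rank")
})

test_that("lasso cox path satisfies KKT and matches its oracles at the ends", {
  set.seed(9)
  n <- 80
  x <- matrix(rnorm(n * 10), n)
  tm <- rexp(n, exp(0.7 * x[, 1] - 0.5 * x[, 2]))
  ev <- rbinom(n, 1, 0.8)
  fit <- lasso_cox_fit(x, tm, ev, mandatory = 3L)
  for (s in fit$lambda[c(3, 15, 35)])
    expect_lt(lasso_kkt_violation(fit, x, s), 1e-6)

  # above the critical penalty nothing penalized enters and the mandatory
  # block equals the unpenalized Cox fit on it alone
  b_top <- lasso_coef(fit, max(fit$lambda))
  expect_true(all(b_top[-3] == 0))
  oracle_m <- survival::coxph(survival::Surv(tm, ev) ~ x[, 3],
                              ties = "breslow")
  expect_equal(b_top[3], unname(coef(oracle_m)), tolerance = 1e-6)

  # lambda -> 0 with p < events matches the unpenalized partial-likelihood fit
  fit0 <- lasso_cox_fit(x[, 1:4], tm, ev,
                        lambda = c(0.2, 0.1, 0.05, 0.01, 1e-3, 1e-6))
  oracle <- survival::coxph(survival::Surv(tm, ev) ~ x[, 1:4],
                            ties = "breslow")
  expect_equal(lasso_coef(fit0, 1e-6), unname(coef(oracle)),
               tolerance = 1e-4)

  # support grows (near-)monotonically as lambda decreases on a 50 x 10
  # problem; isolated drops are logged, not silently accepted
  set.seed(10)
  x2 <- matrix(rnorm(50 * 10), 50)
  tm2 <- rexp(50, exp(0.8 * x2[, 1])); ev2 <- rbinom(50, 1, 0.9)
  f2 <- lasso_cox_fit(x2, tm2, ev2)
  supp <- lapply(f2$lambda, function(s) which(lasso_coef(f2, s) != 0))
  drops <- sum(vapply(seq_len(length(supp) - 1), function(i)
    length(setdiff(supp[[i]], supp[[i + 1]])), numeric(1)))
  expect_lte(drops, 2)

  expect_error(lasso_cox_fit(x, tm, rep(0, n)), "event")
  expect_error(lasso_cox_fit(x, tm, ev, lambda = c(0.1, 0.2)), "decreasing")
})

test_that("cross-validated step selection matches a brute-force LOO enumeration", {
  set.seed(11)
  x <- matrix(rnorm(30 * 4), 30)
  y <- rbinom(30, 1, plogis(1.5 * x[, 1]))
  cv <- cv_tune(x, y, "logistic", "boost", folds = 30, seed = 3, steps = 10)
  fid <- make_folds(y, 30, 3)
  crit <- rep(0, 11)
  for (k in 1:30) {
    f <- boost_fit(x[fid != k, , drop = FALSE], y[fid != k], "logistic",
                   steps = 10)
    eta <- boost_eta_path(f, x[fid == k, , drop = FALSE])
    yk <- y[fid == k]
    p <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
    crit <- crit + as.numeric(yk * log(p) + (1 - yk) * log(1 - p))
  }
  expect_identical(cv$best, which.max(crit) - 1L)
  expect_equal(cv$criterion, crit)
})

test_that("cross-validation stops early on noise and keeps a strong signal", {
  # pure noise: chosen step count stays small (at n = 200 chance
  # full-sample correlations are too weak to masquerade as signal)
  chosen <- vapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(rnorm(200 * 30), 200)
    y <- rbinom(200, 1, 0.5)
    cv_tune(x, y, "logistic", "boost", folds = 5, seed = s, steps = 30)$best
  }, integer(1))
  expect_gte(mean(chosen <= 3), 0.8)

  # single strong covariate: it is in the CV-stopped model
  kept <- vapply(1:10, function(s) {
    set.seed(s + 100)
    x <- matrix(rnorm(80 * 15), 80)
    y <- rbinom(80, 1, plogis(2 * x[, 1]))
    cv <- cv_tune(x, y, "logistic", "boost", folds = 5, seed = s, steps = 30)
    fit <- boost_fit(x, y, "logistic", steps = max(cv$best, 0))
    1L %in% selected_set(fit)
  }, logical(1))
  expect_gte(mean(kept), 0.95)
})

test_that("cox cross-validation uses stratified folds and the lasso route works", {
  sv <- make_survival(n = 120, seed = 12)
  y <- survival::Surv(sv$time, sv$event)
  fid <- make_folds(sv$event, 10, 5)
  expect_equal(length(unique(fid)), 10)
  # stratification: event counts per fold differ by at most 1
  tab <- table(fid[sv$event == 1])
  expect_lte(diff(range(tab)), 1)

  cvb <- cv_tune(sv$x, y, "cox", "boost", folds = 5, seed = 2, steps = 20)
  expect_true(cvb$best >= 0 && cvb$best <= 20)
  cvl <- cv_tune(sv$x, y, "cox", "lasso", folds = 5, seed = 2)
  expect_true(is.finite(cvl$best) && cvl$best > 0)
})
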