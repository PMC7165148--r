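test_that("with no random blocks the posterior matches the conjugate normal fixed-effect solution", {
  set.seed(1)
  n <- 150
  d <- tibble::tibble(x = rnorm(n))
  d$y <- 1 + 2 * d$x + rnorm(n)
  # pin the residual variance at 1 with an overwhelming prior: the fixed
  # effects then have the closed-form Gaussian posterior
  fit <- gibbs_lmm(d, y ~ x, mcmc = mcmc_config(12000, 2000, 5, seed = 2),
                   resid_prior = lmm_prior(1, 1e8), beta_prior_var = 1e4)
  X <- cbind(1, d$x)
  Vn <- solve(crossprod(X) + diag(2) / 1e4)
  mun <- Vn %*% crossprod(X, d$y)
  means <- colMeans(fit$draws[, 1:2])
  sds <- apply(fit$draws[, 1:2], 2, sd)
  expect_equal(unname(means), as.numeric(mun), tolerance = 0.01)
  expect_equal(unname(sds), sqrt(diag(Vn)), tolerance = 0.08)
})

test_that("in the diffuse-prior limit fixed effects agree with OLS", {
  set.seed(3)
  d <- tibble::tibble(x = rnorm(200))
  d$y <- 1 + 2 * d$x + rnorm(200)
  fit <- gibbs_lmm(d, y ~ x, mcmc = fast_mcmc(4))
  ols <- coef(lm(y ~ x, d))
  sm <- tidy(fit)
  psd <- apply(fit$draws[, 1:2], 2, sd)
  expect_true(all(abs(sm$posterior_mean - ols) < 3 * psd))
})

test_that("collapsing identical rows to weighted sufficient statistics leaves the chain unchanged", {
  set.seed(4)
  g <- sample(1:6, 400, TRUE)
  d <- tibble::tibble(y = rnorm(400, g, 1), g = factor(g))
  full <- gibbs_lmm(d, y ~ 1, random = list(ranef_block("g")),
                    mcmc = fast_mcmc(5))
  cells <- d |>
    dplyr::group_by(g) |>
    dplyr::summarise(w = dplyr::n(), ss = sum((y - mean(y))^2),
                     y = mean(y), .groups = "drop")
  coll <- gibbs_lmm(cells, y ~ 1, random = list(ranef_block("g")),
                    weights = "w", ss_extra = sum(cells$ss),
                    mcmc = fast_mcmc(5))
  expect_equal(full$draws[, c("(Intercept)", "var_g", "var_residual")],
               coll$draws[, c("(Intercept)", "var_g", "var_residual")],
               tolerance = 1e-10)
})

test_that("random-intercept variance components are recovered across seeded replicates", {
  reps <- 25
  cover <- logical(reps)
  rel_err <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(100 + r)
    g <- rep(1:30, each = 20)
    u <- rnorm(30, 0, 2)
    d <- tibble::tibble(y = 5 + u[g] + rnorm(600), g = factor(g))
    fit <- gibbs_lmm(d, y ~ 1, random = list(ranef_block("g")),
                     mcmc = mcmc_config(4000, 800, 4, seed = 200 + r))
    vg <- fit$draws[, "var_g"]
    h <- hpd_interval(vg)
    cover[r] <- h[["lower"]] <= 4 && h[["upper"]] >= 4
    rel_err[r] <- abs(mean(vg) - 4) / 4
  }
  expect_gte(mean(cover), 0.9)
  expect_lt(median(rel_err), 0.3)
})

test_that("zero true group variance concentrates the posterior near zero", {
  set.seed(6)
  g <- rep(1:20, each = 15)
  d <- tibble::tibble(y = rnorm(300, 3, 1), g = factor(g))
  fit <- gibbs_lmm(d, y ~ 1, random = list(ranef_block("g")),
                   mcmc = fast_mcmc(7))
  expect_lt(median(fit$draws[, "var_g"]),
            median(fit$draws[, "var_residual"]) / 10)
})

test_that("correlated random slopes shrink toward but track the per-group OLS slopes", {
  set.seed(8)
  G <- 15; nper <- 60
  g <- rep(1:G, each = nper)
  x <- rep(seq(-2, 2, length.out = nper), G)
  u0 <- rnorm(G, 0, 2); u1 <- rnorm(G, 0, 1)
  d <- tibble::tibble(y = 1 + u0[g] + u1[g] * x + rnorm(G * nper, 0, 1),
                      g = factor(g), x = x)
  fit <- gibbs_lmm(d, y ~ 1, random = list(ranef_block("g", slope = "x")),
                   mcmc = fast_mcmc(9))
  est <- colMeans(ranef_draws(fit, "g", "slope"))
  ols <- sapply(split(d, d$g), function(dd) coef(lm(y ~ x, dd))[[2]])
  expect_lt(sqrt(mean((est - u1)^2)), 0.3)
  expect_gt(cor(est, ols), 0.95)
})

test_that("posterior summaries are stable under a permutation of the rows", {
  set.seed(10)
  g <- sample(1:8, 300, TRUE)
  d <- tibble::tibble(x = rnorm(300))
  d$y <- 2 + d$x + rnorm(8)[g] + rnorm(300)
  d$g <- factor(g)
  fit1 <- gibbs_lmm(d, y ~ x, random = list(ranef_block("g")),
                    mcmc = fast_mcmc(11))
  perm <- sample(nrow(d))
  fit2 <- gibbs_lmm(d[perm, ], y ~ x, random = list(ranef_block("g")),
                    mcmc = fast_mcmc(11))
  s1 <- tidy(fit1); s2 <- tidy(fit2)
  mcse <- apply(fit1$draws[, 1:2], 2, sd) / sqrt(s1$n_eff)
  expect_true(all(abs(s1$posterior_mean - s2$posterior_mean) < 4 * mcse))
})

test_that("a rank-deficient fixed design fails naming the aliased column", {
  d <- tibble::tibble(x = rnorm(20))
  d$x2 <- 2 * d$x
  d$y <- rnorm(20)
  expect_error(gibbs_lmm(d, y ~ x + x2, mcmc = fast_mcmc(1)),
               regexp = "x2", class = "mothshift_rank_error")
})

test_that("HPD intervals are shortest, earliest on ties, and inside the draw range", {
  expect_equal(hpd_interval(rep(3.5, 100)), c(lower = 3.5, upper = 3.5))
  h <- hpd_interval(1:100, 0.95)
  expect_equal(h[["upper"]] - h[["lower"]], 94)
  expect_equal(h[["lower"]], 1)  # earliest of the tied windows
  set.seed(12)
  z <- rnorm(1e5)
  hz <- hpd_interval(z)
  expect_equal(hz[["lower"]], -1.96, tolerance = 0.05)
  expect_equal(hz[["upper"]], 1.96, tolerance = 0.05)
  for (i in 1:20) {
    x <- rgamma(500, shape = 2)
    h <- hpd_interval(x, 0.9)
    eq <- quantile(x, c(0.05, 0.95))
    expect_gte(h[["lower"]], min(x))
    expect_lte(h[["upper"]], max(x))
    expect_lte(h[["upper"]] - h[["lower"]], eq[[2]] - eq[[1]] + 1e-12)
  }
  expect_error(hpd_interval(rnorm(100), prob = 1.2),
               class = "mothshift_config_error")
})

test_that("effective sample size matches its iid and AR(1) limits", {
  set.seed(13)
  x <- rnorm(1e4)
  expect_gt(effective_sample_size(x), 0.8e4)
  expect_lt(effective_sample_size(x), 1.2e4)
  phi <- 0.5
  ar <- as.numeric(arima.sim(list(ar = phi), 1e5))
  ratio <- effective_sample_size(ar) / 1e5
  expect_equal(ratio, (1 - phi) / (1 + phi), tolerance = 0.2 / 3)
  expect_equal(effective_sample_size(rep(2, 500)), 1)
})

test_that("prior sensitivity refits shift well-identified posteriors by less than half an SD", {
  set.seed(14)
  g <- rep(1:25, each = 12)
  d <- tibble::tibble(x = rnorm(300))
  d$y <- 1 + 0.8 * d$x + rnorm(25, 0, 1.5)[g] + rnorm(300)
  d$g <- factor(g)
  fit <- gibbs_lmm(d, y ~ x, random = list(ranef_block("g")),
                   mcmc = fast_mcmc(15))
  sens <- prior_sensitivity(fit)
  fixed <- sens[sens$parameter %in% c("(Intercept)", "x"), ]
  expect_true(all(fixed$shift_sd < 0.5))
})

test_that("tidy and glance expose the broom-style surfaces", {
  set.seed(16)
  d <- tibble::tibble(x = rnorm(50))
  d$y <- d$x + rnorm(50)
  fit <- gibbs_lmm(d, y ~ x, mcmc = fast_mcmc(17))
  td <- tidy(fit)
  expect_named(td, c("parameter", "posterior_mean", "hpd_lower",
                     "hpd_upper", "n_eff"))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 50)
  expect_equal(gl$n_draws, nrow(fit$draws))
})
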