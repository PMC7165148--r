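test_that("period aggregation pools counts, fills absences and yields 99 assemblages", {
  sim <- small_sim()
  yrs <- sort(unique(sim$catches$year))
  ps <- period_spec(start_year = yrs[1], period_length = 4,
                    n_periods = 4, end_year = yrs[1] + 14)
  asm <- aggregate_periods(sim$catches, ps)
  expect_equal(dplyr::n_distinct(paste(asm$trap_id, asm$period)), 44L)
  # conservation: pooled counts equal the sum of the yearly counts
  pooled <- sum(asm$n)
  direct <- sim$catches |>
    dplyr::filter(year <= ps$end_year) |>
    dplyr::summarise(n = sum(count))
  expect_equal(pooled, direct$n)
  # a cell with nine individuals maps to log10(10) = 1
  one <- asm[asm$n == 9, ]
  if (nrow(one) > 0) expect_equal(one$value, rep(1, nrow(one)))
  # default specification tiles 1978-2012 into 9 periods, 11 x 9 = 99
  full <- period_spec()
  years <- 1978:2012
  idx <- pmin((years - full$start_year) %/% full$period_length + 1, full$n_periods)
  expect_equal(max(idx), 9)
  expect_equal(sum(idx == 9), 3)  # final period 2010-2012
  fake <- tibble::tibble(species = "x", trap_id = "T01", elevation_m = 340,
                         zone = "a", year = years, day = 200, count = 1L)
  expect_warning(asm99 <- aggregate_periods(fake, full), "no captures")
  expect_equal(dplyr::n_distinct(paste(asm99$trap_id, asm99$period)), 99L)
})

test_that("Bray-Curtis follows its closed form and matches the community-ecology standard", {
  m <- rbind(a = c(1, 2), b = c(2, 0), c = c(1, 2))
  bc <- bray_curtis(m)
  expect_equal(bc["a", "b"], 0.6)
  expect_equal(bc["a", "c"], 0)
  expect_equal(bc, t(bc))
  disjoint <- rbind(c(3, 0, 0), c(0, 2, 5))
  expect_equal(bray_curtis(disjoint)[1, 2], 1)
  expect_warning(zz <- bray_curtis(rbind(c(0, 0), c(0, 0))), "All-zero")
  expect_equal(zz[1, 2], 0)
  skip_if_not_installed("vegan")
  set.seed(71)
  r <- matrix(rexp(60), 10, 6)
  expect_equal(unname(bray_curtis(r)),
               unname(as.matrix(vegan::vegdist(r, "bray"))),
               tolerance = 1e-12)
})

test_that("isotonic regression equals the exhaustive constrained least-squares oracle", {
  expect_equal(isotonic_fit(1:6, c(1, 2, 3, 4, 5, 6)), c(1, 2, 3, 4, 5, 6))
  expect_equal(isotonic_fit(1:5, c(5, 4, 3, 2, 1)), rep(3, 5))
  set.seed(72)
  for (i in 1:100) {
    n <- sample(3:8, 1)
    y <- rnorm(n)
    expect_equal(isotonic_fit(seq_len(n), y), isotonic_brute(y),
                 tolerance = 1e-10)
  }
})

test_that("tied dissimilarities are left unconstrained among themselves (primary treatment)", {
  dis <- c(1, 1, 2)
  dist <- c(0.9, 0.2, 0.5)
  fit <- isotonic_fit(dis, dist)
  # ties ordered by distance: 0.2, 0.9 then 0.5 pools with 0.9
  expect_equal(sort(fit[dis == 1]), c(0.2, 0.7))
  expect_equal(fit[3], 0.7)
})

test_that("three equidistant points embed exactly and stress is invariant to isometries", {
  D <- matrix(1, 3, 3); diag(D) <- 0
  o <- nmds(D, n_restarts = 3, seed = 1)
  expect_lt(o$stress, 1e-3)
  expect_lte(o$stress, min(o$restart_stress) + 1e-12)
  # rotation/translation/scaling of a configuration leave stress unchanged
  set.seed(73)
  X <- matrix(rnorm(24), 12, 2)
  D2 <- as.matrix(dist(X))
  stress_of <- function(Y) {
    cd <- as.numeric(dist(Y))
    dv <- D2[upper.tri(D2)]
    dh <- isotonic_fit(dv, cd)
    sqrt(sum((cd - dh)^2) / sum(cd^2))
  }
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(stress_of(X), stress_of(sweep(3.2 * X %*% R, 2, c(5, -2))),
               tolerance = 1e-8)
})

test_that("planar distance data are recovered with near-zero stress", {
  set.seed(74)
  P <- matrix(rnorm(40), 20, 2)
  o <- nmds(as.matrix(dist(P)), n_restarts = 5, seed = 2)
  expect_lt(o$stress, 0.01)
  # unit-RMS scaling and centring of the returned configuration
  expect_equal(colMeans(o$points), c(NMDS1 = 0, NMDS2 = 0), tolerance = 1e-8)
  expect_equal(sqrt(mean(dist(o$points)^2)), 1, tolerance = 1e-6)
})

test_that("the ordination agrees with the field-standard implementation on assemblage data", {
  skip_if_not_installed("vegan")
  sim <- small_sim()
  yrs <- sort(unique(sim$catches$year))
  ps <- period_spec(start_year = yrs[1], period_length = 4, n_periods = 4,
                    end_year = yrs[1] + 14)
  mat <- assemblage_matrix(aggregate_periods(sim$catches, ps))
  o <- nmds(bray_curtis(mat), n_restarts = 8, seed = 3)
  ref <- vegan::metaMDS(mat, k = 2, trace = 0)
  expect_lt(abs(o$stress - ref$stress), 0.02)
  expect_gt(vegan::protest(ref$points, o$points, permutations = 49)$t0, 0.95)
})

test_that("envfit reports exact alignment and rejects constant variables", {
  set.seed(75)
  X <- matrix(rnorm(60), 30, 2)
  env <- data.frame(v = X[, 1])
  ef <- envfit_ord(X, env, n_perm = 199, seed = 4)
  expect_equal(abs(ef$axis1), 1, tolerance = 1e-8)
  expect_equal(ef$axis2, 0, tolerance = 1e-8)
  expect_equal(ef$r2, 1, tolerance = 1e-10)
  expect_equal(ef$p, 1 / 200)
  expect_error(envfit_ord(X, data.frame(v = rep(1, 30))),
               class = "mothshift_data_error")
})

test_that("ordered factors are vector-fitted as integer ranks; factors get centroid r2", {
  set.seed(76)
  X <- matrix(rnorm(72), 36, 2)
  of <- factor(rep(1:9, each = 4), ordered = TRUE)
  e1 <- envfit_ord(X, data.frame(period = of), n_perm = 99, seed = 5)
  e2 <- envfit_ord(X, data.frame(period = as.integer(of)), n_perm = 99, seed = 5)
  expect_equal(e1$r2, e2$r2, tolerance = 1e-12)
  expect_equal(e1$type, "vector")
  fac <- factor(rep(c("x", "y", "z"), each = 12))
  e3 <- envfit_ord(X, data.frame(zone = fac), n_perm = 99, seed = 6)
  expect_equal(e3$type, "factor")
  # centroid r2 equals the among-group share of the configuration SS
  Xc <- scale(X, scale = FALSE)
  within <- sum(unlist(lapply(split(as.data.frame(Xc), fac), function(g) {
    sum(sweep(as.matrix(g), 2, colMeans(as.matrix(g)))^2)
  })))
  expect_equal(e3$r2, 1 - within / sum(Xc^2), tolerance = 1e-10)
})

test_that("envfit matches the field-standard vector fit", {
  skip_if_not_installed("vegan")
  set.seed(77)
  X <- matrix(rnorm(60), 30, 2)
  v <- X[, 1] * 0.8 + rnorm(30, 0, 0.5)
  ef <- envfit_ord(X, data.frame(v = v), n_perm = 199, seed = 7)
  vf <- vegan::envfit(X, data.frame(v = v), permutations = 199)
  expect_equal(ef$r2, unname(vf$vectors$r), tolerance = 1e-8)
  expect_equal(abs(c(ef$axis1, ef$axis2)), abs(as.numeric(vf$vectors$arrows)),
               tolerance = 1e-6)
})

test_that("dispersion is zero for coincident points and invariant to rotation", {
  X <- rbind(matrix(1, 4, 2), matrix(rnorm(8), 4, 2))
  g <- rep(c("same", "spread"), each = 4)
  disp <- assemblage_dispersion(X, g)
  expect_equal(disp$dispersion[disp$group == "same"], 0)
  th <- 1.1; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  disp_rot <- assemblage_dispersion(X %*% R, g)
  expect_equal(disp$dispersion, disp_rot$dispersion, tolerance = 1e-10)
  expect_warning(assemblage_dispersion(X[1:5, ], c(rep("a", 4), "b")),
                 "single")
})

test_that("injected tundra stochasticity yields the largest dispersion on the summit", {
  hits <- sapply(1:5, function(r) {
    w <- simulate_weather(weather_config(n_years = 17, seed = 80 + r))
    sim <- generate_catches(w, species = small_species_set(), seed = 90 + r,
                            zone_noise_sd = c(a = .05, b = .05, c = .05, d = .4))
    yrs <- sort(unique(sim$catches$year))
    ps <- period_spec(start_year = yrs[1], period_length = 4, n_periods = 4,
                      end_year = yrs[1] + 14)
    mat <- assemblage_matrix(aggregate_periods(sim$catches, ps))
    o <- nmds(bray_curtis(mat), n_restarts = 4, seed = r)
    lay <- trap_layout()
    zone <- lay$zone[match(sub(":.*", "", rownames(mat)), lay$trap_id)]
    disp <- assemblage_dispersion(o, zone)
    disp$group[which.max(disp$dispersion)] == "d"
  })
  expect_gte(mean(hits), 0.8)
})
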