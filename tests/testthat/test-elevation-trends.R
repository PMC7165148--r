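test_that("centre of gravity is the count-weighted mean elevation", {
  expect_equal(center_of_gravity(rep(400, 5), rep(10, 5)), 400)
  expect_equal(center_of_gravity(c(340, 470), c(10, 10)), 405)
  expect_equal(center_of_gravity(c(360, 470), c(3, 1)), 387.5)
  expect_error(center_of_gravity(c(340, 400), c(0, 0)),
               class = "mothshift_data_error")
})

test_that("centre of gravity is scale invariant and bounded by the trap range", {
  set.seed(1)
  for (i in 1:20) {
    e <- sample(trap_layout()$elevation_m, 6)
    n <- rpois(6, 20) + 1
    cog <- center_of_gravity(e, n)
    expect_equal(center_of_gravity(e, 7 * n), cog)
    expect_gte(cog, min(e))
    expect_lte(cog, max(e))
  }
})

test_that("annual COG skips zero-count species-years", {
  catches <- tibble::tibble(
    species = c("a", "a", "b"), year = c(2000, 2001, 2000),
    elevation_m = c(400, 420, 350), count = c(5L, 0L, 2L)
  )
  cy <- cog_by_year(catches)
  expect_equal(nrow(cy), 2L)
  expect_equal(cy$cog[cy$species == "a"], 400)
})

test_that("standardization uses the sample SD and reproduces hand values", {
  s <- standardize_historical_range(c(340, 400, 460))
  expect_equal(s$z, c(-1, 0, 1))
  expect_equal(s$z_sq, c(1, 0, 1))
  two <- standardize_historical_range(c(350, 450))
  expect_equal(two$z, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  set.seed(2)
  any_in <- standardize_historical_range(rnorm(30, 400, 40))
  expect_equal(mean(any_in$z), 0, tolerance = 1e-12)
  expect_equal(sd(any_in$z), 1, tolerance = 1e-12)
  expect_error(standardize_historical_range(rep(5, 4)),
               class = "mothshift_data_error")
})

test_that("trend classification is a pure function of the HPD signs", {
  tbl <- tibble::tibble(hpd_lower = c(0.1, -0.2, -0.5, 0.0),
                        hpd_upper = c(0.5, 0.3, -0.1, 0.2))
  expect_equal(classify_trends(tbl),
               tibble::tibble(increased = 1L, stable = 2L, decreased = 1L))
  straddle <- tibble::tibble(hpd_lower = rep(-1, 7), hpd_upper = rep(1, 7))
  expect_equal(classify_trends(straddle)$stable, 7L)
  set.seed(3)
  rnd <- tibble::tibble(hpd_lower = rnorm(50), hpd_upper = NA_real_)
  rnd$hpd_upper <- rnd$hpd_lower + rexp(50)
  brute <- c(sum(rnd$hpd_lower > 0),
             sum(rnd$hpd_lower <= 0 & rnd$hpd_upper >= 0),
             sum(rnd$hpd_upper < 0))
  expect_equal(unlist(classify_trends(rnd), use.names = FALSE), brute)
})

test_that("hierarchical species slopes recover drift and agree with the two-stage check", {
  sim <- small_sim()
  sl <- suppressMessages(species_slopes(sim$catches, mcmc = fast_mcmc(21)))
  truth <- setNames(small_species_set()$elevation_drift,
                    small_species_set()$species_id)
  abundant <- sl$species[sl$species %in% c("spA", "spB", "spC", "spD", "spF")]
  for (spp in abundant) {
    row <- sl[sl$species == spp, ]
    expect_lt(abs(row$slope - truth[[spp]]), 0.35)
    expect_lt(abs(row$slope - row$slope_ols), 0.12)
  }
  expect_equal(sl$classification,
               ifelse(sl$hpd_lower > 0, "increased",
                      ifelse(sl$hpd_upper < 0, "decreased", "stable")))
})

test_that("species observed in a single year are excluded with a message", {
  sim <- small_sim()
  extra <- sim$catches[1, ]
  extra$species <- "one_year_wonder"
  expect_message(
    sl <- species_slopes(dplyr::bind_rows(sim$catches, extra),
                         mcmc = fast_mcmc(22)),
    "one_year_wonder")
  expect_false("one_year_wonder" %in% sl$species)
})

test_that("historical COG pools the first five years", {
  catches <- tibble::tibble(
    species = "a",
    year = rep(2000:2006, each = 2),
    elevation_m = rep(c(360, 470), 7),
    count = c(rep(1L, 10), rep(100L, 4))
  )
  # years 2000-2004 contribute 5 each at both elevations -> midpoint
  expect_equal(historical_cog(catches)$cog_hist, 415)
})

test_that("the trait model recovers an injected over-wintering offset and a quadratic sign", {
  roster <- make_species_roster(60, seed = 31)
  gt <- generate_traits(roster, c("larva-fullgrown-or-pupa" = 20), seed = 32,
                        baseline = 25)
  set.seed(33)
  slopes <- tibble::tibble(species = gt$truth$species,
                           slope = gt$truth$true_slope + rnorm(60, 0, 0.03))
  traits <- gt$traits
  traits$cog_hist <- runif(60, 350, 460)
  tm <- trait_model(slopes, traits, fast_mcmc(34))
  ow <- tm[tm$parameter == "overwinter_stagelarva-fullgrown-or-pupa", ]
  expect_gt(ow$hpd_lower, 0)
  expect_lt(abs(ow$posterior_mean - 20), 8)

  # inverted-U dependence on the historical range gives a negative quadratic
  z <- standardize_historical_range(traits$cog_hist)$z
  slopes2 <- tibble::tibble(species = gt$truth$species,
                            slope = (30 - 8 * z^2) / 100 + rnorm(60, 0, 0.03))
  tm2 <- trait_model(slopes2, traits, fast_mcmc(35))
  expect_lt(tm2$hpd_upper[tm2$parameter == "z_sq"], 0)
})

test_that("null trait structure leaves contrasts straddling zero", {
  roster <- make_species_roster(60, seed = 36)
  set.seed(37)
  slopes <- tibble::tibble(species = roster$species_id,
                           slope = rnorm(60, 0.3, 0.1))
  traits <- generate_traits(roster, numeric(0), seed = 38,
                            taxo_sd = c(genus = 0, family = 0, superfamily = 0))$traits
  traits$cog_hist <- runif(60, 350, 460)
  tm <- trait_model(slopes, traits, fast_mcmc(39))
  contrasts <- tm[grepl("overwinter|host|life", tm$parameter), ]
  covered <- contrasts$hpd_lower <= 0 & contrasts$hpd_upper >= 0
  expect_gte(mean(covered), 0.85)
})

test_that("Moran's I follows its closed forms and a brute-force oracle", {
  expect_equal(morans_i(c(1, 1, 2, 2), c("p1", "p1", "p2", "p2")), 1)
  # permutation expectation is -1/(n-1)
  set.seed(41)
  x <- rnorm(12)
  g <- rep(letters[1:4], each = 3)
  perms <- replicate(20000, morans_i(sample(x), g))
  expect_lt(abs(mean(perms) - (-1 / 11)), 0.006)
  # brute-force double loop on a random fixture
  x2 <- rnorm(9); g2 <- rep(c("u", "v", "w"), each = 3)
  n <- 9; xc <- x2 - mean(x2); num <- 0; s0 <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i != j && g2[i] == g2[j]) { num <- num + xc[i] * xc[j]; s0 <- s0 + 1 }
  }
  expect_equal(morans_i(x2, g2), (n / s0) * num / sum(xc^2), tolerance = 1e-12)
  expect_error(morans_i(rnorm(5), letters[1:5]), class = "mothshift_data_error")
})

test_that("Moran's I matches the phylogenetics-package implementation on balanced groups", {
  skip_if_not_installed("ape")
  set.seed(42)
  x <- rnorm(12)
  g <- rep(letters[1:3], each = 4)
  w <- outer(g, g, "==") & !diag(12)
  expect_equal(morans_i(x, g), ape::Moran.I(x, w)$observed, tolerance = 1e-10)
})

test_that("values constant within well-separated groups push Moran's I towards its maximum", {
  g <- rep(c("a", "b", "c"), each = 4)
  x <- rep(c(-5, 0, 5), each = 4)
  expect_gt(morans_i(x, g), 0.9)
})
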