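make_audit_catches <- function() {
  # three species with hand-designed histories over a 35-year record
  rows <- list()
  add <- function(species, years, annual) {
    for (i in seq_along(years)) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        species = species, year = years[i], trap_id = "T01",
        elevation_m = 340, zone = "a", day = 200, count = as.integer(annual[i]))
    }
  }
  add("exactly7", 1978:2012, rep(7, 35))          # mean exactly 7 -> excluded
  add("rare_but_old", 1978:2006, rep(100, 29))    # 29 years only -> excluded
  add("good", 1978:2012, rep(c(40, 10), length.out = 35))  # qualifies
  dplyr::bind_rows(rows)
}

test_that("selection filters apply the strict boundaries of the wording", {
  sel <- select_species(make_audit_catches())
  expect_false(sel$in_base[sel$species == "exactly7"])     # "more than seven"
  expect_false(sel$in_base[sel$species == "rare_but_old"]) # "at least in 30"
  expect_true(sel$in_base[sel$species == "good"])
  g <- sel[sel$species == "good", ]
  expect_equal(g$n_years_observed, 35L)
  expect_equal(g$mean_annual_catch, mean(rep(c(40, 10), length.out = 35)))
  expect_equal(g$n_high_years, sum(rep(c(40, 10), length.out = 35) > 30))
})

test_that("selection audit counts equal the generator ledger", {
  sim <- small_sim()
  sel <- select_species(sim$catches)
  led <- sim$truth$cog |>
    dplyr::group_by(species) |>
    dplyr::summarise(n_years_observed = sum(realized_total > 0),
                     total = sum(realized_total),
                     n_high = sum(realized_total > 30), .groups = "drop")
  j <- dplyr::inner_join(sel, led, by = "species")
  expect_equal(j$n_years_observed.x, j$n_years_observed.y)
  expect_equal(j$mean_annual_catch, j$total / dplyr::n_distinct(sim$catches$year))
  expect_equal(j$n_high_years, j$n_high)
})

test_that("flight duration handles empty, step and Gaussian daily curves", {
  days <- 135:288
  zero <- tibble::tibble(day = days, mean_catch = 0)
  expect_equal(flight_period_duration(zero)$duration_days, 0L)

  step <- tibble::tibble(day = days,
                         mean_catch = ifelse(days >= 180 & days <= 209, 2, 0))
  # log10(3) = 0.477 > 0.2 on 30 days; allow the smoother 2 days at the edges
  d <- flight_period_duration(step)
  expect_lte(abs(d$duration_days - 30L), 2)

  # Gaussian curve with an analytic width above the threshold
  peak <- 4; s <- 9
  curve <- tibble::tibble(day = days,
                          mean_catch = peak * exp(-(days - 200)^2 / (2 * s^2)))
  thr <- 10^0.2 - 1
  width_true <- sum(curve$mean_catch > thr)
  dg <- flight_period_duration(curve)
  expect_lte(abs(dg$duration_days - width_true), 2)
})

test_that("flight duration falls back to the raw rule for sparse years", {
  days <- 135:288
  sparse <- tibble::tibble(day = days,
                           mean_catch = ifelse(days %in% c(200, 201, 202), 3, 0))
  expect_warning(d <- flight_period_duration(sparse), "Fewer than 5")
  expect_equal(d$duration_days, 3L)
})

test_that("duration is monotone in the threshold and in the catch scale", {
  sim <- small_sim()
  curves <- daily_mean_catch(
    dplyr::filter(sim$catches, species == "spA", year == min(year)),
    n_traps = 11, day_range = c(135, 288))
  durs <- sapply(c(0.1, 0.2, 0.4, 0.8),
                 function(th) flight_period_duration(curves, th)$duration_days)
  expect_true(all(diff(durs) <= 0))
  doubled <- dplyr::mutate(curves, mean_catch = 2 * mean_catch)
  expect_gte(flight_period_duration(doubled)$duration_days,
             flight_period_duration(curves)$duration_days)
  expect_lte(flight_period_duration(curves)$duration_days, 288 - 135 + 1)
})

test_that("flight-window weather covariates follow two-point arithmetic", {
  wconst <- tibble::tibble(day = 180:210, temp_c = 15)
  expect_equal(flight_weather(wconst, c(185, 200)),
               tibble::tibble(temp_mean = 15, temp_cv = 0, flagged = FALSE))
  w2 <- tibble::tibble(day = c(200, 201), temp_c = c(10, 20))
  fw <- flight_weather(w2, c(200, 201))
  expect_equal(fw$temp_mean, 15)
  expect_equal(fw$temp_cv, sd(c(10, 20)) / 15, tolerance = 1e-12)
  expect_equal(round(fw$temp_cv, 4), 0.4714)
  cold <- tibble::tibble(day = 135:150, temp_c = 3)
  expect_true(flight_weather(cold, c(135, 150))$flagged)
})

test_that("estimated flight windows match the generator ledger within two days", {
  sim <- small_sim()
  w <- small_weather()
  fp <- flight_period_table(dplyr::filter(sim$catches, species == "spA"),
                            w, n_traps = 11, day_range = c(135, 288))
  j <- dplyr::inner_join(fp, sim$truth$cog, by = c("species", "year"))
  expect_lt(mean(abs(j$duration_days - j$flight_width)), 3)
  # weather covariates are stable to small window perturbations
  shifted <- flight_weather(w[w$year == j$year[1], ],
                            c(j$first_day[1] + 2, j$last_day[1] - 2))
  orig <- flight_weather(w[w$year == j$year[1], ],
                         c(j$first_day[1], j$last_day[1]))
  expect_lt(abs(shifted$temp_mean - orig$temp_mean) / orig$temp_mean, 0.05)
})

test_that("the flight-period model recovers injected weather effects and a null year trend", {
  set.seed(51)
  species <- sprintf("fsp%02d", 1:20)
  grid <- tidyr::expand_grid(species = species, year = 1978:2007)
  grid$temp_mean <- rnorm(nrow(grid), 12, 1.5)
  grid$temp_cv <- runif(nrow(grid), 0.1, 0.5)
  grid$log_abundance <- rnorm(nrow(grid), 2, 0.4)
  sp_int <- rnorm(20, 0, 4)
  grid$duration_days <- 60 + sp_int[match(grid$species, species)] +
    0 * grid$year - 2 * grid$temp_mean - 5 * grid$temp_cv +
    2.5 * grid$temp_mean * grid$temp_cv + 5 * grid$log_abundance +
    rnorm(nrow(grid), 0, 3)
  fit <- flight_period_model(grid, fast_mcmc(52))
  get <- function(p) fit[fit$parameter == p, ]
  expect_lt(get("temp_mean")$hpd_upper, 0)
  expect_gt(get("temp_mean:temp_cv")$hpd_lower, 0)
  expect_gt(get("log_abundance")$hpd_lower, 0)
  yr <- get("year")
  expect_true(yr$hpd_lower <= 0 && yr$hpd_upper >= 0)
  expect_lt(abs(get("temp_mean")$posterior_mean - (-2)), 0.6)
})
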