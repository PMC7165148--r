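#' Multi-year period specification
#'
#' Tiles the monitoring span into consecutive periods (by default nine
#' 4-year periods over 1978-2012, the last one clipped to 3 years).
#'
#' @param start_year First year of the first period.
#' @param period_length Nominal period length in years.
#' @param n_periods Number of periods.
#' @param end_year Final year of the record (clips the last period).
#' @return List of class `period_spec`.
#' @export
period_spec <- function(start_year = 1978, period_length = 4, n_periods = 9,
                        end_year = 2012) {
  if (end_year < start_year) abort("`end_year` before `start_year`.",
                                   class = "mothshift_config_error")
  if (end_year > start_year + period_length * n_periods - 1) {
    abort("Periods do not cover the record.", class = "mothshift_config_error")
  }
  structure(list(start_year = start_year, period_length = period_length,
                 n_periods = n_periods, end_year = end_year),
            class = "period_spec")
}

#' Pool catches into trap-by-period assemblages
#'
#' Sums each species' catch per trap over each multi-year period and
#' log10(n + 1)-transforms the pooled totals. Every trap-period carries the
#' full shared species set (absences as zeros); a trap with no captures at
#' all in a period yields an all-zero assemblage with a warning. The
#' default layout and period specification give 99 assemblages (11 traps x
#' 9 periods).
#'
#' @param catches Catch records.
#' @param spec A [period_spec()].
#' @param layout Trap layout (defines the full trap set).
#' @return Tibble: `trap_id`, `period` (integer 1..n), `species`, `n`
#'   (pooled count), `value` (log10(n + 1)).
#' @export
aggregate_periods <- function(catches, spec = period_spec(),
                              layout = trap_layout()) {
  d <- catches |>
    dplyr::filter(.data$year >= spec$start_year, .data$year <= spec$end_year) |>
    dplyr::mutate(period = pmin(
      (.data$year - spec$start_year) %/% spec$period_length + 1L,
      spec$n_periods))
  species <- sort(unique(d$species))
  grid <- tidyr::expand_grid(trap_id = layout$trap_id,
                             period = seq_len(spec$n_periods),
                             species = species)
  pooled <- d |>
    dplyr::group_by(.data$trap_id, .data$period, .data$species) |>
    dplyr::summarise(n = sum(.data$count), .groups = "drop")
  out <- grid |>
    dplyr::left_join(pooled, by = c("trap_id", "period", "species")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  value = log10(.data$n + 1))
  empties <- out |>
    dplyr::group_by(.data$trap_id, .data$period) |>
    dplyr::summarise(tot = sum(.data$n), .groups = "drop") |>
    dplyr::filter(.data$tot == 0)
  if (nrow(empties) > 0) {
    warn(sprintf("%d trap-period assemblage(s) have no captures at all.",
                 nrow(empties)))
  }
  out
}

#' Assemblage matrix from long form
#'
#' @param assemblages Output of [aggregate_periods()].
#' @return Numeric matrix (assemblages x species) of log abundances, rows
#'   named `trap:period`.
#' @export
assemblage_matrix <- function(assemblages) {
  wide <- assemblages |>
    dplyr::mutate(id = paste(.data$trap_id, .data$period, sep = ":")) |>
    dplyr::select("id", "species", "value") |>
    tidyr::pivot_wider(names_from = "species", values_from = "value")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$id
  m
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)`, in [0, 1] for non-negative
#' data; a semimetric (triangle inequality not guaranteed). Two all-zero
#' assemblages are defined as identical (d = 0) with a warning.
#'
#' @param m Numeric matrix, rows = assemblages.
#' @return Symmetric dissimilarity matrix with the row names of `m`.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) abort("Need at least 2 assemblages.",
                         class = "mothshift_data_error")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  warned <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- sum(m[i, ] + m[j, ])
      if (denom == 0) {
        if (!warned) {
          warn("All-zero assemblage pair; dissimilarity defined as 0.")
          warned <- TRUE
        }
        d[i, j] <- d[j, i] <- 0
      } else {
        d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / denom
      }
    }
  }
  d
}

#' Least-squares monotone regression of distances on dissimilarities
#'
#' Pool-adjacent-violators fit of configuration distances as a
#' non-decreasing function of dissimilarity rank, using Kruskal's primary
#' treatment of ties: tied dissimilarities are unconstrained among
#' themselves (ties are pre-sorted by the distance value so the fit never
#' forces them together unnecessarily).
#'
#' @param dissimilarities,distances Paired numeric vectors.
#' @return Fitted monotone distances, in the input order.
#' @export
isotonic_fit <- function(dissimilarities, distances) {
  stopifnot(length(dissimilarities) == length(distances))
  ord <- order(dissimilarities, distances)
  fit <- pava_cpp(distances[ord], rep(1, length(ord)))
  out <- numeric(length(ord))
  out[ord] <- fit
  out
}

nmds_stress <- function(cdist, dhat) {
  sqrt(sum((cdist - dhat)^2) / sum(cdist^2))
}

nmds_run <- function(dvec, X, pair_i, pair_j, max_iter, tol) {
  n <- nrow(X)
  cd <- function(X) sqrt(rowSums((X[pair_i, , drop = FALSE] -
                                    X[pair_j, , drop = FALSE])^2))
  cdist <- cd(X)
  dhat <- isotonic_fit(dvec, cdist)
  stress <- nmds_stress(cdist, dhat)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # Guttman transform towards the current monotone targets
    ratio <- ifelse(cdist > 1e-12, dhat / cdist, 0)
    Xg <- X
    for (k in seq_len(ncol(X))) {
      diff_k <- X[pair_i, k] - X[pair_j, k]
      contrib <- ratio * diff_k
      acc <- numeric(n)
      acc_i <- tapply(contrib, pair_i, sum)
      acc_j <- tapply(contrib, pair_j, sum)
      acc[as.integer(names(acc_i))] <- acc[as.integer(names(acc_i))] + acc_i
      acc[as.integer(names(acc_j))] <- acc[as.integer(names(acc_j))] - acc_j
      Xg[, k] <- acc / (n - 1)
    }
    dir <- Xg - X
    step <- 1
    improved <- FALSE
    for (half in 1:20) {
      Xt <- X + step * dir
      cdt <- cd(Xt)
      dht <- isotonic_fit(dvec, cdt)
      st <- nmds_stress(cdt, dht)
      if (st < stress) {
        X <- Xt; cdist <- cdt; dhat <- dht
        improved <- TRUE
        if (abs(stress - st) < tol * stress || stress - st < 1e-12) {
          stress <- st
          converged <- TRUE
        } else {
          stress <- st
        }
        break
      }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    if (converged) break
  }
  list(X = X, stress = stress, converged = converged)
}

#' Nonmetric multidimensional scaling
#'
#' Minimizes Kruskal's stress-1,
#' `sqrt(sum((d_config - d_fitted)^2) / sum(d_config^2))`, by alternating
#' monotone (isotonic) regression of configuration distances on the
#' dissimilarities with Guttman-transform steps under a halving line search
#' that only ever accepts stress-decreasing moves, so stress is
#' non-increasing within a run. The best of one metric-scaling start plus
#' `n_restarts` random starts is returned, centred, rotated to principal
#' axes and scaled to unit root-mean-square distance.
#'
#' @param d Dissimilarity matrix (or `dist`).
#' @param k Embedding dimension (default 2).
#' @param n_restarts Number of random restarts in addition to the metric
#'   start.
#' @param max_iter,tol Iteration cap and relative stress tolerance.
#' @param seed Integer seed for the random starts.
#' @return Object of class `moth_nmds`: `points` (n x k), `stress`,
#'   `converged`, `n_restarts`, `restart_stress`, `seed`.
#' @export
nmds <- function(d, k = 2, n_restarts = 10, max_iter = 300, tol = 1e-7,
                 seed = 1L) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (n < k + 1) abort("Too few points for the requested dimension.",
                       class = "mothshift_data_error")
  pr <- which(upper.tri(m), arr.ind = TRUE)
  pair_i <- pr[, 1]; pair_j <- pr[, 2]
  dvec <- m[upper.tri(m)]
  set.seed(seed)
  starts <- list(suppressWarnings(cmdscale(stats::as.dist(m), k = k)))
  for (r in seq_len(n_restarts)) {
    starts[[r + 1]] <- matrix(rnorm(n * k), n, k)
  }
  runs <- purrr::map(starts, ~ nmds_run(dvec, .x, pair_i, pair_j, max_iter, tol))
  stresses <- purrr::map_dbl(runs, "stress")
  best <- runs[[which.min(stresses)]]
  X <- scale(best$X, center = TRUE, scale = FALSE)
  X <- X %*% svd(X)$v  # principal-axis rotation
  cdist <- sqrt(rowSums((X[pair_i, , drop = FALSE] - X[pair_j, , drop = FALSE])^2))
  X <- X / sqrt(mean(cdist^2))
  rownames(X) <- rownames(m)
  colnames(X) <- paste0("NMDS", seq_len(k))
  structure(list(points = X, stress = best$stress,
                 converged = best$converged, n_restarts = n_restarts,
                 restart_stress = stresses, seed = seed),
            class = "moth_nmds")
}

#' @export
print.moth_nmds <- function(x, ...) {
  cat(sprintf("NMDS: %d points in %d dimensions, stress-1 = %.4f (%s)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Fit environmental variables onto an ordination
#'
#' Continuous variables (ordered factors are first encoded as integer
#' ranks) are regressed on the ordination axes; the reported direction
#' cosines are the unit-normalized regression coefficients and r2 is the
#' variance fraction explained. Unordered factors are summarized by level
#' centroids with r2 the among-centroid share of the configuration sum of
#' squares. Significance comes from permuting the variable's rows:
#' `p = (1 + #{permuted r2 >= observed}) / (n_perm + 1)`.
#'
#' @param ord A `moth_nmds` object or a coordinate matrix.
#' @param env Data frame of environmental variables, rows aligned with the
#'   ordination points.
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutations.
#' @return Tibble of class `moth_envfit`: `variable`, `type`, `axis1`,
#'   `axis2` (direction cosines, `NA` for factors), `r2`, `p`. Factor
#'   centroids are kept in attribute `centroids`.
#' @export
envfit_ord <- function(ord, env, n_perm = 999, seed = 1L) {
  X <- if (inherits(ord, "moth_nmds")) ord$points else as.matrix(ord)
  if (nrow(env) != nrow(X)) abort("`env` rows must align with the ordination.")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  set.seed(seed)
  centroids <- list()

  fit_vector <- function(v) {
    if (sd(v) == 0) abort("Constant environmental variable.",
                          class = "mothshift_data_error")
    vc <- v - mean(v)
    b <- solve(crossprod(Xc), crossprod(Xc, vc))
    r2 <- sum((Xc %*% b)^2) / sum(vc^2)
    list(dir = as.numeric(b / sqrt(sum(b^2))), r2 = r2)
  }
  fit_factor <- function(f) {
    f <- factor(f)
    if (nlevels(f) < 2) abort("Constant environmental variable.",
                              class = "mothshift_data_error")
    tot <- sum(Xc^2)
    within <- 0
    cent <- matrix(NA_real_, nlevels(f), ncol(Xc),
                   dimnames = list(levels(f), colnames(X)))
    for (lv in levels(f)) {
      rows <- Xc[f == lv, , drop = FALSE]
      cm <- colMeans(rows)
      cent[lv, ] <- cm + attr(Xc, "scaled:center")
      within <- within + sum(sweep(rows, 2, cm)^2)
    }
    list(r2 = 1 - within / tot, centroids = cent)
  }

  purrr::map_dfr(names(env), function(nm) {
    v <- env[[nm]]
    if (is.ordered(v)) v <- as.integer(v)
    if (is.numeric(v)) {
      obs <- fit_vector(v)
      perm <- purrr::map_dbl(seq_len(n_perm),
                             ~ fit_vector(sample(v))$r2)
      tibble::tibble(variable = nm, type = "vector",
                     axis1 = obs$dir[1], axis2 = obs$dir[2],
                     r2 = obs$r2,
                     p = (1 + sum(perm >= obs$r2)) / (n_perm + 1))
    } else {
      obs <- fit_factor(v)
      centroids[[nm]] <<- obs$centroids
      perm <- purrr::map_dbl(seq_len(n_perm),
                             ~ fit_factor(sample(v))$r2)
      tibble::tibble(variable = nm, type = "factor",
                     axis1 = NA_real_, axis2 = NA_real_,
                     r2 = obs$r2,
                     p = (1 + sum(perm >= obs$r2)) / (n_perm + 1))
    }
  }) -> out
  structure(out, class = c("moth_envfit", class(out)), centroids = centroids)
}

#' Within-group dispersion of an ordination
#'
#' Mean Euclidean distance of each group's points to the group centroid in
#' ordination space; a larger value means more turnover among that group's
#' assemblages. Singleton groups give `NA` with a warning.
#'
#' @param ord A `moth_nmds` object or coordinate matrix.
#' @param grouping Group label per ordination point (e.g. vegetation zone).
#' @return Tibble: `group`, `n`, `dispersion`.
#' @export
assemblage_dispersion <- function(ord, grouping) {
  X <- if (inherits(ord, "moth_nmds")) ord$points else as.matrix(ord)
  if (length(grouping) != nrow(X)) abort("`grouping` must align with the points.")
  out <- purrr::map_dfr(unique(grouping), function(g) {
    rows <- X[grouping == g, , drop = FALSE]
    if (nrow(rows) < 2) {
      warn(sprintf("Group `%s` has a single assemblage; dispersion undefined.", g))
      return(tibble::tibble(group = g, n = nrow(rows), dispersion = NA_real_))
    }
    cm <- colMeans(rows)
    tibble::tibble(group = g, n = nrow(rows),
                   dispersion = mean(sqrt(rowSums(sweep(rows, 2, cm)^2))))
  })
  out
}

#' Ordination plot
#'
#' @param object A `moth_nmds` object.
#' @param groups Optional group labels (colour).
#' @param ... Unused.
#' @return A ggplot of the first two ordination axes.
#' @export
autoplot.moth_nmds <- function(object, groups = NULL, ...) {
  d <- tibble::as_tibble(object$points, rownames = "assemblage")
  if (!is.null(groups)) d$group <- groups
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("NMDS (stress-1 = %.3f)", object$stress))
  if (is.null(groups)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' Environmental table for trap-by-period assemblages
#'
#' One row per assemblage (aligned with [assemblage_matrix()] rows): trap
#' elevation, the time period as an ordered factor, and the minimum season
#' length among the period's years.
#'
#' @param assemblages Output of [aggregate_periods()].
#' @param layout Trap layout.
#' @param metrics Season metrics ([season_metrics()]).
#' @param spec The [period_spec()] used for aggregation.
#' @return Tibble: `trap_id`, `period` (ordered factor), `elevation_m`,
#'   `min_season_length`.
#' @export
build_env_table <- function(assemblages, layout, metrics,
                            spec = period_spec()) {
  ids <- assemblages |>
    dplyr::distinct(.data$trap_id, .data$period)
  min_len <- metrics |>
    dplyr::filter(.data$year >= spec$start_year, .data$year <= spec$end_year) |>
    dplyr::mutate(period = pmin(
      (.data$year - spec$start_year) %/% spec$period_length + 1L,
      spec$n_periods)) |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(min_season_length = min(.data$length_days), .groups = "drop")
  ids |>
    dplyr::left_join(dplyr::select(layout, "trap_id", "elevation_m"),
                     by = "trap_id") |>
    dplyr::left_join(min_len, by = "period") |>
    dplyr::mutate(period = factor(.data$period,
                                  levels = seq_len(spec$n_periods),
                                  ordered = TRUE)) |>
    dplyr::arrange(.data$trap_id, .data$period)
}
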