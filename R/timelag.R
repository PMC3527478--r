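#' Hellinger transformation of a fingerprint table
#'
#' Replaces each entry with the square root of its row-relative abundance,
#' so every transformed row has unit Euclidean norm. Euclidean distance on
#' transformed rows is the Hellinger distance (maximum \eqn{\sqrt 2}),
#' which down-weights dominant bands relative to raw profiles.
#'
#' @param fingerprint A fingerprint tibble with positive row sums.
#' @return The transformed fingerprint tibble.
#' @export
hellinger_transform <- function(fingerprint) {
  m <- band_matrix(fingerprint)
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    rlang::abort("Hellinger transform undefined for all-zero rows",
      class = "lagbeta_domain_error"
    )
  }
  as_fingerprint(sqrt(m / rs))
}

#' Pairwise community distance matrix
#'
#' @param fingerprint A fingerprint tibble (at least 2 samples).
#' @param metric `"hellinger"` (Euclidean distance between
#'   Hellinger-transformed profiles, the default) or `"bray_curtis"`.
#' @return A symmetric numeric matrix with zero diagonal and sample ids as
#'   dimnames.
#' @export
community_distance <- function(fingerprint, metric = c("hellinger", "bray_curtis")) {
  metric <- match.arg(metric)
  m <- band_matrix(fingerprint)
  if (nrow(m) < 2) rlang::abort("need at least 2 samples for a distance matrix")
  pairwise_distances(m, metric)
}

pairwise_distances <- function(m, metric) {
  if (metric == "hellinger") {
    rs <- rowSums(m)
    if (any(rs <= 0)) {
      rlang::abort("all-zero row", class = "lagbeta_domain_error")
    }
    h <- sqrt(m / rs)
    d <- as.matrix(stats::dist(h, method = "euclidean"))
  } else {
    rs <- rowSums(m)
    if (any(rs <= 0)) {
      rlang::abort("all-zero row", class = "lagbeta_domain_error")
    }
    m <- m / rs # Bray-Curtis on relative abundances
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- bray_curtis(m[i, ], m[j, ])
      }
    }
  }
  d
}

#' Build time-lag pairs from a distance matrix and sampling dates
#'
#' One pair per unordered date pair: `sqrt_lag` is the square root of the
#' time difference in `time_unit`, `distance` the corresponding community
#' distance. The square-root transform of the lag axis reduces the
#' leverage of the few long-lag pairs.
#'
#' @param d Symmetric distance matrix over one group's per-date composites.
#' @param dates `Date` vector matching the rows of `d`; must be distinct.
#' @param time_unit `"months"` (30.44 days, default), `"days"` or
#'   `"years"` (365.25 days).
#' @param group Label recorded with the pairs.
#' @return A tibble with `group`, `sqrt_lag`, `distance`.
#' @export
lag_pairs <- function(d, dates, time_unit = c("months", "days", "years"),
                      group = "overall") {
  time_unit <- match.arg(time_unit)
  stopifnot(is.matrix(d), nrow(d) == length(dates))
  dates <- as.Date(dates)
  if (anyDuplicated(dates)) {
    rlang::abort("duplicate sampling dates within a group",
      class = "lagbeta_validation_error"
    )
  }
  unit_days <- c(months = 30.44, days = 1, years = 365.25)[[time_unit]]
  n <- length(dates)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  lag_days <- abs(as.numeric(dates[idx[, 1]] - dates[idx[, 2]]))
  tibble::tibble(
    group = group,
    sqrt_lag = sqrt(lag_days / unit_days),
    distance = d[idx]
  )
}

#' Fit a time-lag regression
#'
#' Ordinary least squares of community distance on the square root of the
#' time lag. A positive, significant slope indicates directional community
#' change; a flat slope indicates stochastic fluctuation around a stable
#' composition. The parametric p-value is the classical t-test on the
#' slope; because lag pairs share underlying samples and are not
#' independent, a permutation p-value is also available (see Details).
#'
#' @details Two permutation schemes are implemented. `"relabel"` (default)
#' permutes the sampling dates within each group and rebuilds the lag axis,
#' keeping the distance matrix intact — the analogue of a Mantel-style
#' matrix permutation, and the scheme that preserves the dependence
#' structure among pairs sharing a sample. `"shuffle"` permutes the pooled
#' distance values freely against the fixed `sqrt_lag` design; it is
#' retained for comparison but is anti-conservative when pairs share
#' samples. Both use \eqn{p = (1 + \#\{|b^*| \ge |b|\})/(1 + n_{perm})}.
#'
#' @param pairs A tibble from [lag_pairs()] (columns `sqrt_lag`,
#'   `distance`; at least 3 rows, `sqrt_lag` not constant). For the
#'   `"relabel"` scheme the attributes set by [tla_pairs()] are used when
#'   present; otherwise relabeling falls back to shuffling.
#' @param n_perm Number of permutations for the permutation p-value;
#'   0 (default) skips it.
#' @param scheme Permutation scheme, `"relabel"` or `"shuffle"`.
#' @param seed Optional integer seed for the permutations.
#' @return An object of class `tla_fit` with elements `group`, `slope`,
#'   `intercept`, `r_squared`, `p_parametric`, `p_permutation`, `n_pairs`,
#'   `n_perm`, `scheme`, and the `pairs` used.
#' @export
fit_tla <- function(pairs, n_perm = 0, scheme = c("relabel", "shuffle"),
                    seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("sqrt_lag", "distance") %in% names(pairs)))
  x <- pairs$sqrt_lag
  y <- pairs$distance
  if (length(x) < 3) {
    rlang::abort("time-lag regression needs at least 3 pairs",
      class = "lagbeta_insufficient_data_error"
    )
  }
  if (stats::var(x) == 0) {
    rlang::abort("sqrt_lag has zero variance; degenerate design",
      class = "lagbeta_degenerate_design_error"
    )
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact fits (zero residual variance); those are
  # legitimate inputs here (e.g. constructed lines), so silence it
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    perm_slopes <- tla_permute(pairs, n_perm, scheme)
    p_perm <- (1 + sum(abs(perm_slopes) >= abs(slope) - 1e-12)) / (1 + n_perm)
  }
  structure(
    list(
      group = if ("group" %in% names(pairs)) unique(pairs$group)[1] else "overall",
      slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      r_squared = sm$r.squared,
      p_parametric = sm$coefficients[2, 4],
      p_permutation = p_perm,
      n_pairs = length(x),
      n_perm = n_perm,
      scheme = scheme,
      pairs = pairs
    ),
    class = "tla_fit"
  )
}

# Permutation slopes for a TLA fit. For "relabel", sampling dates are
# permuted independently within each group listed in attr(pairs,
# "group_structure"); distances keep their pair identity through the
# stored pair index matrix.
tla_permute <- function(pairs, n_perm, scheme) {
  x <- pairs$sqrt_lag
  y <- pairs$distance
  gs <- attr(pairs, "group_structure")
  if (scheme == "relabel" && !is.null(gs)) {
    slopes <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      xp <- x
      for (g in gs) {
        # g: list(rows = pair row indices, pair_idx = 2-col composite index,
        #         n_dates)
        perm <- sample.int(g$n_dates)
        # distance between composites i,j is now plotted at the lag of
        # dates perm[i], perm[j]
        xp[g$rows] <- g$lag_lookup[cbind(
          perm[g$pair_idx[, 1]],
          perm[g$pair_idx[, 2]]
        )]
      }
      slopes[b] <- ols_slope(xp, y)
    }
    slopes
  } else {
    vapply(seq_len(n_perm), function(b) ols_slope(x, sample(y)), numeric(1))
  }
}

ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc * xc)
}

#' Assemble time-lag pairs per site from fingerprint data
#'
#' Builds per-(site, date) composite profiles, computes the chosen
#' community distance within each site, and returns the lag pairs for
#' every site, carrying the structure needed for date-relabeling
#' permutations.
#'
#' @inheritParams composite_profiles
#' @inheritParams lag_pairs
#' @param metric Distance passed to [community_distance()].
#' @return A tibble of pairs (`group` = site id, `sqrt_lag`, `distance`)
#'   with a `group_structure` attribute used by [fit_tla()]'s relabeling
#'   permutation.
#' @export
tla_pairs <- function(fingerprint, metadata,
                      metric = c("hellinger", "bray_curtis"),
                      time_unit = c("months", "days", "years"),
                      replicate_policy = c("mean", "separate")) {
  metric <- match.arg(metric)
  time_unit <- match.arg(time_unit)
  replicate_policy <- match.arg(replicate_policy)
  comp <- composite_profiles(fingerprint, metadata, replicate_policy)
  sites <- unique(comp$site_id)
  pieces <- list()
  structure_list <- list()
  offset <- 0L
  for (s in sites) {
    rows <- comp[comp$site_id == s, , drop = FALSE]
    if (nrow(rows) < 2) next
    m <- band_matrix(dplyr::select(rows, -"site_id", -"date"))
    d <- pairwise_distances(m, metric)
    p <- lag_pairs(d, rows$date, time_unit, group = s)
    n <- nrow(rows)
    pair_idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
    unit_days <- c(months = 30.44, days = 1, years = 365.25)[[time_unit]]
    dd <- abs(outer(as.numeric(rows$date), as.numeric(rows$date), "-"))
    structure_list[[s]] <- list(
      rows = offset + seq_len(nrow(p)),
      pair_idx = pair_idx,
      n_dates = n,
      lag_lookup = sqrt(dd / unit_days)
    )
    offset <- offset + nrow(p)
    pieces[[s]] <- p
  }
  if (length(pieces) == 0) {
    rlang::abort("no site has 2 or more time points",
      class = "lagbeta_insufficient_data_error"
    )
  }
  out <- dplyr::bind_rows(pieces)
  attr(out, "group_structure") <- structure_list
  out
}

#' Time-lag analysis per site and overall
#'
#' Runs [fit_tla()] for every site and for the pooled set of all sites'
#' pairs (`"overall"`), mirroring a per-site-plus-overall summary table.
#' Pooling (rather than averaging per-site slopes) keeps a single
#' R-squared over all points.
#'
#' @inheritParams tla_pairs
#' @inheritParams fit_tla
#' @param overall One of `"pooled"` (default: single regression over all
#'   sites' pairs) or `"mean_slope"` (average of per-site slopes; reported
#'   without p-value).
#' @return A tibble with one row per site plus an `overall` row: `group`,
#'   `slope`, `intercept`, `r_squared`, `p_parametric`, `p_permutation`,
#'   `n_pairs`.
#' @export
tla <- function(fingerprint, metadata,
                metric = c("hellinger", "bray_curtis"),
                time_unit = c("months", "days", "years"),
                replicate_policy = c("mean", "separate"),
                n_perm = 0, scheme = c("relabel", "shuffle"),
                overall = c("pooled", "mean_slope"),
                seed = NULL) {
  overall <- match.arg(overall)
  scheme <- match.arg(scheme)
  pairs <- tla_pairs(fingerprint, metadata, metric, time_unit, replicate_policy)
  gs <- attr(pairs, "group_structure")
  sites <- unique(pairs$group)
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(sites, function(s) {
    p <- pairs[pairs$group == s, , drop = FALSE]
    g <- gs[[s]]
    g$rows <- seq_len(nrow(p))
    attr(p, "group_structure") <- list(g)
    fit_tla(p, n_perm = n_perm, scheme = scheme)
  })
  rows <- purrr::map_dfr(fits, tidy_tla_row)
  if (overall == "pooled") {
    pooled <- pairs
    pooled$group <- "overall"
    attr(pooled, "group_structure") <- gs
    rows <- dplyr::bind_rows(
      rows,
      tidy_tla_row(fit_tla(pooled, n_perm = n_perm, scheme = scheme))
    )
  } else {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      group = "overall",
      slope = mean(rows$slope),
      intercept = mean(rows$intercept),
      r_squared = NA_real_,
      p_parametric = NA_real_,
      p_permutation = NA_real_,
      n_pairs = sum(rows$n_pairs)
    ))
  }
  rows
}

tidy_tla_row <- function(fit) {
  tibble::tibble(
    group = fit$group,
    slope = fit$slope,
    intercept = fit$intercept,
    r_squared = fit$r_squared,
    p_parametric = fit$p_parametric,
    p_permutation = fit$p_permutation,
    n_pairs = fit$n_pairs
  )
}

#' @export
print.tla_fit <- function(x, ...) {
  cat("<tla_fit>", x$group, "\n")
  cat(sprintf(
    "  distance = %.4f + %.4f * sqrt(lag)   R^2 = %.3f\n",
    x$intercept, x$slope, x$r_squared
  ))
  cat(sprintf("  parametric p = %.4g", x$p_parametric))
  if (!is.na(x$p_permutation)) {
    cat(sprintf("   permutation p = %.4g (%d perms, %s)",
                x$p_permutation, x$n_perm, x$scheme))
  }
  cat("\n  n pairs:", x$n_pairs, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a time-lag fit into term estimates
#'
#' @param x A `tla_fit`.
#' @param ... Unused.
#' @return A tibble with one row per regression term.
#' @method tidy tla_fit
#' @export
tidy.tla_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "sqrt_lag"),
    estimate = c(x$intercept, x$slope)
  )
}

#' One-row summary of a time-lag fit
#'
#' @param x A `tla_fit`.
#' @param ... Unused.
#' @return A one-row tibble: slope, intercept, R-squared, p-values, pair
#'   count.
#' @method glance tla_fit
#' @export
glance.tla_fit <- function(x, ...) {
  tidy_tla_row(x)
}
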