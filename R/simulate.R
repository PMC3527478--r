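#' Define a synthetic fingerprint-series scenario
#'
#' A scenario bundles the generative parameters for a multi-site,
#' multi-year community fingerprint time series: a latent lognormal
#' community per site, directional turnover implemented as gradual
#' replacement of the resident community by an incoming one, seasonal
#' modulation, date-level and replicate-level lognormal noise,
#' detection censoring of rare taxa (emulating the limited sensitivity of
#' gel fingerprinting, which resolves only taxa above roughly 0.1-1% of
#' the community), and an optional linkage that makes composition covary
#' with soil chemistry at a known effect size.
#'
#' @param name Scenario label.
#' @param n_sites,n_dates,n_replicates Design dimensions. Sampling dates
#'   follow a fixed three-year field calendar (Apr/Jun/Sep/Nov year 1,
#'   Apr/Jun/Oct year 2, Feb/Apr/Jul/Sep year 3); `n_dates` takes the
#'   first `n_dates` of the 11 calendar dates.
#' @param n_taxa Size of the latent taxon pool per site.
#' @param drift_rate Directional turnover rate \eqn{\theta}: fraction of
#'   community mass shifted from the resident to the incoming community
#'   per month. Scalar (recycled) or one value per site. `0` gives a
#'   stochastic (exchangeable-in-time) regime.
#' @param noise_sd Replicate-level lognormal jitter (sd on the log scale).
#' @param temporal_sd Date-level lognormal jitter shared by all replicates
#'   of a sampling (sd on the log scale); exchangeable across dates, so it
#'   creates temporal scatter without directional trend.
#' @param seasonal_amplitude Amplitude of a per-taxon seasonal sinusoid on
#'   the log-abundance scale (random phase per site and taxon).
#' @param detection_fraction Relative-abundance detection threshold: taxa
#'   below this community fraction yield no band.
#' @param chemistry_linkage Named numeric vector of per-variable effect
#'   sizes (log-abundance shift per standard deviation of the variable,
#'   through fixed per-taxon loadings). Names among `ph`, `nh4`, `no3`,
#'   `om`, `clay`, `moisture`.
#' @param abundance_sd Spread (sd of log abundance) of the lognormal
#'   rank-abundance baseline.
#' @param seed Default seed used by the simulators when none is given.
#' @return A `synthetic_scenario` list.
#' @export
scenario <- function(name = "custom",
                     n_sites = 8, n_dates = 11, n_replicates = 4,
                     n_taxa = 150,
                     drift_rate = 0,
                     noise_sd = 0.3,
                     temporal_sd = 0.3,
                     seasonal_amplitude = 0,
                     detection_fraction = 0.01,
                     chemistry_linkage = NULL,
                     abundance_sd = 1.2,
                     seed = NULL) {
  stopifnot(
    n_sites >= 1, n_dates >= 1, n_dates <= 11, n_replicates >= 1, n_taxa >= 1,
    all(drift_rate >= 0), noise_sd >= 0, temporal_sd >= 0,
    seasonal_amplitude >= 0,
    detection_fraction > 0, detection_fraction <= 1
  )
  drift_rate <- rep_len(drift_rate, n_sites)
  linkage <- c(ph = 0, nh4 = 0, no3 = 0, om = 0, clay = 0, moisture = 0)
  if (!is.null(chemistry_linkage)) {
    bad <- setdiff(names(chemistry_linkage), names(linkage))
    if (length(bad) > 0) {
      rlang::abort(paste("unknown chemistry variable(s):", paste(bad, collapse = ", ")))
    }
    linkage[names(chemistry_linkage)] <- chemistry_linkage
  }
  structure(
    list(
      name = name,
      n_sites = n_sites, n_dates = n_dates, n_replicates = n_replicates,
      n_taxa = n_taxa,
      drift_rate = drift_rate,
      noise_sd = noise_sd, temporal_sd = temporal_sd,
      seasonal_amplitude = seasonal_amplitude,
      detection_fraction = detection_fraction,
      chemistry_linkage = linkage,
      abundance_sd = abundance_sd,
      seed = seed
    ),
    class = "synthetic_scenario"
  )
}

#' Named scenario presets
#'
#' * `paper_scale` — full study design: 8 sites (half sandy, half clayey)
#'   sampled 11 times over three years with 4 replicates, modest
#'   site-specific directional drift and a moderate nitrate linkage.
#' * `desk_small` — 3 sites, 6 dates, 2 replicates; fast, zero drift.
#' * `null` — desk-small design, all drift rates 0 (stochastic regime).
#' * `directional` — desk-small design with three distinct positive drift
#'   rates across the sites.
#' * `seasonal_only` — desk-small design, zero drift, seasonal amplitude
#'   0.6.
#' * `linked` — desk-small design with a strong (effect size 1.0) nitrate
#'   linkage and no drift.
#'
#' @return Named list of `synthetic_scenario` objects.
#' @export
scenario_presets <- function() {
  list(
    paper_scale = scenario(
      name = "paper_scale",
      n_sites = 8, n_dates = 11, n_replicates = 4, n_taxa = 150,
      drift_rate = seq(0.004, 0.025, length.out = 8),
      seasonal_amplitude = 0.3,
      chemistry_linkage = c(no3 = 0.5)
    ),
    desk_small = scenario(
      name = "desk_small",
      n_sites = 3, n_dates = 6, n_replicates = 2, n_taxa = 80
    ),
    null = scenario(
      name = "null",
      n_sites = 3, n_dates = 6, n_replicates = 2, n_taxa = 80,
      drift_rate = 0
    ),
    directional = scenario(
      name = "directional",
      n_sites = 3, n_dates = 6, n_replicates = 2, n_taxa = 80,
      drift_rate = c(0.01, 0.025, 0.05)
    ),
    seasonal_only = scenario(
      name = "seasonal_only",
      n_sites = 3, n_dates = 6, n_replicates = 2, n_taxa = 80,
      seasonal_amplitude = 0.6
    ),
    linked = scenario(
      name = "linked",
      n_sites = 3, n_dates = 6, n_replicates = 2, n_taxa = 80,
      chemistry_linkage = c(no3 = 1.0)
    )
  )
}

# Three-year field sampling calendar (day 15 of each month).
sampling_calendar <- function(n_dates) {
  all_dates <- as.Date(c(
    "2009-04-15", "2009-06-15", "2009-09-15", "2009-11-15",
    "2010-04-15", "2010-06-15", "2010-10-15",
    "2011-02-15", "2011-04-15", "2011-07-15", "2011-09-15"
  ))
  all_dates[seq_len(n_dates)]
}

#' Simulate a fingerprint time series
#'
#' Generates observed band tables, sample metadata and the ground truth
#' for a scenario. Each site holds a resident and an independent incoming
#' lognormal community; at drift rate \eqn{\theta} per month, the latent
#' relative profile at month \eqn{t} is the mixture
#' \eqn{(1-w)\,\pi_{res} + w\,\pi_{inc}} with
#' \eqn{w = \min(1, \theta t)}. Seasonal sinusoids, chemistry effects and
#' lognormal date/replicate noise act on the log-abundance scale; observed
#' bands are the relative abundances of taxa whose community fraction
#' exceeds `detection_fraction`, renormalized. Identical seeds give
#' bit-identical output.
#'
#' @param scenario A `synthetic_scenario` (see [scenario()]).
#' @param seed Integer seed; defaults to the scenario's own seed.
#' @return A list: `fingerprint` (tibble), `metadata` (tibble),
#'   `ground_truth` (list with `drift_rate`, `chemistry` tibble keyed by
#'   site and date, `chemistry_linkage`, `loadings`, `latent` — the
#'   noise-free latent relative profiles per (site, date) — and
#'   `uncensored` — pre-censoring relative abundances per sample).
#' @export
simulate_fingerprint_series <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (!is.null(seed)) set.seed(seed)
  sc <- scenario
  sites <- sprintf("S%d", seq_len(sc$n_sites))
  texture <- ifelse(seq_len(sc$n_sites) <= ceiling(sc$n_sites / 2), "sandy", "clayey")
  dates <- sampling_calendar(sc$n_dates)
  months <- as.numeric(dates - dates[1]) / 30.44
  yearfrac <- as.numeric(format(dates, "%j")) / 365.25

  chem <- simulate_chemistry_values(sites, texture, dates)
  linked_vars <- names(sc$chemistry_linkage)[sc$chemistry_linkage != 0]
  loadings <- matrix(0, sc$n_taxa, length(linked_vars),
    dimnames = list(NULL, linked_vars)
  )
  if (length(linked_vars) > 0) {
    loadings[] <- stats::rnorm(sc$n_taxa * length(linked_vars))
  }
  # standardized chemistry across the whole design, for the linkage term
  zchem <- chem
  for (v in linked_vars) {
    zchem[[v]] <- as.numeric(scale(chem[[v]]))
  }

  n_samples <- sc$n_sites * sc$n_dates * sc$n_replicates
  band_names <- sprintf("b%03d", seq_len(sc$n_taxa))
  obs <- matrix(0, n_samples, sc$n_taxa, dimnames = list(NULL, band_names))
  unc <- matrix(0, n_samples, sc$n_taxa, dimnames = list(NULL, band_names))
  latent <- array(NA_real_,
    dim = c(sc$n_sites, sc$n_dates, sc$n_taxa),
    dimnames = list(sites, format(dates), band_names)
  )
  meta <- vector("list", n_samples)

  row <- 0L
  for (i in seq_len(sc$n_sites)) {
    pi_res <- rlnorm_profile(sc$n_taxa, sc$abundance_sd)
    pi_inc <- rlnorm_profile(sc$n_taxa, sc$abundance_sd)
    phase <- stats::runif(sc$n_taxa, 0, 2 * pi)
    for (t in seq_len(sc$n_dates)) {
      w <- min(1, sc$drift_rate[i] * months[t])
      mix <- (1 - w) * pi_res + w * pi_inc
      eff <- sc$seasonal_amplitude * sin(2 * pi * yearfrac[t] + phase)
      for (v in linked_vars) {
        zv <- zchem[[v]][zchem$site_id == sites[i] & zchem$date == dates[t]]
        eff <- eff + sc$chemistry_linkage[[v]] * zv * loadings[, v]
      }
      lat <- mix * exp(eff)
      lat <- lat / sum(lat)
      latent[i, t, ] <- lat
      eps_date <- stats::rnorm(sc$n_taxa, 0, sc$temporal_sd)
      for (k in seq_len(sc$n_replicates)) {
        row <- row + 1L
        attempt <- 0L
        repeat {
          eps_rep <- stats::rnorm(sc$n_taxa, 0, sc$noise_sd)
          ab <- lat * exp(eps_date + eps_rep)
          rel <- ab / sum(ab)
          cen <- censor_bands(rel, sc$detection_fraction)
          if (sum(cen) > 0 || attempt >= 50L) break
          attempt <- attempt + 1L
        }
        if (sum(cen) == 0) {
          rlang::warn(sprintf(
            "sample %s_%s_r%d had no detectable band after regeneration",
            sites[i], format(dates[t], "%Y%m"), k
          ))
          cen[which.max(rel)] <- 1
        }
        unc[row, ] <- rel
        obs[row, ] <- cen
        meta[[row]] <- tibble::tibble(
          sample_id = sprintf("%s_%s_r%d", sites[i], format(dates[t], "%Y%m"), k),
          site_id = sites[i], date = dates[t], replicate = k,
          texture = texture[i]
        )
      }
    }
  }
  metadata <- dplyr::bind_rows(meta)
  rownames(obs) <- rownames(unc) <- metadata$sample_id
  # drop bands never detected anywhere so the table mirrors a called gel
  seen <- colSums(obs) > 0
  list(
    fingerprint = as_fingerprint(obs[, seen, drop = FALSE]),
    metadata = metadata,
    ground_truth = list(
      drift_rate = stats::setNames(sc$drift_rate, sites),
      chemistry = chem,
      chemistry_linkage = sc$chemistry_linkage,
      loadings = loadings,
      latent = latent,
      uncensored = unc,
      scenario = sc
    )
  )
}

rlnorm_profile <- function(n_taxa, sdlog) {
  a <- exp(stats::rnorm(n_taxa, 0, sdlog))
  a / sum(a)
}

#' Apply detection censoring to a relative-abundance profile
#'
#' Taxa whose relative abundance is below `detection_fraction` are zeroed
#' and the remainder renormalized — the idealized behaviour of band
#' calling on a gel that only resolves dominant community members.
#' Censoring never increases a taxon's relative-abundance rank.
#'
#' @param rel Non-negative vector (or samples-by-taxa matrix) of relative
#'   abundances.
#' @param detection_fraction Threshold in (0, 1\].
#' @return The censored, renormalized profile(s); rows with no surviving
#'   taxon are returned as all-zero.
#' @export
censor_bands <- function(rel, detection_fraction) {
  if (is.matrix(rel)) {
    out <- t(apply(rel, 1, censor_bands, detection_fraction = detection_fraction))
    dimnames(out) <- dimnames(rel)
    return(out)
  }
  keep <- rel >= detection_fraction
  out <- rel * keep
  s <- sum(out)
  if (s > 0) out <- out / s
  out
}

# Chemistry value templates per (site, date). pH and clay are constant per
# site (texture-determined levels); nitrate and ammonium follow a
# within-year declining seasonal template around site-specific baselines;
# organic matter and moisture fluctuate mildly around site baselines.
simulate_chemistry_values <- function(sites, texture, dates) {
  months_of <- as.integer(format(dates, "%m"))
  no3_f <- c(`2` = 0.8, `4` = 1.0, `6` = 0.7, `7` = 0.6, `9` = 0.35, `10` = 0.3, `11` = 0.35)
  nh4_f <- c(`2` = 0.8, `4` = 1.0, `6` = 0.7, `7` = 0.5, `9` = 0.2, `10` = 0.5, `11` = 0.4)
  rows <- list()
  for (i in seq_along(sites)) {
    sandy <- texture[i] == "sandy"
    ph_site <- if (sandy) stats::rnorm(1, 4.9, 0.15) else stats::rnorm(1, 7.3, 0.10)
    clay_site <- if (sandy) stats::runif(1, 3, 8) else stats::runif(1, 20, 30)
    om_site <- exp(stats::rnorm(1, log(4), 0.3))
    no3_site <- stats::runif(1, 40, 90)
    nh4_site <- stats::runif(1, 8, 16)
    moist_site <- stats::runif(1, 15, 30)
    for (t in seq_along(dates)) {
      mo <- as.character(months_of[t])
      rows[[length(rows) + 1]] <- tibble::tibble(
        site_id = sites[i],
        date = dates[t],
        ph = ph_site,
        nh4 = nh4_site * nh4_f[[mo]] * exp(stats::rnorm(1, 0, 0.25)),
        no3 = no3_site * no3_f[[mo]] * exp(stats::rnorm(1, 0, 0.25)),
        om = om_site * exp(stats::rnorm(1, 0, 0.08)),
        clay = clay_site,
        moisture = min(100, max(0, moist_site + stats::rnorm(1, 0, 3)))
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Return the chemistry table of a simulated series
#'
#' The chemistry values are generated together with the fingerprint series
#' (they may drive composition through the scenario's linkage); this
#' accessor returns them as a (site, date)-keyed table, optionally
#' augmented with pure-noise candidate variables for selection
#' experiments.
#'
#' @param scenario The scenario used for the simulation.
#' @param metadata Metadata returned by [simulate_fingerprint_series()].
#' @param ground_truth Ground truth returned by the same call.
#' @param n_noise Number of standard-normal noise columns (`noise1`, ...)
#'   to append, drawn per (site, date).
#' @param seed Optional seed for the noise columns.
#' @return A chemistry tibble keyed by `site_id` and `date`.
#' @export
simulate_chemistry <- function(scenario, metadata, ground_truth,
                               n_noise = 0, seed = NULL) {
  chem <- ground_truth$chemistry
  chem <- chem[chem$site_id %in% unique(metadata$site_id) &
                 chem$date %in% unique(metadata$date), , drop = FALSE]
  if (n_noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (j in seq_len(n_noise)) {
      chem[[paste0("noise", j)]] <- stats::rnorm(nrow(chem))
    }
  }
  chem
}

#' Simulate a complete aligned dataset
#'
#' Convenience wrapper running [simulate_fingerprint_series()] and
#' [simulate_chemistry()] for one scenario.
#'
#' @inheritParams simulate_fingerprint_series
#' @inheritParams simulate_chemistry
#' @return A list: `fingerprint`, `metadata`, `chemistry`, `ground_truth`.
#' @export
simulate_dataset <- function(scenario, seed = scenario$seed, n_noise = 0) {
  sim <- simulate_fingerprint_series(scenario, seed = seed)
  chem <- simulate_chemistry(scenario, sim$metadata, sim$ground_truth,
    n_noise = n_noise
  )
  list(
    fingerprint = sim$fingerprint,
    metadata = sim$metadata,
    chemistry = chem,
    ground_truth = sim$ground_truth
  )
}
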