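#' Shannon diversity of an abundance vector
#'
#' \eqn{H' = -\sum_i p_i \log p_i} over the strictly positive entries,
#' where \eqn{p_i} is the relative abundance. The input is renormalized
#' internally, so any non-negative intensity scale is accepted.
#'
#' @param x Non-negative numeric vector with at least one positive entry.
#' @param base Logarithm base; the default `exp(1)` reports H' in nats.
#' @return Shannon index H' (single number).
#' @examples
#' shannon(c(0.25, 0.25, 0.25, 0.25)) # == log(4)
#' @export
shannon <- function(x, base = exp(1)) {
  check_abundance(x)
  p <- x[x > 0]
  p <- p / sum(p)
  -sum(p * log(p, base = base))
}

#' Band richness of an abundance vector
#'
#' Counts entries strictly above a detection threshold. The default
#' `epsilon = 0` counts any positive intensity as a band, since fingerprint
#' band calling has already applied a detection cutoff.
#'
#' @param x Non-negative numeric vector.
#' @param epsilon Detection threshold; entries `> epsilon` count.
#' @return Integer band count.
#' @export
band_richness <- function(x, epsilon = 0) {
  stopifnot(is.numeric(x), all(x >= 0))
  sum(x > epsilon)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \eqn{\sum_i |a_i - b_i| / \sum_i (a_i + b_i)}; 0 for identical
#' vectors, 1 for disjoint supports.
#'
#' @param a,b Non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b) {
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0))
  tot <- sum(a) + sum(b)
  if (tot == 0) {
    rlang::abort("Bray-Curtis undefined for two all-zero vectors",
      class = "lagbeta_domain_error"
    )
  }
  sum(abs(a - b)) / tot
}

#' Per-sample alpha diversity
#'
#' Computes the Shannon index and band richness for every sample of a
#' fingerprint table.
#'
#' @param fingerprint A fingerprint tibble.
#' @param epsilon Detection threshold passed to [band_richness()].
#' @param base Logarithm base passed to [shannon()].
#' @return A tibble with columns `sample_id`, `shannon`, `richness`.
#' @export
alpha_diversity <- function(fingerprint, epsilon = 0, base = exp(1)) {
  m <- band_matrix(fingerprint)
  tibble::tibble(
    sample_id = rownames(m),
    shannon = apply(m, 1, shannon, base = base),
    richness = as.integer(apply(m, 1, band_richness, epsilon = epsilon))
  )
}

#' Composite community profiles per site and sampling date
#'
#' Collapses replicates into one relative-abundance profile per
#' (site, date). Under the default `"mean"` policy the replicate
#' relative-abundance vectors are averaged and renormalized; under
#' `"separate"` every replicate is kept as its own profile.
#'
#' @param fingerprint A fingerprint tibble.
#' @param metadata Sample metadata with `sample_id`, `site_id`, `date`.
#' @param replicate_policy `"mean"` (default) or `"separate"`.
#' @return A tibble with `site_id`, `date`, `sample_id` (composite label)
#'   and the band columns, rows summing to 1.
#' @export
composite_profiles <- function(fingerprint, metadata,
                               replicate_policy = c("mean", "separate")) {
  replicate_policy <- match.arg(replicate_policy)
  ds <- align_samples(fingerprint, metadata)
  m <- band_matrix(normalize_fingerprint(ds$fingerprint))
  md <- ds$metadata

  if (replicate_policy == "separate") {
    out <- dplyr::bind_cols(
      dplyr::select(md, "site_id", "date", "sample_id"),
      tibble::as_tibble(m, .name_repair = "minimal")
    )
    return(dplyr::arrange(out, .data$site_id, .data$date))
  }

  key <- paste(md$site_id, format(md$date), sep = "|")
  agg <- rowsum(m, group = key) / as.vector(table(key)[sort(unique(key))])
  agg <- agg / rowSums(agg)
  parts <- strsplit(rownames(agg), "|", fixed = TRUE)
  out <- dplyr::bind_cols(
    tibble::tibble(
      site_id = vapply(parts, `[`, "", 1L),
      date = as.Date(vapply(parts, `[`, "", 2L)),
      sample_id = rownames(agg)
    ),
    tibble::as_tibble(agg, .name_repair = "minimal")
  )
  dplyr::arrange(out, .data$site_id, .data$date)
}

#' Temporal beta diversity per site
#'
#' Quantifies the turnover of a site's community over its time series as
#' the mean of all pairwise Bray-Curtis dissimilarities among the site's
#' per-date composite profiles. The measure uses no temporal order, only
#' the set of composites.
#'
#' @param fingerprint A fingerprint tibble.
#' @param metadata Sample metadata.
#' @param replicate_policy Passed to [composite_profiles()].
#' @return A tibble with `site_id`, `beta` (mean pairwise Bray-Curtis in
#'   \[0, 1\]), `n_dates` and `n_pairs`.
#' @export
temporal_beta <- function(fingerprint, metadata,
                          replicate_policy = c("mean", "separate")) {
  replicate_policy <- match.arg(replicate_policy)
  comp <- composite_profiles(fingerprint, metadata, replicate_policy)
  sites <- unique(comp$site_id)
  purrr::map_dfr(sites, function(s) {
    rows <- comp[comp$site_id == s, , drop = FALSE]
    m <- band_matrix(dplyr::select(rows, -"site_id", -"date"))
    t_n <- nrow(m)
    if (t_n < 2) {
      rlang::abort(
        sprintf("site %s has %d time point(s); temporal beta needs at least 2", s, t_n),
        class = "lagbeta_insufficient_data_error"
      )
    }
    d <- pairwise_distances(m, metric = "bray_curtis")
    vals <- d[lower.tri(d)]
    tibble::tibble(
      site_id = s,
      beta = mean(vals),
      n_dates = t_n,
      n_pairs = length(vals)
    )
  })
}

#' Summarize a per-sample or per-site statistic by soil texture class
#'
#' @param data Tibble holding the statistic and a key shared with
#'   `metadata` (`sample_id` or `site_id`).
#' @param metadata Sample metadata carrying the `texture` column.
#' @param var Name of the statistic column to summarize (string).
#' @return A tibble with `texture`, `mean`, `se`, `n`.
#' @export
texture_summary <- function(data, metadata, var) {
  stopifnot(var %in% names(data))
  key <- intersect(c("sample_id", "site_id"), names(data))[1]
  if (is.na(key)) rlang::abort("data must carry sample_id or site_id")
  tex <- dplyr::distinct(metadata, .data[[key]], .data$texture)
  dplyr::inner_join(data, tex, by = key) |>
    dplyr::group_by(.data$texture) |>
    dplyr::summarise(
      mean = mean(.data[[var]], na.rm = TRUE),
      se = stats::sd(.data[[var]], na.rm = TRUE) / sqrt(sum(!is.na(.data[[var]]))),
      n = sum(!is.na(.data[[var]])),
      .groups = "drop"
    )
}

check_abundance <- function(x) {
  if (!is.numeric(x) || any(x < 0) || anyNA(x)) {
    rlang::abort("abundances must be non-negative and complete",
      class = "lagbeta_domain_error"
    )
  }
  if (sum(x) == 0) {
    rlang::abort("all-zero abundance vector", class = "lagbeta_domain_error")
  }
  invisible(x)
}
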