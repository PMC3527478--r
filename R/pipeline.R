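#' Build a pipeline run configuration
#'
#' @param replicate_policy Replicate handling for composites (`"mean"` or
#'   `"separate"`).
#' @param metric Distance for the time-lag analysis.
#' @param time_unit Lag unit for the time-lag analysis.
#' @param n_perm Permutations for TLA and ordination tests.
#' @param alpha Forward-selection retention threshold.
#' @param seed Global seed; each stage derives its own seed from it so
#'   stages can be re-run individually with identical results.
#' @param variables Chemistry variables entering the ordination and the
#'   correlation screen; `NULL` uses every numeric chemistry column.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(replicate_policy = "mean",
                       metric = "hellinger",
                       time_unit = "months",
                       n_perm = 999,
                       alpha = 0.05,
                       seed = 1L,
                       variables = NULL) {
  structure(
    list(
      replicate_policy = replicate_policy,
      metric = metric,
      time_unit = time_unit,
      n_perm = as.integer(n_perm),
      alpha = alpha,
      seed = as.integer(seed),
      variables = variables
    ),
    class = "run_config"
  )
}

#' Read a flat key=value configuration file
#'
#' Each non-empty, non-comment (`#`) line holds `key = value`; keys mirror
#' the arguments of [run_config()]. `variables` may be a comma-separated
#' list.
#'
#' @param path Path to the configuration file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  cfg <- run_config()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(cfg)) {
      rlang::abort(paste("unknown configuration key:", k),
        class = "lagbeta_format_error"
      )
    }
    cfg[[k]] <- switch(k,
      n_perm = as.integer(vals[i]),
      seed = as.integer(vals[i]),
      alpha = as.numeric(vals[i]),
      variables = strsplit(vals[i], ",")[[1]] |> trimws(),
      vals[i]
    )
  }
  cfg
}

#' Run the full turnover analysis pipeline
#'
#' Executes, in order: per-sample alpha diversity, per-site temporal beta
#' diversity, time-lag analysis (per site and pooled), constrained
#' ordination against chemistry (full CCA, forward selection, variance
#' partitioning), and the Pearson correlation screen of site-level biotic
#' summaries against site-mean chemistry. One artifact is written per
#' stage; every artifact embeds the resolved configuration and package
#' version, and a fixed seed makes two runs byte-identical.
#'
#' @param fingerprint,metadata,chemistry Input tibbles (see the `read_*`
#'   functions).
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @return Invisibly, a list with the per-stage results and the paths of
#'   the written artifacts.
#' @export
run_full_pipeline <- function(fingerprint, metadata, chemistry, out_dir,
                              config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- align_samples(fingerprint, metadata, chemistry)
  prov <- provenance_header(config)

  # stage 1: alpha diversity (+ texture summaries)
  alpha <- alpha_diversity(ds$fingerprint)
  alpha_tex <- dplyr::bind_rows(
    dplyr::mutate(texture_summary(alpha, ds$metadata, "shannon"), statistic = "shannon"),
    dplyr::mutate(texture_summary(alpha, ds$metadata, "richness"), statistic = "richness")
  )
  p_alpha <- file.path(out_dir, "diversity.csv")
  write_artifact(alpha, p_alpha, prov)
  write_artifact(alpha_tex, file.path(out_dir, "diversity_by_texture.csv"), prov)

  # stage 2: temporal beta diversity
  beta <- temporal_beta(ds$fingerprint, ds$metadata,
    replicate_policy = config$replicate_policy
  )
  p_beta <- file.path(out_dir, "beta.csv")
  write_artifact(beta, p_beta, prov)

  # stage 3: time-lag analysis
  tla_tbl <- tla(ds$fingerprint, ds$metadata,
    metric = config$metric, time_unit = config$time_unit,
    replicate_policy = config$replicate_policy,
    n_perm = config$n_perm, seed = config$seed + 1L
  )
  p_tla <- file.path(out_dir, "tla.csv")
  write_artifact(tla_tbl, p_tla, prov)

  # stage 4: constrained ordination
  built <- composite_predictors(
    ds$fingerprint, ds$metadata, chemistry,
    variables = config$variables,
    replicate_policy = config$replicate_policy, transform = TRUE
  )
  cca <- cca_fit(built$y, built$x)
  cca_test <- cca_permutation_test(built$y, built$x,
    n_perm = config$n_perm, seed = config$seed + 2L
  )
  fs <- forward_select_cca(built$y, built$x,
    alpha = config$alpha,
    n_perm = config$n_perm, seed = config$seed + 3L
  )
  vp <- variance_partition(built$y, built$x)
  p_cca <- file.path(out_dir, "cca.json")
  jsonlite::write_json(
    list(
      provenance = provenance_list(config),
      total_inertia = cca$total_inertia,
      constrained_inertia = cca$constrained_inertia,
      explained_fraction = cca$explained_fraction,
      eigenvalues = cca$eigenvalues,
      pseudo_F = cca_test$pseudo_F,
      p_permutation = cca_test$p_value,
      forward_selection = list(
        selected = fs$selected,
        stopping_reason = fs$stopping_reason,
        trace = fs$trace
      ),
      variance_partition = list(
        unique = vp$unique,
        total_explained = vp$total_explained,
        residual = vp$residual
      )
    ),
    p_cca,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  # stage 5: correlation screen (site-level biotic summaries vs chemistry)
  site_alpha <- dplyr::inner_join(alpha, dplyr::select(ds$metadata, "sample_id", "site_id"),
    by = "sample_id"
  ) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      shannon = mean(.data$shannon),
      richness = mean(.data$richness), .groups = "drop"
    )
  site_slope <- tla_tbl |>
    dplyr::filter(.data$group != "overall") |>
    dplyr::select(site_id = "group", tla_slope = "slope")
  biotic <- site_alpha |>
    dplyr::inner_join(dplyr::select(beta, "site_id", "beta"), by = "site_id") |>
    dplyr::inner_join(site_slope, by = "site_id")
  chem_site <- built$composites |>
    dplyr::select("site_id", "sample_id") |>
    dplyr::bind_cols(tibble::as_tibble(as.matrix(built$x))) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::where(is.numeric), mean),
      .groups = "drop"
    )
  # chemistry is already transformed; biotic summaries get the policy
  screen <- pearson_screen(biotic, chem_site, transform = FALSE)
  p_cor <- file.path(out_dir, "correlations.csv")
  write_artifact(screen, p_cor, prov)

  invisible(list(
    alpha = alpha, beta = beta, tla = tla_tbl,
    cca = cca, cca_test = cca_test,
    forward_selection = fs, variance_partition = vp,
    correlations = screen,
    paths = c(
      diversity = p_alpha, beta = p_beta, tla = p_tla,
      cca = p_cca, correlations = p_cor
    )
  ))
}

provenance_list <- function(config) {
  c(
    list(package = "lagbeta", version = as.character(utils::packageVersion("lagbeta"))),
    lapply(unclass(config), function(v) if (is.null(v)) NA else v)
  )
}

provenance_header <- function(config) {
  paste0(
    "# ",
    jsonlite::toJSON(provenance_list(config), auto_unbox = TRUE, digits = NA)
  )
}

write_artifact <- function(tbl, path, header) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con)
  readr::write_csv(tbl, con)
  invisible(path)
}

#' Read a pipeline CSV artifact, skipping the provenance header
#'
#' @param path Artifact path written by [run_full_pipeline()].
#' @return The tibble, with the provenance line in attribute
#'   `"provenance"`.
#' @export
read_artifact <- function(path) {
  prov <- readLines(path, n = 1L)
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  attr(out, "provenance") <- sub("^# ", "", prov)
  out
}
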