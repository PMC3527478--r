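#' Canonical correspondence analysis
#'
#' Constrained ordination of a non-negative community matrix `Y` on
#' environmental variables `X`, in the classical chi-square formulation:
#' the doubly standardized matrix
#' \eqn{Q_{ij} = (p_{ij} - r_i c_j)/\sqrt{r_i c_j}} (with \eqn{p} the
#' matrix of proportions, \eqn{r} row masses and \eqn{c} column masses) is
#' projected, with row-mass weighting, onto the span of the standardized
#' environmental variables; singular values of the fitted matrix give the
#' constrained eigenvalues. Total inertia is \eqn{\sum_{ij} Q_{ij}^2}, the
#' sum of all correspondence-analysis eigenvalues.
#'
#' With covariables `Z` (partial CCA) the weighted fit of `Z` is removed
#' from both `Q` and `X` before projection, and the explained fraction is
#' reported against the *original* total inertia, so unique fractions from
#' different focus variables are on a common scale.
#'
#' @param y Community data: a samples-by-species non-negative matrix, or a
#'   fingerprint tibble (first column `sample_id`).
#' @param x Environmental variables: numeric matrix or data frame with one
#'   row per sample.
#' @param z Optional covariables, same row order as `x`.
#' @param standardize If `TRUE` (default), environmental variables are
#'   standardized to weighted mean 0 and weighted variance 1, making
#'   biplot arrow lengths comparable.
#' @return An object of class `cca_fit`: `eigenvalues` (constrained,
#'   ordered), `total_inertia`, `constrained_inertia`,
#'   `explained_fraction`, `residual_inertia`, `rank_x`, `rank_z`,
#'   `site_scores`, `species_scores` (scaled by eigenvalues, type-2
#'   scaling), `biplot_arrows`, and the row/column masses.
#' @export
cca_fit <- function(y, x, z = NULL, standardize = TRUE) {
  ym <- as_community_matrix(y)
  xm <- as_predictor_matrix(x, nrow(ym))
  zm <- if (!is.null(z)) as_predictor_matrix(z, nrow(ym)) else NULL
  cca_engine(ym, xm, zm, standardize = standardize)
}

cca_engine <- function(Y, X, Z = NULL, standardize = TRUE) {
  n <- nrow(Y)
  if (n < 3) rlang::abort("CCA needs at least 3 samples")
  if (any(rowSums(Y) <= 0)) {
    rlang::abort("community matrix has an all-zero sample row",
      class = "lagbeta_domain_error"
    )
  }
  keep_sp <- colSums(Y) > 0
  Y <- Y[, keep_sp, drop = FALSE]

  P <- Y / sum(Y)
  r <- rowSums(P)
  cm <- colSums(P)
  Q <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  total <- sum(Q^2)
  if (total < 1e-12) {
    rlang::abort("community matrix has no compositional variation (total inertia 0)",
      class = "lagbeta_degenerate_design_error"
    )
  }

  Xw <- weight_predictors(X, r, standardize)
  rank_z <- 0L
  Q1 <- Q
  Xw1 <- Xw
  if (!is.null(Z)) {
    Zw <- weight_predictors(Z, r, standardize)
    qz <- qr(Zw)
    rank_z <- qz$rank
    Q1 <- Q - qr.fitted(qz, Q)
    Xw1 <- Xw - qr.fitted(qz, Xw)
  }
  # drop focus columns absorbed by the covariables (residual numerically 0);
  # a copy of a covariable then has, correctly, nothing left to explain
  orig_norm <- sqrt(colSums(Xw^2))
  live <- sqrt(colSums(Xw1^2)) > 1e-8 * pmax(orig_norm, .Machine$double.xmin)
  Xw1 <- Xw1[, live, drop = FALSE]
  if (ncol(Xw1) == 0) {
    return(empty_cca_fit(Q1, total, n, rank_z, rownames(Y), colnames(Y), r, cm))
  }
  qx <- qr(Xw1)
  rank_x <- qx$rank
  if (rank_x + rank_z >= n - 1) {
    rlang::abort("predictors saturate the sample space (rank >= n - 1)",
      class = "lagbeta_saturated_design_error"
    )
  }

  Qhat <- qr.fitted(qx, Q1)
  sv <- svd(Qhat)
  eig <- sv$d^2
  naxes <- min(rank_x, sum(eig > max(eig[1], 1e-300) * 1e-12))
  eig_kept <- eig[seq_len(naxes)]
  constrained <- sum(eig)
  residual <- sum((Q1 - Qhat)^2)

  u <- sv$u[, seq_len(naxes), drop = FALSE]
  v <- sv$v[, seq_len(naxes), drop = FALSE]
  d <- sv$d[seq_len(naxes)]
  site_scores <- (1 / sqrt(r)) * u
  species_scores <- (1 / sqrt(cm)) * v %*% diag(d, naxes)
  arrows <- crossprod(Xw1, u)
  axis_names <- paste0("CCA", seq_len(naxes))
  colnames(site_scores) <- colnames(species_scores) <- colnames(arrows) <- axis_names
  rownames(site_scores) <- rownames(Y)
  rownames(species_scores) <- colnames(Y)
  rownames(arrows) <- colnames(X)

  structure(
    list(
      eigenvalues = eig_kept,
      total_inertia = total,
      constrained_inertia = constrained,
      explained_fraction = constrained / total,
      residual_inertia = residual,
      rank_x = rank_x,
      rank_z = rank_z,
      n = n,
      site_scores = site_scores,
      species_scores = species_scores,
      biplot_arrows = arrows,
      row_masses = r,
      col_masses = cm
    ),
    class = "cca_fit"
  )
}

empty_cca_fit <- function(Q1, total, n, rank_z, site_ids, band_ids, r, cm) {
  structure(
    list(
      eigenvalues = numeric(0),
      total_inertia = total,
      constrained_inertia = 0,
      explained_fraction = 0,
      residual_inertia = sum(Q1^2),
      rank_x = 0L,
      rank_z = rank_z,
      n = n,
      site_scores = matrix(0, n, 0, dimnames = list(site_ids, NULL)),
      species_scores = matrix(0, length(band_ids), 0, dimnames = list(band_ids, NULL)),
      biplot_arrows = matrix(0, 0, 0),
      row_masses = r,
      col_masses = cm
    ),
    class = "cca_fit"
  )
}

weight_predictors <- function(X, r, standardize = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  wmean <- colSums(X * r)
  Xc <- sweep(X, 2, wmean)
  if (standardize) {
    wsd <- sqrt(colSums(Xc^2 * r))
    zero <- wsd < 1e-12
    if (any(zero)) {
      rlang::abort(
        paste("constant predictor column(s):",
              paste(colnames(X)[zero], collapse = ", ")),
        class = "lagbeta_degenerate_design_error"
      )
    }
    Xc <- sweep(Xc, 2, wsd, "/")
  }
  Xc * sqrt(r)
}

as_community_matrix <- function(y) {
  if (is.data.frame(y)) {
    if ("sample_id" %in% names(y)) {
      y <- y[setdiff(names(y), c("site_id", "date"))]
      return(band_matrix(y))
    }
    return(as.matrix(y))
  }
  m <- as.matrix(y)
  storage.mode(m) <- "double"
  m
}

as_predictor_matrix <- function(x, n) {
  m <- if (is.data.frame(x)) {
    as.matrix(x[vapply(x, is.numeric, logical(1))])
  } else {
    as.matrix(x)
  }
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("x", seq_len(ncol(m)))
  if (nrow(m) != n) rlang::abort("predictor rows do not match community samples")
  if (anyNA(m)) rlang::abort("predictors contain missing values")
  m
}

#' Unique explained fraction of focus variables given covariables
#'
#' Partial CCA: removes the weighted fit of the covariables from both the
#' chi-square community matrix and the focus variables, ordinates the
#' residuals, and reports the conditional constrained inertia as a
#' fraction of the original total inertia. With empty covariables this is
#' identical to [cca_fit()].
#'
#' @inheritParams cca_fit
#' @param x_focus Focus variables.
#' @param z_covariables Covariables (may be `NULL`).
#' @return The `cca_fit` for the conditional analysis; its
#'   `explained_fraction` is the unique fraction of `x_focus`.
#' @export
partial_cca <- function(y, x_focus, z_covariables = NULL, standardize = TRUE) {
  cca_fit(y, x_focus, z = z_covariables, standardize = standardize)
}

#' Monte Carlo permutation test for (partial) CCA
#'
#' The test statistic is the pseudo-F
#' \eqn{F = (I_{constr}/q) / (I_{resid}/(n - q - c - 1))} with \eqn{q} the
#' rank of the focus variables and \eqn{c} the rank of the covariables.
#' Under the reduced-model scheme the focus variables are residualized on
#' the covariables and the rows of those residuals are permuted; the
#' community matrix is held fixed. The p-value carries the +1 correction,
#' so it is never 0 and its floor is \eqn{1/(n_{perm}+1)}.
#'
#' @inheritParams partial_cca
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed; fixed seed gives bit-identical
#'   results.
#' @return A list: `pseudo_F`, `p_value`, `n_perm`, `rank_x`, `rank_z`,
#'   and the observed `fit`.
#' @export
cca_permutation_test <- function(y, x_focus, z_covariables = NULL,
                                 n_perm = 999, seed = NULL,
                                 standardize = TRUE) {
  stopifnot(n_perm >= 1)
  ym <- as_community_matrix(y)
  xm <- as_predictor_matrix(x_focus, nrow(ym))
  zm <- if (!is.null(z_covariables)) as_predictor_matrix(z_covariables, nrow(ym)) else NULL

  obs <- cca_engine(ym, xm, zm, standardize = standardize)
  df_res <- obs$n - obs$rank_x - obs$rank_z - 1
  if (df_res <= 0) {
    rlang::abort("non-positive residual degrees of freedom",
      class = "lagbeta_saturated_design_error"
    )
  }
  f_obs <- (obs$constrained_inertia / obs$rank_x) / (obs$residual_inertia / df_res)

  # precompute pieces shared by all permutations
  keep_sp <- colSums(ym) > 0
  Ym <- ym[, keep_sp, drop = FALSE]
  P <- Ym / sum(Ym)
  r <- rowSums(P)
  cm <- colSums(P)
  Q <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  Xw <- weight_predictors(xm, r, standardize)
  Q1 <- Q
  E <- Xw
  qz <- NULL
  if (!is.null(zm)) {
    Zw <- weight_predictors(zm, r, standardize)
    qz <- qr(Zw)
    Q1 <- Q - qr.fitted(qz, Q)
    E <- Xw - qr.fitted(qz, Xw)
  }
  E_sample <- E / sqrt(r) # residualized predictors back in sample space

  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Ym)
  f_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    Ep <- E_sample[sample.int(n), , drop = FALSE] * sqrt(r)
    if (!is.null(qz)) Ep <- Ep - qr.fitted(qz, Ep)
    qe <- qr(Ep)
    fitted <- qr.fitted(qe, Q1)
    constr <- sum(fitted^2)
    resid <- sum((Q1 - fitted)^2)
    f_perm[b] <- (constr / obs$rank_x) / (resid / df_res)
  }
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
  list(
    pseudo_F = f_obs, p_value = p, n_perm = n_perm,
    rank_x = obs$rank_x, rank_z = obs$rank_z, fit = obs
  )
}

#' Greedy forward selection of environmental variables for CCA
#'
#' At each step the candidate adding the largest conditional explained
#' inertia (given the already-selected variables) is proposed, and kept
#' only if its conditional permutation test is significant at `alpha`;
#' selection stops when no candidate passes, candidates are exhausted, or
#' `max_select` variables have been retained.
#'
#' @inheritParams cca_permutation_test
#' @param x_all Candidate variables (data frame or matrix, named columns).
#' @param alpha Retention threshold on the conditional permutation
#'   p-value (default 0.05). `alpha = 1` disables filtering, giving the
#'   pure greedy ordering.
#' @param max_select Maximum number of variables to retain.
#' @return An object of class `forward_selection`: tibble `trace` with
#'   columns `variable`, `added_fraction`, `cumulative_fraction`,
#'   `pseudo_F`, `p_value`, plus `selected` (character vector) and
#'   `stopping_reason`.
#' @export
forward_select_cca <- function(y, x_all, alpha = 0.05, n_perm = 999,
                               seed = NULL, max_select = Inf,
                               standardize = TRUE) {
  ym <- as_community_matrix(y)
  xm <- as_predictor_matrix(x_all, nrow(ym))
  candidates <- colnames(xm)
  if (!is.null(seed)) set.seed(seed)

  selected <- character(0)
  trace <- list()
  reason <- "candidates exhausted"
  cumulative <- 0
  while (length(selected) < min(length(candidates), max_select)) {
    remaining <- setdiff(candidates, selected)
    zc <- if (length(selected) > 0) xm[, selected, drop = FALSE] else NULL
    added <- vapply(remaining, function(v) {
      fit <- tryCatch(
        cca_engine(ym, xm[, v, drop = FALSE], zc, standardize = standardize),
        error = function(e) NULL
      )
      if (is.null(fit)) -Inf else fit$explained_fraction
    }, numeric(1))
    if (all(!is.finite(added))) {
      reason <- "no admissible candidate"
      break
    }
    best <- remaining[which.max(added)]
    test <- cca_permutation_test(ym, xm[, best, drop = FALSE], zc,
      n_perm = n_perm, standardize = standardize
    )
    keep <- test$p_value <= alpha
    if (keep) {
      selected <- c(selected, best)
      cumulative <- cumulative + added[[best]]
      trace[[length(trace) + 1]] <- tibble::tibble(
        variable = best,
        added_fraction = added[[best]],
        cumulative_fraction = cumulative,
        pseudo_F = test$pseudo_F,
        p_value = test$p_value
      )
      if (length(selected) >= max_select) {
        reason <- "max_select reached"
      } else if (length(selected) == length(candidates)) {
        reason <- "candidates exhausted"
      }
    } else {
      reason <- "no candidate significant"
      break
    }
  }
  structure(
    list(
      trace = if (length(trace) > 0) dplyr::bind_rows(trace) else
        tibble::tibble(
          variable = character(), added_fraction = numeric(),
          cumulative_fraction = numeric(), pseudo_F = numeric(),
          p_value = numeric()
        ),
      selected = selected,
      stopping_reason = reason,
      alpha = alpha,
      n_perm = n_perm
    ),
    class = "forward_selection"
  )
}

#' Variance partitioning across environmental variables
#'
#' Runs a full CCA on all variables for the total explained fraction, then
#' one partial CCA per variable (that variable as focus, all others as
#' covariables) for its unique conditional fraction. The residual fraction
#' is 1 minus the total explained fraction. Shared fractions are not
#' reported.
#'
#' @inheritParams forward_select_cca
#' @param n_perm If > 0, a conditional permutation test is run per
#'   variable and p-values are reported.
#' @return An object of class `variance_partition`: tibble `unique` with
#'   `variable`, `unique_fraction` (and `pseudo_F`, `p_value` when tested),
#'   plus `total_explained`, `residual`, `total_inertia`.
#' @export
variance_partition <- function(y, x_all, n_perm = 0, seed = NULL,
                               standardize = TRUE) {
  ym <- as_community_matrix(y)
  xm <- as_predictor_matrix(x_all, nrow(ym))
  if (!is.null(seed)) set.seed(seed)
  full <- cca_engine(ym, xm, NULL, standardize = standardize)
  vars <- colnames(xm)
  unique_tbl <- purrr::map_dfr(vars, function(v) {
    others <- xm[, setdiff(vars, v), drop = FALSE]
    zc <- if (ncol(others) > 0) others else NULL
    fit <- cca_engine(ym, xm[, v, drop = FALSE], zc, standardize = standardize)
    row <- tibble::tibble(variable = v, unique_fraction = fit$explained_fraction)
    if (n_perm > 0) {
      test <- cca_permutation_test(ym, xm[, v, drop = FALSE], zc,
        n_perm = n_perm, standardize = standardize
      )
      row$pseudo_F <- test$pseudo_F
      row$p_value <- test$p_value
    }
    row
  })
  structure(
    list(
      unique = unique_tbl,
      total_explained = full$explained_fraction,
      residual = 1 - full$explained_fraction,
      total_inertia = full$total_inertia
    ),
    class = "variance_partition"
  )
}

#' CCA of fingerprint composites against soil chemistry
#'
#' Convenience wrapper: builds per-(site, date) composite profiles,
#' broadcasts chemistry to the composites (averaging replicate-keyed
#' chemistry within each sampling), applies the log(x+1) transform policy
#' to all variables except pH, and runs [cca_fit()].
#'
#' @inheritParams composite_profiles
#' @param chemistry Chemistry tibble keyed by `sample_id` or
#'   `(site_id, date)`.
#' @param variables Character vector of chemistry columns to use;
#'   default: every numeric chemistry column.
#' @param transform Apply the log(x+1)-except-pH policy (default `TRUE`).
#' @param exempt Columns exempt from the transform (default `"ph"`).
#' @param ... Passed on to [cca_fit()].
#' @return A `cca_fit` plus attributes `composites` and `predictors`.
#' @export
cca_fingerprint <- function(fingerprint, metadata, chemistry,
                            variables = NULL,
                            replicate_policy = c("mean", "separate"),
                            transform = TRUE, exempt = "ph", ...) {
  replicate_policy <- match.arg(replicate_policy)
  built <- composite_predictors(
    fingerprint, metadata, chemistry, variables, replicate_policy, transform,
    exempt = exempt
  )
  fit <- cca_fit(built$y, built$x, ...)
  attr(fit, "composites") <- built$composites
  attr(fit, "predictors") <- built$x
  fit
}

#' Build aligned community and predictor matrices for ordination
#'
#' Collapses replicate fingerprints to per-`(site, date)` composites,
#' aggregates chemistry to the same level, inner-joins the two, and applies
#' the log(x+1)-except-pH transform policy to the predictors. This is the
#' data-preparation step behind [cca_fingerprint()], exposed for workflows
#' that need the matrices directly (e.g. [forward_select_cca()] or
#' [variance_partition()]).
#'
#' @inheritParams cca_fingerprint
#' @param replicate_policy `"mean"` (default) or `"separate"`, as in
#'   [composite_profiles()].
#' @return A list with `y` (community matrix, composites x bands), `x`
#'   (predictor tibble aligned to the rows of `y`), and `composites` (the
#'   composite profile tibble with `site_id` and `date`).
#' @export
composite_predictors <- function(fingerprint, metadata, chemistry,
                                 variables = NULL,
                                 replicate_policy = "mean",
                                 transform = TRUE, exempt = "ph") {
  comp <- composite_profiles(fingerprint, metadata, replicate_policy)
  if ("sample_id" %in% names(chemistry) && !all(c("site_id", "date") %in% names(chemistry))) {
    chemistry <- dplyr::inner_join(
      dplyr::select(metadata, "sample_id", "site_id", "date"),
      chemistry,
      by = "sample_id"
    )
  }
  chem_cols <- setdiff(
    names(chemistry)[vapply(chemistry, is.numeric, logical(1))],
    c("replicate")
  )
  chem_by_date <- chemistry |>
    dplyr::group_by(.data$site_id, .data$date) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(chem_cols), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  joined <- dplyr::inner_join(
    dplyr::select(comp, "site_id", "date", "sample_id"),
    chem_by_date,
    by = c("site_id", "date")
  )
  comp <- comp[match(joined$sample_id, comp$sample_id), , drop = FALSE]
  if (is.null(variables)) variables <- chem_cols
  x <- joined[variables]
  if (transform) x <- transform_variables(x, exempt = exempt)
  list(
    y = band_matrix(dplyr::select(comp, -"site_id", -"date")),
    x = x,
    composites = comp
  )
}

#' @export
print.cca_fit <- function(x, ...) {
  cat("<cca_fit>\n")
  cat("  total inertia:", format(x$total_inertia, digits = 5), "\n")
  cat("  constrained inertia:", format(x$constrained_inertia, digits = 5),
      sprintf("(%.1f%% explained)\n", 100 * x$explained_fraction))
  cat("  constrained eigenvalues:",
      paste(format(x$eigenvalues, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.forward_selection <- function(x, ...) {
  cat("<forward_selection>", length(x$selected), "variable(s) retained;",
      x$stopping_reason, "\n")
  print(x$trace)
  invisible(x)
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("<variance_partition>\n")
  cat(sprintf(
    "  total explained: %.1f%%   residual: %.1f%%\n",
    100 * x$total_explained, 100 * x$residual
  ))
  print(x$unique)
  invisible(x)
}

#' Tidy the eigenstructure of a CCA fit
#'
#' @param x A `cca_fit`.
#' @param ... Unused.
#' @return A tibble with one row per constrained axis: eigenvalue and the
#'   fraction of total inertia it carries.
#' @method tidy cca_fit
#' @export
tidy.cca_fit <- function(x, ...) {
  tibble::tibble(
    axis = paste0("CCA", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    fraction_of_total = x$eigenvalues / x$total_inertia
  )
}

#' One-row summary of a CCA fit
#'
#' @param x A `cca_fit`.
#' @param ... Unused.
#' @return A one-row tibble: inertia decomposition and ranks.
#' @method glance cca_fit
#' @export
glance.cca_fit <- function(x, ...) {
  tibble::tibble(
    total_inertia = x$total_inertia,
    constrained_inertia = x$constrained_inertia,
    explained_fraction = x$explained_fraction,
    rank_x = x$rank_x,
    rank_z = x$rank_z,
    n = x$n
  )
}

#' Tidy a variance partition into one row per variable
#'
#' @param x A `variance_partition`.
#' @param ... Unused.
#' @return The `unique` tibble with total/residual rows appended.
#' @method tidy variance_partition
#' @export
tidy.variance_partition <- function(x, ...) {
  dplyr::bind_rows(
    x$unique,
    tibble::tibble(
      variable = c("(all variables)", "(residual)"),
      unique_fraction = c(x$total_explained, x$residual)
    )
  )
}
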