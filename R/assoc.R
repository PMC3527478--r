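#' Apply the log(x+1) transform policy
#'
#' Applies `log(x + 1)` to every numeric column except those listed in
#' `exempt` (by default pH, which is already on a log scale). Key columns
#' (`sample_id`, `site_id`, `date`, `replicate`) are never transformed.
#' The transform applied to each column is recorded in the
#' `"transforms"` attribute.
#'
#' @param data A data frame of numeric variables.
#' @param exempt Character vector of column names left untransformed
#'   (matched case-insensitively); default `"ph"`.
#' @return The transformed tibble with a `"transforms"` attribute naming
#'   the treatment of every numeric column.
#' @export
transform_variables <- function(data, exempt = "ph") {
  keys <- c("sample_id", "site_id", "date", "replicate")
  out <- tibble::as_tibble(data)
  transforms <- character(0)
  for (col in names(out)) {
    if (col %in% keys || !is.numeric(out[[col]])) next
    if (tolower(col) %in% tolower(exempt)) {
      transforms[col] <- "identity"
      next
    }
    v <- out[[col]]
    if (any(v < -1 + 1e-12, na.rm = TRUE)) {
      rlang::abort(sprintf("column %s has values below -1; log(x+1) undefined", col),
        class = "lagbeta_domain_error"
      )
    }
    out[[col]] <- log1p(v)
    transforms[col] <- "log(x+1)"
  }
  attr(out, "transforms") <- transforms
  out
}

#' Pearson correlation screen between biotic and abiotic tables
#'
#' Computes the Pearson correlation and two-sided t-test p-value for every
#' (biotic, abiotic) variable pair over aligned observations, after
#' applying the log(x+1)-except-pH transform policy to both tables.
#' Missing cells are handled by pairwise-complete deletion; pairs with
#' fewer than 3 complete observations are reported with `NA` statistics
#' rather than failing the screen. Because such a grid multiplies tests, a
#' Benjamini-Hochberg adjusted q-value column is emitted alongside the raw
#' p-values.
#'
#' @param biotic,abiotic Data frames aligned by a shared key column
#'   (`sample_id` or `site_id`) when one exists in both, otherwise by row
#'   order.
#' @param exempt Columns exempt from the log(x+1) transform (default pH).
#' @param transform Apply the transform policy (default `TRUE`).
#' @return A tibble with one row per variable pair: `biotic`, `abiotic`,
#'   `r`, `p_value`, `q_bh`, `n`, `biotic_transform`, `abiotic_transform`.
#' @export
pearson_screen <- function(biotic, abiotic, exempt = "ph", transform = TRUE) {
  key <- intersect(
    intersect(c("sample_id", "site_id"), names(biotic)),
    names(abiotic)
  )
  if (length(key) > 0) {
    key <- key[1]
    merged <- dplyr::inner_join(biotic, abiotic,
      by = key, suffix = c(".biotic", ".abiotic")
    )
    bcols0 <- setdiff(names(biotic), key)
    acols0 <- setdiff(names(abiotic), key)
    bcols <- ifelse(bcols0 %in% acols0, paste0(bcols0, ".biotic"), bcols0)
    acols <- ifelse(acols0 %in% bcols0, paste0(acols0, ".abiotic"), acols0)
    b <- merged[bcols]
    a <- merged[acols]
    names(b) <- bcols0
    names(a) <- acols0
  } else {
    stopifnot(nrow(biotic) == nrow(abiotic))
    b <- tibble::as_tibble(biotic)
    a <- tibble::as_tibble(abiotic)
  }
  b <- b[vapply(b, is.numeric, logical(1))]
  a <- a[vapply(a, is.numeric, logical(1))]
  if (transform) {
    b <- transform_variables(b, exempt)
    a <- transform_variables(a, exempt)
  }
  tb <- attr(b, "transforms") %||% stats::setNames(rep("identity", ncol(b)), names(b))
  ta <- attr(a, "transforms") %||% stats::setNames(rep("identity", ncol(a)), names(a))

  grid <- tidyr::expand_grid(biotic = names(b), abiotic = names(a))
  out <- purrr::pmap_dfr(grid, function(biotic, abiotic) {
    x <- b[[biotic]]
    y <- a[[abiotic]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(tibble::tibble(
        biotic = biotic, abiotic = abiotic,
        r = NA_real_, p_value = NA_real_, n = n
      ))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(
      biotic = biotic, abiotic = abiotic,
      r = unname(ct$estimate), p_value = ct$p.value, n = n
    )
  })
  out$q_bh <- stats::p.adjust(out$p_value, method = "BH")
  out$biotic_transform <- unname(tb[out$biotic])
  out$abiotic_transform <- unname(ta[out$abiotic])
  out
}
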