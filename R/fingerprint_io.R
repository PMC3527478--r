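#' Read a fingerprint band table
#'
#' Reads a delimited (comma or tab, sniffed from the header line) table of
#' band intensities: first column `sample_id`, remaining columns numeric
#' band intensities, one row per sample. Band intensities are arbitrary
#' non-negative reals, typically relative band volumes exported from gel
#' analysis software.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param normalize If `TRUE` (default) each row is rescaled to sum to 1,
#'   so downstream analyses operate on relative abundances. All-zero rows
#'   are rejected under normalization.
#' @return A tibble with a character `sample_id` column followed by numeric
#'   band columns.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,b1,b2,b3", "s1,2,1,1", "s2,0,4,0"), tf)
#' read_fingerprint(tf)
#' @export
read_fingerprint <- function(path, normalize = TRUE) {
  raw <- read_delim_sniff(path)
  if (ncol(raw) < 2) {
    abort_format("fingerprint table needs a sample_id column plus at least one band column")
  }
  names(raw)[1] <- "sample_id"
  fp <- dplyr::mutate(raw, sample_id = as.character(.data$sample_id))
  validate_fingerprint(fp)
  if (normalize) fp <- normalize_fingerprint(fp)
  fp
}

#' Write a fingerprint band table
#'
#' @param fingerprint A fingerprint tibble (see [read_fingerprint()]).
#' @param path Output CSV path.
#' @return `fingerprint`, invisibly.
#' @export
write_fingerprint <- function(fingerprint, path) {
  validate_fingerprint(fingerprint)
  readr::write_csv(fingerprint, path)
  invisible(fingerprint)
}

#' Rescale each fingerprint row to relative abundance
#'
#' @param fingerprint A fingerprint tibble.
#' @return The fingerprint with every band row summing to 1.
#' @export
normalize_fingerprint <- function(fingerprint) {
  m <- band_matrix(fingerprint)
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    abort_validation(paste0(
      "cannot normalize all-zero sample row(s): ",
      paste(rownames(m)[rs <= 0], collapse = ", ")
    ))
  }
  as_fingerprint(m / rs)
}

#' Extract the numeric band matrix from a fingerprint tibble
#'
#' @param fingerprint A fingerprint tibble.
#' @return A numeric matrix, samples in rows (rownames = sample ids),
#'   bands in columns.
#' @export
band_matrix <- function(fingerprint) {
  stopifnot(is.data.frame(fingerprint), "sample_id" %in% names(fingerprint))
  m <- as.matrix(fingerprint[setdiff(names(fingerprint), "sample_id")])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(fingerprint$sample_id)
  m
}

#' Build a fingerprint tibble from a band matrix
#'
#' @param m Numeric matrix with sample ids as rownames.
#' @return A fingerprint tibble.
#' @export
as_fingerprint <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(m)),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `site_id`, `date`, `replicate`, `texture`.
#' Dates are parsed to day precision; month-only values such as `2009-04`
#' are taken as the 15th of the month so lag computations stay
#' deterministic. `texture` must be `"sandy"` or `"clayey"`.
#'
#' @param path Path to a CSV/TSV file.
#' @return A tibble ordered by site and date.
#' @export
read_sample_metadata <- function(path) {
  raw <- read_delim_sniff(path)
  required <- c("sample_id", "site_id", "date", "replicate", "texture")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort_format(paste("metadata is missing column(s):", paste(missing, collapse = ", ")))
  }
  md <- tibble::tibble(
    sample_id = as.character(raw$sample_id),
    site_id = as.character(raw$site_id),
    date = parse_sample_date(raw$date),
    replicate = as.integer(raw$replicate),
    texture = as.character(raw$texture)
  )
  validate_metadata(md)
  dplyr::arrange(md, .data$site_id, .data$date, .data$replicate)
}

#' Read a soil chemistry table
#'
#' Keyed either per sample (`sample_id`) or per site and date
#' (`site_id` + `date`), in which case values broadcast to all replicates
#' during alignment. Recognized variables: `ph`, `nh4` (mg/kg), `no3`
#' (mg/kg), `om` (%), `clay` (%), `moisture` (%); extra numeric columns
#' pass through untouched. Missing cells are allowed and propagate as `NA`.
#'
#' @param path Path to a CSV/TSV file.
#' @return A tibble with lower-cased variable names.
#' @export
read_chemistry <- function(path) {
  raw <- read_delim_sniff(path)
  names(raw) <- tolower(names(raw))
  if (!("sample_id" %in% names(raw)) && !all(c("site_id", "date") %in% names(raw))) {
    abort_format("chemistry table must be keyed by sample_id or by site_id + date")
  }
  if ("date" %in% names(raw)) raw$date <- parse_sample_date(raw$date)
  for (col in c("sample_id", "site_id")) {
    if (col %in% names(raw)) raw[[col]] <- as.character(raw[[col]])
  }
  validate_chemistry(raw)
  tibble::as_tibble(raw)
}

#' Align fingerprint, metadata and chemistry by sample key
#'
#' Inner-joins the fingerprint and metadata on `sample_id` and attaches
#' chemistry either per sample or broadcast from a (site, date) key to all
#' replicates of that sampling. Samples present in only one input are
#' dropped and reported.
#'
#' @param fingerprint A fingerprint tibble.
#' @param metadata A metadata tibble (see [read_sample_metadata()]).
#' @param chemistry Optional chemistry tibble (see [read_chemistry()]).
#' @return A `fingerprint_dataset`: list with elements `fingerprint`,
#'   `metadata`, `chemistry` (all restricted to the shared samples) and
#'   `dropped` (character vector of sample ids lost in the join).
#' @export
align_samples <- function(fingerprint, metadata, chemistry = NULL) {
  validate_fingerprint(fingerprint)
  validate_metadata(metadata)
  keep <- intersect(fingerprint$sample_id, metadata$sample_id)
  if (length(keep) == 0) {
    rlang::abort("no sample ids shared between fingerprint and metadata",
      class = "lagbeta_alignment_error"
    )
  }
  dropped <- union(
    setdiff(fingerprint$sample_id, keep),
    setdiff(metadata$sample_id, keep)
  )
  md <- dplyr::filter(metadata, .data$sample_id %in% keep)
  fp <- fingerprint[match(md$sample_id, fingerprint$sample_id), , drop = FALSE]

  chem <- NULL
  if (!is.null(chemistry)) {
    if ("sample_id" %in% names(chemistry)) {
      chem <- dplyr::inner_join(
        dplyr::select(md, "sample_id"), chemistry,
        by = "sample_id"
      )
    } else {
      chem <- dplyr::inner_join(
        dplyr::select(md, "sample_id", "site_id", "date"), chemistry,
        by = c("site_id", "date")
      )
    }
    if (nrow(chem) == 0) {
      rlang::abort("chemistry keys do not intersect the aligned samples",
        class = "lagbeta_alignment_error"
      )
    }
  }

  structure(
    list(fingerprint = fp, metadata = md, chemistry = chem, dropped = dropped),
    class = "fingerprint_dataset"
  )
}

#' @export
print.fingerprint_dataset <- function(x, ...) {
  cat("<fingerprint_dataset>\n")
  cat("  samples:", nrow(x$fingerprint), " bands:", ncol(x$fingerprint) - 1L, "\n")
  cat("  sites:", length(unique(x$metadata$site_id)),
      " dates:", length(unique(x$metadata$date)), "\n")
  if (!is.null(x$chemistry)) {
    cat("  chemistry variables:",
        paste(setdiff(names(x$chemistry), c("sample_id", "site_id", "date")),
              collapse = ", "), "\n")
  }
  if (length(x$dropped) > 0) {
    cat("  dropped samples:", length(x$dropped), "\n")
  }
  invisible(x)
}

# --- internal helpers ------------------------------------------------------

read_delim_sniff <- function(path) {
  if (!file.exists(path)) abort_format(paste("file not found:", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    trim_ws = TRUE
  )
}

parse_sample_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- trimws(as.character(x))
  # month-precision inputs become the 15th of the month
  x <- ifelse(grepl("^\\d{4}-\\d{2}$", x), paste0(x, "-15"), x)
  out <- as.Date(x, format = "%Y-%m-%d")
  if (anyNA(out[!is.na(x)])) {
    bad <- unique(x[is.na(out) & !is.na(x)])
    abort_format(paste("unparseable date(s):", paste(bad, collapse = ", ")))
  }
  out
}

validate_fingerprint <- function(fp) {
  if (!"sample_id" %in% names(fp)) abort_format("fingerprint lacks a sample_id column")
  if (anyDuplicated(fp$sample_id)) {
    abort_format(paste(
      "duplicated sample id(s):",
      paste(unique(fp$sample_id[duplicated(fp$sample_id)]), collapse = ", ")
    ))
  }
  band_cols <- setdiff(names(fp), "sample_id")
  if (anyDuplicated(band_cols)) abort_format("duplicated band id(s)")
  m <- band_matrix(fp)
  if (anyNA(m)) abort_validation("fingerprint contains missing band intensities")
  if (any(m < 0)) abort_validation("negative band intensity")
  invisible(fp)
}

validate_metadata <- function(md) {
  if (anyDuplicated(md$sample_id)) abort_format("duplicated sample id in metadata")
  bad <- setdiff(unique(md$texture), c("sandy", "clayey"))
  if (length(bad) > 0) {
    abort_validation(paste("unknown texture class:", paste(bad, collapse = ", ")))
  }
  if (anyNA(md$date)) abort_format("missing or unparseable metadata date")
  invisible(md)
}

validate_chemistry <- function(chem) {
  check_range <- function(col, lo, hi) {
    if (col %in% names(chem)) {
      v <- chem[[col]]
      if (any(v < lo | v > hi, na.rm = TRUE)) {
        abort_validation(sprintf("%s outside [%g, %g]", col, lo, hi))
      }
    }
  }
  check_range("ph", 0, 14)
  for (col in c("om", "clay", "moisture")) check_range(col, 0, 100)
  for (col in c("nh4", "no3")) {
    if (col %in% names(chem) && any(chem[[col]] < 0, na.rm = TRUE)) {
      abort_validation(paste(col, "contains negative concentrations"))
    }
  }
  invisible(chem)
}

abort_format <- function(msg) rlang::abort(msg, class = "lagbeta_format_error")
abort_validation <- function(msg) rlang::abort(msg, class = "lagbeta_validation_error")
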