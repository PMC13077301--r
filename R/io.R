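#' Read a tidy time-series dataset
#'
#' Reads a CSV with columns `time_h, id, replicate, observable, value` and
#' optional `below_detection`, validating types, non-negativity, and
#' (time, id, replicate, observable) key uniqueness. Malformed rows are
#' reported with their line numbers (header is line 1).
#'
#' @param path CSV file path.
#' @return A `ts_dataset` tibble. If a sidecar manifest written by
#'   [write_timeseries()] exists it is re-attached.
#' @export
read_timeseries <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("time_h", "id", "replicate", "observable", "value")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  line <- seq_len(nrow(raw)) + 1L
  time_h <- suppressWarnings(as.numeric(raw$time_h))
  value <- suppressWarnings(as.numeric(raw$value))
  replicate <- suppressWarnings(as.integer(raw$replicate))
  bad <- which(is.na(time_h) | is.na(value) | is.na(replicate) | value < 0)
  if (length(bad)) {
    stop("malformed rows (non-numeric or negative values) at line(s): ",
         paste(utils::head(line[bad], 10), collapse = ", "), call. = FALSE)
  }
  key <- paste(raw$time_h, raw$id, raw$replicate, raw$observable)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    stop("duplicate (time, id, replicate, observable) keys at line(s): ",
         paste(line[dup], collapse = ", "), call. = FALSE)
  }
  below <- if ("below_detection" %in% names(raw)) {
    as.logical(raw$below_detection)
  } else {
    rep(FALSE, nrow(raw))
  }
  records <- tibble::tibble(time_h = time_h, id = raw$id,
                            replicate = replicate,
                            observable = raw$observable, value = value,
                            below_detection = below)
  manifest_path <- manifest_path_for(path)
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  new_ts_dataset(records, manifest)
}

manifest_path_for <- function(path) sub("\\.csv$", "_manifest.json", path)

#' Write a time-series dataset (CSV plus JSON manifest)
#'
#' @param x A `ts_dataset` (or compatible tibble).
#' @param path Output CSV path; the provenance manifest, if present, is
#'   written next to it as `<stem>_manifest.json`.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  cols <- c("time_h", "id", "replicate", "observable", "value",
            "below_detection")
  stopifnot(all(cols %in% names(x)))
  readr::write_csv(dplyr::select(x, dplyr::all_of(cols)), path)
  manifest <- dataset_manifest(x)
  if (!is.null(manifest)) {
    manifest$file_md5 <- unname(tools::md5sum(path))
    jsonlite::write_json(manifest, manifest_path_for(path),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", force = TRUE)
  }
  invisible(path)
}

#' Read an infection matrix from CSV
#'
#' Hosts as rows (first column = host id), phage as columns, entries 0/1.
#'
#' @param path CSV file path.
#' @param n_hosts,n_phages Optional declared dimensions; a mismatch is an
#'   error (guards against transposed files).
#' @return An [infection_matrix()].
#' @export
read_infection_matrix <- function(path, n_hosts = NULL, n_phages = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  hosts <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!all(m %in% c(0, 1))) {
    stop("infection matrix entries must be 0/1", call. = FALSE)
  }
  if (!is.null(n_hosts) && nrow(m) != n_hosts) {
    stop(sprintf("expected %d hosts but file has %d rows (transposed file?)",
                 n_hosts, nrow(m)), call. = FALSE)
  }
  if (!is.null(n_phages) && ncol(m) != n_phages) {
    stop(sprintf("expected %d phages but file has %d columns (transposed file?)",
                 n_phages, ncol(m)), call. = FALSE)
  }
  infection_matrix(m, hosts = hosts, phages = colnames(m))
}

#' Write an infection matrix to CSV
#'
#' @param x An [infection_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_infection_matrix <- function(x, path) {
  stopifnot(inherits(x, "infection_matrix"))
  df <- tibble::as_tibble(1 * x$mask)
  df <- dplyr::bind_cols(tibble::tibble(host_id = x$hosts), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a per-pair trait table from CSV
#'
#' Expected columns: `host_id, phage_id, r, phi, tau, n_e, beta`.
#'
#' @param path CSV file path.
#' @return A validated trait table tibble.
#' @export
read_trait_table <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  tb$n_e <- as.integer(tb$n_e)
  validate_trait_table(tb)
  tibble::as_tibble(tb)
}

#' Write a per-pair trait table to CSV
#'
#' @param x Trait table tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(x, path) {
  validate_trait_table(x)
  readr::write_csv(x, path)
  invisible(path)
}
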