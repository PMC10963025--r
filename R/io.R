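#' Write a count matrix to CSV with a JSON metadata sidecar
#'
#' The on-disk form is one row per train with header columns
#' `stim_1 .. stim_n`, comma-separated, UTF-8.  Counts are always stored
#' per synapse.  Provenance (protocol, generating parameters, seed) goes
#' to `<path>.json` unless `sidecar = FALSE`.
#'
#' @param cm A [count_matrix()].
#' @param path Output CSV path.
#' @param sidecar Write the JSON sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path, sidecar = TRUE) {
  stopifnot(inherits(cm, "count_matrix"))
  utils::write.csv(as.data.frame(cm$counts), path, row.names = FALSE,
                   quote = FALSE)
  if (sidecar) {
    meta <- list(protocol = unclass(cm$protocol),
                 normalization = cm$normalization,
                 params = if (!is.null(cm$params)) unclass(cm$params),
                 ip = if (!is.null(cm$ip)) unclass(cm$ip),
                 seed = cm$seed, scheduling = cm$scheduling)
    jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a count matrix from CSV
#'
#' Reads the format written by [write_count_matrix()], restoring protocol
#' and provenance from the JSON sidecar when present.  Malformed cells
#' (negative, non-integer, or missing values) raise an error naming the
#' offending row and column.
#'
#' Spreadsheet exports with extra columns or different headers are
#' supported through `colmap`: a character vector of the file's column
#' names, in stimulus order, mapping that layout onto `stim_1 ..`.
#'
#' @param path CSV path.
#' @param colmap Optional character vector of source column names in
#'   stimulus order.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, colmap = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(colmap)) {
    missing_cols <- setdiff(colmap, names(df))
    if (length(missing_cols) > 0) {
      stop("columns not found in ", path, ": ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    df <- df[colmap]
    names(df) <- paste0("stim_", seq_along(colmap))
  }
  for (j in seq_along(df)) {
    x <- df[[j]]
    bad <- which(!is.finite(x) | x < 0 | x != round(x))
    if (length(bad) > 0) {
      stop(sprintf("invalid count at row %d, column '%s' of %s",
                   bad[1], names(df)[j], path), call. = FALSE)
    }
  }
  counts <- as.matrix(df)
  sidecar <- paste0(path, ".json")
  protocol <- NULL
  out <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    protocol <- train_protocol(meta$protocol$n_stim,
                               meta$protocol$freq_hz,
                               nrow(counts))
    out <- count_matrix(counts, protocol)
    if (!is.null(meta$params)) {
      out$params <- model_params(meta$params$model_kind,
                                 meta$params$n_sites, meta$params$delta,
                                 meta$params$rho, meta$params$p_r,
                                 meta$params$r, meta$params$s)
    }
    out$seed <- meta$seed
    out$scheduling <- meta$scheduling
    out$normalization <- meta$normalization
  } else {
    out <- count_matrix(counts)
  }
  out
}

#' Write / read an event raster as CSV
#'
#' Columns `train`, `stimulus`, `latency_ms`, `pathway`.
#'
#' @param raster An [event_raster()].
#' @param path CSV path.
#' @return `path` (write) or an `event_raster` (read).
#' @export
write_event_raster <- function(raster, path) {
  stopifnot(inherits(raster, "event_raster"))
  utils::write.csv(as.data.frame(raster), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_event_raster
#' @param protocol Protocol to attach on read.
#' @export
read_event_raster <- function(path, protocol = NULL) {
  df <- utils::read.csv(path)
  event_raster(df$train, df$stimulus, df$latency_ms, df$pathway, protocol)
}

#' Write / read a current trace as two-column CSV
#'
#' Columns `time_ms`, `current_pa`.
#' @param trace A `synaptic_trace` (or compatible data frame).
#' @param path CSV path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_ms = trace$time_ms,
                              current_pa = trace$current_pa),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  structure(df, class = c("synaptic_trace", "data.frame"))
}
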