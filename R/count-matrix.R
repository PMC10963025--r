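#' Construct a count matrix of released vesicles
#'
#' The central observable of the analysis: an integer matrix of released
#' synaptic-vesicle counts with one row per stimulation train and one
#' column per stimulus within the train (`s_i` for train `t`).
#'
#' @param counts Integer matrix, trains by stimuli; all cells must be
#'   non-negative integers.
#' @param protocol A [train_protocol()]; its `n_stim` and `n_trains` must
#'   match the matrix dimensions (`n_trains` is updated to `nrow(counts)`
#'   if it differs).
#' @param normalization `"per_synapse"` (raw counts, the stored form) or
#'   `"per_site"` (counts divided by the docking-site number; only
#'   produced as a view, never stored on disk).
#' @param params,ip,seed,scheduling Optional provenance of simulated data.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, protocol = NULL,
                         normalization = "per_synapse") {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(!is.finite(counts)) ||
      any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be a matrix of non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (is.null(protocol)) {
    protocol <- train_protocol(ncol(counts), 100, nrow(counts))
  }
  if (ncol(counts) != protocol$n_stim) {
    stop("`counts` has ", ncol(counts), " columns but the protocol has ",
         protocol$n_stim, " stimuli", call. = FALSE)
  }
  protocol$n_trains <- nrow(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("stim_", seq_len(ncol(counts)))
  }
  new_count_matrix(counts, protocol, normalization = normalization)
}

new_count_matrix <- function(counts, protocol,
                             normalization = "per_synapse",
                             params = NULL, ip = NULL, seed = NULL,
                             scheduling = NULL) {
  structure(list(counts = counts, protocol = protocol,
                 normalization = normalization, params = params,
                 ip = ip, seed = seed, scheduling = scheduling),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d trains x %d stimuli (%g Hz), %s\n",
              nrow(x$counts), ncol(x$counts), x$protocol$freq_hz,
              x$normalization))
  cat("  mean counts:",
      paste(sprintf("%.2f", colMeans(x$counts)), collapse = " "), "\n")
  invisible(x)
}

#' Per-site view of a count matrix
#'
#' Divides counts by the docking-site number `N`.  This is a derived view
#' used for normalized summaries; on-disk count matrices are always stored
#' per synapse.
#'
#' @param cm A `count_matrix`.
#' @param n_sites Docking-site number; defaults to the generating model's
#'   `n_sites` when the matrix came from a simulation.
#' @return A numeric matrix of per-site counts.
#' @export
per_site_counts <- function(cm, n_sites = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(n_sites)) {
    if (is.null(cm$params)) {
      stop("`n_sites` must be given for data without model provenance",
           call. = FALSE)
    }
    n_sites <- cm$params$n_sites
  }
  cm$counts / n_sites
}

#' Event raster of release latencies
#'
#' One row per release event: the train and stimulus it belongs to, the
#' latency from stimulus onset in ms, and a pathway tag (`"fast"` for
#' direct docked-vesicle release, `"slow"` for two-step release).
#'
#' @param train,stimulus Integer vectors.
#' @param latency_ms Non-negative numeric vector.
#' @param pathway Character vector (`"fast"`/`"slow"`).
#' @param protocol A [train_protocol()].
#' @return A data frame of class `event_raster` with attribute
#'   `protocol`.
#' @export
event_raster <- function(train = integer(), stimulus = integer(),
                         latency_ms = numeric(),
                         pathway = character(), protocol = NULL) {
  if (any(latency_ms < 0)) {
    stop("latencies must be non-negative", call. = FALSE)
  }
  if (length(pathway) == 0 && length(train) > 0) {
    pathway <- rep("fast", length(train))
  }
  df <- data.frame(train = as.integer(train),
                   stimulus = as.integer(stimulus),
                   latency_ms = as.numeric(latency_ms),
                   pathway = as.character(pathway))
  structure(df, class = c("event_raster", "data.frame"),
            protocol = protocol)
}

#' Absolute event times within a train, in ms
#'
#' @param raster An `event_raster`.
#' @param protocol Protocol; defaults to the raster's own.
#' @return Numeric vector: `(stimulus - 1) * interval + latency`.
#' @export
event_times_ms <- function(raster, protocol = attr(raster, "protocol")) {
  stopifnot(inherits(raster, "event_raster"), !is.null(protocol))
  (raster$stimulus - 1) * interval_ms(protocol) + raster$latency_ms
}

#' Simulate trains and attach fast-pathway release latencies
#'
#' Runs [simulate_trains()] and draws one latency per released vesicle
#' from the fast (docked-release) component of the latency model: an
#' exponential with time constant `tau_fast_ms` shifted by
#' `onset_delay_ms`.  The discrete-time model has no intra-interval
#' fusion, so no slow-pathway events are generated here; mixtures with a
#' slow component are produced by [generate_condition_dataset()].
#'
#' @inheritParams simulate_trains
#' @param latency A [latency_model()].
#' @return A list with `counts` (the `count_matrix`) and `raster` (an
#'   `event_raster`).
#' @export
simulate_events <- function(params, protocol, latency = latency_model(),
                            ip = NULL, seed = NULL) {
  stopifnot(inherits(latency, "latency_model"))
  local_seed(seed)
  cm <- simulate_trains(params, protocol, ip = ip)
  k <- cm$counts
  n_ev <- sum(k)
  if (n_ev == 0) {
    return(list(counts = cm,
                raster = event_raster(protocol = protocol)))
  }
  idx <- which(k > 0, arr.ind = TRUE)
  reps <- k[k > 0]
  train <- rep(idx[, 1], reps)
  stimulus <- rep(idx[, 2], reps)
  lat <- latency$onset_delay_ms +
    stats::rexp(n_ev, rate = 1 / latency$tau_fast_ms)
  o <- order(train, stimulus, lat)
  list(counts = cm,
       raster = event_raster(train[o], stimulus[o], lat[o],
                             rep("fast", n_ev), protocol))
}
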