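# Brute-force oracle: exhaustive enumeration of the single-site
# probability tree (every Bernoulli branch expanded) for short trains.
# Independent of the package's simulator and of its state-distribution
# recursion: works on explicit outcome paths.

# Returns a data.frame with columns s1..s<n_stim> and prob, one row per
# distinct release-count path, probabilities summing to 1.
enumerate_site <- function(model_kind, delta, rho, p_r, r, s, n_stim) {
  acc <- list()
  record <- function(counts, prob) {
    key <- paste(counts, collapse = ",")
    acc[[key]] <<- (if (is.null(acc[[key]])) 0 else acc[[key]]) + prob
  }

  if (model_kind == "RSDS") {
    step <- function(rs, ds, i, counts, prob) {
      if (i > n_stim) {
        record(counts, prob)
        return(invisible())
      }
      release <- function(rs, ds, rel, pr) {
        cnt <- counts
        cnt[i] <- cnt[i] + rel
        dock(rs, ds, cnt, pr)
      }
      dock <- function(rs, ds, cnt, pr) {
        if (rs && !ds) {
          replenish(0, 1, cnt, pr * r)
          replenish(1, 0, cnt, pr * (1 - r))
        } else {
          replenish(rs, ds, cnt, pr)
        }
      }
      replenish <- function(rs, ds, cnt, pr) {
        if (!rs) {
          nxt(1, ds, cnt, pr * s)
          nxt(0, ds, cnt, pr * (1 - s))
        } else {
          nxt(rs, ds, cnt, pr)
        }
      }
      nxt <- function(rs, ds, cnt, pr) {
        if (pr > 0) step(rs, ds, i + 1, cnt, pr)
      }
      if (ds) {
        release(rs, 0, 1, prob * p_r)
        release(rs, 1, 0, prob * (1 - p_r))
      } else {
        release(rs, 0, 0, prob)
      }
    }
    init <- expand.grid(rs = c(1, 0), ds = c(1, 0))
    for (k in seq_len(nrow(init))) {
      p0 <- (if (init$rs[k]) rho else 1 - rho) *
        (if (init$ds[k]) delta else 1 - delta)
      if (p0 > 0) step(init$rs[k], init$ds[k], 1, numeric(n_stim), p0)
    }
  } else {
    # LSTS slot state: 0 empty, 1 loose, 2 tight
    step <- function(st, i, counts, prob) {
      if (i > n_stim) {
        record(counts, prob)
        return(invisible())
      }
      dock <- function(st, cnt, pr) {
        if (st == 1) {
          replenish(2, cnt, pr * r)
          replenish(1, cnt, pr * (1 - r))
        } else {
          replenish(st, cnt, pr)
        }
      }
      replenish <- function(st, cnt, pr) {
        if (st == 0) {
          nxt(1, cnt, pr * s)
          nxt(0, cnt, pr * (1 - s))
        } else {
          nxt(st, cnt, pr)
        }
      }
      nxt <- function(st, cnt, pr) {
        if (pr > 0) step(st, i + 1, cnt, pr)
      }
      if (st == 2) {
        cnt <- counts
        cnt[i] <- cnt[i] + 1
        dock(0, cnt, prob * p_r)
        dock(2, counts, prob * (1 - p_r))
      } else {
        dock(st, counts, prob)
      }
    }
    for (st in 0:2) {
      p0 <- switch(as.character(st),
                   "2" = delta,
                   "1" = (1 - delta) * rho,
                   "0" = (1 - delta) * (1 - rho))
      if (p0 > 0) step(st, 1, numeric(n_stim), p0)
    }
  }

  keys <- names(acc)
  counts <- do.call(rbind, lapply(strsplit(keys, ","), as.numeric))
  out <- as.data.frame(counts)
  names(out) <- paste0("s", seq_len(n_stim))
  out$prob <- unlist(acc, use.names = FALSE)
  stopifnot(abs(sum(out$prob) - 1) < 1e-12)
  out
}

# Expected per-stimulus means from the enumerated distribution.
enum_means <- function(dist) {
  sc <- grep("^s\\d+$", names(dist))
  vapply(sc, function(j) sum(dist[[j]] * dist$prob), numeric(1))
}

# Exact cov(S_i, s_{i+1}) from the enumerated distribution.
enum_covariance <- function(dist) {
  sc <- grep("^s\\d+$", names(dist))
  n_stim <- length(sc)
  S <- t(apply(as.matrix(dist[sc]), 1, cumsum))
  vapply(seq_len(n_stim - 1), function(i) {
    x <- S[, i]
    y <- dist[[sc[i + 1]]]
    mx <- sum(x * dist$prob)
    my <- sum(y * dist$prob)
    sum((x - mx) * (y - my) * dist$prob)
  }, numeric(1))
}

# Monte-Carlo standard error of a per-stimulus mean.
mc_se <- function(x) stats::sd(x) / sqrt(length(x))

# Standard error of the empirical covariance of (x, y).
cov_se <- function(x, y) {
  z <- (x - mean(x)) * (y - mean(y))
  stats::sd(z) / sqrt(length(z))
}
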