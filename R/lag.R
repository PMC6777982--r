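#' Standardize a signal (mean 0, population sd 1)
#'
#' De-means and scales by the population (1/T) standard deviation, the
#' normalization under which the zero-shift self-correlation of the
#' cross-correlogram equals exactly 1.
#'
#' @param x numeric vector, length >= 2, finite, non-constant.
#' @return standardized vector.
#' @export
standardize <- function(x) {
  if (length(x) < 2) stop_invalid("need at least 2 samples")
  if (any(!is.finite(x))) stop_invalid("signal contains non-finite values")
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) stop_degenerate("constant signal: sd is zero")
  (x - mu) / s
}

#' Shifted cross-correlogram of two signals
#'
#' Computes, for every integer shift \eqn{k} with \eqn{|k| \le
#' \tau_{max}/TR},
#' \deqn{C(k) = \frac{1}{n_k} \sum_t s_i(t)\, s_j(t + k), \qquad n_k = T - |k|,}
#' where \eqn{s_i, s_j} are the full-series standardized inputs and the sum
#' runs over the overlapping window. A positive peak shift means `s_j` is a
#' delayed copy of `s_i` (i leads).
#'
#' @param s_i,s_j numeric vectors of equal length T.
#' @param tr sampling interval in seconds.
#' @param tau_max maximum shift in seconds (default 10 s); rounded down to
#'   an integer number of samples.
#' @return object of class `cross_correlogram`: list with
#'   `shifts_seconds` (symmetric grid), `values`, `n_overlap`, `tr`.
#' @export
cross_correlogram <- function(s_i, s_j, tr, tau_max = 10) {
  if (length(s_i) != length(s_j)) stop_invalid("signals differ in length")
  if (tr <= 0 || tau_max <= 0) stop_invalid("need tr > 0 and tau_max > 0")
  T_ <- length(s_i)
  k_max <- floor(tau_max / tr + 1e-9)
  if (T_ <= 2 * k_max) {
    stop_invalid("series too short for the requested maximum shift")
  }
  si <- standardize(s_i)
  sj <- standardize(s_j)
  shifts <- (-k_max):k_max
  vals <- vapply(shifts, function(k) {
    if (k >= 0) {
      sum(si[seq_len(T_ - k)] * sj[seq_len(T_ - k) + k]) / (T_ - k)
    } else {
      sum(si[seq_len(T_ + k) - k] * sj[seq_len(T_ + k)]) / (T_ + k)
    }
  }, numeric(1))
  structure(list(shifts_seconds = shifts * tr, values = vals,
                 n_overlap = T_ - abs(shifts), tr = tr),
            class = "cross_correlogram")
}

#' Peak lag of a cross-correlogram with parabolic interpolation
#'
#' Locates the integer-shift argmax \eqn{k^*} and, when it is interior to
#' the grid, refines it with the vertex of the parabola through the three
#' points around the peak:
#' \deqn{\delta = \frac{C(k^*-1) - C(k^*+1)}
#'   {2\,[C(k^*-1) - 2C(k^*) + C(k^*+1)]}, \qquad \delta \in [-0.5, 0.5].}
#' Boundary peaks are returned uninterpolated and flagged so analyses can
#' exclude saturated estimates. Argmax ties break toward the smallest
#' absolute shift, then toward the negative shift.
#'
#' @param ccf a [cross_correlogram()].
#' @return list with `lag_seconds` (signed), `peak_correlation` (parabola
#'   vertex value at interior peaks), `boundary` flag.
#' @export
peak_lag <- function(ccf) {
  stopifnot(inherits(ccf, "cross_correlogram"))
  v <- ccf$values
  if (length(v) == 0) stop_invalid("empty correlogram")
  if (max(v) - min(v) == 0) stop_degenerate("flat correlogram")
  # deterministic tie-break: smallest |shift|, then negative shift
  ord <- order(-v, abs(ccf$shifts_seconds), ccf$shifts_seconds)
  k <- ord[1]

  if (k == 1L || k == length(v)) {
    return(list(lag_seconds = ccf$shifts_seconds[k],
                peak_correlation = v[k], boundary = TRUE))
  }
  a <- v[k - 1]; b <- v[k]; c <- v[k + 1]
  denom <- a - 2 * b + c
  delta <- if (denom == 0) 0 else (a - c) / (2 * denom)
  delta <- max(-0.5, min(0.5, delta))
  peak <- b + ((c - a) / 2) * delta + (denom / 2) * delta^2
  list(lag_seconds = ccf$shifts_seconds[k] + delta * ccf$tr,
       peak_correlation = peak, boundary = FALSE)
}

#' Homotopic synchronization lags for one subject
#'
#' Estimates the synchronization lag of every homotopic region pair from a
#' regions x timepoints BOLD matrix. The right-hemisphere signal is `s_i`
#' and the left `s_j`, so a positive lag means the right hemisphere leads
#' (the left signal is delayed). Constant signals are flagged degenerate and
#' excluded from averages rather than failing the whole subject.
#'
#' @param bold regions x timepoints matrix with rownames equal to
#'   `region_id` (or rows aligned with `regions`).
#' @param regions region table ([gen_parcellation()] schema).
#' @param tr repetition time in seconds.
#' @param tau_max maximum shift in seconds (default 10 s).
#' @return `data.frame` (one row per pair): `pair_id`, `region_left`,
#'   `region_right`, `lag_seconds`, `abs_lag_seconds`, `peak_correlation`,
#'   `zero_lag_r` (plain Pearson correlation at zero shift), `boundary`,
#'   `degenerate`.
#' @export
homotopic_lags <- function(bold, regions, tr, tau_max = 10) {
  check_regions(regions)
  bold <- as.matrix(bold)
  if (is.null(rownames(bold))) rownames(bold) <- regions$region_id
  if (any(!is.finite(bold))) stop_invalid("BOLD matrix contains non-finite values")
  pairs <- sort(unique(regions$pair_id))
  if (length(pairs) == 0) stop_invalid("no homotopic pairs in region table")

  rows <- lapply(pairs, function(p) {
    rid <- regions$region_id[regions$pair_id == p & regions$hemisphere == "right"]
    lid <- regions$region_id[regions$pair_id == p & regions$hemisphere == "left"]
    s_r <- bold[as.character(rid), ]
    s_l <- bold[as.character(lid), ]
    res <- tryCatch({
      ccf <- cross_correlogram(s_r, s_l, tr, tau_max)
      pk <- peak_lag(ccf)
      data.frame(pair_id = p, region_left = lid, region_right = rid,
                 lag_seconds = pk$lag_seconds,
                 abs_lag_seconds = abs(pk$lag_seconds),
                 peak_correlation = pk$peak_correlation,
                 zero_lag_r = cor(s_r, s_l),
                 boundary = pk$boundary, degenerate = FALSE)
    }, lagnav_degenerate_signal = function(e) {
      data.frame(pair_id = p, region_left = lid, region_right = rid,
                 lag_seconds = NA_real_, abs_lag_seconds = NA_real_,
                 peak_correlation = NA_real_, zero_lag_r = NA_real_,
                 boundary = FALSE, degenerate = TRUE)
    })
    res
  })
  do.call(rbind, rows)
}

#' Mean absolute synchronization lag over a set of pairs
#'
#' @param lag_table output of [homotopic_lags()].
#' @param pairs pair ids to average over (default: all).
#' @return arithmetic mean of `abs_lag_seconds`, excluding degenerate pairs.
#' @export
mean_lag <- function(lag_table, pairs = NULL) {
  keep <- !lag_table$degenerate
  if (!is.null(pairs)) keep <- keep & lag_table$pair_id %in% pairs
  if (!any(keep)) stop_invalid("no usable pairs in the requested subset")
  mean(lag_table$abs_lag_seconds[keep])
}

#' Partition homotopic pairs into affected / unaffected networks
#'
#' A subnetwork is *affected* for a subject when it contains at least one
#' lesioned region; a pair is affected when its subnetwork is. The
#' `affected_intact` subset keeps affected pairs in which neither region is
#' itself lesioned (downstream effects only).
#'
#' @param regions region table.
#' @param lesion_regions integer vector of lesioned region ids (empty for a
#'   control subject).
#' @return list of pair-id vectors: `affected`, `unaffected`,
#'   `affected_intact`.
#' @export
classify_affected <- function(regions, lesion_regions) {
  check_regions(regions)
  lesion_regions <- as.integer(lesion_regions)
  hit_nets <- unique(regions$subnetwork[regions$region_id %in% lesion_regions])
  all_pairs <- sort(unique(regions$pair_id))
  pair_net <- regions$subnetwork[match(all_pairs, regions$pair_id)]
  affected <- all_pairs[pair_net %in% hit_nets]
  lesioned_pairs <- unique(regions$pair_id[regions$region_id %in% lesion_regions])
  list(affected = affected,
       unaffected = setdiff(all_pairs, affected),
       affected_intact = setdiff(affected, lesioned_pairs))
}

#' Histogram of synchronization lags
#'
#' Counts lags over half-open bins `[k*w, (k+1)*w)`. Optionally drops the
#' bin containing zero so the tail of the distribution is visible.
#'
#' @param lags numeric vector of lags in seconds.
#' @param bin_width bin width in seconds (default 0.5).
#' @param drop_zero drop the `[0, w)` bin.
#' @return `data.frame` with `bin_lo`, `bin_hi`, `count`.
#' @export
lag_histogram <- function(lags, bin_width = 0.5, drop_zero = FALSE) {
  if (bin_width <= 0) stop_invalid("`bin_width` must be > 0")
  if (length(lags) == 0) {
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0)))
  }
  k <- floor(lags / bin_width)
  tab <- table(k)
  out <- data.frame(bin_lo = as.numeric(names(tab)) * bin_width,
                    bin_hi = (as.numeric(names(tab)) + 1) * bin_width,
                    count = as.integer(tab))
  if (drop_zero) out <- out[!(out$bin_lo <= 0 & out$bin_hi > 0), ]
  rownames(out) <- NULL
  out
}
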