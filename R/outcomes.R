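#' Percentage of time glucose lies in a band
#'
#' Interpolates the reference glucose trace piecewise-linearly between
#' consecutive samples and computes the exact fraction of total time with
#' `low <= G <= high`; band crossing times are solved analytically per
#' segment. A sample-counting mode (fraction of samples in band) is
#' provided for sensitivity analysis.
#'
#' @param t sample times, min, strictly increasing (>= 2 samples).
#' @param G glucose values, mM.
#' @param low,high band limits, mM (`low` may be `-Inf`/0, `high` `Inf`).
#' @param mode `"interpolate"` (default) or `"samples"`.
#' @return Percentage of time in \[`low`, `high`\], in \[0, 100\].
#' @export
time_in_range <- function(t, G, low, high, mode = c("interpolate",
                                                    "samples")) {
  mode <- match.arg(mode)
  if (length(t) < 2) stop("need at least 2 samples")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (length(t) != length(G)) stop("t and G lengths differ")
  if (mode == "samples") return(100 * mean(G >= low & G <= high))
  total <- t[length(t)] - t[1]
  inside <- 0
  for (i in seq_len(length(t) - 1)) {
    dt <- t[i + 1] - t[i]
    g1 <- G[i]; g2 <- G[i + 1]
    if (g1 == g2) {
      if (g1 >= low && g1 <= high) inside <- inside + dt
    } else {
      glo <- min(g1, g2); ghi <- max(g1, g2)
      ov <- min(ghi, high) - max(glo, low)
      if (ov > 0) inside <- inside + ov / (ghi - glo) * dt
    }
  }
  100 * inside / total
}

#' Count glycemic episodes
#'
#' An episode is a maximal run of consecutive reference samples beyond the
#' threshold; runs separated by at least one in-range sample count
#' separately. Hyperglycemic episodes use `G >= threshold` (direction
#' `"above"`), hypoglycemic ones `G < threshold` (direction `"below"`),
#' matching how such endpoint tables are printed.
#'
#' @param G reference glucose samples, mM.
#' @param threshold episode threshold, mM.
#' @param direction `"above"` or `"below"`.
#' @return Integer episode count.
#' @export
glycemic_episodes <- function(G, threshold, direction = c("above",
                                                          "below")) {
  direction <- match.arg(direction)
  out <- if (direction == "above") G >= threshold else G < threshold
  r <- rle(out)
  sum(r$values)
}

#' Sensor accuracy metrics
#'
#' Pairs each reference sample with the nearest available sensor value
#' within 5 min (unpaired references are dropped) and returns the
#' standard continuous-glucose-monitor accuracy panel: MAD (median
#' absolute deviation, mM), MARD (median relative absolute deviation, %),
#' and the percentage of sensor values within 20% of reference.
#'
#' @param sensor data frame with columns `t` (min) and `G` (mM); `NA`
#'   values are treated as unavailable.
#' @param reference data frame with columns `t` and `G`.
#' @return List with `mad`, `mard`, `pct_within20`, `n_pairs`.
#' @export
sensor_accuracy <- function(sensor, reference) {
  s <- sensor[!is.na(sensor$G), , drop = FALSE]
  if (!nrow(s) || !nrow(reference)) stop("no sensor-reference pairs")
  pairs <- vapply(seq_len(nrow(reference)), function(i) {
    d <- abs(s$t - reference$t[i])
    j <- which.min(d)
    if (d[j] <= 5) s$G[j] else NA_real_
  }, numeric(1))
  keep <- !is.na(pairs)
  if (!any(keep)) stop("no sensor-reference pairs")
  sv <- pairs[keep]; rv <- reference$G[keep]
  rel <- abs(sv - rv) / rv
  list(mad = median(abs(sv - rv)), mard = 100 * median(rel),
       pct_within20 = 100 * mean(rel <= 0.20), n_pairs = sum(keep))
}
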