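#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U test as used for non-normally distributed
#' trial endpoints. For small samples (both groups of size <= 9) the p
#' value is exact by tie-aware enumeration of all
#' `choose(n1 + n2, n1)` group assignments of the pooled (mid-rank)
#' values; otherwise a normal approximation with tie correction and
#' continuity correction is used. When every pooled value is identical
#' the p value is 1.
#'
#' @param x,y numeric samples (each of length >= 1).
#' @param exact_max largest per-group size for which enumeration is used.
#' @return List with `U` (statistic of group `x`) and `p` (two-sided).
#' @export
mann_whitney_u <- function(x, y, exact_max = 9) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("each group needs at least one value")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1)
    return(list(U = U, p = 1))
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(n1 + n2, n1)
    Us <- apply(idx, 2, function(ii)
      sum(r[ii]) - n1 * (n1 + 1) / 2)
    lo <- min(U, n1 * n2 - U); hi <- max(U, n1 * n2 - U)
    eps <- 1e-9
    p <- (sum(Us <= lo + eps) + sum(Us >= hi - eps)) / ncol(idx)
    return(list(U = U, p = min(1, p)))
  }
  N <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
  mu <- n1 * n2 / 2
  z <- (U - mu - sign(U - mu) * 0.5) / sigma
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Unpaired two-sample t test
#'
#' Pooled-variance two-sided t test for normally distributed endpoints.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @return List with `t` and `p`.
#' @export
unpaired_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least two values")
  if (sd(c(x - mean(x), y - mean(y))) == 0)
    stop("zero pooled variance")
  ans <- t.test(x, y, var.equal = TRUE)
  list(t = unname(ans$statistic), p = ans$p.value)
}

## median (IQR) formatting helper
fmt_med_iqr <- function(v, digits = 1) {
  q <- quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%.*f (%.*f-%.*f)", digits, q[2], digits, q[1], digits, q[3])
}

#' Per-subject outcome panel
#'
#' Computes the endpoint battery for one simulated subject: time in the
#' primary 6.0--8.0 mM band and the wider/outer bands from the hourly
#' reference trace (piecewise-linear interpolation), mean and SD of
#' reference glucose, hyper- and hypoglycemic episode counts, insulin and
#' dextrose totals from the command log, sensor accuracy (MAD, MARD, %
#' within 20%), calibration counts per study day, and minutes of sensor
#' unavailability.
#'
#' @param record a `trial_record` from [simulate_subject()].
#' @return A one-row data frame.
#' @export
summarize_subject <- function(record) {
  ref <- record$reference
  tir <- function(lo, hi) time_in_range(ref$t, ref$G, lo, hi)
  cmd <- record$commands
  end_min <- record$duration_h * 60
  ## zero-order-hold integral of a command column, U or mL over [0, upto]
  zoh_total <- function(col, upto) {
    tt <- c(cmd$t_min, end_min)
    dt <- pmin(tt[-1], upto) - pmin(tt[-length(tt)], upto)
    sum(cmd[[col]] * pmax(dt, 0)) / 60
  }
  insulin_24h <- zoh_total("insulin_Uh", min(1440, end_min))
  insulin_total <- zoh_total("insulin_Uh", end_min)
  dextrose_48h_g <- zoh_total("dextrose_mLh", end_min) * 0.2
  acc <- tryCatch(sensor_accuracy(record$sensor, ref),
                  error = function(e) list(mad = NA_real_, mard = NA_real_,
                                           pct_within20 = NA_real_))
  cal <- record$cal_events
  sens <- record$sensor
  unavail <- if (nrow(sens) > 1) sum(!sens$available[-1]) else NA_real_
  data.frame(
    id = record$id, arm = record$arm,
    pct_time_6_8 = tir(6, 8), pct_4_10 = tir(4, 10),
    pct_5p6_10 = tir(5.6, 10),
    pct_gt8 = tir(8 + 1e-12, Inf), pct_gt10 = tir(10 + 1e-12, Inf),
    pct_lt6 = tir(-Inf, 6 - 1e-12), pct_lt5p6 = tir(-Inf, 5.6 - 1e-12),
    pct_lt4 = tir(-Inf, 4 - 1e-12),
    mean_G = mean(ref$G), sd_G = sd(ref$G),
    min_ref = min(ref$G),
    episodes_ge15 = glycemic_episodes(ref$G, 15, "above"),
    episodes_ge17 = glycemic_episodes(ref$G, 17, "above"),
    episodes_lt4 = glycemic_episodes(ref$G, 4, "below"),
    insulin_24h = insulin_24h,
    insulin_hourly = insulin_total / record$duration_h,
    dextrose_48h = dextrose_48h_g,
    mad = acc$mad, mard = acc$mard, pct_within20 = acc$pct_within20,
    cal_count_day1 = if (nrow(cal)) sum(cal$t <= 1440) else 0L,
    cal_count_day2 = if (nrow(cal)) sum(cal$t > 1440) else 0L,
    sensor_unavail_min = unavail,
    stringsAsFactors = FALSE)
}

#' Trial-level endpoint summary
#'
#' Aggregates per-subject outcome panels by arm into a results table in
#' the shape such trials report: median (IQR) per arm with Mann-Whitney U
#' p values for the skewed endpoints, and mean (SD) with an unpaired t
#' test for the per-subject glucose SD.
#'
#' @param records list of `trial_record` objects.
#' @return List of class `outcome_summary` with `per_subject` (data
#'   frame), `table` (formatted comparison table) and `p_values`.
#' @export
summarize_trial <- function(records) {
  per <- do.call(rbind, lapply(records, summarize_subject))
  cl <- per[per$arm == "CL", , drop = FALSE]
  ss <- per[per$arm == "SS", , drop = FALSE]
  mw_metrics <- c("pct_time_6_8", "pct_4_10", "pct_5p6_10", "pct_gt8",
                  "pct_gt10", "pct_lt6", "pct_lt5p6", "pct_lt4",
                  "mean_G", "insulin_24h", "insulin_hourly")
  rows <- list(); pv <- list()
  both <- nrow(cl) > 0 && nrow(ss) > 0
  for (m in mw_metrics) {
    p <- if (both) mann_whitney_u(cl[[m]], ss[[m]])$p else NA_real_
    rows[[m]] <- data.frame(
      endpoint = m, test = "Mann-Whitney U",
      SS = if (nrow(ss)) fmt_med_iqr(ss[[m]]) else NA,
      CL = if (nrow(cl)) fmt_med_iqr(cl[[m]]) else NA,
      p = p, stringsAsFactors = FALSE)
    pv[[m]] <- p
  }
  p_sd <- if (both && nrow(cl) > 1 && nrow(ss) > 1)
    tryCatch(unpaired_t(cl$sd_G, ss$sd_G)$p, error = function(e) NA_real_)
  else NA_real_
  rows$sd_G <- data.frame(
    endpoint = "sd_G", test = "unpaired t",
    SS = if (nrow(ss)) sprintf("%.1f (%.1f)", mean(ss$sd_G), sd(ss$sd_G))
         else NA,
    CL = if (nrow(cl)) sprintf("%.1f (%.1f)", mean(cl$sd_G), sd(cl$sd_G))
         else NA,
    p = p_sd, stringsAsFactors = FALSE)
  pv$sd_G <- p_sd
  structure(list(per_subject = per, table = do.call(rbind, rows),
                 p_values = pv), class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat("In-silico trial endpoint summary",
      sprintf("(CL n=%d, SS n=%d)\n",
              sum(x$per_subject$arm == "CL"),
              sum(x$per_subject$arm == "SS")))
  tab <- x$table
  tab$p <- ifelse(is.na(tab$p), "NA", sprintf("%.3f", tab$p))
  print(tab, row.names = FALSE)
  invisible(x)
}
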