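#' The intravenous sliding-scale insulin protocol
#'
#' The paper-based local protocol: hourly blood glucose is mapped to a
#' fixed insulin infusion rate by glucose band. Bands are printed to one
#' decimal and are contiguous at 0.1 mM resolution, so lookups round the
#' measured value to one decimal first. Rows flagged `notify` require the
#' physician to be informed (the 8.6--11.0 band only when glucose exceeds
#' 10 mM).
#'
#' @return Data frame with columns `lower` (mM, inclusive after rounding),
#'   `rate` (U/h) and `notify`.
#' @export
sliding_scale_table <- function() {
  data.frame(
    lower  = c(-Inf, 4.0, 5.6, 7.1, 8.6, 11.1, 14.1, 17.1, 20.1),
    rate   = c(0, 0.5, 1.0, 1.5, 2.0, 2.5, 3.0, 4.0, 6.0),
    notify = c(TRUE, FALSE, FALSE, FALSE, NA, TRUE, TRUE, TRUE, TRUE))
}

#' Sliding-scale rate lookup
#'
#' Rounds the blood glucose to one decimal, finds its protocol band and
#' returns the insulin infusion rate, optionally shifted by whole rows
#' (physician-prescribed scale alteration: +1 selects the next more
#' aggressive row).
#'
#' @param BG blood glucose, mM (> 0).
#' @param scale_shift integer row shift in \[-2, 2\].
#' @return Insulin rate, U/h, with logical attribute `"notify"`.
#' @export
lookup_rate <- function(BG, scale_shift = 0) {
  if (!is.finite(BG) || BG <= 0) stop("BG must be positive")
  if (scale_shift < -2 || scale_shift > 2 ||
      scale_shift != round(scale_shift))
    stop("scale_shift must be an integer in [-2, 2]")
  tab <- sliding_scale_table()
  g <- round(BG, 1)
  row <- findInterval(g + 1e-9, tab$lower)
  notify <- tab$notify[row]
  if (is.na(notify)) notify <- g > 10  # 8.6-11.0 band: inform if > 10
  row_eff <- clamp(row + scale_shift, 1, nrow(tab))
  structure(tab$rate[row_eff], notify = notify)
}

#' One hourly nurse cycle of the sliding-scale arm
#'
#' Applies the protocol to the latest hourly reference glucose: the rate
#' from [lookup_rate()] is held constant until the next measurement.
#' Optionally (default off) models physician escalation: two consecutive
#' hourly values above 12 mM shift the scale one row up.
#'
#' @param BG latest reference blood glucose, mM.
#' @param ps protocol state as returned by a previous call, or `NULL` at
#'   the first cycle.
#' @param escalation enable the deterministic escalation rule.
#' @return List with `rate` (U/h), `notify` (logical), and the updated
#'   protocol state `ps` (fields `scale_shift`, `high_streak`).
#' @export
nurse_cycle <- function(BG, ps = NULL, escalation = FALSE) {
  if (is.null(ps)) ps <- list(scale_shift = 0, high_streak = 0)
  if (escalation) {
    ps$high_streak <- if (BG > 12) ps$high_streak + 1 else 0
    if (ps$high_streak >= 2) {
      ps$scale_shift <- min(2, ps$scale_shift + 1)
      ps$high_streak <- 0
    }
  }
  r <- lookup_rate(BG, ps$scale_shift)
  list(rate = as.numeric(r), notify = attr(r, "notify"), ps = ps)
}
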