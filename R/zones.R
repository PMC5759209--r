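# Canonical heart-rate zone boundaries as percentages of FTHR. The printed
# zone-3 row of the reference table repeats zone 4's bpm range (137-146)
# although its percentages (75.76-82.42) imply 125-136 bpm; "percent" keeps
# the percentage-consistent reading, "printed" reproduces the duplicate.
.zone_pct <- data.frame(
  zone   = 0:9,
  pct_lo = c(30.91, 49.70, 68.48, 75.76, 83.03, 89.09, 94.55, 100.61,
             105.45, 110.30),
  pct_hi = c(49.09, 67.88, 75.15, 82.42, 88.48, 93.94, 100.00, 104.85,
             109.70, 114.55))

#' Heart-rate percentage of FTHR
#'
#' Expresses a heart rate as a percentage of the athlete's functional
#' threshold heart rate, `100 * hr / fthr`, rounded to two decimals as in
#' standard zone tables.
#'
#' @param avg_hr Heart rate(s), bpm; vectorized.
#' @param athlete An [athlete_profile()].
#' @param digits Rounding digits, default 2; use `NULL` for no rounding.
#' @return Percentage(s) of FTHR.
#' @examples
#' hr_pct_fthr(81, simulated_athlete())  # 49.09
#' @export
hr_pct_fthr <- function(avg_hr, athlete, digits = 2) {
  p <- 100 * avg_hr / athlete$fthr
  if (is.null(digits)) p else round(p, digits)
}

#' Heart-rate and duration zone table for an athlete
#'
#' The ten Coggan-style heart-rate zones (0..9), anchored to the athlete's
#' FTHR. Zone boundaries are stored as percentages of FTHR and converted to
#' bpm at runtime (`bpm = round(pct * fthr / 100)`), so the table
#' personalizes to any athlete; for the simulated reference athlete
#' (FTHR 165) it reproduces the canonical bpm columns. Each zone `z` also
#' carries a maximum session duration of `30 * (z + 1)` minutes.
#'
#' @param athlete An [athlete_profile()].
#' @param zone3 `"percent"` (default) resolves the ambiguous zone-3 bpm
#'   range from its FTHR percentages (125-136 bpm for FTHR 165);
#'   `"printed"` reproduces the duplicated 137-146 bpm range of the
#'   reference table.
#' @return Data frame with columns `zone`, `hr_lo_bpm`, `hr_hi_bpm`,
#'   `pct_lo`, `pct_hi`, `duration_min`.
#' @export
zone_table <- function(athlete, zone3 = c("percent", "printed")) {
  zone3 <- match.arg(zone3)
  tab <- .zone_pct
  tab$hr_lo_bpm <- round(tab$pct_lo * athlete$fthr / 100)
  tab$hr_hi_bpm <- round(tab$pct_hi * athlete$fthr / 100)
  # anchor the extreme zones to the athlete's physiological range
  tab$hr_lo_bpm[1L] <- athlete$resting_hr
  tab$hr_hi_bpm[10L] <- athlete$max_hr
  if (zone3 == "printed") {
    tab$hr_lo_bpm[4L] <- tab$hr_lo_bpm[5L]
    tab$hr_hi_bpm[4L] <- tab$hr_hi_bpm[5L]
  }
  tab$duration_min <- 30 * (tab$zone + 1L)
  tab[, c("zone", "hr_lo_bpm", "hr_hi_bpm", "pct_lo", "pct_hi",
          "duration_min")]
}

#' Heart-rate zone of a session intensity
#'
#' Returns the index (0..9) of the zone whose heart-rate interval contains
#' `avg_hr`. Heart rates falling in the one-bpm gaps between printed zone
#' boundaries are assigned to the zone below (intervals are treated as
#' right-closed at their upper bpm boundary).
#'
#' @inheritParams hr_pct_fthr
#' @param zone3 Passed to [zone_table()].
#' @return Integer zone index/indices in 0..9.
#' @examples
#' hr_zone_of(81, simulated_athlete())   # 0
#' hr_zone_of(189, simulated_athlete())  # 9
#' @export
hr_zone_of <- function(avg_hr, athlete, zone3 = "percent") {
  bad <- which(avg_hr < athlete$resting_hr | avg_hr > athlete$max_hr)
  if (length(bad))
    stop(sprintf("avg_hr = %.2f bpm outside athlete range [%g, %g]",
                 avg_hr[bad[1L]], athlete$resting_hr, athlete$max_hr),
         call. = FALSE)
  tab <- zone_table(athlete, zone3 = zone3)
  vapply(avg_hr, function(h) {
    tab$zone[which(h <= tab$hr_hi_bpm)[1L]]
  }, integer(1L))
}
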