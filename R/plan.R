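#' Construct a training plan
#'
#' A training plan is an ordered sequence of daily sessions, each prescribed
#' as an average heart rate (bpm) and a duration (minutes). It is stored as a
#' data frame with columns `day`, `avg_hr_bpm`, `duration_min` and carries
#' class `training_plan`. A plan of `M` sessions corresponds one-to-one to a
#' `2M`-dimensional decision vector (see [encode_plan()]).
#'
#' @param avg_hr Numeric vector of per-session average heart rates, bpm.
#' @param duration Numeric vector of per-session durations, minutes
#'   (recycled if length 1).
#' @param athlete Optional [athlete_profile()]; when given, heart rates are
#'   validated against `[resting_hr, max_hr]`.
#' @param duration_bounds Length-2 numeric, allowed duration range in
#'   minutes. Default `c(30, 300)`.
#'
#' @return A `training_plan` data frame.
#' @examples
#' plan <- training_plan(rep(120, 7), rep(60, 7))
#' nrow(plan)
#' @export
training_plan <- function(avg_hr, duration, athlete = NULL,
                          duration_bounds = c(30, 300)) {
  if (length(duration) == 1L) duration <- rep(duration, length(avg_hr))
  if (length(avg_hr) != length(duration))
    stop("avg_hr and duration must have equal length", call. = FALSE)
  if (length(avg_hr) == 0L)
    stop("a training plan needs at least one session", call. = FALSE)
  if (any(!is.finite(avg_hr)) || any(!is.finite(duration)))
    stop("non-finite session values", call. = FALSE)
  if (any(duration < 0))
    stop("durations must be non-negative", call. = FALSE)
  plan <- data.frame(day = seq_along(avg_hr),
                     avg_hr_bpm = as.numeric(avg_hr),
                     duration_min = as.numeric(duration))
  class(plan) <- c("training_plan", "data.frame")
  if (!is.null(athlete)) validate_plan(plan, athlete, duration_bounds)
  plan
}

#' Validate a training plan against an athlete's physiological bounds
#'
#' @param plan A [training_plan()].
#' @param athlete An [athlete_profile()].
#' @param duration_bounds Allowed duration range, minutes.
#' @return `plan`, invisibly; errors describe the first offending row.
#' @export
validate_plan <- function(plan, athlete, duration_bounds = c(30, 300)) {
  stopifnot(inherits(plan, "training_plan"))
  bad_hr <- which(plan$avg_hr_bpm < athlete$resting_hr |
                  plan$avg_hr_bpm > athlete$max_hr)
  if (length(bad_hr))
    stop(sprintf(
      "session %d: avg HR %.1f bpm outside athlete range [%g, %g]",
      bad_hr[1L], plan$avg_hr_bpm[bad_hr[1L]],
      athlete$resting_hr, athlete$max_hr), call. = FALSE)
  bad_d <- which(plan$duration_min < duration_bounds[1L] |
                 plan$duration_min > duration_bounds[2L])
  if (length(bad_d))
    stop(sprintf(
      "session %d: duration %.1f min outside bounds [%g, %g]",
      bad_d[1L], plan$duration_min[bad_d[1L]],
      duration_bounds[1L], duration_bounds[2L]), call. = FALSE)
  invisible(plan)
}

#' Plan / decision-vector codec
#'
#' The optimizer represents an `M`-session plan as a `2M` vector with
#' interleaved layout `HR1, D1, HR2, D2, ..., HRM, DM`. `encode_plan()` and
#' `decode_plan()` convert between the two representations;
#' `decode_plan(encode_plan(p))` is the identity.
#'
#' @param plan A [training_plan()].
#' @return `encode_plan()`: numeric vector of length `2 * nrow(plan)`.
#' @export
encode_plan <- function(plan) {
  stopifnot(inherits(plan, "training_plan"))
  as.vector(rbind(plan$avg_hr_bpm, plan$duration_min))
}

#' @rdname encode_plan
#' @param x Numeric vector of even length (interleaved HR, duration).
#' @export
decode_plan <- function(x) {
  if (length(x) %% 2L != 0L)
    stop("decision vector must have even length, got ", length(x),
         call. = FALSE)
  idx <- seq(1L, length(x), by = 2L)
  training_plan(avg_hr = x[idx], duration = x[idx + 1L])
}

#' Read / write a training plan as CSV
#'
#' The file format has a header `day,avg_hr_bpm,duration_min` with one row
#' per session and a contiguous 1-based `day` column. `read_plan()` rejects
#' malformed files with a message naming the offending row.
#'
#' @param path CSV file path.
#' @param athlete Optional [athlete_profile()] for bound validation.
#' @return `read_plan()`: a [training_plan()]; `write_plan()`: `path`,
#'   invisibly.
#' @export
read_plan <- function(path, athlete = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "avg_hr_bpm", "duration_min")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("plan CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("plan CSV has no sessions", call. = FALSE)
  bad <- which(df$day != seq_len(nrow(df)))
  if (length(bad))
    stop(sprintf("plan CSV days must be contiguous 1..%d: row %d has day %s",
                 nrow(df), bad[1L], df$day[bad[1L]]), call. = FALSE)
  plan <- training_plan(df$avg_hr_bpm, df$duration_min)
  if (!is.null(athlete)) validate_plan(plan, athlete)
  plan
}

#' @rdname read_plan
#' @param plan A [training_plan()].
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "training_plan"))
  utils::write.csv(as.data.frame(plan), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @export
print.training_plan <- function(x, ...) {
  cat(sprintf("Training plan: %d sessions, %.0f min total\n",
              nrow(x), sum(x$duration_min)))
  NextMethod()
}
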