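#' Athlete physiological profile
#'
#' Bundles the heart-rate constants of one athlete that anchor every
#' downstream computation: TRIMP session loads, heart-rate training zones and
#' the search-space bounds of the plan optimizer.
#'
#' @param resting_hr Resting heart rate, bpm.
#' @param max_hr Maximum heart rate, bpm.
#' @param fthr Functional threshold heart rate, bpm. Must lie strictly
#'   between `resting_hr` and `max_hr`.
#' @param sex `"male"` or `"female"`; selects the default TRIMP exponent
#'   (1.92 for males, 1.67 for females).
#' @param sex_factor Optional positive override of the TRIMP exponent `y`.
#' @param p0 Baseline performance, arbitrary performance units. Default 0.
#'
#' @return An object of class `athlete_profile`.
#' @examples
#' ath <- athlete_profile(resting_hr = 51, max_hr = 189, fthr = 165)
#' normalized_hr(120, ath)
#' @export
athlete_profile <- function(resting_hr, max_hr, fthr,
                            sex = c("male", "female"),
                            sex_factor = NULL, p0 = 0) {
  sex <- match.arg(sex)
  for (v in c(resting_hr = resting_hr, max_hr = max_hr, fthr = fthr)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("heart-rate fields must be single positive numbers", call. = FALSE)
  }
  if (!(resting_hr < fthr && fthr < max_hr))
    stop(sprintf(
      "require resting_hr < fthr < max_hr; got %s, %s, %s",
      resting_hr, fthr, max_hr), call. = FALSE)
  y <- if (is.null(sex_factor)) {
    if (sex == "male") 1.92 else 1.67
  } else {
    if (!is.numeric(sex_factor) || sex_factor <= 0)
      stop("sex_factor must be a positive number", call. = FALSE)
    sex_factor
  }
  structure(
    list(resting_hr = as.numeric(resting_hr),
         max_hr = as.numeric(max_hr),
         fthr = as.numeric(fthr),
         sex = sex,
         sex_factor = as.numeric(y),
         p0 = as.numeric(p0)),
    class = "athlete_profile")
}

#' The simulated reference athlete
#'
#' A 35-year-old male cyclist with resting HR 51 bpm, FTHR 165 bpm and
#' maximum HR 189 bpm -- the fixture used throughout the package's examples
#' and tests.
#'
#' @param p0 Baseline performance, default 0.
#' @return An [athlete_profile()].
#' @export
simulated_athlete <- function(p0 = 0) {
  athlete_profile(resting_hr = 51, max_hr = 189, fthr = 165,
                  sex = "male", p0 = p0)
}

#' @export
print.athlete_profile <- function(x, ...) {
  cat("Athlete profile\n")
  cat(sprintf("  resting HR : %g bpm\n", x$resting_hr))
  cat(sprintf("  FTHR       : %g bpm\n", x$fthr))
  cat(sprintf("  max HR     : %g bpm\n", x$max_hr))
  cat(sprintf("  sex        : %s (TRIMP exponent y = %g)\n",
              x$sex, x$sex_factor))
  cat(sprintf("  baseline p0: %g\n", x$p0))
  invisible(x)
}

#' Read / write an athlete profile as JSON
#'
#' The on-disk format is a flat JSON object, e.g.
#' `{"resting_hr": 51, "max_hr": 189, "fthr": 165, "sex": "male", "p0": 0.0}`.
#' An optional `"sex_factor"` key overrides the sex-derived TRIMP exponent.
#'
#' @param path File path.
#' @return `read_athlete()` returns an [athlete_profile()];
#'   `write_athlete()` returns `path` invisibly.
#' @export
read_athlete <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("resting_hr", "max_hr", "fthr")
  if (!all(need %in% names(obj)))
    stop("athlete JSON must contain fields: ",
         paste(need, collapse = ", "), call. = FALSE)
  athlete_profile(resting_hr = obj$resting_hr, max_hr = obj$max_hr,
                  fthr = obj$fthr,
                  sex = if (is.null(obj$sex)) "male" else obj$sex,
                  sex_factor = obj$sex_factor,
                  p0 = if (is.null(obj$p0)) 0 else obj$p0)
}

#' @rdname read_athlete
#' @param athlete An [athlete_profile()].
#' @export
write_athlete <- function(athlete, path) {
  stopifnot(inherits(athlete, "athlete_profile"))
  jsonlite::write_json(
    list(resting_hr = athlete$resting_hr, max_hr = athlete$max_hr,
         fthr = athlete$fthr, sex = athlete$sex,
         sex_factor = athlete$sex_factor, p0 = athlete$p0),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
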