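# internal helpers shared across modules

HOURS_PER_DAY <- 24
WINTER_MONTHS <- c(12L, 1L, 2L)

season_of_month <- function(month) {
  ifelse(month %in% WINTER_MONTHS, "winter", "warm")
}

DIEL_PERIODS <- c("crepuscular", "diurnal", "nocturnal")

hours_to_radians <- function(h) h * 2 * pi / HOURS_PER_DAY
radians_to_hours <- function(theta) (theta %% (2 * pi)) * HOURS_PER_DAY / (2 * pi)

# fractional hour-of-day of a clock POSIXct (stored in UTC, interpreted as
# local standard time)
clock_hour <- function(t) {
  as.numeric(t - lubridate::floor_date(t, "day"), units = "hours")
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# deterministic child seed from a master seed and a stream label
child_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 1009L + as.integer(h %% 100000L)) %% 2147483647L
}
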