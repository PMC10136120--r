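#' Diurnal heat-wave regime profiles
#'
#' The experiments expose mite females to one of two programmed incubator
#' regimes that mimic Central-European summer heat waves: a *mild* regime
#' with a daily maximum of 32.0 degrees C (representative of present-day
#' heat waves) and an *extreme* regime with a daily maximum of 38.0 degrees C
#' (representative of projected future heat waves).  Each regime is a
#' repeating 24-h cycle of twelve 2-hour temperature / relative-humidity
#' blocks under a 16:8 h light:dark photoperiod.  The extreme regime is the
#' mild regime shifted upward by exactly 6.0 degrees C in every block.
#'
#' Profiles are stored as data constants; they are experimental settings,
#' not quantities estimated from data.
#'
#' @param regime `"mild"` or `"extreme"`.
#' @return An object of class `heatwave_profile`: a list with elements
#'   `regime`, `steps` (data frame with columns `start_hour`,
#'   `temperature_C`, `rh_percent`; twelve rows covering 00:00-24:00) and
#'   `photoperiod_h` (light hours, 16).
#' @examples
#' p <- heatwave_profile("mild")
#' profile_mean(p, "temperature")   # 22.58333; displays as 22.6
#' @export
heatwave_profile <- function(regime = c("mild", "extreme")) {
  if (!is.character(regime) || length(regime) != 1L ||
      !regime %in% c("mild", "extreme")) {
    stop("unknown regime ", deparse(substitute(regime)),
         "; valid regimes are \"mild\" and \"extreme\"", call. = FALSE)
  }
  # extreme-regime blocks; mild is a uniform -6 C shift with its own RH column
  start_hour <- seq(0L, 22L, by = 2L)
  temp_extreme <- c(24, 23, 22, 25, 33, 36, 38, 35, 30, 28, 25, 24)
  rh_extreme   <- c(65, 70, 75, 65, 50, 50, 50, 50, 55, 60, 65, 65)
  rh_mild      <- c(75, 80, 85, 75, 60, 50, 50, 55, 65, 70, 75, 75)
  steps <- if (regime == "mild") {
    data.frame(start_hour = start_hour,
               temperature_C = temp_extreme - 6.0,
               rh_percent = rh_mild)
  } else {
    data.frame(start_hour = start_hour,
               temperature_C = temp_extreme,
               rh_percent = rh_extreme)
  }
  structure(list(regime = regime, steps = steps, photoperiod_h = 16L),
            class = "heatwave_profile")
}

#' Mean of a regime channel over the 24-h cycle
#'
#' Unweighted arithmetic mean of the twelve 2-hour block values.  The value
#' is returned unrounded; display rounding (one decimal, half-up) is applied
#' only by the print method.
#'
#' @param profile a [heatwave_profile()] object.
#' @param channel `"temperature"` or `"humidity"`.
#' @return A single numeric value (degrees C or % RH).
#' @export
profile_mean <- function(profile, channel = c("temperature", "humidity")) {
  stopifnot(inherits(profile, "heatwave_profile"))
  channel <- match.arg(channel)
  col <- if (channel == "temperature") "temperature_C" else "rh_percent"
  mean(profile$steps[[col]])
}

# round-half-up at `digits` decimals (display convention for regime tables)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' @export
print.heatwave_profile <- function(x, ...) {
  cat(sprintf("Diurnal %s heat-wave regime (photoperiod %d:%d h L:D)\n",
              x$regime, x$photoperiod_h, 24L - x$photoperiod_h))
  print(x$steps, row.names = FALSE)
  cat(sprintf("MEAN  temperature %.1f C, RH %.1f %%\n",
              round_half_up(profile_mean(x, "temperature")),
              round_half_up(profile_mean(x, "humidity"))))
  invisible(x)
}

#' @export
as.data.frame.heatwave_profile <- function(x, ...) {
  cbind(regime = x$regime, x$steps)
}

#' Write a regime profile as CSV
#'
#' Columns: `regime`, `start_hour`, `temperature_C`, `rh_percent`.
#' Reading the file back with [read_heatwave_profile()] reproduces the
#' profile exactly.
#'
#' @param profile a [heatwave_profile()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_heatwave_profile <- function(profile, path) {
  stopifnot(inherits(profile, "heatwave_profile"))
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a regime profile from CSV
#'
#' @param path CSV written by [write_heatwave_profile()].
#' @return A `heatwave_profile` object.
#' @export
read_heatwave_profile <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("regime", "start_hour", "temperature_C", "rh_percent")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("profile CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  regime <- unique(df$regime)
  if (length(regime) != 1L)
    stop("profile CSV must contain exactly one regime", call. = FALSE)
  structure(list(regime = regime,
                 steps = df[order(df$start_hour),
                            c("start_hour", "temperature_C", "rh_percent")],
                 photoperiod_h = 16L),
            class = "heatwave_profile")
}
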