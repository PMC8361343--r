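#' Clock-time helpers on the hours-since-noon scale
#'
#' Night-level clock statistics (onset, midpoint, out-of-bed time) are
#' computed on a continuous "hours since the previous noon" scale, so that
#' e.g. 23:30 maps to 11.5 and 02:00 (the next calendar day) maps to 14.0.
#' This removes the midnight wrap-around that would otherwise corrupt means
#' and standard deviations of bed and rise times.
#'
#' @param t `POSIXct` times.
#' @param noon `POSIXct` reference noon (the noon that starts the night's
#'   24-h window).
#' @return Numeric hours since `noon`.
#' @examples
#' noon <- as.POSIXct("2024-01-01 12:00:00", tz = "UTC")
#' hoursSinceNoon(noon + 11.5 * 3600, noon)  # 23:30 -> 11.5
#' @export
hoursSinceNoon <- function(t, noon) {
  as.numeric(difftime(t, noon, units = "hours"))
}

#' @rdname hoursSinceNoon
#' @param h Numeric hours since `noon`.
#' @export
noonOffsetToTime <- function(h, noon) {
  noon + h * 3600
}

#' Format hours-since-noon as a clock string
#'
#' @param h Hours since noon (0 = 12:00, 14 = 02:00 next day).
#' @return Character `"HH:MM"` clock labels.
#' @export
formatClock <- function(h) {
  clock <- (h + 12) %% 24
  sprintf("%02d:%02d", floor(clock), round((clock - floor(clock)) * 60) %% 60)
}

# Reference noon (POSIXct) for night `night` of a recording starting at
# `start`, which is itself the noon of day 1.
.nightNoon <- function(start, night) {
  start + (night - 1) * 86400
}

.isCount <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)
}
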