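## Time-unit conventions: one year is the circle, T = 2*pi radians; a
## 365-day year gives 1 day = 2*pi/365 ~ 0.017 rad.

DAYS_PER_YEAR <- 365

#' Convert between radians and days on the annual circle
#'
#' The package measures season as an angle: one year equals \eqn{2\pi}
#' radians, and a 365-day year is assumed, so one day is
#' \eqn{2\pi/365 \approx 0.017} radians.
#'
#' @param x numeric vector of radians (or days for `daysToRadians`).
#' @return numeric vector in the target unit.
#' @examples
#' radiansToDays(0.48)   # about 28 days
#' daysToRadians(1)      # about 0.017
#' @export
radiansToDays <- function(x) x * DAYS_PER_YEAR / (2 * pi)

#' @rdname radiansToDays
#' @export
daysToRadians <- function(x) x * 2 * pi / DAYS_PER_YEAR

#' Map a seasonal phase to a week-of-year index
#'
#' With the year split into `m` equal intervals ("weeks" when `m = 48`),
#' a phase angle maps to the 1-based index of the interval it falls in,
#' rounded to the nearest interval boundary midpoint convention used in
#' reports: `round(phase * m / (2*pi))`.
#'
#' @param phase numeric vector of phase angles in radians.
#' @param m number of seasonal intervals per year (default 48).
#' @return integer vector of week indices.
#' @examples
#' phaseToWeek(1.70)  # 13
#' phaseToWeek(4.58)  # 35
#' @export
phaseToWeek <- function(phase, m = 48L) {
    as.integer(round(wrapAngle(phase) * m / (2 * pi)))
}

## Wrap angles into [0, 2*pi).
wrapAngle <- function(x) {
    y <- x %% (2 * pi)
    y[y < 0] <- y[y < 0] + 2 * pi
    ## %% can return 2*pi for tiny negative inputs due to rounding
    y[y >= 2 * pi] <- 0
    y
}
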