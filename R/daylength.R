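#' Astronomical daylength (CBM model)
#'
#' Daylength in hours for a latitude and day of year under the CBM model of
#' Forsythe and colleagues, with a twilight coefficient `p` giving the solar
#' depression angle (degrees below the horizon) still counted as daylight.
#' `p = 0` is sunrise-to-sunset; `p = 6` (the default) is civil twilight,
#' the convention under which plants are generally considered to perceive
#' photoperiod.
#'
#' The model is, with all angles in radians internally:
#' \deqn{\theta = 0.2163108 + 2 \arctan[0.9671396 \tan(0.00860 (J - 186))]}
#' \deqn{\phi = \arcsin(0.39795 \cos\theta)}
#' \deqn{D = 24 - \frac{24}{\pi} \arccos\left[\frac{\sin(p\pi/180) +
#'   \sin(L\pi/180)\sin\phi}{\cos(L\pi/180)\cos\phi}\right]}
#' where J is the day of year, L the latitude and \eqn{\phi} the solar
#' declination.
#'
#' Above polar circles the arccos argument can leave `[-1, 1]`; it is then
#' clamped, giving 24 h (polar day) or 0 h (polar night), with a warning.
#' Day 366 of leap years is treated as day 365 (sub-minute effect).
#'
#' @param latitude Latitude in decimal degrees, positive north, in
#'   `[-90, 90]`. Vectorized.
#' @param doy Day of year, 1-366. Vectorized (recycled against `latitude`).
#' @param twilight Twilight coefficient p in degrees of solar depression,
#'   in `[0, 18]`. Default 6 (civil twilight).
#' @return Daylength(s) in hours, in `[0, 24]`.
#' @examples
#' cbm_daylength(0, 80, twilight = 0)    # equator, no twilight: 12 h
#' cbm_daylength(45, 172)                # mid-latitude summer solstice
#' @export
cbm_daylength <- function(latitude, doy, twilight = 6) {
  if (any(abs(latitude) > 90)) {
    stop("latitude must lie in [-90, 90]", call. = FALSE)
  }
  if (any(doy < 1 | doy > 366)) {
    stop("day of year must lie in [1, 366]", call. = FALSE)
  }
  if (length(twilight) != 1L || twilight < 0 || twilight > 18) {
    stop("twilight coefficient must be a single value in [0, 18]",
         call. = FALSE)
  }
  j <- ifelse(doy > 365, 365, doy)
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (j - 186)))
  phi <- asin(0.39795 * cos(theta))
  lat_r <- latitude * pi / 180
  p_r <- twilight * pi / 180
  arg <- (sin(p_r) + sin(lat_r) * sin(phi)) / (cos(lat_r) * cos(phi))
  if (any(arg < -1 | arg > 1)) {
    warning("polar day/night: daylength clamped to 0 or 24 h", call. = FALSE)
    arg <- pmin(pmax(arg, -1), 1)
  }
  24 - (24 / pi) * acos(arg)
}

#' Daily rate of photoperiodic change
#'
#' Central difference of the CBM daylength about day `doy`:
#' `(D(doy + 1) - D(doy - 1)) / 2`, in hours per day. Positive in the
#' lengthening half of the year (before the summer solstice in the north),
#' negative after, approximately zero at the solstices. The day index wraps
#' around the year.
#'
#' @inheritParams cbm_daylength
#' @return Rate(s) in hours per day.
#' @export
photoperiod_change_rate <- function(latitude, doy, twilight = 6) {
  wrap <- function(j) ((j - 1) %% 365) + 1
  before <- cbm_daylength(latitude, wrap(doy - 1), twilight)
  after <- cbm_daylength(latitude, wrap(doy + 1), twilight)
  (after - before) / 2
}
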