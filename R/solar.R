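# ---- time helpers -----------------------------------------------------------

# Days since the J2000.0 epoch (2000-01-01 12:00 UT) for a calendar date plus
# minutes-from-midnight UT. `date` may be a Date or anything as.Date accepts.
days_since_j2000 <- function(date, minutes_ut = 0) {
  d <- as.numeric(as.Date(date) - as.Date("2000-01-01"))
  d + minutes_ut / 1440 - 0.5
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Circular residual between two times of day
#'
#' Minimal signed difference `a - b` on the 1440-minute clock, in
#' (-720, 720].
#'
#' @param a,b times in minutes from midnight (any real numbers).
#' @return signed residual in minutes.
#' @export
circular_minutes <- function(a, b) {
  r <- (a - b) %% 1440
  ifelse(r > 720, r - 1440, r)
}

# ---- solar ephemeris --------------------------------------------------------

# Low-precision solar position (Astronomical Almanac formulation): mean
# longitude and anomaly linear in days since J2000, equation of centre,
# obliquity. Accurate to ~0.01 degrees over 1940-2100, ample for twilight
# prediction at 20-minute observation noise.
sun_position <- function(n) {
  L <- (280.460 + 0.9856474 * n) %% 360   # mean longitude, deg
  g <- deg2rad((357.528 + 0.9856003 * n) %% 360)  # mean anomaly
  lambda <- deg2rad(L + 1.915 * sin(g) + 0.020 * sin(2 * g)) # ecliptic lon
  eps <- deg2rad(23.439 - 0.0000004 * n)  # obliquity of the ecliptic
  dec <- asin(sin(eps) * sin(lambda))
  ra <- atan2(cos(eps) * sin(lambda), cos(lambda)) # radians
  list(
    declination_deg = rad2deg(dec),
    ra_hours = (rad2deg(ra) / 15) %% 24
  )
}

#' Solar declination
#'
#' Declination of the sun at a given UT instant, from a low-precision
#' ephemeris (mean elements plus equation of centre).
#'
#' @param date calendar date (Date or ISO-8601 string).
#' @param minutes_ut minutes from midnight UT (default 720 = noon).
#' @return declination in degrees, in \[-23.45, 23.45\].
#' @export
solar_declination <- function(date, minutes_ut = 720) {
  n <- days_since_j2000(date, minutes_ut)
  yr <- 2000 + n / 365.25
  if (any(yr < 1940 | yr > 2100))
    stop("solar ephemeris only supported between years 1940 and 2100")
  sun_position(n)$declination_deg
}

#' Greenwich mean sidereal time
#'
#' GMST in hours for a UT instant (IAU 1982 linear formulation, adequate to
#' well under a second over the supported epoch range).
#'
#' @inheritParams solar_declination
#' @return hours in \[0, 24).
#' @export
gmst_hours <- function(date, minutes_ut = 0) {
  n <- days_since_j2000(date, minutes_ut)
  (18.697374558 + 24.06570982441908 * n) %% 24
}

# ---- event prediction -------------------------------------------------------

# Core vectorized solver. lon/lat in degrees (vectors of equal length).
# Solves, for each point, the UT at which the sun's local hour angle
# LHA = GMST*15 + lon - RA*15 equals -omega (sunrise) or +omega (sunset),
# where cos(omega) = (sin h0 - sin(phi) sin(delta)) / (cos(phi) cos(delta)).
# delta and RA are refreshed at each provisional event time (fixed-point
# iteration; 3 passes leave updates far below 0.5 min).
solve_event <- function(lon, lat, date, h0, rising, iterations = 3) {
  stopifnot(length(lon) == length(lat))
  phi <- deg2rad(lat)
  sinh0 <- sin(deg2rad(h0))
  n0 <- days_since_j2000(date, 0)
  # provisional: local solar noon offset by +/- 6 h
  t <- 720 - 4 * lon + if (rising) -360 else 360
  status <- rep("normal", length(lon))
  for (k in seq_len(iterations)) {
    sp <- sun_position(n0 + t / 1440)
    delta <- deg2rad(sp$declination_deg)
    cosw <- (sinh0 - sin(phi) * sin(delta)) / (cos(phi) * cos(delta))
    status <- ifelse(cosw < -1, "polar_day", ifelse(cosw > 1, "polar_night", "normal"))
    w <- rad2deg(acos(pmin(1, pmax(-1, cosw))))
    target <- if (rising) -w else w  # local hour angle at event, deg
    gmst <- (18.697374558 + 24.06570982441908 * (n0 + t / 1440)) %% 24
    lha <- (gmst * 15 + lon - sp$ra_hours * 15) %% 360
    dlha <- ((target - lha + 180) %% 360) - 180
    # LHA advances at the sidereal rate, 360.9856 deg per UT day
    t <- t + dlha * 1440 / 360.985647
  }
  list(ut = t %% 1440, status = status)
}

#' Predict sunrise and sunset times
#'
#' Universal times of sunrise and sunset for positions and a date, at a
#' configurable twilight altitude. Vectorized over `lon`/`lat`.
#'
#' @param lon longitude, degrees east in \[-180, 180).
#' @param lat latitude, degrees north, |lat| <= 89.
#' @param date calendar date.
#' @param h0 sun altitude defining the event, degrees (default -0.833,
#'   geometric sunrise with standard refraction; must lie in \[-18, 0\]).
#' @param iterations fixed-point refinements of the solar position at the
#'   provisional event time.
#' @return data.frame with columns `sunrise_ut`, `sunset_ut` (minutes from
#'   midnight UT, NA when not "normal") and `status` (one of "normal",
#'   "polar_day", "polar_night").
#' @export
predict_event_times <- function(lon, lat, date, h0 = -0.833, iterations = 3) {
  if (h0 < -18 || h0 > 0) stop("h0 must lie in [-18, 0] degrees")
  if (any(abs(lat) > 89)) stop("|lat| must be <= 89")
  sr <- solve_event(lon, lat, date, h0, rising = TRUE, iterations = iterations)
  ss <- solve_event(lon, lat, date, h0, rising = FALSE, iterations = iterations)
  status <- ifelse(sr$status != "normal", sr$status,
                   ifelse(ss$status != "normal", ss$status, "normal"))
  bad <- status != "normal"
  out <- data.frame(
    sunrise_ut = ifelse(bad, NA_real_, sr$ut),
    sunset_ut = ifelse(bad, NA_real_, ss$ut),
    status = status,
    stringsAsFactors = FALSE
  )
  out
}

#' Gaussian log-likelihood of an observed solar event time
#'
#' Circular-residual Gaussian log-density of an observed sunrise or sunset
#' time given predictions, with a finite floor for positions in polar
#' day/night (strong but not absorbing penalty, exp(-8) of the mode).
#'
#' @param obs_min observed event time, minutes UT.
#' @param pred_min predicted event time(s), minutes UT (NA allowed where
#'   `status` is not "normal").
#' @param sigma_min observation standard deviation in minutes (default 20).
#' @param status prediction status vector (see [predict_event_times()]).
#' @return log-density, same length as `pred_min`.
#' @export
event_log_likelihood <- function(obs_min, pred_min, sigma_min = 20,
                                 status = "normal") {
  if (sigma_min <= 0) stop("sigma_min must be > 0")
  mode_log <- -log(sigma_min * sqrt(2 * pi))
  r <- circular_minutes(obs_min, pred_min)
  ll <- mode_log - r^2 / (2 * sigma_min^2)
  floor_ll <- mode_log - 8
  ifelse(status != "normal" | is.na(pred_min), floor_ll, ll)
}
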