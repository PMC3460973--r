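#' Wrap an angle to the interval [-180, 180)
#'
#' All torsion angles in the package live on this interval, in degrees.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector with every element in `[-180, 180)`.
#' @export
wrap_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

#' Circular mean of angles in degrees
#'
#' The mean direction `atan2(mean(sin), mean(cos))`, which is the correct
#' average for torsion angles (the arithmetic mean of 170 and -170 is 0,
#' the circular mean is 180).
#'
#' @param x numeric vector of angles in degrees.
#' @return a single angle in `[-180, 180)`.
#' @export
circular_mean <- function(x) {
  r <- x * pi / 180
  wrap_angle(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

## shortest signed arc from `from` to `to`, in degrees in [-180, 180)
angle_diff <- function(to, from) {
  wrap_angle(to - from)
}

## circular equality helper used throughout (treats -180 and 180 as equal)
angles_close <- function(a, b, tol = 1e-6) {
  all(abs(wrap_angle(a - b)) < tol |
        abs(abs(wrap_angle(a - b)) - 360) < tol)
}
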