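#' Define a collective-variable space
#'
#' A CV space is an ordered set of named axes. Each axis is either linear or
#' periodic (with a stated period). Periodicity of the base-rolling angle
#' chi' is handled by embedding it as (cos chi', sin chi'), so the default
#' space used throughout the package is purely linear.
#'
#' @param axes character vector of axis names (at least 2).
#' @param kind character vector, `"linear"` or `"periodic"` per axis.
#' @param period numeric vector of periods; must be finite and positive for
#'   periodic axes, `NA` for linear axes.
#' @param units character vector of units per axis (`"rad"` or
#'   `"dimensionless"`).
#' @return An object of class `cv_space`.
#' @export
cv_space <- function(axes,
                     kind = rep("linear", length(axes)),
                     period = rep(NA_real_, length(axes)),
                     units = rep("dimensionless", length(axes))) {
  if (length(axes) < 2L) stop("a CV space needs at least 2 axes")
  if (length(kind) != length(axes) || length(period) != length(axes) ||
      length(units) != length(axes))
    stop("axes, kind, period and units must have equal length")
  if (!all(kind %in% c("linear", "periodic")))
    stop("axis kind must be 'linear' or 'periodic'")
  bad <- kind == "periodic" & (!is.finite(period) | period <= 0)
  if (any(bad))
    stop("periodic axes must declare a positive finite period: ",
         paste(axes[bad], collapse = ", "))
  structure(list(axes = axes, kind = kind, period = period, units = units),
            class = "cv_space")
}

#' Default embedded CV space for base-pair transitions
#'
#' The space spanned by cos(chi'), sin(chi') and the base-opening angle
#' theta. The first two axes are linear in [-1, 1]; theta is linear in rad.
#'
#' @return A [cv_space()] with axes `cos_chiprime`, `sin_chiprime`, `theta`.
#' @export
default_cv_space <- function() {
  cv_space(c("cos_chiprime", "sin_chiprime", "theta"),
           kind = c("linear", "linear", "linear"),
           units = c("dimensionless", "dimensionless", "rad"))
}

#' Embed (chi', theta) dynamical coordinates into the path space
#'
#' @param chi base-rolling angle chi' in rad (vector).
#' @param theta base-opening angle in rad (vector).
#' @return A matrix with columns cos(chi'), sin(chi'), theta.
#' @export
embed_angles <- function(chi, theta) {
  cbind(cos(chi), sin(chi), theta, deparse.level = 0)
}

# Period-2 minimum image on the s axis: maps into [-1, 1).
wrap_s <- function(x) ((x + 1) %% 2) - 1

# Wrap an angle to [-pi, pi).
wrap_angle <- function(x) ((x + pi) %% (2 * pi)) - pi
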