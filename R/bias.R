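#' Create a (possibly empty) metadynamics hill list
#'
#' Hills are Gaussians on the periodic path-progress axis s, with domain
#' period 2. The list is append-only and shared by all standard walkers of
#' one path; evaluation uses the minimum-image distance on s.
#'
#' @param center,width,height,time equal-length numeric vectors (may be
#'   empty). Defaults follow the production protocol: width 0.1 path units,
#'   height 0.05 kcal/mol.
#' @return A `hill_list` data frame with columns time, center, width, height.
#' @export
hill_list <- function(center = numeric(0), width = numeric(0),
                      height = numeric(0), time = numeric(0)) {
  n <- length(center)
  if (any(width <= 0)) stop("hill width must be positive")
  if (any(height <= 0)) stop("hill height must be positive")
  structure(data.frame(time = rep_len(as.numeric(time), n),
                       center = as.numeric(center),
                       width = rep_len(as.numeric(width), n),
                       height = rep_len(as.numeric(height), n)),
            class = c("hill_list", "data.frame"), period = 2)
}

#' Deposit a hill at a walker's current path progress
#'
#' Only standard walkers deposit; attractors take no part in the
#' free-energy calculation and are refused.
#'
#' @param hills a [hill_list()].
#' @param s current path progress of the depositing walker.
#' @param time deposit time in ps.
#' @param role walker role, `"standard"` or `"attractor"`.
#' @param width,height Gaussian parameters (defaults 0.1 and 0.05).
#' @return The extended [hill_list()].
#' @export
deposit_hill <- function(hills, s, time, role = "standard",
                         width = 0.1, height = 0.05) {
  if (!identical(role, "standard"))
    stop("only standard walkers deposit hills; role was '", role, "'")
  out <- rbind(hills, data.frame(time = time, center = wrap_s(s),
                                 width = width, height = height))
  structure(out, class = c("hill_list", "data.frame"), period = 2)
}

#' Metadynamics bias energy and force along s
#'
#' Energy is the sum of Gaussians at the period-2 minimum-image distance;
#' the force is the analytic negative gradient -dE/ds.
#'
#' @param s path progress value(s) in [-1, 1].
#' @param hills a [hill_list()].
#' @return `list(energy =, force =)`, vectorized over `s`.
#' @export
bias_energy_force <- function(s, hills) {
  if (is.null(hills) || nrow(hills) == 0L)
    return(list(energy = rep(0, length(s)), force = rep(0, length(s))))
  r <- cpp_hills_energy(as.numeric(s), hills$center, hills$width, hills$height)
  list(energy = r$energy, force = -r$dEds)
}

#' Tube potential: upper harmonic wall on the perpendicular distance z
#'
#' An upper wall at z = 0 penalizes any excursion from the path with energy
#' k z^2 / 2; the force restores toward the path.
#'
#' @param z perpendicular distance(s), >= 0.
#' @param k force constant in kcal/mol per squared path unit (default 50).
#' @return `list(energy =, force =)` with force = -k z.
#' @export
tube_energy_force <- function(z, k = 50) {
  list(energy = 0.5 * k * z^2, force = -k * z)
}

#' Define a harmonic restraint, optionally steered
#'
#' The restraint center is either fixed or moves linearly from `steer_from`
#' to `center` over the first `window` ps (a moving harmonic restraint);
#' after the window the center is constant. For periodic targets the
#' center interpolation and the restraint difference both use the
#' minimum-image convention.
#'
#' @param target which CV the restraint acts on: `"s"`, `"theta"`, or
#'   `"point"` (a full CV-space point).
#' @param k force constant (kcal/mol per squared CV unit).
#' @param center target value (or point).
#' @param steer_from starting center for a steered restraint, or `NULL`.
#' @param window steering window in ps (> 0 when steering).
#' @param period CV period (2 for s), or `NULL` for non-periodic CVs.
#' @return An object of class `restraint_schedule`.
#' @export
restraint_schedule <- function(target = c("s", "theta", "point"), k, center,
                               steer_from = NULL, window = NULL,
                               period = NULL) {
  target <- match.arg(target)
  if (!is.null(steer_from) && (is.null(window) || window <= 0))
    stop("steered restraints need a positive steering window")
  structure(list(target = target, k = k, center = center,
                 steer_from = steer_from, window = window, period = period),
            class = "restraint_schedule")
}

#' Restraint center at a given time
#' @param schedule a [restraint_schedule()].
#' @param t time in ps.
#' @return The (possibly interpolated) center.
#' @export
restraint_center <- function(schedule, t) {
  if (is.null(schedule$steer_from)) return(schedule$center)
  a <- pmin(1, pmax(0, t / schedule$window))
  delta <- schedule$center - schedule$steer_from
  if (!is.null(schedule$period))
    delta <- delta - schedule$period * round(delta / schedule$period)
  cen <- schedule$steer_from + a * delta
  if (!is.null(schedule$period))
    cen <- cen - schedule$period * round(cen / schedule$period)
  cen
}

#' Harmonic restraint energy and force
#'
#' Energy is k (value - center(t))^2 / 2 with a period-aware difference for
#' periodic CVs.
#'
#' @param value current CV value (or point for `target = "point"`).
#' @param schedule a [restraint_schedule()].
#' @param t time in ps.
#' @return `list(energy =, force =)`; force = -k (value - center(t)).
#' @export
restraint_energy_force <- function(value, schedule, t = 0) {
  cen <- restraint_center(schedule, t)
  d <- value - cen
  if (!is.null(schedule$period))
    d <- d - schedule$period * round(d / schedule$period)
  list(energy = 0.5 * schedule$k * sum(d^2), force = -schedule$k * d)
}

#' Write a hill list as a plain-text HILLS table
#'
#' One hill per line: time, center, sigma, height (17 significant digits,
#' in the spirit of common metadynamics hill logs). [read_hills()] parses
#' it back losslessly.
#'
#' @param hills a [hill_list()].
#' @param file output path.
#' @export
write_hills <- function(hills, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time center sigma height", con)
  if (nrow(hills) > 0L)
    writeLines(sprintf("%.17g %.17g %.17g %.17g", hills$time, hills$center,
                       hills$width, hills$height), con)
  invisible(file)
}

#' Read a HILLS table written by [write_hills()]
#' @param file HILLS file.
#' @return A [hill_list()].
#' @export
read_hills <- function(file) {
  lines <- grep("^#", readLines(file), invert = TRUE, value = TRUE)
  if (length(lines) == 0L) return(hill_list())
  m <- do.call(rbind, lapply(strsplit(trimws(lines), " +"), as.numeric))
  hill_list(center = m[, 2L], width = m[, 3L], height = m[, 4L],
            time = m[, 1L])
}
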