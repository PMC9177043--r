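#' Parameters of the rotor-flip model landscape
#'
#' An analytic two-channel surrogate for the WCF/HG base-pairing landscape
#' in the (chi', theta) plane. The two minima sit near (chi_wcf, 0) and
#' (chi_hg, 0). The rotation barrier factor
#' `r(chi') = (1 - cos(chi' - chi_wcf)) (1 - cos(chi' - chi_hg))`
#' vanishes quadratically at both minima; its prefactor is blended between
#' the 3' half (chi' near 0) and the 5' half (chi' near +-pi) and is lowered
#' by a Gaussian gate of width sigma_theta centered on the outside channel
#' `theta_out * [sin(chi'-chi_wcf) sin(chi'-chi_hg)]^2`, which sits at
#' theta_out at mid-rotation and descends along a gentle diagonal into the
#' closed-helix basins (the base flips out only while it rotates). `k_open theta^2` closes the
#' helix, and a smooth tilt raises the HG basin by df_hg. With the defaults
#' the four saddle heights order as
#' outside-3' < inside-3' < outside-5' < inside-5'.
#'
#' @param chi_wcf,chi_hg stable-state rolling angles in rad (+1.5 / -1.5).
#' @param b_in_3p,b_in_5p inside barrier scales, kcal/mol.
#' @param b_out_3p,b_out_5p outside (gated) barrier scales, kcal/mol.
#' @param theta_out outside channel opening angle, rad (-pi/2: major groove).
#' @param sigma_theta gate width, rad.
#' @param k_open opening stiffness, kcal/mol per rad^2.
#' @param df_hg free-energy offset of the HG basin above WCF, kcal/mol (> 0).
#' @param gate_exp exponent applied to the squared-sine gate-center
#'   profile (1 = plain).
#' @return A named parameter vector of class `rotor_flip_params`.
#' @export
rotor_flip_params <- function(chi_wcf = 1.5, chi_hg = -1.5,
                              b_in_3p = 4.2, b_in_5p = 5.0,
                              b_out_3p = 1.0, b_out_5p = 2.0,
                              theta_out = -1.8, sigma_theta = 0.5,
                              k_open = 0.7, df_hg = 1.0, gate_exp = 0.5) {
  if (df_hg < 0) stop("df_hg must be non-negative")
  structure(c(chi_wcf = chi_wcf, chi_hg = chi_hg, b_in_3p = b_in_3p,
              b_in_5p = b_in_5p, b_out_3p = b_out_3p, b_out_5p = b_out_5p,
              theta_out = theta_out, sigma_theta = sigma_theta,
              k_open = k_open, df_hg = df_hg, gate_exp = gate_exp),
            class = "rotor_flip_params")
}

#' Rotor-flip energy
#' @param chi,theta coordinates in rad (vectorized).
#' @param params a [rotor_flip_params()].
#' @return Energy in kcal/mol.
#' @export
rotor_flip_energy <- function(chi, theta, params = rotor_flip_params()) {
  n <- max(length(chi), length(theta))
  cpp_rotor_flip(rep_len(as.numeric(chi), n), rep_len(as.numeric(theta), n),
                 unclass(params))$energy
}

#' Rotor-flip analytic gradient
#' @inheritParams rotor_flip_energy
#' @return A two-column matrix (dV/dchi, dV/dtheta).
#' @export
rotor_flip_gradient <- function(chi, theta, params = rotor_flip_params()) {
  n <- max(length(chi), length(theta))
  r <- cpp_rotor_flip(rep_len(as.numeric(chi), n),
                      rep_len(as.numeric(theta), n), unclass(params))
  cbind(dchi = r$dchi, dtheta = r$dtheta)
}

# Generic analytic-potential container. `cpp_id`/`cpp_par` let the compiled
# propagators evaluate the same closed form.
make_potential <- function(kind, cpp_id, cpp_par, energy, gradient, dim,
                           periodic = rep(FALSE, dim)) {
  structure(list(kind = kind, cpp_id = cpp_id, cpp_par = as.numeric(cpp_par),
                 energy = energy, gradient = gradient, dim = dim,
                 periodic = periodic),
            class = "analytic_potential")
}

#' Rotor-flip analytic potential
#' @param params a [rotor_flip_params()].
#' @return An `analytic_potential` over (chi', theta), periodic in chi'.
#' @export
potential_rotor_flip <- function(params = rotor_flip_params()) {
  make_potential("rotor_flip", 1L, unclass(params),
                 energy = function(x) {
                   x <- if (is.null(dim(x))) matrix(x, ncol = 2) else x
                   rotor_flip_energy(x[, 1L], x[, 2L], params)
                 },
                 gradient = function(x) {
                   x <- if (is.null(dim(x))) matrix(x, ncol = 2) else x
                   rotor_flip_gradient(x[, 1L], x[, 2L], params)
                 },
                 dim = 2L, periodic = c(TRUE, FALSE))
}

#' Harmonic well potential
#' @param k spring constant(s), one per axis (recycled).
#' @param dim dimensionality.
#' @return An `analytic_potential` with energy sum(k x^2)/2.
#' @export
potential_harmonic <- function(k = 1, dim = length(k)) {
  k <- rep_len(k, dim)
  make_potential("harmonic", 2L, k,
                 energy = function(x) {
                   x <- if (is.null(dim(x))) matrix(x, ncol = dim) else x
                   drop(x^2 %*% (k / 2))
                 },
                 gradient = function(x) {
                   x <- if (is.null(dim(x))) matrix(x, ncol = dim) else x
                   sweep(x, 2L, k, "*")
                 },
                 dim = dim)
}

#' Flat potential
#' @param dim dimensionality.
#' @param periodic logical per axis (chi'-like axes wrap at +-pi).
#' @return An `analytic_potential` with zero energy everywhere.
#' @export
potential_flat <- function(dim = 2L, periodic = c(TRUE, FALSE)) {
  make_potential("flat", 3L, numeric(0),
                 energy = function(x) rep(0, NROW(if (is.null(dim(x)))
                   matrix(x, ncol = dim) else x)),
                 gradient = function(x) {
                   x <- if (is.null(dim(x))) matrix(x, ncol = dim) else x
                   matrix(0, nrow(x), ncol(x))
                 },
                 dim = dim, periodic = rep_len(periodic, dim))
}

#' Channel barrier heights by dense grid search
#'
#' Saddle oracle for two-channel landscapes: for every chi' slice between
#' the two minima (in the stated half of the rotation), the pass energy of a
#' channel is the minimum of V over the channel's theta window; the channel
#' barrier is the maximum of these pass energies along chi', referenced to
#' the WCF minimum.
#'
#' @param potential an `analytic_potential` over (chi', theta).
#' @param params a [rotor_flip_params()] (for the minima positions).
#' @param theta_inside,theta_outside theta windows (rad) of the two channels.
#' @param n_chi,n_theta grid resolution.
#' @return Named vector of barriers (kcal/mol): `outside_3p`, `inside_3p`,
#'   `outside_5p`, `inside_5p`, plus `v_wcf`, `v_hg`.
#' @export
channel_barriers <- function(potential = potential_rotor_flip(params),
                             params = rotor_flip_params(),
                             theta_inside = c(-0.35, 1.2),
                             theta_outside = c(-2.6, -0.85),
                             n_chi = 721L, n_theta = 601L) {
  chi_wcf <- params[["chi_wcf"]]
  chi_hg <- params[["chi_hg"]]
  pass <- function(chi_grid, theta_win) {
    th <- seq(theta_win[1L], theta_win[2L], length.out = n_theta)
    g <- expand.grid(chi = chi_grid, theta = th)
    V <- matrix(potential$energy(cbind(g$chi, g$theta)),
                nrow = length(chi_grid))
    apply(V, 1L, min)
  }
  # 3' half: from chi_hg up through 0 to chi_wcf; 5' half: from chi_wcf up
  # through pi to chi_hg + 2 pi
  chi_3p <- seq(chi_hg, chi_wcf, length.out = n_chi)
  chi_5p <- seq(chi_wcf, chi_hg + 2 * pi, length.out = n_chi)
  v_wcf <- min(potential$energy(cbind(chi_wcf,
                                      seq(-0.5, 0.5, length.out = 201L))))
  v_hg <- min(potential$energy(cbind(chi_hg,
                                     seq(-0.5, 0.5, length.out = 201L))))
  c(outside_3p = max(pass(chi_3p, theta_outside)) - v_wcf,
    inside_3p = max(pass(chi_3p, theta_inside)) - v_wcf,
    outside_5p = max(pass(chi_5p, theta_outside)) - v_wcf,
    inside_5p = max(pass(chi_5p, theta_inside)) - v_wcf,
    v_wcf = v_wcf, v_hg = v_hg)
}
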