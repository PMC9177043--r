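#' Reference free-energy profile by dense grid quadrature
#'
#' Independent oracle for the metadynamics estimate: on a dense 2D grid of
#' configurations, Boltzmann weights of the biased system
#' `exp(-(V + k z^2 / 2) / kT)` are accumulated into the s bin that each
#' configuration projects to on the given path, and
#' `F(s) = -kT log(sum of weights)` is anchored to 0 at the WCF bin
#' (s = +-1).
#'
#' @param potential an `analytic_potential`.
#' @param path a [path_curve()] (typically the converged path).
#' @param tube_k tube force constant applied to z.
#' @param kT thermal energy, kcal/mol.
#' @param n_bins number of s bins (default 200 on [-1, 1]).
#' @param grid1,grid2 quadrature grids for the two dynamical coordinates.
#'   With `embedding = "angles"` these are chi' (periodic, default 2000
#'   points on [-pi, pi)) and theta (default 500 points on [-3.2, 1.8]).
#' @param embedding `"angles"` maps grid points through
#'   [embed_angles()]; `"cartesian"` uses them directly (2D paths).
#' @param check if `TRUE`, recompute at double resolution and fail when any
#'   bin moves by more than `0.05 kT` (grid too coarse).
#' @return A `fes_profile` (see [averaged_profile()]) with zero std.
#' @export
reference_fes_quadrature <- function(potential, path, tube_k = 50, kT = 0.596,
                                     n_bins = 200L,
                                     grid1 = NULL, grid2 = NULL,
                                     embedding = c("angles", "cartesian"),
                                     check = TRUE) {
  embedding <- match.arg(embedding)
  if (is.null(grid1))
    grid1 <- seq(-pi, pi, length.out = 2001L)[-2001L]
  if (is.null(grid2))
    grid2 <- seq(-3.2, 1.8, length.out = 501L)
  one <- function(g1, g2) {
    gr <- expand.grid(a = g1, b = g2)
    x <- cbind(gr$a, gr$b)
    V <- potential$energy(x)
    pts <- if (embedding == "angles") embed_angles(x[, 1L], x[, 2L]) else x
    pr <- cpp_project_batch(pts, path$nodes)
    s <- -1 + 2 * pr[, 1L]
    w <- exp(-(V + 0.5 * tube_k * pr[, 2L]^2) / kT)
    bin <- pmin(pmax(floor((s + 1) / 2 * n_bins) + 1L, 1L), n_bins)
    tot <- rep(0, n_bins)
    agg <- tapply(w, bin, sum)
    tot[as.integer(names(agg))] <- agg
    if (any(tot == 0))
      stop("quadrature grid too coarse: empty s bins")
    F <- -kT * log(tot)
    F - mean(F[c(1L, n_bins)])
  }
  F <- one(grid1, grid2)
  if (check) {
    refine <- function(g) {
      h <- diff(g[1:2]) / 2
      sort(c(g, g + h))
    }
    F2 <- one(refine(grid1), refine(grid2))
    if (max(abs(F2 - F)) > 0.05 * kT)
      stop("quadrature not converged: refinement moved the profile by ",
           signif(max(abs(F2 - F)) / kT, 3), " kT")
    F <- F2
  }
  fes_profile(fes_grid(n_bins), F, std = rep(0, n_bins), times = numeric(0))
}
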