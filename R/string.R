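# Equal-arc-length resampling of a polyline (shared by reparameterize()
# and the string oracle). One pass: nodes placed at uniform arc fractions.
resample_polyline <- function(nodes, n = nrow(nodes)) {
  seg <- segment_lengths(nodes)
  L <- sum(seg)
  if (L <= 0) stop("degenerate polyline")
  cum <- c(0, cumsum(seg))
  target <- seq(0, L, length.out = n)
  out <- matrix(NA_real_, n, ncol(nodes))
  out[1L, ] <- nodes[1L, ]
  out[n, ] <- nodes[nrow(nodes), ]
  for (i in 2:(n - 1L)) {
    j <- findInterval(target[i], cum, rightmost.closed = TRUE)
    j <- min(max(j, 1L), nrow(nodes) - 1L)
    t <- (target[i] - cum[j]) / (cum[j + 1L] - cum[j])
    out[i, ] <- nodes[j, ] + t * (nodes[j + 1L, ] - nodes[j, ])
  }
  out
}

#' Zero-temperature string-method minimum free-energy path
#'
#' Independent oracle for the adaptive-path machinery: gradient descent of
#' string nodes on the analytic potential with equal-arc-length
#' reparameterization after every step, endpoints pinned at the WCF anchor.
#' The string lives in the (phi, theta) plane with phi the unwrapped
#' rolling angle over one full revolution; since the embedding
#' [cos chi', sin chi', theta] is isometric to that plane, the converged
#' string is the MFEP of the embedded space as well.
#'
#' @param potential an `analytic_potential` over (chi', theta).
#' @param n_nodes number of string nodes.
#' @param mechanism `"inside"` (initial guess flat at theta = 0) or
#'   `"outside"` (initial guess dipping to `theta_out` in each half).
#' @param chi_wcf WCF rolling angle (anchor), rad.
#' @param theta_wcf anchor base-opening value, rad.
#' @param theta_out outside-channel opening used for the initial guess.
#' @param step descent step size.
#' @param n_iter iteration cap.
#' @param tol stop when the largest node move per iteration drops below.
#' @return `list(phi =, theta =, nodes =)` with `nodes` the embedded
#'   [cos chi', sin chi', theta] node matrix, of class `string_mfep`.
#' @export
string_mfep <- function(potential, n_nodes = 39L,
                        mechanism = c("inside", "outside"),
                        chi_wcf = 1.5, theta_wcf = 0, theta_out = -pi / 2,
                        step = 0.004, n_iter = 20000L, tol = 1e-10) {
  mechanism <- match.arg(mechanism)
  frac <- seq(0, 1, length.out = n_nodes)
  phi <- chi_wcf + 2 * pi * frac
  theta <- if (mechanism == "inside") rep(theta_wcf, n_nodes)
           else theta_wcf + (theta_out - theta_wcf) * abs(sin(2 * pi * frac))
  nodes <- cbind(phi, theta)
  resample_every <- 25L
  for (it in seq_len(n_iter)) {
    g <- potential$gradient(cbind(wrap_angle(nodes[, 1L]), nodes[, 2L]))
    # move by the perpendicular gradient component only: tangential motion
    # is parameterization, not shape, and skipping it limits the
    # corner-cutting that per-iteration resampling would accumulate
    tang <- nodes[3:n_nodes, ] - nodes[1:(n_nodes - 2L), ]
    tang <- tang / sqrt(rowSums(tang^2))
    gi <- g[2:(n_nodes - 1L), ]
    gperp <- gi - tang * rowSums(gi * tang)
    prev <- nodes
    nodes[2:(n_nodes - 1L), ] <- nodes[2:(n_nodes - 1L), ] - step * gperp
    if (it %% resample_every == 0L) nodes <- resample_polyline(nodes)
    if (max(abs(nodes - prev)) < tol && it %% resample_every == 0L) break
  }
  nodes <- resample_polyline(nodes)
  structure(list(phi = nodes[, 1L], theta = nodes[, 2L],
                 nodes = embed_angles(nodes[, 1L], nodes[, 2L])),
            class = "string_mfep")
}

#' Distance from path nodes to a reference curve
#'
#' Densely resamples the reference polyline and reports, for each query
#' node, the distance to the nearest point on it.
#'
#' @param nodes query node matrix (embedded space).
#' @param ref reference node matrix in the same space.
#' @param n_dense dense resampling resolution.
#' @return Vector of distances, one per query node.
#' @export
nodes_to_curve_distance <- function(nodes, ref, n_dense = 4000L) {
  dense <- resample_polyline(ref, n = n_dense)
  pr <- cpp_project_batch(as.matrix(nodes), dense)
  pr[, 2L]
}

# Newton/BFGS refinement of a stationary point from a grid seed.
refine_saddle <- function(potential, chi_win, theta_win, n_grid = 61L) {
  g <- expand.grid(chi = seq(chi_win[1L], chi_win[2L], length.out = n_grid),
                   theta = seq(theta_win[1L], theta_win[2L],
                               length.out = n_grid))
  gn <- rowSums(potential$gradient(cbind(g$chi, g$theta))^2)
  x0 <- unlist(g[which.min(gn), ])
  obj <- function(x) sum(potential$gradient(matrix(x, 1L))^2)
  stats::optim(x0, obj, method = "BFGS",
               control = list(reltol = 1e-16, maxit = 500L))$par
}

# Normalized steepest-descent trajectory from a displaced saddle.
descend_path <- function(potential, x0, step = 0.002, gtol = 1e-6,
                         max_steps = 60000L) {
  x <- x0
  out <- matrix(NA_real_, max_steps, 2L)
  n <- 0L
  for (i in seq_len(max_steps)) {
    g <- drop(potential$gradient(matrix(x, 1L)))
    gn <- sqrt(sum(g^2))
    if (gn < gtol) break
    x <- x - step * g / max(gn, 0.25)
    n <- n + 1L
    out[n, ] <- x
  }
  out[seq_len(n), , drop = FALSE]
}

#' Minimum free-energy path by steepest descent from the saddles
#'
#' The exact zero-temperature limit of the adaptive path: for the chosen
#' channel, the two saddle points (5' and 3') are refined from grid seeds
#' and the MFEP is assembled from the four steepest-descent trajectories
#' they spawn (WCF -> 5' saddle -> HG -> 3' saddle -> WCF), then resampled
#' to equidistant nodes. Unlike a finite string, this resolves the narrow
#' entrance channels into the minima exactly.
#'
#' @param potential an `analytic_potential` over (chi', theta).
#' @param mechanism `"inside"` or `"outside"` channel.
#' @param n_nodes nodes of the returned discretized curve.
#' @param chi_wcf WCF rolling angle (cycle anchor).
#' @param theta_windows list with `inside` and `outside` theta windows for
#'   the saddle search.
#' @return `list(phi =, theta =, nodes =, saddles =)` of class
#'   `mfep_descent`; `nodes` is the embedded node matrix.
#' @export
mfep_descent <- function(potential, mechanism = c("inside", "outside"),
                         n_nodes = 401L, chi_wcf = 1.5,
                         theta_windows = list(inside = c(-0.4, 0.4),
                                              outside = c(-1.7, -1.0))) {
  mechanism <- match.arg(mechanism)
  win <- theta_windows[[mechanism]]
  # 5' saddle near chi' = +-pi, 3' saddle near chi' = 0
  sad5 <- refine_saddle(potential, c(pi - 0.8, pi + 0.8), win)
  sad3 <- refine_saddle(potential, c(-0.8, 0.8), win)
  phi_of <- function(chi) chi_wcf + ((chi - chi_wcf) %% (2 * pi))
  # continuous unwrap of a descent trajectory onto the phi coordinate of
  # the revolution, anchored at the saddle's phi
  branch <- function(sad, dirsign, phi0) {
    m <- descend_path(potential, sad + dirsign * c(1e-4, 0))
    phi1 <- phi0 + wrap_angle(m[1L, 1L] - phi0)
    phi <- phi1 + cumsum(c(0, wrap_angle(diff(m[, 1L]))))
    cbind(phi, m[, 2L])
  }
  phi5 <- phi_of(sad5[1L])
  phi3 <- phi_of(sad3[1L])
  b5_wcf <- branch(sad5, -1, phi5)   # 5' saddle -> WCF
  b5_hg <- branch(sad5, +1, phi5)    # 5' saddle -> HG
  b3_hg <- branch(sad3, -1, phi3)    # 3' saddle -> HG
  b3_wcf <- branch(sad3, +1, phi3)   # 3' saddle -> WCF
  curve <- rbind(c(chi_wcf, 0),
                 b5_wcf[rev(seq_len(nrow(b5_wcf))), ],
                 c(phi5, sad5[2L]),
                 b5_hg,
                 b3_hg[rev(seq_len(nrow(b3_hg))), ],
                 c(phi3, sad3[2L]),
                 b3_wcf,
                 c(chi_wcf + 2 * pi, 0))
  nodes <- resample_polyline(curve, n = n_nodes)
  structure(list(phi = nodes[, 1L], theta = nodes[, 2L],
                 nodes = embed_angles(nodes[, 1L], nodes[, 2L]),
                 saddles = rbind(sad5 = sad5, sad3 = sad3)),
            class = "mfep_descent")
}
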