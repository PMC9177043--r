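#' Construct a path curve in an embedded CV space
#'
#' A path curve is an ordered sequence of nodes in the CV space. Cyclic
#' paths represent a full revolution of the rolling base: the first and the
#' last node coincide at the shared fixed endpoint (the WCF anchor), and the
#' progress coordinate s is periodic on [-1, +1] with the anchor at s = +-1.
#'
#' @param nodes numeric matrix, one node per row, one CV axis per column.
#' @param space a [cv_space()]; defaults to [default_cv_space()].
#' @param cyclic logical; cyclic paths must close on their first node.
#' @param mechanism optional label (`"inside"` or `"outside"`).
#' @return An object of class `path_curve`.
#' @export
path_curve <- function(nodes, space = default_cv_space(), cyclic = TRUE,
                       mechanism = NULL) {
  nodes <- as.matrix(nodes)
  if (nrow(nodes) < 3L) stop("a path needs at least 3 nodes")
  if (ncol(nodes) != length(space$axes))
    stop("node dimensionality (", ncol(nodes), ") does not match the CV space (",
         length(space$axes), " axes)")
  if (cyclic) {
    if (max(abs(nodes[1L, ] - nodes[nrow(nodes), ])) > 1e-9)
      stop("cyclic paths must have identical first and last nodes")
    nodes[nrow(nodes), ] <- nodes[1L, ]
  }
  colnames(nodes) <- space$axes
  structure(list(nodes = nodes, space = space, cyclic = cyclic,
                 anchor = nodes[1L, ], mechanism = mechanism),
            class = "path_curve")
}

#' @export
print.path_curve <- function(x, ...) {
  cat(sprintf("path_curve: %d nodes, %s, axes [%s]%s\n",
              nrow(x$nodes), if (x$cyclic) "cyclic" else "open",
              paste(x$space$axes, collapse = ", "),
              if (is.null(x$mechanism)) "" else paste0(", ", x$mechanism)))
  invisible(x)
}

# Arc length of each segment of the polyline.
segment_lengths <- function(nodes) {
  d <- diff(nodes)
  sqrt(rowSums(d * d))
}

#' Total arc length of a path
#' @param path a [path_curve()].
#' @return Total polyline length in CV-space units.
#' @export
path_length <- function(path) sum(segment_lengths(path$nodes))

#' Initialize a cyclic WCF -> HG -> WCF path with no flipping
#'
#' The initial guess traces a full revolution of the rolling base along the
#' chi' unit circle at the WCF base-opening value: from the WCF anchor,
#' through the 5' half (chi' near +-pi at s < 0), past the HG state near
#' s ~ 0, back through the 3' half (chi' near 0 at s > 0) to the anchor.
#' Nodes are equidistant chords on the circle.
#'
#' @param wcf_point embedded CV point `[cos chi', sin chi', theta]` of the
#'   WCF state (shared fixed endpoint).
#' @param hg_point embedded CV point of the HG state; must lie at the same
#'   theta (no flipping in the initial guess).
#' @param n_nodes number of string nodes (>= 3); 39 for outside paths,
#'   11 for inside paths.
#' @param mechanism `"inside"` or `"outside"`; stored as a label.
#' @return A cyclic [path_curve()].
#' @export
init_cyclic_path <- function(wcf_point, hg_point, n_nodes,
                             mechanism = c("inside", "outside")) {
  mechanism <- match.arg(mechanism)
  space <- default_cv_space()
  if (length(wcf_point) != 3L || length(hg_point) != 3L)
    stop("wcf_point and hg_point must be 3-vectors in [cos chi', sin chi', theta]")
  if (n_nodes < 3L) stop("n_nodes must be at least 3")
  chi_wcf <- atan2(wcf_point[2L], wcf_point[1L])
  theta_wcf <- wcf_point[3L]
  # rotation direction: increasing chi' visits the 5' half (chi' ~ +-pi)
  # first, so that -1 < s < 0 is the 5' rotation and 0 < s < 1 the 3' one
  phi <- chi_wcf + 2 * pi * seq(0, 1, length.out = n_nodes)
  nodes <- cbind(cos(phi), sin(phi), rep(theta_wcf, n_nodes))
  nodes[n_nodes, ] <- nodes[1L, ] <- wcf_point
  path_curve(nodes, space = space, cyclic = TRUE, mechanism = mechanism)
}

#' Project a CV point onto a path
#'
#' Piecewise-linear nearest-segment projection. The progress s is the
#' arc-length-normalized position of the closest point on the path, mapped
#' to [-1, +1] with the WCF anchor at s = +-1; z is the Euclidean distance
#' from the point to the path.
#'
#' @param p embedded CV point (or a matrix of points, one per row).
#' @param path a [path_curve()].
#' @return For a single point, `list(s =, z =)`; for a matrix, a two-column
#'   matrix of (s, z).
#' @export
project_point <- function(p, path) {
  if (is.null(path$nodes) || nrow(path$nodes) < 2L)
    stop("cannot project onto an empty path")
  single <- is.null(dim(p))
  pm <- if (single) matrix(p, nrow = 1L) else as.matrix(p)
  if (ncol(pm) != ncol(path$nodes))
    stop("point dimensionality does not match the path")
  pr <- cpp_project_batch(pm, path$nodes)
  s <- -1 + 2 * pr[, 1L]
  if (single) list(s = s[1L], z = pr[1L, 2L])
  else cbind(s = s, z = pr[, 2L])
}

#' Redistribute path nodes to equal arc length
#'
#' Nodes are moved along a cubic spline through the current nodes until
#' consecutive chord lengths are equal to within `tol` of their mean
#' (relative). Spline (rather than chord) interpolation avoids the
#' systematic inward erosion that repeated piecewise-linear resampling
#' inflicts on convex curves. Node count, endpoints and curve geometry are
#' preserved.
#'
#' @param path a [path_curve()].
#' @param tol relative chord-length tolerance.
#' @param max_iter resampling iterations cap.
#' @return The reparameterized [path_curve()].
#' @export
reparameterize <- function(path, tol = 1e-8, max_iter = 200L) {
  nodes <- path$nodes
  n <- nrow(nodes)
  seg <- segment_lengths(nodes)
  if (sum(seg) <= 0) stop("degenerate path: all nodes coincide")
  if (max(abs(seg - mean(seg))) / mean(seg) < tol) return(path)
  u0 <- c(0, cumsum(seg))
  keep <- c(TRUE, diff(u0) > 0)   # drop coincident nodes from the knots
  # shape-preserving Hermite interpolation: a natural cubic overshoots at
  # sharp features (e.g. the tip of an attractor-held dip) and the
  # overshoot feeds back through the update cycle into a runaway needle;
  # Fritsch-Carlson slopes cannot overshoot
  fs <- lapply(seq_len(ncol(nodes)), function(k)
    stats::splinefun(u0[keep], nodes[keep, k], method = "monoH.FC"))
  u <- u0
  pts <- nodes
  for (iter in seq_len(max_iter)) {
    pts <- vapply(fs, function(f) f(u), numeric(n))
    pts[1L, ] <- nodes[1L, ]
    pts[n, ] <- nodes[n, ]
    seg <- segment_lengths(pts)
    if (max(abs(seg - mean(seg))) / mean(seg) < tol) break
    cum <- c(0, cumsum(seg))
    u <- stats::approx(cum, u, xout = seq(0, cum[n], length.out = n))$y
  }
  colnames(pts) <- colnames(nodes)
  path$nodes <- pts
  path
}

#' Create the fading-memory state for path updates
#'
#' Carries the per-node accumulated sample weights. With a finite half-life
#' tau, the weight of a sample decays by a factor of 2 for every tau of
#' simulation time, so the path stays flexible; with an infinite half-life
#' weights only accumulate and the path stiffens as sampling proceeds.
#'
#' @param n_nodes number of path nodes.
#' @param half_life half-life tau in ps (`Inf` for no decay).
#' @param update_pace interval between path moves in ps.
#' @return An object of class `path_update_state`.
#' @export
path_update_state <- function(n_nodes, half_life = Inf, update_pace = 1) {
  if (!(is.infinite(half_life) || half_life > 0))
    stop("half_life must be positive or Inf")
  structure(list(weights = rep(0, n_nodes), half_life = half_life,
                 update_pace = update_pace, last_time = 0),
            class = "path_update_state")
}

#' Move path nodes toward the fading-memory mean of recent samples
#'
#' Each sample is assigned to its nearest node (Euclidean distance in the
#' embedded space; ties to the lower index) and contributes its displacement
#' from that node, weighted by `2^(-(time - t_sample)/half_life)`. Interior
#' nodes move by the weighted mean displacement, diluted by the accumulated
#' historical weight and capped at half the mean node spacing; endpoint
#' nodes never move. The path is reparameterized before return.
#'
#' @param path a [path_curve()].
#' @param samples matrix of embedded CV points, one per row.
#' @param state a [path_update_state()].
#' @param times numeric vector of sample timestamps in ps (recycled if
#'   length 1).
#' @param time current simulation time; defaults to `max(times)`.
#' @return `list(path =, state =)` with the updated curve and state.
#' @export
update_path <- function(path, samples, state, times = 0,
                        time = max(times, state$last_time)) {
  nodes <- path$nodes
  n <- nrow(nodes)
  if (length(state$weights) != n)
    stop("update state was built for a different node count")
  decay <- if (is.infinite(state$half_life)) 1
           else 2^(-(time - state$last_time) / state$half_life)
  state$weights <- state$weights * decay
  state$last_time <- time

  if (!is.null(samples) && length(samples) > 0L) {
    if (is.null(dim(samples)))
      samples <- matrix(samples, ncol = ncol(nodes), byrow = TRUE)
    samples <- as.matrix(samples)
    times <- rep_len(times, nrow(samples))
    w <- if (is.infinite(state$half_life)) rep(1, nrow(samples))
         else 2^(-(time - times) / state$half_life)
    # nearest-node assignment, ties to the lower index
    d2 <- outer(rowSums(samples^2), rowSums(nodes^2), "+") -
      2 * samples %*% t(nodes)
    assign <- max.col(-d2, ties.method = "first")
    cap <- 0.5 * mean(segment_lengths(nodes))
    new_w <- state$weights
    for (i in 2:(n - 1L)) {
      sel <- assign == i
      if (!any(sel)) next
      wi <- w[sel]
      disp <- colSums(matrix(wi, nrow = sum(sel), ncol = ncol(nodes)) *
                        (samples[sel, , drop = FALSE] -
                           matrix(nodes[i, ], sum(sel), ncol(nodes), byrow = TRUE)))
      new_w[i] <- state$weights[i] + sum(wi)
      step <- disp / new_w[i]
      len <- sqrt(sum(step^2))
      if (len > cap) step <- step * (cap / len)
      nodes[i, ] <- nodes[i, ] + step
    }
    state$weights <- new_w
    # endpoints pinned at the anchor
    nodes[1L, ] <- path$anchor
    nodes[n, ] <- path$anchor
    path$nodes <- nodes
    path <- reparameterize(path)
  }
  list(path = path, state = state)
}

#' Write a path to a plain-text node table
#'
#' One node per line, one column per CV axis, 17 significant digits; a
#' header names the axes and the cyclic flag. [read_path()] round-trips
#' bit-exactly on this decimal representation.
#'
#' @param path a [path_curve()].
#' @param file output path.
#' @export
write_path <- function(path, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste("# axes:", paste(path$space$axes, collapse = " ")),
               paste("# cyclic:", path$cyclic),
               paste("# mechanism:", if (is.null(path$mechanism)) "NA"
                     else path$mechanism)), con)
  writeLines(apply(path$nodes, 1L,
                   function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(file)
}

#' Read a path written by [write_path()]
#' @param file path file.
#' @return A [path_curve()].
#' @export
read_path <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  axes <- strsplit(sub("^# axes: *", "", hdr[1L]), " ")[[1L]]
  cyclic <- as.logical(sub("^# cyclic: *", "", hdr[2L]))
  mech <- sub("^# mechanism: *", "", hdr[3L])
  nodes <- do.call(rbind, lapply(strsplit(trimws(grep("^#", lines,
                                                      invert = TRUE,
                                                      value = TRUE)), " +"),
                                 as.numeric))
  space <- if (identical(axes, default_cv_space()$axes)) default_cv_space()
           else cv_space(axes)
  path_curve(nodes, space = space, cyclic = cyclic,
             mechanism = if (mech == "NA") NULL else mech)
}

#' Smooth path nodes by local averaging
#'
#' Repeated local (umbrella) averaging of interior nodes,
#' `x_i <- x_i + (lambda/2) (x_{i-1} + x_{i+1} - 2 x_i)`, followed by
#' reparameterization. Removes node-scale sampling zigzag from an adapted
#' path while preserving features wider than about `sqrt(passes * lambda)`
#' node spacings; endpoints never move.
#'
#' @param path a [path_curve()].
#' @param passes number of averaging sweeps.
#' @param lambda averaging strength in (0, 1].
#' @return The smoothed [path_curve()].
#' @export
path_smooth <- function(path, passes = 10L, lambda = 0.5) {
  nodes <- path$nodes
  n <- nrow(nodes)
  for (p in seq_len(passes)) {
    interior <- 2:(n - 1L)
    lap <- nodes[interior - 1L, , drop = FALSE] +
      nodes[interior + 1L, , drop = FALSE] -
      2 * nodes[interior, , drop = FALSE]
    nodes[interior, ] <- nodes[interior, ] + (lambda / 2) * lap
  }
  path$nodes <- nodes
  reparameterize(path)
}
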