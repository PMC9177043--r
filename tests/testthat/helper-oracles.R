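# Brute-force projection oracle: densely resample the path polyline and
# take the nearest of the dense points.
dense_projection_oracle <- function(pts, path, n_dense = 1e5) {
  nodes <- path$nodes
  seg <- sqrt(rowSums(diff(nodes)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  arc <- seq(0, L, length.out = n_dense)
  j <- pmin(findInterval(arc, cum, rightmost.closed = TRUE),
            nrow(nodes) - 1L)
  t <- (arc - cum[j]) / seg[j]
  dense <- nodes[j, , drop = FALSE] + t * (nodes[j + 1L, , drop = FALSE] -
                                             nodes[j, , drop = FALSE])
  out <- matrix(NA_real_, nrow(pts), 2L)
  for (i in seq_len(nrow(pts))) {
    d2 <- rowSums(sweep(dense, 2L, pts[i, ])^2)
    k <- which.min(d2)
    out[i, ] <- c(-1 + 2 * arc[k] / L, sqrt(d2[k]))
  }
  out
}

# Quaternion-based torsion oracle: rotate the frame so b2 lies along +z
# using an axis-angle quaternion, then read the angle between the
# projections of the outer bonds in the xy plane.
quat_rotate <- function(v, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  q <- c(cos(angle / 2), sin(angle / 2) * axis)
  t <- 2 * c(q[3] * v[3] - q[4] * v[2],
             q[4] * v[1] - q[2] * v[3],
             q[2] * v[2] - q[3] * v[1])
  v + q[1] * t + c(q[3] * t[3] - q[4] * t[2],
                   q[4] * t[1] - q[2] * t[3],
                   q[2] * t[2] - q[3] * t[1])
}

dihedral_quaternion_oracle <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  z <- c(0, 0, 1)
  axis <- c(b2[2] * z[3] - b2[3] * z[2],
            b2[3] * z[1] - b2[1] * z[3],
            b2[1] * z[2] - b2[2] * z[1])
  ang <- acos(max(-1, min(1, sum(b2 * z) / sqrt(sum(b2^2)))))
  rot <- function(v) {
    if (sqrt(sum(axis^2)) < 1e-12) {
      if (sum(b2 * z) < 0) c(v[1], -v[2], -v[3]) else v
    } else quat_rotate(v, axis, ang)
  }
  u <- rot(p1 - p2)
  w <- rot(p4 - p3)
  a <- atan2(w[2], w[1]) - atan2(u[2], u[1])
  a <- ((a + pi) %% (2 * pi)) - pi
  if (a <= -pi) a <- a + 2 * pi
  -a
}

# Random 3D rotation matrix from a seeded draw.
random_rotation <- function() {
  repeat {
    q <- rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-8) break
  }
  q <- q / n
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
           2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
           2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]),
           2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
         3L, 3L)
}

wrap_s_for_test <- function(x) ((x + 1) %% 2) - 1

hill_sum_snapshot_for_test <- function(hills, t) {
  multipmd:::hill_sum_snapshot(hills, t, fes_grid(200L))
}
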