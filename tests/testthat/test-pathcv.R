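wcf <- drop(embed_angles(1.5, -0.1))
hg <- drop(embed_angles(-1.5, -0.1))

test_that("cyclic path initialization traces the rolling circle", {
  for (n in c(11L, 39L)) {
    p <- init_cyclic_path(wcf, hg, n, if (n == 39L) "outside" else "inside")
    expect_equal(nrow(p$nodes), n)
    expect_identical(p$nodes[1L, ], p$nodes[n, ])
    expect_equal(unname(p$nodes[1L, ]), unname(wcf))
    # all nodes on the unit chi' circle at the WCF theta
    expect_equal(max(abs(p$nodes[, 1L]^2 + p$nodes[, 2L]^2 - 1)), 0)
    expect_equal(unname(p$nodes[, 3L]), rep(-0.1, n))
    seg <- multipmd:::segment_lengths(p$nodes)
    expect_lt(max(abs(seg - mean(seg))) / mean(seg), 1e-6)
  }
  expect_error(init_cyclic_path(wcf, hg, 2L), "at least 3")
  expect_error(init_cyclic_path(c(1, 0), hg, 11L), "3-vectors")
})

test_that("s respects the rotation-direction and periodicity conventions", {
  p <- init_cyclic_path(wcf, hg, 39L, "outside")
  # the shared endpoint projects to s = +-1, the HG point to s near 0
  expect_equal(abs(project_point(wcf, p)$s), 1)
  expect_lt(abs(project_point(hg, p)$s), 0.1)
  # 5' half (chi' ~ pi) at s < 0, 3' half (chi' ~ 0) at s > 0
  expect_lt(project_point(drop(embed_angles(pi, -0.1)), p)$s, 0)
  expect_gt(project_point(drop(embed_angles(0, -0.1)), p)$s, 0)
  # s wraps continuously across +-1
  eps <- 1e-3
  s_lo <- project_point(drop(embed_angles(1.5 - eps, -0.1)), p)$s
  s_hi <- project_point(drop(embed_angles(1.5 + eps, -0.1)), p)$s
  gap <- abs(multipmd:::wrap_s(s_hi - s_lo))
  expect_lt(gap, 2 / 38)
})

test_that("on-path points and perpendicular offsets project exactly", {
  p <- init_cyclic_path(wcf, hg, 11L, "inside")
  n <- nrow(p$nodes)
  for (k in c(2L, 5L, 9L)) {
    pr <- project_point(p$nodes[k, ], p)
    expect_equal(pr$z, 0)
    expect_equal(pr$s, -1 + 2 * (k - 1) / (n - 1), tolerance = 1e-12)
  }
  # displace a segment midpoint along the theta axis (normal to the path)
  mid <- (p$nodes[3L, ] + p$nodes[4L, ]) / 2
  for (d in c(0.05, 0.3)) {
    pr <- project_point(mid + c(0, 0, d), p)
    expect_equal(pr$z, d, tolerance = 1e-12)
  }
})

test_that("projection matches the dense-resampling oracle", {
  set.seed(42)
  p <- init_cyclic_path(wcf, hg, 39L, "outside")
  pts <- cbind(runif(200, -1.2, 1.2), runif(200, -1.2, 1.2),
               runif(200, -2, 1.5))
  got <- project_point(pts, p)
  want <- dense_projection_oracle(pts, p, n_dense = 4e5)
  ds <- abs(multipmd:::wrap_s(got[, 1L] - want[, 1L]))
  expect_lt(max(ds), 0.5 * 2 / 38)
  expect_lt(max(abs(got[, 2L] - want[, 2L])), 1e-6)
})

test_that("reparameterization equidistributes without distorting geometry", {
  # already-equidistant path is a fixed point
  p <- init_cyclic_path(wcf, hg, 21L, "inside")
  expect_equal(reparameterize(p)$nodes, p$nodes, tolerance = 1e-12)
  # nodes clustered in one half of a circle end up equidistant on it
  phi <- c(seq(0, pi, length.out = 14L), seq(pi + 0.3, 2 * pi - 0.3,
                                             length.out = 7L), 0)
  cl <- path_curve(cbind(cos(phi), sin(phi), 0.2), cyclic = TRUE)
  rp <- reparameterize(cl)
  seg <- multipmd:::segment_lengths(rp$nodes)
  expect_lt(max(abs(seg - mean(seg))) / mean(seg), 1e-6)
  expect_lt(max(abs(sqrt(rowSums(rp$nodes[, 1:2]^2)) - 1)), 0.05)
  # arc length preserved against a fine-resampling oracle
  set.seed(7)
  base <- init_cyclic_path(wcf, hg, 31L, "outside")
  base$nodes[2:30, ] <- base$nodes[2:30, ] + 0.03 * matrix(rnorm(29 * 3), 29)
  L_fine <- sum(multipmd:::segment_lengths(
    multipmd:::resample_polyline(base$nodes, 20000L)))
  L_rep <- path_length(reparameterize(base))
  expect_lt(abs(L_rep - L_fine) / L_fine, 0.01)
  # degenerate path errors
  degen <- p
  degen$nodes[] <- rep(degen$nodes[1L, ], each = nrow(degen$nodes))
  expect_error(reparameterize(degen), "degenerate")
})

test_that("path updates pull nodes toward samples and pin the endpoints", {
  p <- init_cyclic_path(wcf, hg, 11L, "inside")
  st <- path_update_state(11L, half_life = Inf)
  # samples exactly on the nodes leave the path unchanged
  upd <- update_path(p, p$nodes, st, times = 1)
  expect_equal(upd$path$nodes, p$nodes, tolerance = 1e-12)
  # constant perpendicular offset pulls interior nodes toward it,
  # with displacement non-decreasing in accumulated weight
  off <- p$nodes
  off[, 3L] <- off[, 3L] + 0.4
  u1 <- update_path(p, off, st, times = 1)
  d1 <- u1$path$nodes[6L, 3L] - p$nodes[6L, 3L]
  expect_gt(d1, 0.05)
  u2 <- update_path(u1$path, off, u1$state, times = 2)
  d2 <- u2$path$nodes[6L, 3L] - p$nodes[6L, 3L]
  expect_gte(d2, d1)
  # anchor nodes never move, bit-exactly
  expect_identical(u2$path$nodes[1L, ], p$anchor)
  expect_identical(u2$path$nodes[11L, ], p$anchor)
})

test_that("sample influence fades with the configured half-life", {
  tau <- 10
  p <- init_cyclic_path(wcf, hg, 11L, "inside")
  st <- path_update_state(11L, half_life = tau)
  node <- p$nodes[6L, ]
  up <- node + c(0, 0, 0.3)
  dn <- node - c(0, 0, 0.3)
  # young sample vs one exactly tau older: the old one counts half
  u <- update_path(p, rbind(up, dn), st, times = c(20, 20 - tau), time = 20)
  got <- unname(u$path$nodes[6L, 3L] - node[3L])
  want <- (1 * 0.3 + 0.5 * (-0.3)) / 1.5
  expect_equal(got, want, tolerance = 0.02)
  # doubling the age halves the influence again
  st2 <- path_update_state(11L, half_life = tau)
  u2 <- update_path(p, rbind(up, dn), st2, times = c(20, 20 - 2 * tau),
                    time = 20)
  got2 <- unname(u2$path$nodes[6L, 3L] - node[3L])
  want2 <- (1 * 0.3 + 0.25 * (-0.3)) / 1.25
  expect_equal(got2, want2, tolerance = 0.02)
})

test_that("path tables round-trip bit-exactly", {
  p <- init_cyclic_path(wcf, hg, 13L, "inside")
  p$nodes[5L, 3L] <- pi / 7
  p <- reparameterize(p)
  f <- withr::local_tempfile(fileext = ".dat")
  write_path(p, f)
  q <- read_path(f)
  expect_identical(q$nodes, p$nodes)
  expect_identical(q$cyclic, TRUE)
  expect_identical(q$mechanism, "inside")
})

test_that("path smoothing removes node-scale zigzag and keeps endpoints", {
  p <- init_cyclic_path(wcf, hg, 39L, "outside")
  zig <- p
  zig$nodes[, 3L] <- zig$nodes[, 3L] + rep_len(c(0.05, -0.05), 39L)
  zig$nodes[c(1L, 39L), 3L] <- -0.1
  sm <- path_smooth(zig, passes = 4L)
  expect_lt(stats::sd(diff(sm$nodes[, 3L])), stats::sd(diff(zig$nodes[, 3L])))
  expect_identical(sm$nodes[1L, ], zig$anchor)
})
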