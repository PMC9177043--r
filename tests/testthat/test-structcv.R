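test_that("torsions hit the planar reference angles and refuse degeneracy", {
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                              c(1, 0, 0)), 0)
  expect_equal(dihedral_angle(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                              c(1, 0, 0)), pi)
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                              c(1, 0, 1)), -pi / 4, tolerance = 1e-12)
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "degenerate|collinear")
})

test_that("torsions are rotation invariant against the quaternion oracle", {
  set.seed(12)
  for (i in 1:200) {
    pts <- matrix(rnorm(12), 4L, 3L)
    a0 <- try(dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
              silent = TRUE)
    if (inherits(a0, "try-error")) next
    R <- random_rotation()
    tr <- rnorm(3)
    rp <- sweep(pts %*% t(R), 2L, tr, "+")
    a1 <- dihedral_angle(rp[1, ], rp[2, ], rp[3, ], rp[4, ])
    ao <- dihedral_quaternion_oracle(rp[1, ], rp[2, ], rp[3, ], rp[4, ])
    expect_lt(abs(((a1 - a0 + pi) %% (2 * pi)) - pi), 1e-10)
    expect_lt(abs(((a1 - ao + pi) %% (2 * pi)) - pi), 1e-10)
  }
})

test_that("center-of-mass pseudo-dihedrals reduce to plain torsions", {
  f <- make_fixture("WCF")
  single <- atom_group_spec(atom_sel("A", 2L, "O4'"), atom_sel("A", 2L, "C1'"),
                            atom_sel("A", 2L, "N9"), atom_sel("A", 2L, "C4"))
  expect_equal(com_pseudo_dihedral(f, single),
               glycosidic_chi(f, "A", 2L), tolerance = 1e-12)
  # a symmetric two-atom group centered on a single atom gives the same
  # angle: duplicate the N9 reference with mirrored ghost positions
  g <- f
  n9 <- as.numeric(g[g$chain == "A" & g$resno == 2L & g$elety == "N9",
                     c("x", "y", "z")])
  c1 <- as.numeric(g[g$chain == "A" & g$resno == 2L & g$elety == "C1'",
                     c("x", "y", "z")])
  ghost <- rbind(n9 + (n9 - c1), n9 - (n9 - c1))
  g <- rbind(g, data.frame(elety = c("XG1", "XG2"), resname = "DA",
                           resno = 2L, chain = "A", x = ghost[, 1L],
                           y = ghost[, 2L], z = ghost[, 3L]))
  class(g) <- class(f)
  pair_spec <- atom_group_spec(atom_sel("A", 2L, "O4'"),
                               atom_sel("A", 2L, "C1'"),
                               atom_sel("A", 2L, c("XG1", "XG2")),
                               atom_sel("A", 2L, "C4"))
  # override the ghost masses so their COM sits exactly on N9
  ov <- c(XG1 = 1, XG2 = 1)
  expect_equal(com_pseudo_dihedral(g, pair_spec, mass_overrides = ov),
               com_pseudo_dihedral(f, single), tolerance = 1e-10)
  # unresolved selectors are named in the error
  bad <- atom_group_spec(atom_sel("A", 2L, "O9'"), atom_sel("A", 2L, "C1'"),
                         atom_sel("A", 2L, "N9"), atom_sel("A", 2L, "C4"))
  expect_error(com_pseudo_dihedral(f, bad), "O9'")
})

test_that("fixtures land at the stable-state structural signatures", {
  w <- compute_cv_record(make_fixture("WCF"))
  h <- compute_cv_record(make_fixture("HG"))
  expect_lt(abs(w$chiprime - 1.5), 0.3)
  expect_lt(abs(h$chiprime + 1.5), 0.3)
  expect_lt(abs(w$d_cc - 10.6), 0.5)
  expect_lt(abs(h$d_cc - 9.1), 0.5)
  # hydrogen bonds around 3 Angstrom
  expect_lt(abs(w$d_wcf - 3), 0.4)
  expect_lt(abs(h$d_hg - 3), 0.4)
  expect_identical(classify_state(w), "WCF")
  expect_identical(classify_state(h), "HG")
  expect_identical(classify_state(compute_cv_record(make_fixture("mid"))),
                   "intermediate")
  # flipped: opening angle beyond pi/4 toward the major groove
  fl <- compute_cv_record(make_fixture("flipped"))
  expect_lt(fl$theta, -pi / 4)
})

test_that("classification round-trips under coordinate noise", {
  for (sd in 1:25) {
    expect_identical(classify_state(compute_cv_record(
      make_fixture("WCF", noise = 0.2, seed = sd))), "WCF")
    expect_identical(classify_state(compute_cv_record(
      make_fixture("HG", noise = 0.2, seed = sd + 500L))), "HG")
  }
})

test_that("all CVs are invariant under rigid motion", {
  f <- make_fixture("HG")
  cv <- compute_cv_record(f)
  set.seed(33)
  R <- random_rotation()
  tr <- c(5, -3, 11)
  g <- f
  xyz <- as.matrix(f[, c("x", "y", "z")]) %*% t(R)
  g[, c("x", "y", "z")] <- sweep(xyz, 2L, tr, "+")
  cv2 <- compute_cv_record(g)
  for (nm in c("chi", "chiprime", "theta"))
    expect_equal(cv2[[nm]], cv[[nm]], tolerance = 1e-10)
  for (nm in c("d_wcf", "d_hg", "d_hb", "d_cc", "d_nb"))
    expect_equal(cv2[[nm]], cv[[nm]], tolerance = 1e-10)
  # plain translation leaves distances bit-near-exact
  t2 <- f
  t2[, c("x", "y", "z")] <- f[, c("x", "y", "z")] + 7.5
  pd <- pair_distances(t2, list("A", 2L), list("B", 5L), list("A", 1L),
                       list("A", 3L))
  pd0 <- pair_distances(f, list("A", 2L), list("B", 5L), list("A", 1L),
                        list("A", 3L))
  expect_equal(pd, pd0, tolerance = 1e-12)
})

test_that("water counting respects the cutoff and the minimum image", {
  f <- make_fixture("WCF")
  expect_identical(n_water(f, "A", 2L), 0L)
  # place oxygens at controlled distances from N6
  n6 <- as.numeric(f[f$chain == "A" & f$resno == 2L & f$elety == "N6",
                     c("x", "y", "z")])
  d <- c(rep(5.9, 5L), rep(6.1, 3L))
  set.seed(8)
  dirs <- matrix(rnorm(24), 8L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  wat <- data.frame(elety = "O", resname = "HOH", resno = 100 + 1:8,
                    chain = "W", x = n6[1L] + d * dirs[, 1L],
                    y = n6[2L] + d * dirs[, 2L], z = n6[3L] + d * dirs[, 3L])
  g <- rbind(f, wat)
  class(g) <- class(f)
  expect_equal(n_water(g, "A", 2L), 5L)
  # periodic counting equals brute-force image enumeration
  box <- c(14, 15, 16)
  set.seed(14)
  watp <- data.frame(elety = "OW", resname = "SOL", resno = 200 + 1:40,
                     chain = "W", x = runif(40, 0, box[1L]),
                     y = runif(40, 0, box[2L]), z = runif(40, 0, box[3L]))
  gp <- rbind(f, watp)
  class(gp) <- class(f)
  attr(gp, "box") <- box
  got <- n_water(gp, "A", 2L, cutoff = 6)
  brute <- 0L
  for (i in seq_len(nrow(watp))) {
    best <- Inf
    for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
      p <- c(watp$x[i] + ix * box[1L], watp$y[i] + iy * box[2L],
             watp$z[i] + iz * box[3L])
      best <- min(best, sqrt(sum((p - n6)^2)))
    }
    if (best <= 6) brute <- brute + 1L
  }
  expect_identical(got, brute)
  expect_error(n_water(f, "A", 2L, elety = "N99"), "matched 0")
})

test_that("PDB files round-trip the frame through bio3d", {
  f <- make_fixture("HG")
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_frame(f, tf)
  g <- read_pdb_frame(tf)
  expect_identical(g$elety, f$elety)
  expect_identical(g$resno, f$resno)
  expect_equal(as.matrix(g[, c("x", "y", "z")]),
               as.matrix(f[, c("x", "y", "z")]), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_identical(classify_state(compute_cv_record(g)), "HG")
})
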