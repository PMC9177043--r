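test_that("rotor-flip landscape has the constructed critical points", {
  par <- rotor_flip_params()
  # exact minimum at the WCF point
  expect_lt(max(abs(rotor_flip_gradient(par[["chi_wcf"]], 0, par))), 1e-8)
  # HG minimum sits within a few hundredths of the nominal point
  gr <- expand.grid(chi = seq(-1.7, -1.3, 0.005),
                    theta = seq(-0.2, 0.2, 0.005))
  vg <- rotor_flip_energy(gr$chi, gr$theta, par)
  hg_min <- gr[which.min(vg), ]
  expect_lt(abs(hg_min$chi - par[["chi_hg"]]), 0.05)
  expect_lt(abs(hg_min$theta), 0.05)
  # HG basin raised by df_hg (up to small curvature differences)
  cb <- channel_barriers(theta_outside = c(-2.2, -0.9))
  expect_equal(unname(cb["v_hg"] - cb["v_wcf"]), par[["df_hg"]],
               tolerance = 0.05)
})

test_that("mirror symmetry holds for symmetric scales and zero offset", {
  ps <- rotor_flip_params(b_in_3p = 4, b_in_5p = 4, b_out_3p = 1.5,
                          b_out_5p = 1.5, df_hg = 0)
  set.seed(2)
  chi <- runif(100, -pi, pi)
  theta <- runif(100, -2.2, 1.5)
  expect_equal(rotor_flip_energy(chi, theta, ps),
               rotor_flip_energy(-chi, theta, ps), tolerance = 1e-12)
})

test_that("grid search verifies the four-channel barrier ordering", {
  cb <- channel_barriers(theta_outside = c(-2.2, -0.9))
  expect_lt(cb[["outside_3p"]], cb[["inside_3p"]])
  expect_lt(cb[["inside_3p"]], cb[["outside_5p"]])
  expect_lt(cb[["outside_5p"]], cb[["inside_5p"]])
})

test_that("rotor-flip gradient matches finite differences", {
  set.seed(4)
  chi <- runif(50, -pi, pi)
  theta <- runif(50, -2, 1.5)
  g <- rotor_flip_gradient(chi, theta)
  eps <- 1e-6
  fd_chi <- (rotor_flip_energy(chi + eps, theta) -
               rotor_flip_energy(chi - eps, theta)) / (2 * eps)
  fd_theta <- (rotor_flip_energy(chi, theta + eps) -
                 rotor_flip_energy(chi, theta - eps)) / (2 * eps)
  expect_equal(unname(g[, 1L]), fd_chi, tolerance = 1e-6)
  expect_equal(unname(g[, 2L]), fd_theta, tolerance = 1e-6)
})

test_that("langevin stepping is deterministic and quiescent at kT = 0", {
  cfg0 <- langevin_config(kT = 0)
  flat <- potential_flat()
  expect_equal(langevin_step(c(0.3, -0.2), flat, cfg0), c(0.3, -0.2))
  # equal seeds give bit-identical trajectories
  set.seed(9)
  a <- run_langevin(potential_rotor_flip(), c(1.5, 0), 500L)
  set.seed(9)
  b <- run_langevin(potential_rotor_flip(), c(1.5, 0), 500L)
  expect_identical(a, b)
  # non-finite forces are refused with a meaningful error
  bad <- potential_harmonic(1, dim = 2L)
  bad$gradient <- function(x) matrix(NaN, nrow(x), 2L)
  expect_error(langevin_step(c(0, 0), bad, langevin_config()),
               "non-finite potential gradient")
})

test_that("harmonic sampling satisfies equipartition", {
  set.seed(21)
  k <- 2
  x <- run_langevin(potential_harmonic(k, dim = 1L), 0, 2e5L,
                    langevin_config(kT = 0.596))
  v <- stats::var(drop(x))
  expect_equal(v, 0.596 / k, tolerance = 0.08)
})

test_that("quadrature reduces exactly on separable landscapes", {
  # flat potential, straight path: constant profile (commensurate grid)
  sp <- cv_space(c("x", "y"))
  straight <- path_curve(cbind(seq(0, 1, length.out = 11L), 0), space = sp,
                         cyclic = FALSE)
  gx <- seq(0.0005, 0.9995, length.out = 1000L)
  gy <- seq(-0.6, 0.6, length.out = 241L)
  qf <- reference_fes_quadrature(potential_flat(dim = 2L,
                                                periodic = c(FALSE, FALSE)),
                                 straight, tube_k = 50, kT = 0.596,
                                 n_bins = 100L, grid1 = gx, grid2 = gy,
                                 embedding = "cartesian", check = FALSE)
  expect_lt(diff(range(qf$mean)), 1e-9)
  # a 1D double well along the path factorizes into the 1D Boltzmann sum
  dw <- potential_flat(dim = 2L, periodic = c(FALSE, FALSE))
  dw$energy <- function(x) {
    x <- if (is.null(dim(x))) matrix(x, ncol = 2L) else x
    4 * (x[, 1L] - 0.5)^2 * (1 - (x[, 1L] - 0.5)^2 * 4) + 2 * x[, 1L]
  }
  q2 <- reference_fes_quadrature(dw, straight, tube_k = 50, kT = 0.596,
                                 n_bins = 100L, grid1 = gx, grid2 = gy,
                                 embedding = "cartesian", check = FALSE)
  kT <- 0.596
  U <- dw$energy(cbind(gx, 0))
  bin <- pmin(pmax(floor(gx * 100) + 1L, 1L), 100L)
  Fo <- -kT * log(as.numeric(tapply(exp(-U / kT), bin, sum)))
  Fo <- Fo - mean(Fo[c(1L, 100L)])
  expect_equal(q2$mean, Fo, tolerance = 1e-6)
  # self-convergence check on the production landscape
  p <- init_cyclic_path(drop(embed_angles(1.5, 0)),
                        drop(embed_angles(-1.5, 0)), 39L, "outside")
  expect_silent(reference_fes_quadrature(potential_rotor_flip(), p,
                                         check = TRUE))
})

test_that("basin occupancies match the Boltzmann weights", {
  # elevated temperature so unbiased dynamics crosses the barriers often
  kT <- 2.4
  set.seed(31)
  x <- run_langevin(potential_rotor_flip(), c(1.5, 0), 4e5L,
                    langevin_config(kT = kT), record_every = 10L)
  in_wcf <- abs(multipmd:::wrap_angle(x[, 1L] - 1.5)) < 1
  in_hg <- abs(multipmd:::wrap_angle(x[, 1L] + 1.5)) < 1
  ratio <- sum(in_hg) / sum(in_wcf)
  # quadrature oracle for the same basin windows
  g <- expand.grid(chi = seq(-pi, pi, length.out = 600L),
                   theta = seq(-3, 2.2, length.out = 500L))
  w <- exp(-rotor_flip_energy(g$chi, g$theta) / kT)
  z_wcf <- sum(w[abs(multipmd:::wrap_angle(g$chi - 1.5)) < 1])
  z_hg <- sum(w[abs(multipmd:::wrap_angle(g$chi + 1.5)) < 1])
  want <- z_hg / z_wcf
  n_cross <- sum(abs(diff(in_wcf)) > 0)
  se <- ratio * sqrt(2 / n_cross)   # effective samples ~ basin exchanges
  expect_lt(abs(ratio - want), 3 * se + 0.02)
})
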