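# Short runs keep these contracts cheap; the production-scale behavior is
# exercised by the acceptance suite.
short_cfg <- function(...) {
  multipmd_config(total_ps = 30, equil_ps = 10, steer_window = 5,
                  update_start = 5, update_stop = 10,
                  paths = list(list(name = "outside", n_nodes = 21L,
                                    half_life = 20, theta_attractor = -pi / 2,
                                    smooth = 2L)), ...)
}

test_that("identical config and seed reproduce every output file", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_multipmd(short_cfg(), seed = 7L, out_dir = d1)
  run_multipmd(short_cfg(), seed = 7L, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))),
                     info = f)
  }
  # and a different seed changes the trajectories
  d3 <- withr::local_tempdir()
  run_multipmd(short_cfg(), seed = 8L, out_dir = d3)
  expect_false(identical(
    readLines(file.path(d1, "WALKERS-outside.tsv")),
    readLines(file.path(d3, "WALKERS-outside.tsv"))))
})

test_that("attractors adapt the path but never deposit hills", {
  # no standard walkers: the attractors still bend the path, no hills
  cfg <- short_cfg(n_standard = 0L)
  cfg$update_stop <- 30
  run <- run_multipmd(cfg, seed = 3L)
  p <- run$paths$outside
  expect_equal(nrow(p$hills), 0L)
  expect_gt(max(abs(p$path$nodes[, 3L])), 0.3)
  # no walkers at all: the path stays the initial guess
  cfg0 <- short_cfg(n_standard = 0L, attractors = FALSE)
  run0 <- run_multipmd(cfg0, seed = 3L)
  init <- init_cyclic_path(drop(embed_angles(1.5, 0)),
                           drop(embed_angles(-1.5, 0)), 21L, "outside")
  expect_equal(run0$paths$outside$path$nodes, init$nodes, tolerance = 1e-12)
  # standard walkers deposit one hill per walker per pace, in index order
  cfg2 <- short_cfg(n_standard = 3L)
  run2 <- run_multipmd(cfg2, seed = 3L)
  h <- run2$paths$outside$hills
  expect_equal(nrow(h), 3L * 31L)   # production deposits start at reset
  expect_equal(h$time[1:6], rep(0:1, each = 3L))
})

test_that("walkers cover the whole cycle on a flat landscape", {
  cfg <- multipmd_config(total_ps = 60, equil_ps = 0, update_start = Inf,
                         update_stop = Inf,
                         potential = list(kind = "flat"), attractors = FALSE,
                         paths = list(list(name = "flat", n_nodes = 21L,
                                           half_life = Inf, smooth = 0L)))
  run <- run_multipmd(cfg, seed = 5L)
  s <- as.vector(run$paths$flat$traj$s)
  bins <- table(cut(s, seq(-1, 1, length.out = 21L)))
  expect_true(all(bins > 0))
})

test_that("walkers escaping the CV bounds raise a diagnostic", {
  cfg <- short_cfg(theta_bound = 0.05)
  expect_error(run_multipmd(cfg, seed = 1L), "left CV-space bounds")
})

test_that("configurations round-trip through YAML", {
  cfg <- multipmd_config(total_ps = 123, tube_k = 45)
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), f)
  cfg2 <- read_multipmd_config(f)
  expect_equal(cfg2$total_ps, 123)
  expect_equal(cfg2$tube_k, 45)
  expect_equal(cfg2$paths[[2L]]$n_nodes, 39L)
  expect_equal(cfg2$hill_height, 0.05)
})

test_that("hill and walker logs round-trip and stay in sync", {
  d <- withr::local_tempdir()
  run <- run_multipmd(short_cfg(), seed = 2L, out_dir = d)
  h <- read_hills(file.path(d, "HILLS-outside.dat"))
  expect_identical(h$center, run$paths$outside$hills$center)
  p <- read_path(file.path(d, "PATH-outside.dat"))
  expect_identical(p$nodes, run$paths$outside$path$nodes)
})

test_that("tube confinement keeps walkers near the path", {
  run <- run_multipmd(short_cfg(), seed = 4L)
  z <- run$paths$outside$traj$z[, 1:9]
  late <- run$paths$outside$traj$time > 15
  expect_lt(mean(z[late, ]), 3 * sqrt(0.596 / 50))
})

test_that("long deposition flattens the bias on a flat landscape", {
  cfg <- multipmd_config(total_ps = 300, equil_ps = 0, update_start = Inf,
                         update_stop = Inf,
                         potential = list(kind = "flat"), attractors = FALSE,
                         paths = list(list(name = "flat", n_nodes = 21L,
                                           half_life = Inf, smooth = 0L)))
  run <- run_multipmd(cfg, seed = 3L)
  pa <- averaged_profile(run$paths$flat$hills, 100, 300, 10)
  # flat to within the plain-metadynamics ripple floor (a few hill heights)
  expect_lt(diff(range(pa$mean)), 0.3)
})
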