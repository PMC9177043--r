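#' Default multiple-path metadynamics configuration
#'
#' Encodes the production protocol at engine scale: two cyclic paths
#' (inside, 11 nodes, infinite half-life; outside, 39 nodes, 20 ps
#' half-life), nine standard walkers plus three attractors per path, hills
#' of width 0.1 and height 0.05 kcal/mol deposited every 1 ps, path updates
#' every 1 ps, a tube potential of 50 kcal/mol per squared path unit,
#' intermediate attractors steered to s = +-0.5 over the first 20 ps with
#' k = 5000 and theta-restrained (k = 5000) at 0 (inside) or -pi/2
#' (outside), and an HG attractor restrained at the HG point with k = 50.
#'
#' @param total_ps production run length in engine ps (1 ps = 100 Langevin
#'   steps at dt = 0.01). The default 1200 ps keeps the production schedule
#'   ratios: burn-in 2/7 of the run, snapshots every 1/70 of the run.
#' @param equil_ps path-equilibration stage before production, ps. The
#'   cyclic paths must rearrange substantially from the no-flip initial
#'   guess; bias deposited while the path (and hence the s map) is still
#'   moving leaves a frozen misplaced imprint in the hill sum, so the hill
#'   list is reset when production starts and hill times are counted on
#'   the production clock. Path updates continue throughout.
#' @param potential potential specification: `list(kind =, params =)`;
#'   kinds `rotor_flip`, `flat`, `harmonic`.
#' @param paths list of per-path settings: `name`, `n_nodes`, `half_life`,
#'   `theta_attractor`, and optionally `init_nodes` (an explicit initial
#'   node matrix in place of the default no-flip circle).
#' @param n_standard number of standard (hill-depositing) walkers.
#' @param attractors logical: include the three attractor walkers.
#' @param hill_pace,hill_width,hill_height metadynamics hill settings.
#' @param update_pace path update interval, ps.
#' @param update_start time at which path updates begin, ps; defaults to
#'   the steering window so the attractors reach their intermediate
#'   stations before the path starts to adapt toward them.
#' @param update_stop time after which the path stops adapting, ps. The
#'   default freezes the path when production starts: the nearest-segment
#'   progress map must be stationary and kink-free for the hill sum to be
#'   an unbiased free-energy estimate, so the production profile is
#'   measured along the frozen, smoothed, adapted path.
#' @param smooth_passes default local-averaging sweeps applied to a path
#'   when it is frozen (see [path_smooth()]); each path entry can override
#'   via its `smooth` field. A light touch removes residual zigzag from
#'   the densely discretized outside path; the 11-node inside path is too
#'   coarse to smooth without shrinking it and keeps `smooth = 0`.
#' @param freeze_avg length (ps) of the adaptation tail over which node
#'   positions are time-averaged to form the frozen production path.
#' @param update_smooth lambda of a single [path_smooth()] pass applied
#'   after every path update (0 = off); per-path override via
#'   `update_smooth` in the path entry. Provides the string tension that
#'   lets the attractor-nucleated channel opening propagate node to node.
#'   A length-2 value `c(strong, weak)` uses the strong tension while the
#'   opening nucleates and the weak one afterwards, so the converged path
#'   can settle into the channel floor.
#' @param update_smooth_switch time (ps) of the strong-to-weak tension
#'   switch for length-2 `update_smooth`.
#' @param tube_k tube force constant.
#' @param steer_window steering window for intermediate attractors, ps.
#' @param k_attr_theta,k_attr_s,k_hg attractor force constants.
#' @param kT,gamma,dt Langevin settings.
#' @param wcf,hg stable-state CV points, `list(chi =, theta =)`.
#' @param attr_substeps Langevin substeps for the stiffly restrained
#'   intermediate attractors (k = 5000 needs k dt/gamma <= 1).
#' @param theta_bound diagnostic bound on |theta|, rad.
#' @param imprint hold the intermediate attractors' positions on their
#'   nearest path nodes at every update (see Details in the vignette).
#' @param traj_stride store every k-th step in trajectory output files.
#' @return A nested configuration list of class `multipmd_config`.
#' @export
multipmd_config <- function(total_ps = 1200, equil_ps = 300,
                            potential = list(kind = "rotor_flip",
                                             params = as.list(rotor_flip_params())),
                            paths = list(
                              list(name = "inside", n_nodes = 11,
                                   half_life = Inf, theta_attractor = 0,
                                   smooth = 0L),
                              list(name = "outside", n_nodes = 39,
                                   half_life = 20, theta_attractor = -pi / 2,
                                   smooth = 2L)),
                            n_standard = 9, attractors = TRUE,
                            hill_pace = 1, hill_width = 0.1,
                            hill_height = 0.05, update_pace = 1,
                            update_start = steer_window,
                            update_stop = equil_ps, smooth_passes = 0L,
                            freeze_avg = 100L,
                            update_smooth = c(0.1, 0.03),
                            update_smooth_switch = 150,
                            tube_k = 50, steer_window = 20,
                            k_attr_theta = 5000, k_attr_s = 5000, k_hg = 50,
                            kT = 0.596, gamma = 1, dt = 0.01,
                            wcf = list(chi = 1.5, theta = 0),
                            hg = list(chi = -1.5, theta = 0),
                            attr_substeps = 50L, theta_bound = 4,
                            imprint = TRUE, traj_stride = 10L) {
  cfg <- list(total_ps = total_ps, equil_ps = equil_ps,
              potential = potential, paths = paths,
              n_standard = n_standard, attractors = attractors,
              hill_pace = hill_pace, hill_width = hill_width,
              hill_height = hill_height, update_pace = update_pace,
              update_start = update_start, update_stop = update_stop,
              smooth_passes = smooth_passes, freeze_avg = freeze_avg,
              update_smooth = update_smooth,
              update_smooth_switch = update_smooth_switch,
              tube_k = tube_k,
              steer_window = steer_window,
              k_attr_theta = k_attr_theta, k_attr_s = k_attr_s, k_hg = k_hg,
              kT = kT, gamma = gamma, dt = dt, wcf = wcf, hg = hg,
              attr_substeps = attr_substeps, theta_bound = theta_bound,
              imprint = imprint, traj_stride = traj_stride)
  class(cfg) <- "multipmd_config"
  cfg
}

# Build an analytic_potential from a config specification.
potential_from_config <- function(spec) {
  switch(spec$kind,
         rotor_flip = potential_rotor_flip(do.call(rotor_flip_params,
                                                   spec$params %||% list())),
         flat = potential_flat(),
         harmonic = potential_harmonic(unlist(spec$params %||% 1), dim = 2L),
         stop("unknown potential kind: ", spec$kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from a YAML file
#' @param file YAML file with keys matching [multipmd_config()] arguments.
#' @return A `multipmd_config`.
#' @export
read_multipmd_config <- function(file) {
  vals <- yaml::read_yaml(file)
  vals <- vals[names(vals) %in% names(formals(multipmd_config))]
  do.call(multipmd_config, vals)
}

#' Run multiple-walker multiple-path metadynamics
#'
#' Orchestrates, for each path: per-step projection of every walker,
#' tube + hill + restraint forces, overdamped Langevin propagation, shared
#' hill deposition at the pace (standard walkers only, in walker-index
#' order), and fading-memory path updates from the sampled walker positions
#' (attractor samples hold the paths through their intermediate states;
#' only standard walkers deposit hills). Every artifact is a pure function
#' of (config, seed).
#'
#' @param config a [multipmd_config()].
#' @param seed integer RNG seed.
#' @param out_dir if non-NULL, write HILLS-<path>.dat, PATH-<path>.dat and
#'   WALKERS-<path>.tsv tables there.
#' @return An object of class `multipmd_run`: per path the adapted
#'   [path_curve()], the shared [hill_list()], walker roles and the full
#'   (time, chi', theta, s, z, bias energy) trajectories.
#' @export
run_multipmd <- function(config = multipmd_config(), seed = 1L,
                         out_dir = NULL) {
  set.seed(seed)
  pot <- potential_from_config(config$potential)
  wcf_pt <- drop(embed_angles(config$wcf$chi, config$wcf$theta))
  hg_pt <- drop(embed_angles(config$hg$chi, config$hg$theta))
  steps_per_ps <- round(1 / config$dt)
  equil <- round(config$equil_ps %||% 0)
  n_seg <- equil + round(config$total_ps)

  runs <- list()
  for (pcfg in config$paths) {
    mech <- if (identical(pcfg$name, "outside")) "outside" else "inside"
    path <- if (!is.null(pcfg$init_nodes))
      path_curve(as.matrix(pcfg$init_nodes), cyclic = TRUE, mechanism = mech)
    else init_cyclic_path(wcf_pt, hg_pt, pcfg$n_nodes, mechanism = mech)
    state <- path_update_state(nrow(path$nodes),
                               half_life = pcfg$half_life %||% Inf,
                               update_pace = config$update_pace)
    # walker table: standard walkers first, then the three attractors
    role <- rep(0L, config$n_standard)
    if (config$attractors) role <- c(role, 1L, 1L, 2L)
    nw <- length(role)
    pos <- matrix(rep(c(config$wcf$chi, config$wcf$theta), each = nw),
                  nw, 2L)
    restr <- matrix(0, nw, 9L)
    if (config$attractors) {
      ia <- config$n_standard + 1:2
      restr[ia, 1L] <- config$k_attr_theta
      restr[ia, 2L] <- pcfg$theta_attractor %||% 0
      restr[ia, 3L] <- config$k_attr_s
      restr[ia, 4L] <- c(0.5, -0.5)
      restr[ia, 5L] <- -1        # walkers start at the WCF anchor, s = -1
      restr[ia, 6L] <- config$steer_window
      ih <- nw
      restr[ih, 7L] <- config$k_hg
      restr[ih, 8L] <- config$hg$chi
      restr[ih, 9L] <- config$hg$theta
      pos[ih, ] <- c(config$hg$chi, config$hg$theta)
    }
    substeps <- ifelse(role == 1L, as.integer(config$attr_substeps), 1L)
    hills <- hill_list()
    snapshots <- list()
    s_cont <- rep(-1, nw)   # continuous progress state of steered walkers
    path_sum <- NULL
    path_sum_n <- 0L

    n_tot <- n_seg * steps_per_ps
    traj <- list(time = numeric(n_tot),
                 chi = matrix(NA_real_, n_tot, nw),
                 theta = matrix(NA_real_, n_tot, nw),
                 s = matrix(NA_real_, n_tot, nw),
                 z = matrix(NA_real_, n_tot, nw),
                 ebias = matrix(NA_real_, n_tot, nw))

    for (seg in seq_len(n_seg)) {
      if (nw > 0L) {
        res <- cpp_propagate_segment(pos, role, restr, path$nodes,
                                     hills$center %||% numeric(0),
                                     hills$width %||% numeric(0),
                                     hills$height %||% numeric(0),
                                     config$tube_k, pot$cpp_id, pot$cpp_par,
                                     config$dt, config$gamma, config$kT,
                                     seg - 1, steps_per_ps, substeps, 1e-5,
                                     s_cont)
        pos <- res$pos
        s_cont <- res$s_cont
        rows <- (seg - 1L) * steps_per_ps + seq_len(steps_per_ps)
        traj$time[rows] <- res$time
        traj$chi[rows, ] <- res$chi
        traj$theta[rows, ] <- res$theta
        traj$s[rows, ] <- res$s
        traj$z[rows, ] <- res$z
        traj$ebias[rows, ] <- res$ebias
        if (max(abs(res$theta)) > config$theta_bound)
          stop("walker left CV-space bounds (|theta| > ", config$theta_bound,
               ") on path '", pcfg$name, "' at segment ", seg)
        if (seg == equil && equil > 0L) hills <- hill_list()
        if (seg %% config$hill_pace == 0) {
          for (w in which(role == 0L))
            hills <- deposit_hill(hills, res$s[steps_per_ps, w],
                                  time = seg - equil,
                                  width = config$hill_width,
                                  height = config$hill_height)
        }
        if (seg > config$update_start && seg <= config$update_stop &&
            seg %% config$update_pace == 0) {
          samples <- embed_angles(as.vector(res$chi), as.vector(res$theta))
          upd <- update_path(path, samples, state,
                             times = rep(res$time, nw), time = seg)
          path <- upd$path
          state <- upd$state
          # light per-update smoothing acts as string tension: it couples
          # neighboring nodes so an attractor-nucleated channel opening
          # propagates along the path instead of stalling at the
          # inter-channel ridge
          lam <- pcfg$update_smooth %||% config$update_smooth %||% 0
          if (length(lam) > 1L)
            lam <- if (seg <= (config$update_smooth_switch %||% 150))
              lam[1L] else lam[2L]
          if (lam > 0) path <- path_smooth(path, passes = 1L, lambda = lam)
          # walkers live on the unit cylinder of the (cos, sin) embedding;
          # keeping the nodes on it removes the systematic inward shrink
          # of cell-averaged and smoothed positions
          rad <- sqrt(path$nodes[, 1L]^2 + path$nodes[, 2L]^2)
          path$nodes[, 1:2] <- path$nodes[, 1:2] / rad
          # the steered attractors mark the intermediate states the path
          # must pass through: hold their positions on the nearest nodes
          # so the channel opening nucleates (and stays open)
          # deterministically
          if (config$attractors && isTRUE(config$imprint %||% TRUE)) {
            ia <- which(role == 1L)
            att <- embed_angles(pos[ia, 1L], pos[ia, 2L])
            for (j in seq_along(ia)) {
              d2 <- rowSums(sweep(path$nodes, 2L, att[j, ])^2)
              d2[c(1L, nrow(path$nodes))] <- Inf
              path$nodes[which.min(d2), ] <- att[j, ]
            }
          }
          path <- reparameterize(path)
        }
        if (is.finite(config$update_stop)) {
          # accumulate the path over the tail of the adaptation stage so
          # the production path is a time average: node-scale sampling
          # zigzag cancels without the corner-cutting of heavy smoothing
          avg_win <- config$freeze_avg %||% 100L
          if (seg > config$update_stop - avg_win &&
              seg <= config$update_stop) {
            if (is.null(path_sum)) {
              path_sum <- path$nodes
              path_sum_n <- 1L
            } else {
              path_sum <- path_sum + path$nodes
              path_sum_n <- path_sum_n + 1L
            }
          }
          if (seg == config$update_stop) {
            if (!is.null(path_sum) && path_sum_n > 1L) {
              avg <- path_sum / path_sum_n
              avg[1L, ] <- path$anchor
              avg[nrow(avg), ] <- path$anchor
              path$nodes <- avg
              path <- reparameterize(path)
            }
            passes <- pcfg$smooth %||% config$smooth_passes %||% 0L
            if (passes > 0L) path <- path_smooth(path, passes)
          }
        }
        if (seg %% 20 == 0)
          snapshots[[length(snapshots) + 1L]] <- list(time = seg,
                                                      nodes = path$nodes)
      }
    }
    runs[[pcfg$name]] <- list(name = pcfg$name, path = path, hills = hills,
                              state = state, role = role, traj = traj,
                              final_pos = pos, snapshots = snapshots)
  }

  out <- structure(list(config = config, seed = seed, paths = runs),
                   class = "multipmd_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' @export
print.multipmd_run <- function(x, ...) {
  cat(sprintf("multipmd_run: %d path(s), %g ps, seed %d\n",
              length(x$paths), x$config$total_ps, x$seed))
  for (p in x$paths)
    cat(sprintf("  %s: %d nodes, %d hills, %d walkers\n", p$name,
                nrow(p$path$nodes), nrow(p$hills), length(p$role)))
  invisible(x)
}

#' Write run artifacts as plain-text tables
#'
#' Per path: `HILLS-<name>.dat` (shared hill log), `PATH-<name>.dat`
#' (adapted node table), and `WALKERS-<name>.tsv` (long-format trajectory:
#' time, walker, role, chi', theta, s, z, bias energy; thinned by the
#' config's `traj_stride`). Identical (config, seed) pairs reproduce every
#' file bit-identically.
#'
#' @param run a `multipmd_run`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stride <- run$config$traj_stride %||% 10L
  for (p in run$paths) {
    write_hills(p$hills, file.path(out_dir, paste0("HILLS-", p$name, ".dat")))
    write_path(p$path, file.path(out_dir, paste0("PATH-", p$name, ".dat")))
    keep <- seq_along(p$traj$time) %% stride == 0
    nw <- length(p$role)
    con <- file(file.path(out_dir, paste0("WALKERS-", p$name, ".tsv")), "w")
    writeLines("time\twalker\trole\tchi\ttheta\ts\tz\tebias", con)
    if (nw > 0L && any(keep)) {
      tt <- p$traj$time[keep]
      for (w in seq_len(nw)) {
        writeLines(sprintf("%.6f\t%d\t%s\t%.10g\t%.10g\t%.10g\t%.10g\t%.10g",
                           tt, w,
                           c("standard", "attractor", "attractor")[p$role[w] + 1L],
                           p$traj$chi[keep, w], p$traj$theta[keep, w],
                           p$traj$s[keep, w], p$traj$z[keep, w],
                           p$traj$ebias[keep, w]), con)
      }
    }
    close(con)
  }
  invisible(out_dir)
}
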