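#' Bin centers of the free-energy grid on s
#' @param n_bins number of bins on [-1, 1].
#' @return Vector of bin centers.
#' @export
fes_grid <- function(n_bins = 200L) {
  w <- 2 / n_bins
  seq(-1 + w / 2, 1 - w / 2, length.out = n_bins)
}

#' Construct a free-energy profile object
#'
#' @param s bin centers on [-1, 1].
#' @param mean per-bin free energy, kcal/mol, anchored to 0 at the WCF bin
#'   (s = +-1).
#' @param std per-bin standard deviation over snapshots (>= 0).
#' @param times snapshot times that entered the average.
#' @return An object of class `fes_profile`.
#' @export
fes_profile <- function(s, mean, std = rep(0, length(s)),
                        times = numeric(0)) {
  if (length(mean) != length(s) || length(std) != length(s))
    stop("s, mean and std must have equal length")
  if (any(std < -1e-12)) stop("std must be non-negative")
  structure(list(s = s, mean = mean, std = pmax(std, 0), times = times),
            class = "fes_profile")
}

#' @export
print.fes_profile <- function(x, ...) {
  cat(sprintf("fes_profile: %d bins, range %.3f kcal/mol, %d snapshot(s)\n",
              length(x$s), diff(range(x$mean)), max(1L, length(x$times))))
  invisible(x)
}

# Raw snapshot: -sum of hills deposited up to time t, on the bin centers.
hill_sum_snapshot <- function(hills, t, s) {
  sel <- hills$time <= t
  if (!any(sel)) return(rep(0, length(s)))
  -cpp_hills_energy(s, hills$center[sel], hills$width[sel],
                    hills$height[sel])$energy
}

#' Free-energy snapshot from a hill list
#'
#' The metadynamics estimate at time t: the negative of the sum of all
#' Gaussians deposited up to t, shifted so its minimum is 0.
#'
#' @param hills a [hill_list()].
#' @param t snapshot time, ps.
#' @param n_bins number of s bins.
#' @return A `fes_profile` (single snapshot, zero std).
#' @export
profile_from_hills <- function(hills, t = Inf, n_bins = 200L) {
  s <- fes_grid(n_bins)
  F <- hill_sum_snapshot(hills, t, s)
  F <- F - min(F)
  fes_profile(s, F, times = t)
}

#' Time-averaged free-energy profile with error bars
#'
#' Snapshots are taken every `interval` ps from `t_start` to `t_end`, each
#' independently shifted so its minimum is 0 (removing the arbitrary fill
#' level of metadynamics so the spread reflects shape, not fill), then
#' averaged per bin; the mean is re-anchored to 0 at the WCF bin.
#'
#' @param hills a [hill_list()].
#' @param t_start,t_end analysis window, ps (production ratio: the final
#'   5/7 of the run).
#' @param interval snapshot spacing, ps.
#' @param n_bins number of s bins.
#' @return A `fes_profile` with per-bin mean and standard deviation.
#' @export
averaged_profile <- function(hills, t_start, t_end, interval,
                             n_bins = 200L) {
  if (!(t_start < t_end)) stop("t_start must be below t_end")
  if (interval <= 0) stop("interval must be positive")
  times <- seq(t_start, t_end, by = interval)
  if (length(times) < 2L)
    stop("need at least 2 snapshots for mean and std")
  s <- fes_grid(n_bins)
  snaps <- vapply(times, function(t) {
    F <- hill_sum_snapshot(hills, t, s)
    F - min(F)
  }, numeric(n_bins))
  m <- rowMeans(snaps)
  sdv <- apply(snaps, 1L, sd)
  m <- m - mean(m[c(1L, n_bins)])
  fes_profile(s, m, sdv, times)
}

#' Extract direction-resolved barriers and the WCF-to-HG offset
#'
#' On a WCF-anchored profile: the 5' barrier is the maximum over
#' -1 < s < 0, the 3' barrier the maximum over 0 < s < 1 (rotation
#' direction convention of the cyclic path), each relative to F(WCF) = 0;
#' the HG offset is the value at the lowest interior minimum in |s| < 0.5.
#' If no interior minimum exists there, a topology warning is raised and
#' the offset is `NA`.
#'
#' @param profile a `fes_profile` anchored at WCF.
#' @return `list` of class `barrier_summary` with `barrier_5p`,
#'   `barrier_3p`, `delta_f`, transition-state positions `ts_5p`, `ts_3p`
#'   and the HG minimum position `s_hg`.
#' @export
extract_barriers <- function(profile) {
  s <- profile$s
  F <- profile$mean
  i5 <- which(s > -1 & s < 0)
  i3 <- which(s > 0 & s < 1)
  b5 <- max(F[i5]); ts5 <- s[i5[which.max(F[i5])]]
  b3 <- max(F[i3]); ts3 <- s[i3[which.max(F[i3])]]
  win <- which(abs(s) < 0.5)
  imin <- win[which.min(F[win])]
  interior <- imin != win[1L] && imin != win[length(win)] &&
    F[imin] < min(F[win[1L]], F[win[length(win)]]) - 1e-12
  if (!interior) {
    warning("no interior HG minimum found in |s| < 0.5; delta_f undefined")
    df <- NA_real_
    s_hg <- NA_real_
  } else {
    df <- F[imin]
    s_hg <- s[imin]
  }
  structure(list(barrier_5p = b5, barrier_3p = b3, delta_f = df,
                 ts_5p = ts5, ts_3p = ts3, s_hg = s_hg),
            class = "barrier_summary")
}

#' @export
print.barrier_summary <- function(x, ...) {
  cat(sprintf("barriers: 5' %.2f (s = %.2f), 3' %.2f (s = %.2f) kcal/mol\n",
              x$barrier_5p, x$ts_5p, x$barrier_3p, x$ts_3p))
  cat(sprintf("WCF -> HG: %s kcal/mol at s = %s\n",
              format(x$delta_f, digits = 3), format(x$s_hg, digits = 3)))
  invisible(x)
}

#' Free-diffusion diagnostic on the biasing coordinate
#'
#' Flags the earliest time after which, in every subsequent window of
#' length `window`, the walker ensemble completes at least one full
#' end-to-end traversal (s crossing from the WCF region through the HG
#' region and back). A profile is trusted only once this regime is
#' reached.
#'
#' @param times sample times, ps.
#' @param s matrix of s trajectories (one column per standard walker) or a
#'   vector for a single walker.
#' @param window window length, ps; defaults to 1/10 of the analysis span,
#'   i.e. `diff(range(times)) * (5/7) / 10`.
#' @param wcf_width,hg_width half-widths of the WCF (|s| > 1 - w) and HG
#'   (|s| < w) regions.
#' @return `list(flag =, onset =, events =)`; `onset` is `NA` when the
#'   regime is never reached.
#' @export
diffusion_check <- function(times, s, window = NULL,
                            wcf_width = 0.1, hg_width = 0.1) {
  if (is.null(dim(s))) s <- matrix(s, ncol = 1L)
  if (is.null(window)) window <- diff(range(times)) * (5 / 7) / 10
  events <- numeric(0)
  for (w in seq_len(ncol(s))) {
    lab <- ifelse(abs(s[, w]) >= 1 - wcf_width, "W",
                  ifelse(abs(s[, w]) <= hg_width, "H", NA))
    keep <- !is.na(lab)
    if (!any(keep)) next
    lv <- lab[keep]
    tv <- times[keep]
    r <- rle(lv)
    starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    v <- r$values
    # region visits strictly alternate W/H after rle, so every W visit from
    # the third run onward closes a W -> H -> W traversal
    hit <- which(v == "W")
    hit <- hit[hit >= 3L]
    if (length(hit)) events <- c(events, tv[starts[hit]])
  }
  events <- sort(events)
  t_end <- max(times)
  candidates <- sort(unique(c(times[1L], events)))
  onset <- NA_real_
  for (t0 in candidates) {
    n_win <- floor((t_end - t0) / window)
    if (n_win < 1L) break
    k <- 0:(n_win - 1L)
    lo <- t0 + k * window
    hi <- lo + window
    ok <- all(vapply(seq_along(lo), function(i)
      any(events >= lo[i] & events < hi[i]), logical(1L)))
    if (ok) { onset <- t0; break }
  }
  list(flag = !is.na(onset), onset = onset, events = events)
}

#' Ordinary least-squares trend between barriers and a descriptor
#'
#' @param barriers response values (e.g. free-energy barriers, kcal/mol).
#' @param descriptor explanatory values (e.g. d_NB in Angstrom, N_water).
#' @return `list(slope =, intercept =, residuals =)` in the descriptor's
#'   units.
#' @export
linear_trend_fit <- function(barriers, descriptor) {
  if (length(barriers) != length(descriptor))
    stop("barriers and descriptor must have equal length")
  if (length(barriers) < 2L) stop("need at least 2 points")
  if (isTRUE(all.equal(stats::var(descriptor), 0)) ||
      stats::var(descriptor) == 0)
    stop("descriptor has zero variance: trend fit is degenerate")
  fit <- lm(barriers ~ descriptor)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       residuals = unname(stats::residuals(fit)))
}

#' Write a free-energy profile as a plain-text table
#' @param profile a `fes_profile`.
#' @param file output path (columns s, F_mean, F_std).
#' @export
write_fes <- function(profile, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("#! FIELDS s F_mean F_std", con)
  writeLines(sprintf("%.17g %.17g %.17g", profile$s, profile$mean,
                     profile$std), con)
  invisible(file)
}

#' Read a profile written by [write_fes()]
#' @param file FES table.
#' @return A `fes_profile`.
#' @export
read_fes <- function(file) {
  m <- do.call(rbind, lapply(strsplit(trimws(grep("^#", readLines(file),
                                                  invert = TRUE,
                                                  value = TRUE)), " +"),
                             as.numeric))
  fes_profile(m[, 1L], m[, 2L], m[, 3L])
}
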