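# --- idealized base-pair geometry ---------------------------------------
# Regular-polygon base templates (bond 1.39 A), built in a pair-local plane
# (z = 0), paired with ~2.9 A hydrogen bonds along a common pairing
# direction, stacked at 3.4 A rise and 36 deg twist. Good to the few-tenths
# of an Angstrom that the structural-CV checks require; not a force-field
# geometry.

rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                              0, 0, 1), 3L, 3L)

# Rotate points (rows) by angle a about the axis through `origin` along
# unit vector `ax`.
rotate_about_axis <- function(xyz, ax, origin, a) {
  ax <- ax / sqrt(sum(ax^2))
  v <- sweep(xyz, 2L, origin)
  K <- matrix(c(0, ax[3L], -ax[2L], -ax[3L], 0, ax[1L], ax[2L], -ax[1L], 0),
              3L, 3L)
  R <- diag(3L) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  sweep(v %*% t(R), 2L, origin, "+")
}

# Place a fourth point by internal coordinates (NeRF): distance r to c,
# angle `ang` at c with b, torsion `tor` about the b-c axis w.r.t. a.
nerf_place <- function(a, b, c, r, ang, tor) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2L] * bc[3L] - ab[3L] * bc[2L],
         ab[3L] * bc[1L] - ab[1L] * bc[3L],
         ab[1L] * bc[2L] - ab[2L] * bc[1L])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2L] * bc[3L] - n[3L] * bc[2L],
         n[3L] * bc[1L] - n[1L] * bc[3L],
         n[1L] * bc[2L] - n[2L] * bc[1L])
  d <- c(-r * cos(ang), r * sin(ang) * cos(tor), -r * sin(ang) * sin(tor))
  c + d[1L] * bc + d[2L] * m + d[3L] * n
}

# Hexagon template: six ring atoms at radius 1.39, first atom at `a0`.
hexagon <- function(names, a0 = pi / 2) {
  ang <- a0 + (seq_len(6L) - 1L) * pi / 3
  m <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  rownames(m) <- names
  m
}

radial_sub <- function(ring, at, bond) {
  p <- ring[at, ]
  u <- c(p[1L], p[2L], 0)
  u <- u / sqrt(sum(u^2))
  p + bond * u
}

# Purine template (adenine numbering): 6-ring N1..C6 plus fused 5-ring
# C4-C5-N7-C8-N9, N6 on C6, sugar C1' on N9. Planar, z = 0.
purine_template <- function() {
  hx <- hexagon(c("N1", "C2", "N3", "C4", "C5", "C6"))
  c4 <- hx["C4", ]; c5 <- hx["C5", ]
  mid <- (c4 + c5) / 2
  u <- mid / sqrt(sum(mid^2))
  pc <- mid + 0.957 * u                       # pentagon apothem, side 1.39
  ang4 <- atan2(c4[2L] - pc[2L], c4[1L] - pc[1L])
  ang5 <- atan2(c5[2L] - pc[2L], c5[1L] - pc[1L])
  delta <- wrap_angle(ang4 - ang5)
  ang <- ang5 - delta * (1:3)                 # N7, C8, N9 around the ring
  pent <- cbind(1.182 * cos(ang) + pc[1L], 1.182 * sin(ang) + pc[2L], 0)
  rownames(pent) <- c("N7", "C8", "N9")
  n6 <- radial_sub(hx, "C6", 1.34)
  # effective anchor: in the idealized template the sugar C1' sits further
  # out than one bond length because the glycosidic geometry is not radial
  c1p <- pent["N9", ] + 2.9 * (pent["N9", ] - pc) /
    sqrt(sum((pent["N9", ] - pc)^2))
  rbind(hx, pent, N6 = n6, `C1'` = c1p)
}

# Pyrimidine template: ring N1..C6, O2 on C2 plus ring-specific
# substituents, sugar C1' on N1.
pyrimidine_template <- function(kind = c("T", "C")) {
  kind <- match.arg(kind)
  hx <- hexagon(c("N1", "C2", "N3", "C4", "C5", "C6"))
  subs <- rbind(O2 = radial_sub(hx, "C2", 1.23),
                `C1'` = radial_sub(hx, "N1", 2.05))
  if (kind == "T")
    subs <- rbind(subs, O4 = radial_sub(hx, "C4", 1.23),
                  C7 = radial_sub(hx, "C5", 1.50))
  else
    subs <- rbind(subs, N4 = radial_sub(hx, "C4", 1.34))
  rbind(hx, subs)
}

# Put the midpoint of the two base-ring centers at the origin, so the
# stacking axis of the duplex runs through the middle of each pair.
center_pair <- function(geom) {
  mid <- (colMeans(geom$pur[purine_six_ring, , drop = FALSE]) +
            colMeans(geom$pyr[pyrimidine_ring, , drop = FALSE])) / 2
  list(pur = sweep(geom$pur, 2L, mid), pyr = sweep(geom$pyr, 2L, mid))
}

# Rigid in-plane transform mapping two source points onto two targets
# (midpoints aligned, segment directions aligned).
two_point_align <- function(xyz, src1, src2, dst1, dst2) {
  sm <- (src1 + src2) / 2
  dm <- (dst1 + dst2) / 2
  a_src <- atan2(src2[2L] - src1[2L], src2[1L] - src1[1L])
  a_dst <- atan2(dst2[2L] - dst1[2L], dst2[1L] - dst1[1L])
  out <- sweep(xyz, 2L, sm)
  out <- out %*% t(rot_z(a_dst - a_src))
  sweep(out, 2L, dm, "+")
}

# Add O4' so that the rolling pseudo-dihedral (O4', C1', N9/N1, ring com)
# equals `chiprime`.
add_o4prime <- function(xyz, glyco_n, ring_names, chiprime) {
  com <- colMeans(xyz[ring_names, , drop = FALSE])
  o4 <- nerf_place(com, xyz[glyco_n, ], xyz["C1'", ], 2.0,
                   110 * pi / 180, chiprime)
  rbind(xyz, `O4'` = o4)
}

# One WCF pair in its local frame: purine on -x, pyrimidine on +x.
# Returns list(pur =, pyr =) coordinate matrices.
wcf_pair_geometry <- function(pyr_kind = "T", chiprime = pi / 2) {
  pyr <- pyrimidine_template(pyr_kind)
  # pairing edge: N3 (donor/acceptor) and the C4 substituent, facing -x
  hb_dir <- c(-cos(pi / 6), sin(pi / 6), 0)       # common H-bond direction
  acc <- if (pyr_kind == "T") "O4" else "N4"
  q1 <- pyr["N3", ] + 2.8 * hb_dir
  q2 <- pyr[acc, ] + 2.8 * hb_dir
  pur <- purine_template()
  pur <- two_point_align(pur, pur["N1", ], pur["N6", ], q1, q2)
  # set the characteristic N1-N3 hydrogen bond length exactly
  d0 <- pur["N1", ] - pyr["N3", ]
  pur <- sweep(pur, 2L, (2.85 / sqrt(sum(d0^2)) - 1) * d0, "+")
  pur <- add_o4prime(pur, "N9", purine_six_ring, chiprime)
  pyr <- add_o4prime(pyr, "N1", pyrimidine_ring, chiprime)
  center_pair(list(pur = pur, pyr = pyr))
}

# Flip the purine base (ring + N6) 180 deg about the glycosidic C1'-N9
# axis, then re-pair via the Hoogsteen edge (N7 to N3, N6 to the C4
# substituent). The sugar atoms stay put during the base flip; the whole
# nucleotide is then rigidly re-posed, which produces the characteristic
# C1'-C1' constriction.
hg_pair_geometry <- function(pyr_kind = "T", chiprime = pi / 2) {
  g <- wcf_pair_geometry(pyr_kind, chiprime)
  pur <- g$pur
  base <- c(purine_ring, "N6")
  ax <- pur["C1'", ] - pur["N9", ]
  pur[base, ] <- rotate_about_axis(pur[base, , drop = FALSE], ax,
                                   pur["N9", ], pi)
  acc <- if (pyr_kind == "T") "O4" else "N4"
  hb_dir <- c(-cos(pi / 6), sin(pi / 6), 0)
  q1 <- g$pyr["N3", ] + 2.8 * hb_dir
  q2 <- g$pyr[acc, ] + 2.8 * hb_dir
  pur <- two_point_align(pur, pur["N7", ], pur["N6", ], q1, q2)
  # set the characteristic N7-N3 hydrogen bond length exactly
  d0 <- pur["N7", ] - g$pyr["N3", ]
  pur <- sweep(pur, 2L, (2.85 / sqrt(sum(d0^2)) - 1) * d0, "+")
  center_pair(list(pur = pur, pyr = g$pyr))
}

pair_to_atoms <- function(geom, pur_id, pyr_id, transform = identity) {
  mk <- function(xyz, id)
    data.frame(elety = rownames(xyz), resname = id$resname,
               resno = id$resno, chain = id$chain,
               x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
               stringsAsFactors = FALSE)
  pur <- geom$pur
  pyr <- geom$pyr
  pur[, ] <- transform(pur)
  pyr[, ] <- transform(pyr)
  rbind(mk(pur, pur_id), mk(pyr, pyr_id))
}

#' Generate an idealized three-base-pair duplex fixture
#'
#' A synthetic stand-in for an equilibrated duplex: a central A-T pair
#' (chain A residue 2, chain B residue 5) flanked by G-C pairs, built from
#' idealized planar base templates stacked at 3.4 Angstrom rise and 36
#' degree twist. The HG fixture is generated by rotating the adenine base
#' 180 degrees about its glycosidic axis and re-pairing through the
#' Hoogsteen edge (which constricts the C1'-C1' distance); `mid` rotates
#' the base 90 degrees; `flipped` swings the adenine base about the helix
#' axis toward the major groove (an idealized strained geometry that
#' exercises the negative-opening-angle convention).
#'
#' @param kind `"WCF"`, `"HG"`, `"mid"` or `"flipped"`.
#' @param noise per-atom RMS Gaussian displacement in Angstrom
#'   (per-coordinate sd `noise/sqrt(3)`).
#' @param seed RNG seed for the noise (deterministic when set).
#' @return A [structure_frame()] with chains A (G1, A2, C3) and
#'   B (G4, T5, C6).
#' @export
make_fixture <- function(kind = c("WCF", "HG", "mid", "flipped"), noise = 0,
                         seed = NULL) {
  kind <- match.arg(kind)
  central <- switch(kind, HG = hg_pair_geometry("T"),
                    wcf_pair_geometry("T"))
  if (kind == "mid") {
    base <- c(purine_ring, "N6")
    ax <- central$pur["C1'", ] - central$pur["N9", ]
    central$pur[base, ] <- rotate_about_axis(central$pur[base, , drop = FALSE],
                                             ax, central$pur["N9", ], pi / 2)
  }

  gc <- wcf_pair_geometry("C")  # purine on the chain-A side
  place <- function(level) {
    function(xyz) {
      out <- xyz %*% t(rot_z(level * 36 * pi / 180))
      out[, 3L] <- out[, 3L] + level * 3.4
      out
    }
  }
  # pair 1 (5' of A2): G on chain A; pair 3: G on chain B, so the pair
  # frame is turned half a revolution to keep the purine on the B side
  swap <- function(xyz) xyz %*% t(rot_z(pi))
  atoms <- rbind(
    pair_to_atoms(gc, list(resname = "DG", resno = 1L, chain = "A"),
                  list(resname = "DC", resno = 6L, chain = "B"),
                  transform = function(x) place(-1)(x)),
    pair_to_atoms(central, list(resname = "DA", resno = 2L, chain = "A"),
                  list(resname = "DT", resno = 5L, chain = "B")),
    pair_to_atoms(gc, list(resname = "DG", resno = 4L, chain = "B"),
                  list(resname = "DC", resno = 3L, chain = "A"),
                  transform = function(x) place(1)(swap(x)))
  )

  if (kind == "flipped") {
    # swing the base (not the sugar reference) about the helix axis toward
    # the major groove: the opening pseudo-dihedral goes negative
    sel <- atoms$chain == "A" & atoms$resno == 2L &
      atoms$elety %in% c(purine_ring, "N6")
    xyz <- as.matrix(atoms[sel, c("x", "y", "z")])
    xyz <- rotate_about_axis(xyz, c(0, 0, 1), c(0, 0, 0), 1.2)
    atoms[sel, c("x", "y", "z")] <- xyz
  }
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] +
      matrix(rnorm(3L * nrow(atoms), sd = noise / sqrt(3)), ncol = 3L)
  }
  structure_frame(atoms$elety, atoms$resname, atoms$resno, atoms$chain,
                  as.matrix(atoms[, c("x", "y", "z")]))
}
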