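#' Construct a structure frame from atom records
#'
#' A minimal container for atomic coordinates: one row per atom with its
#' PDB-style name, residue name/number, chain and coordinates in Angstrom,
#' plus an optional orthorhombic periodic box.
#'
#' @param elety atom names (PDB v3 style, primes as `'`).
#' @param resname residue names.
#' @param resno residue numbers.
#' @param chain chain identifiers.
#' @param xyz numeric matrix of coordinates (n x 3), Angstrom.
#' @param box optional box lengths `c(lx, ly, lz)` in Angstrom.
#' @return A data frame of class `structure_frame`.
#' @export
structure_frame <- function(elety, resname, resno, chain, xyz, box = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L || nrow(xyz) != length(elety))
    stop("xyz must be an n x 3 matrix matching the atom records")
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  key <- paste(chain, resno, elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom-name) keys: ",
         key[anyDuplicated(key)])
  df <- data.frame(elety = as.character(elety),
                   resname = as.character(resname),
                   resno = as.integer(resno), chain = as.character(chain),
                   x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                   stringsAsFactors = FALSE)
  attr(df, "box") <- box
  class(df) <- c("structure_frame", "data.frame")
  df
}

#' Read a PDB file into a structure frame
#'
#' Parsing goes through [bio3d::read.pdb()]; ATOM and HETATM records are
#' kept. An orthorhombic CRYST1 record, if present, becomes the frame's
#' box.
#'
#' @param file PDB file path.
#' @return A [structure_frame()].
#' @export
read_pdb_frame <- function(file) {
  pdb <- bio3d::read.pdb(file)
  a <- pdb$atom
  box <- NULL
  cr <- grep("^CRYST1", readLines(file, n = 200L), value = TRUE)
  if (length(cr)) {
    v <- as.numeric(c(substr(cr[1L], 7, 15), substr(cr[1L], 16, 24),
                      substr(cr[1L], 25, 33)))
    if (all(is.finite(v)) && all(v > 0)) box <- v
  }
  chain <- ifelse(is.na(a$chain), "A", a$chain)
  structure_frame(a$elety, a$resid, a$resno, chain,
                  cbind(a$x, a$y, a$z), box = box)
}

#' Write a structure frame to a PDB file
#'
#' Writing goes through [bio3d::write.pdb()]; atom serial numbers are
#' assigned sequentially.
#'
#' @param frame a [structure_frame()].
#' @param file output path.
#' @export
write_pdb_frame <- function(frame, file) {
  bio3d::write.pdb(file = file, xyz = as.vector(t(as.matrix(frame[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(frame)),
                   resno = frame$resno, resid = frame$resname,
                   eleno = seq_len(nrow(frame)), elety = frame$elety,
                   chain = frame$chain)
  invisible(file)
}

# Resolve one (chain, resno, elety) selector to a row index.
atom_index <- function(frame, chain, resno, elety) {
  i <- which(frame$chain == chain & frame$resno == resno &
               frame$elety == elety)
  if (length(i) != 1L)
    stop("selector (", chain, ", ", resno, ", ", elety, ") matched ",
         length(i), " atoms")
  i
}

atom_xyz <- function(frame, chain, resno, elety) {
  i <- atom_index(frame, chain, resno, elety)
  c(frame$x[i], frame$y[i], frame$z[i])
}

#' Standard atomic masses with name-based element inference
#'
#' Elements are inferred from the leading alphabetic character of the PDB
#' atom name after stripping digits and primes (fixtures carry no element
#' column); `overrides` is a named vector mapping atom names to masses.
#'
#' @param elety atom names.
#' @param overrides named numeric vector of per-atom-name masses.
#' @return Masses in amu.
#' @export
atom_masses <- function(elety, overrides = NULL) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.973762,
           S = 32.06)
  el <- toupper(substr(gsub("[0-9']", "", elety), 1L, 1L))
  m <- unname(tab[el])
  if (!is.null(overrides)) {
    hit <- elety %in% names(overrides)
    m[hit] <- overrides[elety[hit]]
  }
  if (any(is.na(m)))
    stop("cannot infer element for atom name(s): ",
         paste(unique(elety[is.na(m)]), collapse = ", "))
  m
}

#' Signed torsion angle of four points
#'
#' Standard atan2 construction; result in (-pi, pi].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, Angstrom.
#' @return Torsion in rad.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2L] * b2[3L] - b1[3L] * b2[2L],
          b1[3L] * b2[1L] - b1[1L] * b2[3L],
          b1[1L] * b2[2L] - b1[2L] * b2[1L])
  n2 <- c(b2[2L] * b3[3L] - b2[3L] * b3[2L],
          b2[3L] * b3[1L] - b2[1L] * b3[3L],
          b2[1L] * b3[2L] - b2[2L] * b3[1L])
  scale <- sqrt(sum(b1^2)) * sqrt(sum(b2^2)) * sqrt(sum(b3^2))
  if (scale == 0 || sqrt(sum(n1^2)) < 1e-10 * scale ||
      sqrt(sum(n2^2)) < 1e-10 * scale)
    stop("degenerate geometry: collinear or coincident points")
  m1 <- c(n1[2L] * b2[3L] - n1[3L] * b2[2L],
          n1[3L] * b2[1L] - n1[1L] * b2[3L],
          n1[1L] * b2[2L] - n1[2L] * b2[1L])
  ang <- atan2(sum(m1 * n2) / sqrt(sum(b2^2)), sum(n1 * n2))
  if (ang <= -pi) ang <- ang + 2 * pi
  ang
}

#' Define the four points of a pseudo-dihedral
#'
#' Each point is a single atom or the mass-weighted center of a group of
#' atoms, specified as data frames with columns `chain`, `resno`, `elety`.
#'
#' @param g1,g2,g3,g4 group data frames (non-empty).
#' @return An object of class `atom_group_spec`.
#' @export
atom_group_spec <- function(g1, g2, g3, g4) {
  groups <- list(g1, g2, g3, g4)
  for (g in groups)
    if (NROW(g) < 1L || !all(c("chain", "resno", "elety") %in% names(g)))
      stop("each group needs >= 1 row with chain, resno, elety")
  structure(groups, class = "atom_group_spec")
}

# One selector group -> data frame.
atom_sel <- function(chain, resno, elety) {
  data.frame(chain = chain, resno = resno, elety = elety,
             stringsAsFactors = FALSE)
}

group_com <- function(frame, g, overrides = NULL) {
  idx <- vapply(seq_len(nrow(g)),
                function(i) atom_index(frame, g$chain[i], g$resno[i],
                                       g$elety[i]), integer(1L))
  m <- atom_masses(frame$elety[idx], overrides)
  xyz <- as.matrix(frame[idx, c("x", "y", "z")])
  colSums(xyz * m) / sum(m)
}

#' Center-of-mass pseudo-dihedral
#'
#' The torsion over the four mass-weighted centers of an
#' [atom_group_spec()]; reduces to [dihedral_angle()] when all groups are
#' single atoms.
#'
#' @param frame a [structure_frame()].
#' @param spec an [atom_group_spec()].
#' @param mass_overrides named per-atom-name mass overrides.
#' @return Torsion in rad.
#' @export
com_pseudo_dihedral <- function(frame, spec, mass_overrides = NULL) {
  coms <- lapply(spec, group_com, frame = frame, overrides = mass_overrides)
  dihedral_angle(coms[[1L]], coms[[2L]], coms[[3L]], coms[[4L]])
}

# Ring atom names.
purine_ring <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
purine_six_ring <- c("N1", "C2", "N3", "C4", "C5", "C6")
pyrimidine_ring <- c("N1", "C2", "N3", "C4", "C5", "C6")

base_ring_names <- function(resname) {
  if (grepl("A|G", resname)) purine_ring else pyrimidine_ring
}

#' Glycosidic torsion chi of a purine nucleotide
#'
#' The torsion over atoms O4'-C1'-N9-C4.
#'
#' @param frame a [structure_frame()].
#' @param chain,resno the purine residue.
#' @return chi in rad.
#' @export
glycosidic_chi <- function(frame, chain, resno) {
  dihedral_angle(atom_xyz(frame, chain, resno, "O4'"),
                 atom_xyz(frame, chain, resno, "C1'"),
                 atom_xyz(frame, chain, resno, "N9"),
                 atom_xyz(frame, chain, resno, "C4"))
}

#' Default group definition for the base-rolling pseudo-dihedral chi'
#'
#' chi' corrects the glycosidic torsion so that biasing it rolls the base
#' rather than the sugar: the reference points are the sugar O4' and C1',
#' the glycosidic N9, and the center of mass of the purine 6-ring. The
#' groups are a shipped convention and fully configurable via
#' [atom_group_spec()].
#'
#' @param chain,resno the purine residue.
#' @return An [atom_group_spec()].
#' @export
chiprime_spec <- function(chain, resno) {
  atom_group_spec(atom_sel(chain, resno, "O4'"),
                  atom_sel(chain, resno, "C1'"),
                  atom_sel(chain, resno, "N9"),
                  atom_sel(chain, resno, purine_six_ring))
}

#' Default group definition for the base-opening pseudo-dihedral theta
#'
#' The axis runs through the centers of mass of the two base pairs flanking
#' the rolling purine; the opening angle is the torsion of the purine base
#' ring about that axis, referenced to the purine's own sugar C1' (which
#' stays in the backbone when the base flips). Negative values are flips
#' toward the major groove. The groups are a shipped convention,
#' configurable via [atom_group_spec()].
#'
#' @param frame a [structure_frame()] (for residue names).
#' @param purine `c(chain, resno)` of the rolling purine.
#' @param flank5,flank3 lists of two `c(chain, resno)` pairs: the flanking
#'   base pair on the 5' and the 3' side.
#' @return An [atom_group_spec()].
#' @export
theta_spec <- function(frame, purine, flank5, flank3) {
  res_ring <- function(cr) {
    rn <- frame$resname[frame$chain == cr[[1L]] &
                          frame$resno == as.integer(cr[[2L]])][1L]
    atom_sel(cr[[1L]], as.integer(cr[[2L]]), base_ring_names(rn))
  }
  pair_rings <- function(pair) do.call(rbind, lapply(pair, res_ring))
  atom_group_spec(atom_sel(purine[[1L]], as.integer(purine[[2L]]), "C1'"),
                  pair_rings(flank5), pair_rings(flank3),
                  atom_sel(purine[[1L]], as.integer(purine[[2L]]),
                           purine_ring))
}

#' Characteristic base-pairing distances
#'
#' d_WCF = A:N1-T:N3, d_HG = A:N7-T:N3, d_HB = A:N6-T:O4 (the conserved
#' hydrogen bond), d_CC = the C1'-C1' distance across the pair, and d_NB =
#' the distance between the centers of mass of the two bases neighboring
#' the rolling purine.
#'
#' @param frame a [structure_frame()].
#' @param purine,pyrimidine `c(chain, resno)` of the central pair.
#' @param nb5,nb3 `c(chain, resno)` of the purine's strand neighbors.
#' @return Named vector (Angstrom): d_wcf, d_hg, d_hb, d_cc, d_nb.
#' @export
pair_distances <- function(frame, purine, pyrimidine, nb5, nb3) {
  d <- function(p, q) sqrt(sum((p - q)^2))
  pu <- function(a) atom_xyz(frame, purine[[1L]], as.integer(purine[[2L]]), a)
  py <- function(a) atom_xyz(frame, pyrimidine[[1L]],
                             as.integer(pyrimidine[[2L]]), a)
  base_com <- function(cr) {
    rn <- frame$resname[frame$chain == cr[[1L]] &
                          frame$resno == as.integer(cr[[2L]])][1L]
    group_com(frame, atom_sel(cr[[1L]], as.integer(cr[[2L]]),
                              base_ring_names(rn)))
  }
  c(d_wcf = d(pu("N1"), py("N3")), d_hg = d(pu("N7"), py("N3")),
    d_hb = d(pu("N6"), py("O4")), d_cc = d(pu("C1'"), py("C1'")),
    d_nb = d(base_com(nb5), base_com(nb3)))
}

#' Count water oxygens near an atom
#'
#' Waters are recognized by residue name (HOH, WAT, SOL, TIP3) and an
#' oxygen atom name; distances use the minimum image when the frame has an
#' orthorhombic box.
#'
#' @param frame a [structure_frame()].
#' @param chain,resno,elety the center atom (default the adenine N6).
#' @param cutoff distance cutoff in Angstrom (default 6).
#' @return Integer count.
#' @export
n_water <- function(frame, chain, resno, elety = "N6", cutoff = 6) {
  ctr <- atom_xyz(frame, chain, resno, elety)
  wat <- frame$resname %in% c("HOH", "WAT", "SOL", "TIP3") &
    substr(gsub("[0-9']", "", frame$elety), 1L, 1L) == "O"
  if (!any(wat)) return(0L)
  dx <- cbind(frame$x[wat] - ctr[1L], frame$y[wat] - ctr[2L],
              frame$z[wat] - ctr[3L])
  box <- attr(frame, "box")
  if (!is.null(box))
    dx <- dx - sweep(round(sweep(dx, 2L, box, "/")), 2L, box, "*")
  sum(sqrt(rowSums(dx^2)) <= cutoff)
}

#' Classify the base-pairing state of a CV record
#'
#' WCF when chi' is within 0.6 rad of +1.5 (and d_WCF < 3.5 Angstrom when
#' distances are present); HG when chi' is within 0.6 rad of -1.5 (and
#' d_HG < 3.5); otherwise intermediate.
#'
#' @param cv a list or named vector with `chiprime` and optionally `d_wcf`,
#'   `d_hg`.
#' @return `"WCF"`, `"HG"` or `"intermediate"`.
#' @export
classify_state <- function(cv) {
  cv <- as.list(cv)
  chip <- cv$chiprime
  has_d <- !is.null(cv$d_wcf) && !is.null(cv$d_hg)
  if (abs(chip - 1.5) < 0.6 && (!has_d || cv$d_wcf < 3.5)) return("WCF")
  if (abs(chip + 1.5) < 0.6 && (!has_d || cv$d_hg < 3.5)) return("HG")
  "intermediate"
}

#' Default residue topology of the synthetic three-pair duplex
#'
#' Chain A runs 5'-G1, A2, C3-3'; chain B holds the partners C6, T5, G4.
#' The rolling purine is A2, its partner T5, its strand neighbors G1 (5')
#' and C3 (3'), and the flanking pairs are (G1, C6) and (C3, G4).
#'
#' @return A list of selectors consumed by [compute_cv_record()].
#' @export
default_duplex_topology <- function() {
  list(purine = list("A", 2L), pyrimidine = list("B", 5L),
       nb5 = list("A", 1L), nb3 = list("A", 3L),
       flank5 = list(list("A", 1L), list("B", 6L)),
       flank3 = list(list("A", 3L), list("B", 4L)))
}

#' Compute the full structural CV record of a frame
#'
#' @param frame a [structure_frame()].
#' @param topology selector list as from [default_duplex_topology()].
#' @param water_cutoff cutoff for `n_water`, Angstrom.
#' @return A list: chi, chiprime, theta (rad), the pair distances
#'   (Angstrom) and n_water.
#' @export
compute_cv_record <- function(frame, topology = default_duplex_topology(),
                              water_cutoff = 6) {
  pu <- topology$purine
  dists <- pair_distances(frame, topology$purine, topology$pyrimidine,
                          topology$nb5, topology$nb3)
  c(list(chi = glycosidic_chi(frame, pu[[1L]], pu[[2L]]),
         chiprime = com_pseudo_dihedral(frame, chiprime_spec(pu[[1L]],
                                                             pu[[2L]])),
         theta = com_pseudo_dihedral(frame, theta_spec(frame, pu,
                                                       topology$flank5,
                                                       topology$flank3))),
    as.list(dists),
    list(n_water = n_water(frame, pu[[1L]], pu[[2L]],
                           cutoff = water_cutoff)))
}
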