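# Synthetic structures and alignments with planted ground truth.
#
# Residues are built from internal-coordinate templates (ideal bond
# lengths and angles, extended side chains); only the governing atom
# pair of each planted interaction is placed at an exact distance,
# which is all the distance-threshold detectors ever see.

deg <- pi / 180

# NeRF placement: position D with |C-D| = bond, angle(B,C,D) = ang and
# dihedral(A,B,C,D) = dih (degrees).
place_atom <- function(A, B, C, bond, ang, dih) {
  ang <- ang * deg; dih <- dih * deg
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Side-chain z-matrix rows: name, three reference atoms, bond, angle,
# dihedral.  Chi angles are set to extended (180) unless branching
# requires otherwise.
SIDECHAIN_ZMAT <- list(
  ALA = list(),
  ARG = list(c("CG","N","CA","CB",1.52,114.1,180),
             c("CD","CA","CB","CG",1.52,111.3,180),
             c("NE","CB","CG","CD",1.46,112.0,180),
             c("CZ","CG","CD","NE",1.33,124.2,180),
             c("NH1","CD","NE","CZ",1.33,120.0,0),
             c("NH2","CD","NE","CZ",1.33,120.0,180)),
  ASN = list(c("CG","N","CA","CB",1.52,112.6,180),
             c("OD1","CA","CB","CG",1.23,120.8,0),
             c("ND2","CA","CB","CG",1.33,116.4,180)),
  ASP = list(c("CG","N","CA","CB",1.52,112.6,180),
             c("OD1","CA","CB","CG",1.25,118.5,0),
             c("OD2","CA","CB","CG",1.25,118.5,180)),
  CYS = list(c("SG","N","CA","CB",1.81,114.4,180)),
  GLN = list(c("CG","N","CA","CB",1.52,114.1,180),
             c("CD","CA","CB","CG",1.52,112.6,180),
             c("OE1","CB","CG","CD",1.23,120.8,0),
             c("NE2","CB","CG","CD",1.33,116.4,180)),
  GLU = list(c("CG","N","CA","CB",1.52,114.1,180),
             c("CD","CA","CB","CG",1.52,112.6,180),
             c("OE1","CB","CG","CD",1.25,118.5,0),
             c("OE2","CB","CG","CD",1.25,118.5,180)),
  GLY = list(),
  HIS = list(c("CG","N","CA","CB",1.49,113.8,180),
             c("ND1","CA","CB","CG",1.38,122.7,90),
             c("CE1","CB","CG","ND1",1.32,109.3,180),
             c("NE2","CG","ND1","CE1",1.32,108.4,0),
             c("CD2","ND1","CE1","NE2",1.36,109.0,0)),
  ILE = list(c("CG1","N","CA","CB",1.53,110.4,180),
             c("CG2","N","CA","CB",1.53,110.5,-60),
             c("CD1","CA","CB","CG1",1.52,113.8,180)),
  LEU = list(c("CG","N","CA","CB",1.53,116.3,180),
             c("CD1","CA","CB","CG",1.52,110.7,60),
             c("CD2","CA","CB","CG",1.52,110.7,180)),
  LYS = list(c("CG","N","CA","CB",1.52,114.1,180),
             c("CD","CA","CB","CG",1.52,111.3,180),
             c("CE","CB","CG","CD",1.52,111.3,180),
             c("NZ","CG","CD","CE",1.49,111.9,180)),
  MET = list(c("CG","N","CA","CB",1.52,114.1,180),
             c("SD","CA","CB","CG",1.80,112.7,180),
             c("CE","CB","CG","SD",1.79,100.9,180)),
  PHE = list(c("CG","N","CA","CB",1.51,113.8,180),
             c("CD1","CA","CB","CG",1.39,120.8,90),
             c("CD2","CA","CB","CG",1.39,120.8,-90),
             c("CE1","CB","CG","CD1",1.39,120.0,180),
             c("CE2","CB","CG","CD2",1.39,120.0,180),
             c("CZ","CG","CD1","CE1",1.39,120.0,0)),
  PRO = list(c("CG","N","CA","CB",1.50,104.5,30),
             c("CD","CA","CB","CG",1.51,106.0,-30)),
  SER = list(c("OG","N","CA","CB",1.42,110.8,180)),
  THR = list(c("OG1","N","CA","CB",1.43,109.6,180),
             c("CG2","N","CA","CB",1.53,110.5,-60)),
  TRP = list(c("CG","N","CA","CB",1.50,113.8,180),
             c("CD1","CA","CB","CG",1.37,126.9,90),
             c("NE1","CB","CG","CD1",1.38,110.2,180),
             c("CE2","CG","CD1","NE1",1.37,109.0,0),
             c("CD2","CD1","NE1","CE2",1.40,107.5,0),
             c("CE3","NE1","CE2","CD2",1.40,133.9,180),
             c("CZ2","CD1","NE1","CE2",1.40,128.8,180),
             c("CZ3","CE2","CD2","CE3",1.39,118.6,0),
             c("CH2","NE1","CE2","CZ2",1.37,117.5,180)),
  TYR = list(c("CG","N","CA","CB",1.51,113.8,180),
             c("CD1","CA","CB","CG",1.39,120.8,90),
             c("CD2","CA","CB","CG",1.39,120.8,-90),
             c("CE1","CB","CG","CD1",1.39,120.0,180),
             c("CE2","CB","CG","CD2",1.39,120.0,180),
             c("CZ","CG","CD1","CE1",1.39,120.0,0),
             c("OH","CD1","CE1","CZ",1.38,119.9,180)),
  VAL = list(c("CG1","N","CA","CB",1.53,110.5,180),
             c("CG2","N","CA","CB",1.53,110.5,-60))
)

# Build one residue in a local frame; returns matrix with rownames =
# atom names.
build_residue_xyz <- function(resname) {
  resname <- toupper(resname)
  if (!resname %in% AA3) stop("unknown residue type: ", resname)
  xyz <- list(
    N = c(0, 0, 0),
    CA = c(1.458, 0, 0))
  ang <- 111 * deg
  xyz$C <- xyz$CA + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
  xyz$O <- place_atom(xyz$N, xyz$CA, xyz$C, 1.231, 120.5, 0)
  if (resname != "GLY")
    xyz$CB <- place_atom(xyz$C, xyz$N, xyz$CA, 1.53, 110.5, -122)
  for (row in SIDECHAIN_ZMAT[[resname]]) {
    xyz[[row[1]]] <- place_atom(xyz[[row[2]]], xyz[[row[3]]],
                                xyz[[row[4]]],
                                as.numeric(row[5]), as.numeric(row[6]),
                                as.numeric(row[7]))
  }
  do.call(rbind, xyz)
}

rotation_from_to <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (abs(cth + 1) < 1e-12) {   # antiparallel: rotate about any normal
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(a[2] * p[3] - a[3] * p[2],
           a[3] * p[1] - a[1] * p[3],
           a[1] * p[2] - a[2] * p[1])
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

rotation_about <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  outer(axis, axis) * (1 - ct) + diag(3) * ct +
    matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
             -axis[2], axis[1], 0), 3, 3, byrow = TRUE) * st
}

# Ring atoms and normal of the reference aromatic ring (six-membered
# for TRP).
template_ring <- function(resname, xyz) {
  rings <- c(AROMATIC_RINGS, AROMATIC_RINGS_HIS)[[resname]]
  if (is.null(rings)) return(NULL)
  ring <- rings[[length(rings)]]
  pts <- xyz[ring, , drop = FALSE]
  cen <- colMeans(pts)
  v1 <- pts[2, ] - pts[1, ]; v2 <- pts[3, ] - pts[1, ]
  n <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  list(centroid = cen, normal = n / sqrt(sum(n^2)))
}

# Default governing atoms per interaction type.
governing_atom <- function(resname, type, side) {
  resname <- toupper(resname)
  switch(type,
    HBOND = {
      if (side == "donor" || side == "a") {
        d <- HB_DONORS[[resname]]
        if (!is.null(d)) d[1] else "N"
      } else {
        a <- HB_ACCEPTORS[[resname]]
        if (!is.null(a)) a[1] else "O"
      }
    },
    SALT_BRIDGE = ,
    ELECTROSTATIC = {
      if (!is.null(CATIONIC_ATOMS[[resname]])) CATIONIC_ATOMS[[resname]][1]
      else if (!is.null(ANIONIC_ATOMS[[resname]])) ANIONIC_ATOMS[[resname]][1]
      else stop(resname, " carries no charged group")
    },
    HYDROPHOBIC = {
      ap <- APOLAR_CARBONS[[resname]]
      if (is.null(ap)) stop(resname, " has no apolar carbons")
      ap[length(ap)]
    },
    CATION_PI = {
      if (!is.null(CATION_PI_CATIONS[[resname]]))
        CATION_PI_CATIONS[[resname]][1]
      else "RING"
    },
    NONE = "CA",
    stop("unknown interaction type: ", type))
}

orient_residue <- function(xyz, anchor_xyz, u, spin = 0,
                           face_normal = NULL) {
  cen <- colMeans(xyz)
  if (is.null(face_normal)) {
    v <- anchor_xyz - cen
    if (sqrt(sum(v^2)) < 1e-6) v <- c(1, 0, 0)
    R <- rotation_from_to(v, u)
  } else {
    R <- rotation_from_to(face_normal, u)
  }
  R2 <- rotation_about(u, spin)
  sweep(xyz, 2, anchor_xyz) %*% t(R) %*% t(R2)
}

#' Generate a toy two-chain complex with planted interactions
#'
#' Builds a synthetic PDB-style complex in which each requested
#' residue pair is placed so that the governing atom pair of the
#' requested interaction type sits at exactly the requested distance,
#' with the two residue bodies pointing away from each other along the
#' interaction axis.  Pairs are spaced 30 Angstrom apart, so residues
#' of different pairs never interact.  Chain A holds the first residue
#' of each pair (the "hormone" side), chain B the second (the
#' "receptor" side).
#'
#' The governing atoms default to the type's canonical chemistry (salt
#' bridge: LYS NZ / ASP OD1 style charged atoms; hydrogen bond: first
#' side-chain donor vs first side-chain acceptor, falling back to
#' backbone; hydrophobic: terminal apolar carbon; cation-pi: cation
#' atom vs ring centroid, with the ring oriented face-on).  Type
#' `"NONE"` places a pair at the requested CA-CA distance without any
#' intended interaction.
#'
#' @param spec list of character/numeric vectors
#'   `c(res_a, res_b, type, distance)`, e.g.
#'   `c("LYS", "ASP", "SALT_BRIDGE", 3.5)`.  May be empty: then two
#'   glycines are placed 50 Angstrom apart.
#' @param seed integer; sets the (restored-on-exit) RNG state used for
#'   the random spin of each residue about its interaction axis.
#' @param config `geometry_config` used to annotate which planted
#'   pairs are expected to be detected at their requested distance.
#' @return list with `model` (a `structure_model`) and `truth`
#'   (data.frame: `resno`, `res_a`, `res_b`, `type`, `distance`,
#'   `atom_a`, `atom_b`, `expect_detected`).
#' @examples
#' toy <- make_toy_complex(list(c("ARG", "TYR", "CATION_PI", 5.5),
#'                              c("LEU", "VAL", "HYDROPHOBIC", 4.5)))
#' toy$truth
#' @export
make_toy_complex <- function(spec = list(), seed = 1L,
                             config = geometry_config()) {
  local_seed(seed)
  if (length(spec) == 0L)
    spec <- list(c("GLY", "GLY", "NONE", 50))
  rows <- list()
  truth <- list()
  u <- c(1, 0, 0)
  for (i in seq_along(spec)) {
    sp <- spec[[i]]
    res_a <- toupper(sp[1]); res_b <- toupper(sp[2])
    type <- toupper(sp[3]); d <- as.numeric(sp[4])
    if (!is.finite(d) || d <= 0) stop("infeasible geometry request")
    offset <- c(0, 30 * (i - 1), 0)

    xa <- build_residue_xyz(res_a)
    xb <- build_residue_xyz(res_b)
    ga <- governing_atom(res_a, type, "a")
    gb <- governing_atom(res_b, type, "b")
    # cation-pi: make sure the cation side is handled as such
    if (type == "CATION_PI" && ga == "RING" && gb != "RING") {
      tmp <- res_a; res_a <- res_b; res_b <- tmp
      tmp <- xa; xa <- xb; xb <- tmp
      ga <- governing_atom(res_a, type, "a")
      gb <- governing_atom(res_b, type, "b")
    }

    anchor_a <- xa[ga, ]
    xa_p <- orient_residue(xa, anchor_a, u,
                           spin = stats::runif(1, 0, 2 * pi))
    xa_p <- sweep(xa_p, 2, offset, "+")

    if (gb == "RING") {
      ring <- template_ring(res_b, xb)
      if (is.null(ring)) stop(res_b, " has no aromatic ring")
      xb_p <- orient_residue(xb, ring$centroid, -u,
                             spin = stats::runif(1, 0, 2 * pi),
                             face_normal = ring$normal)
    } else {
      xb_p <- orient_residue(xb, xb[gb, ], -u,
                             spin = stats::runif(1, 0, 2 * pi))
    }
    xb_p <- sweep(xb_p, 2, offset + d * u, "+")

    rows[[length(rows) + 1L]] <- atom_rows(xa_p, "A", i, res_a)
    rows[[length(rows) + 1L]] <- atom_rows(xb_p, "B", i, res_b)
    truth[[length(truth) + 1L]] <- data.frame(
      resno = i, res_a = res_a, res_b = res_b, type = type,
      distance = d, atom_a = ga, atom_b = gb,
      expect_detected = type != "NONE" &&
        d <= type_cutoff(type, config),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df$reskey <- reskey(df$chain, df$resno, df$insert)
  list(model = structure_model(df, id = "toy_complex"),
       truth = do.call(rbind, truth))
}

type_cutoff <- function(type, config) {
  switch(type,
         HBOND = config$hbond_da_max,
         SALT_BRIDGE = config$salt_bridge_max,
         ELECTROSTATIC = config$electrostatic_max,
         HYDROPHOBIC = config$hydrophobic_max,
         CATION_PI = config$cation_pi_max,
         NONE = -Inf)
}

atom_rows <- function(xyz, chain, resno, resname) {
  data.frame(chain = chain, resno = as.integer(resno), insert = "",
             resid = resname, elety = rownames(xyz),
             element = infer_element(rownames(xyz)),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
             is_hydrogen = FALSE,
             is_sidechain = !(rownames(xyz) %in% BACKBONE_ATOMS),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Random many-residue system for detector stress tests
#'
#' Scatters randomly typed, randomly oriented residues uniformly in a
#' cubic box, alternating between two chains.  No interaction truth is
#' planted; these systems exercise the engine against a brute-force
#' reference scan.
#'
#' @param n_residues number of residues.
#' @param box box edge length, Angstrom.
#' @param seed RNG seed (state restored on exit).
#' @return a `structure_model` with chains A and B.
#' @export
make_random_system <- function(n_residues = 25, box = 25, seed = 1L) {
  local_seed(seed)
  rows <- list()
  for (i in seq_len(n_residues)) {
    resname <- sample(AA3, 1L)
    xyz <- build_residue_xyz(resname)
    axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
    R <- rotation_about(axis, stats::runif(1, 0, 2 * pi))
    xyz <- sweep(xyz %*% t(R), 2, stats::runif(3, 0, box), "+")
    chain <- if (i %% 2L == 0L) "B" else "A"
    rows[[i]] <- atom_rows(xyz, chain, (i + 1L) %/% 2L, resname)
  }
  df <- do.call(rbind, rows)
  df$reskey <- reskey(df$chain, df$resno, df$insert)
  structure_model(df, id = sprintf("random_system_seed%d", seed))
}

#' Generate two family alignments with planted specificity columns
#'
#' Emulates a pair of paralogous families: `n_divergent` columns are
#' conserved within each family but on different physicochemical
#' classes (the planted specificity positions), `n_shared` columns are
#' conserved on a common class in both families, and the remaining
#' columns are drawn uniformly over the 20 residues.  Each residue is
#' then independently replaced by a uniform random residue with
#' probability `noise_rate`; with `gap_rate > 0`, non-reference
#' residues are additionally deleted to gaps.  The first sequence of
#' each family is the (never-gapped) reference.
#'
#' @param n_per_family sequences per family.
#' @param L alignment length.
#' @param n_divergent,n_shared numbers of planted divergent/shared
#'   columns (`n_divergent + n_shared <= L`).
#' @param noise_rate per-residue substitution noise in `[0, 0.5)`.
#' @param gap_rate per-residue gap rate for non-reference sequences.
#' @param seed RNG seed (state restored on exit).
#' @param alphabet a `reduced_alphabet`.
#' @return list with `aln_a`, `aln_b` (`family_alignment`s named
#'   `"famA"`/`"famB"`) and `truth` (list: `divergent_positions`,
#'   `shared_positions`, `class_a`, `class_b`, `noise_rate`, `seed`).
#' @examples
#' fp <- make_family_pair(n_per_family = 5, L = 30, n_divergent = 3,
#'                        n_shared = 2, seed = 7)
#' fp$truth$divergent_positions
#' @export
make_family_pair <- function(n_per_family = 20, L = 120,
                             n_divergent = 10, n_shared = 10,
                             noise_rate = 0, gap_rate = 0, seed = 1L,
                             alphabet = reduced_alphabet()) {
  if (n_divergent + n_shared > L)
    stop("n_divergent + n_shared must be <= L")
  if (noise_rate < 0 || noise_rate >= 0.5)
    stop("noise_rate must be in [0, 0.5)")
  local_seed(seed)
  planted <- sample.int(L, n_divergent + n_shared)
  div_pos <- sort(planted[seq_len(n_divergent)])
  shr_pos <- sort(planted[n_divergent + seq_len(n_shared)])
  classes <- names(alphabet)
  class_a <- character(0); class_b <- character(0)
  if (n_divergent > 0) {
    class_a <- sample(classes, n_divergent, replace = TRUE)
    class_b <- vapply(class_a, function(c1)
      sample(setdiff(classes, c1), 1L), character(1))
  }
  class_s <- if (n_shared > 0) sample(classes, n_shared, replace = TRUE)
  else character(0)

  draw_family <- function(div_classes, fam) {
    m <- matrix(sample(unname(AA1), n_per_family * L, replace = TRUE),
                n_per_family, L)
    for (k in seq_along(div_pos))
      m[, div_pos[k]] <- sample(alphabet[[div_classes[k]]],
                                n_per_family, replace = TRUE)
    for (k in seq_along(shr_pos))
      m[, shr_pos[k]] <- sample(alphabet[[class_s[k]]],
                                n_per_family, replace = TRUE)
    if (noise_rate > 0) {
      hit <- matrix(stats::runif(n_per_family * L) < noise_rate,
                    n_per_family, L)
      m[hit] <- sample(unname(AA1), sum(hit), replace = TRUE)
    }
    if (gap_rate > 0) {
      hit <- matrix(stats::runif(n_per_family * L) < gap_rate,
                    n_per_family, L)
      hit[1L, ] <- FALSE   # reference stays ungapped
      m[hit] <- "-"
    }
    seqs <- apply(m, 1L, paste, collapse = "")
    names(seqs) <- c(paste0(fam, "_ref"),
                     sprintf("%s_%02d", fam, seq_len(n_per_family - 1L)))
    family_alignment(seqs, fam)
  }
  list(aln_a = draw_family(class_a, "famA"),
       aln_b = draw_family(class_b, "famB"),
       truth = list(divergent_positions = div_pos,
                    shared_positions = shr_pos,
                    class_a = unname(class_a), class_b = unname(class_b),
                    class_shared = unname(class_s),
                    noise_rate = noise_rate, seed = seed))
}

# Seeded RNG with caller state restored when the caller exits.
local_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(seed, .local_envir = env)
}
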