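# Static per-residue chemistry dictionaries used by the interaction
# detectors and the pharmacophore extractor.  Atom names follow PDB v3
# conventions.  These tables are data, not tunables: the geometric
# cutoffs live in geometry_config().

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

AA3_FROM_1 <- stats::setNames(names(AA1), AA1)

#' One- and three-letter amino-acid code conversion
#'
#' @param x character vector of three-letter (`aa321`) or one-letter
#'   (`aa123`) residue codes.
#' @return character vector of converted codes; unknown codes become `NA`.
#' @examples
#' aa321(c("LYS", "ASP"))
#' aa123(c("K", "D"))
#' @export
aa321 <- function(x) unname(AA1[toupper(x)])

#' @rdname aa321
#' @export
aa123 <- function(x) unname(AA3_FROM_1[toupper(x)])

# Backbone atom names (OXT = C-terminal carboxylate oxygen).
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# Hydrogen-bond donor heavy atoms (N/O carrying at least one polar H in
# the protonated residue).  Backbone amide N is a donor for every
# residue except proline.
HB_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"),
  ASN = "ND2",
  GLN = "NE2",
  HIS = c("ND1", "NE2"),
  LYS = "NZ",
  SER = "OG",
  THR = "OG1",
  TRP = "NE1",
  TYR = "OH"
)

# Hydrogen-bond acceptor heavy atoms; backbone carbonyl O (and OXT)
# accepts for every residue.
HB_ACCEPTORS <- list(
  ASN = "OD1",
  ASP = c("OD1", "OD2"),
  GLN = "OE1",
  GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"),
  SER = "OG",
  THR = "OG1",
  TYR = "OH"
)

# Side-chain charged groups for salt-bridge / ionic detection.
# Histidine is optionally cationic (see geometry_config()).
CATIONIC_ATOMS <- list(
  ARG = c("NH1", "NH2", "NE"),
  LYS = "NZ"
)
CATIONIC_ATOMS_HIS <- list(HIS = c("ND1", "NE2"))

ANIONIC_ATOMS <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2")
)

# Apolar carbons: side-chain carbon atoms bonded only to carbon or
# hydrogen.  Derived once from residue connectivity; carbons bonded to
# N, O or S (e.g. LYS CE, ARG CD, SER CB, MET CG/CE) are excluded, as
# is CA (bonded to backbone N).  Hydrophobic contacts are defined over
# these atoms for every residue type, not over a residue whitelist, so
# e.g. the aliphatic stem of an arginine side chain can register a
# hydrophobic contact.
APOLAR_CARBONS <- list(
  ALA = "CB",
  ARG = c("CB", "CG"),
  ASN = "CB",
  ASP = "CB",
  GLN = c("CB", "CG"),
  GLU = c("CB", "CG"),
  HIS = "CB",
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD"),
  MET = "CB",
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG"),
  THR = "CG2",
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  VAL = c("CB", "CG1", "CG2")
)

# Aromatic ring systems for cation-pi detection; TRP contributes both
# rings and the nearest centroid is used.
AROMATIC_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
)
AROMATIC_RINGS_HIS <- list(HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")))

# Cation-pi cation anchors: LYS ammonium nitrogen; ARG CZ as a proxy
# for the guanidinium centroid.
CATION_PI_CATIONS <- list(LYS = "NZ", ARG = "CZ")

#' Default physicochemical reduced alphabet
#'
#' Partition of the 20 standard amino acids into physicochemical
#' classes: `NEUTRAL` (N, Q, S, T), `ACIDIC` (D, E), `BASIC` (K, R),
#' `AROMATIC` (F, Y, W), `ALIPHATIC` (V, A, L, I, M), and the
#' singleton classes `C`, `P`, `H` and `G`.  Conservation under this
#' alphabet means conservation of side-chain chemistry rather than of
#' residue identity.
#'
#' @param classes named list mapping class labels to character vectors
#'   of one-letter residue codes.  The default is the partition above.
#' @return an object of class `reduced_alphabet`: the validated list,
#'   with a `lookup` attribute mapping each residue to its class.
#' @examples
#' ab <- reduced_alphabet()
#' residue_class("K", ab)  # "BASIC"
#' @export
reduced_alphabet <- function(classes = list(
    NEUTRAL   = c("N", "Q", "S", "T"),
    ACIDIC    = c("D", "E"),
    BASIC     = c("K", "R"),
    AROMATIC  = c("F", "Y", "W"),
    ALIPHATIC = c("V", "A", "L", "I", "M"),
    C = "C", P = "P", H = "H", G = "G")) {
  stopifnot(is.list(classes), !is.null(names(classes)))
  all_res <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(all_res))
    stop("reduced alphabet classes overlap: ",
         paste(unique(all_res[duplicated(all_res)]), collapse = ", "))
  missing <- setdiff(unname(AA1), all_res)
  if (length(missing))
    stop("reduced alphabet does not cover: ", paste(missing, collapse = ", "))
  lookup <- stats::setNames(
    rep(names(classes), lengths(classes)), all_res)
  structure(classes, lookup = lookup, class = "reduced_alphabet")
}

#' @rdname reduced_alphabet
#' @param x character vector of one-letter residue codes.
#' @param alphabet a `reduced_alphabet` object.
#' @export
residue_class <- function(x, alphabet = reduced_alphabet()) {
  lk <- attr(alphabet, "lookup")
  unname(lk[toupper(x)])
}

# Pharmacophore feature dictionary: residue -> list of
# (feature, anchor specification).  Anchor spec is either an atom name,
# "ring_centroid", "carboxylate_mid", or "sidechain_carbons".
PHARMACOPHORE_DICT <- list(
  SER = list(c("DONOR", "OG"), c("ACCEPTOR", "OG")),
  THR = list(c("DONOR", "OG1"), c("ACCEPTOR", "OG1")),
  ASP = list(c("ANION", "carboxylate_mid")),
  GLU = list(c("ANION", "carboxylate_mid")),
  LYS = list(c("CATION", "NZ")),
  ARG = list(c("CATION", "CZ")),
  PHE = list(c("AROMATIC", "ring_centroid")),
  TYR = list(c("AROMATIC", "ring_centroid"), c("DONOR", "OH")),
  TRP = list(c("AROMATIC", "ring_centroid")),
  VAL = list(c("HYDROPHOBE", "sidechain_carbons")),
  ALA = list(c("HYDROPHOBE", "sidechain_carbons")),
  LEU = list(c("HYDROPHOBE", "sidechain_carbons")),
  ILE = list(c("HYDROPHOBE", "sidechain_carbons")),
  MET = list(c("HYDROPHOBE", "sidechain_carbons")),
  PRO = list(c("HYDROPHOBE", "sidechain_carbons")),
  ASN = list(c("DONOR", "ND2"), c("ACCEPTOR", "OD1")),
  GLN = list(c("DONOR", "NE2"), c("ACCEPTOR", "OE1")),
  CYS = list(c("HYDROPHOBE", "SG"), c("DONOR", "SG")),
  HIS = list(c("DONOR", "NE2"), c("AROMATIC", "ring_centroid"))
  # GLY: no side chain, no feature
)
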