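#' Curated binding-specificity residue tables for the human
#' gonadotropin system
#'
#' Literature-curated residue-level reference data for the two human
#' gonadotropin complexes: FSH bound to the FSH-receptor ectodomain
#' and LH bound to the LH/CG-receptor ectodomain.  For each molecule
#' the table lists the binding-specificity residues (author
#' numbering), the wild-type residue, the interface shell, and the
#' residue found at the corresponding position in the paralogous
#' family's human reference sequence (the basis of family-swap mutant
#' design).  Hormone positions for the LH family are given in FSH
#' numbering as well (`pos_in_other`), reflecting the cross-family
#' correspondence; receptor numbering coincides across the two
#' receptors at all listed positions.
#'
#' @return list with elements `receptor` and `hormone`, each a
#'   data.frame with columns `family` (`"FSHR"`/`"LHR"` or
#'   `"FSH"`/`"LH"`), `position`, `wt`, `shell`, `partner`
#'   (corresponding residue in the other family's human reference).
#' @examples
#' gonadotropin_bsrs()$receptor
#' @export
gonadotropin_bsrs <- function() {
  receptor <- data.frame(
    family = c(rep("FSHR", 9L), rep("LHR", 7L)),
    position = c(50, 52, 54, 55, 101, 103, 104, 179, 221,
                 54, 55, 101, 103, 128, 178, 199),
    wt = c("E", "R", "V", "L", "R", "E", "K", "K", "V",
           "A", "Y", "L", "Q", "C", "Y", "E"),
    shell = c("FIRST", "SECOND", "SECOND", "FIRST", "FIRST", "SECOND",
              "FIRST", "FIRST", "FIRST",
              "SECOND", "FIRST", "FIRST", "FIRST", "SECOND", "FIRST",
              "FIRST"),
    partner = c("R", "S", "A", "Y", "L", "Q", "N", "G", "K",
                "V", "L", "R", "E", "S", "N", "N"),
    stringsAsFactors = FALSE)
  hormone <- data.frame(
    family = c(rep("FSH", 7L), rep("LH", 4L)),
    position = c(42, 89, 90, 95, 96, 97, 103, 89, 97, 98, 105),
    wt = c("P", "S", "D", "T", "V", "R", "Y", "R", "P", "K", "D"),
    shell = "FIRST",
    partner = c("V", "R", "S", "G", "G", "P", "T", "S", "R", "G", "S"),
    stringsAsFactors = FALSE)
  list(receptor = receptor, hormone = hormone)
}

#' Synthetic FSH-family alignment encoding the curated conservation
#' classes
#'
#' Builds a small synthetic stand-in for an FSH beta-subunit family
#' alignment: every sequence carries, at each curated
#' binding-specificity position, a residue of the class conserved in
#' the FSH family (cycling through the class members across
#' sequences), and a common filler elsewhere.  Companion aligned
#' queries encode LH-type sequences: a generic LH (carrying the
#' LH-family residue at every FSH BSR position), a horse-type LH
#' (valine at position 96) and a chicken-type LH (proline at position
#' 42).  These objects replay the curated residue-level facts; they
#' are synthetic sequences, not database records.
#'
#' @param n_seq sequences in the family alignment.
#' @param L alignment length (ungapped), covering all BSR positions.
#' @return list with `aln` (a `family_alignment` named `"FSH"`),
#'   `bsr_positions`, and aligned query strings `query_lh`,
#'   `query_horse_lh`, `query_chicken_lh`.
#' @export
synthetic_fsh_family <- function(n_seq = 8L, L = 111L) {
  ref <- gonadotropin_bsrs()$hormone
  fsh <- ref[ref$family == "FSH", , drop = FALSE]
  ab <- reduced_alphabet()
  filler <- "A"
  seqs <- character(n_seq)
  for (i in seq_len(n_seq)) {
    s <- rep(filler, L)
    for (k in seq_len(nrow(fsh))) {
      cls <- residue_class(fsh$wt[k], ab)
      members <- ab[[cls]]
      s[fsh$position[k]] <- if (i == 1L) fsh$wt[k]
      else members[((i - 2L) %% length(members)) + 1L]
    }
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- c("FSH_ref", sprintf("FSH_%02d", seq_len(n_seq - 1L)))
  lh_query <- function(overrides = NULL) {
    s <- rep(filler, L)
    for (k in seq_len(nrow(fsh))) s[fsh$position[k]] <- fsh$partner[k]
    # the LH family conserves leucine at the position corresponding to
    # FSH 42
    s[42L] <- "L"
    if (!is.null(overrides))
      for (p in names(overrides)) s[as.integer(p)] <- overrides[[p]]
    paste(s, collapse = "")
  }
  list(aln = family_alignment(seqs, "FSH"),
       bsr_positions = fsh$position,
       query_lh = lh_query(),
       query_horse_lh = lh_query(list("96" = "V")),
       query_chicken_lh = lh_query(list("42" = "P")))
}
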