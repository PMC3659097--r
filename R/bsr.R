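#' Call binding-specificity residues (BSRs)
#'
#' Integrates the structural and the sequence evidence: a receptor
#' residue is called a BSR iff it is in the first or second interface
#' shell and its alignment position is conserved within the receptor's
#' own family but class-divergent from the paralogous family.
#' Hormone-side BSRs are called analogously over first-shell contact
#' residues only.
#'
#' With `admit_structural_only = TRUE`, shell residues whose position
#' is not divergent are also reported, flagged `waived = TRUE`; this
#' permissive mode reflects curated BSR sets that admit residues on
#' structural evidence alone even when the class divergence is only
#' partial.  Under the default, BSR positions are always a subset of
#' the divergent positions.
#'
#' @param shells shell assignments from [assign_shells()].
#' @param divergent_receptor divergent-position pairs for the receptor
#'   families ([call_divergent_positions()]), with `pos_a` in the
#'   receptor's own family numbering.
#' @param divergent_hormone divergent pairs for the hormone families,
#'   `pos_a` in the hormone's own numbering.
#' @param admit_structural_only keep non-divergent shell residues,
#'   flagged as waived.
#' @param map_receptor,map_hormone optional named integer vectors
#'   mapping structure residue numbers to alignment reference
#'   positions (names = structure numbers); by default structure and
#'   alignment numbering are taken to agree.  Unmappable residues are
#'   skipped with a warning.
#' @return data.frame of class `bsr_calls`: `entity`, `chain`,
#'   `resno`, `resid`, `label`, `shell`, `refpos`, `own_class`,
#'   `other_class`, `conservation_own`, `conservation_other`,
#'   `waived`, `n_evidence`, `evidence`.
#' @export
call_bsrs <- function(shells, divergent_receptor = NULL,
                      divergent_hormone = NULL,
                      admit_structural_only = FALSE,
                      map_receptor = NULL, map_hormone = NULL) {
  if (nrow(shells) == 0L) return(empty_bsrs())
  rows <- list()
  for (i in seq_len(nrow(shells))) {
    sh <- shells[i, , drop = FALSE]
    if (sh$entity == "hormone" && sh$shell != "FIRST") next
    div <- if (sh$entity == "receptor") divergent_receptor
    else divergent_hormone
    map <- if (sh$entity == "receptor") map_receptor else map_hormone
    refpos <- sh$resno
    if (!is.null(map)) {
      refpos <- unname(map[as.character(sh$resno)])
      if (is.na(refpos)) {
        warning("unmappable position ", sh$label, " (", sh$entity,
                "); skipped")
        next
      }
    }
    hit <- if (is.null(div)) integer() else which(div$pos_a == refpos)
    if (length(hit) == 0L && !admit_structural_only) next
    h <- if (length(hit)) hit[1L] else NA_integer_
    rows[[length(rows) + 1L]] <- data.frame(
      entity = sh$entity, chain = sh$chain, resno = sh$resno,
      resid = sh$resid, label = sh$label, shell = sh$shell,
      refpos = refpos,
      own_class = if (!is.na(h)) div$class_a[h] else NA_character_,
      other_class = if (!is.na(h)) div$class_b[h] else NA_character_,
      conservation_own = if (!is.na(h)) div$conservation_a[h]
      else NA_real_,
      conservation_other = if (!is.na(h)) div$conservation_b[h]
      else NA_real_,
      waived = is.na(h),
      n_evidence = sh$n_evidence, evidence = sh$evidence,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_bsrs())
  out <- do.call(rbind, rows)
  out <- out[order(out$entity, out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bsr_calls", "data.frame")
  out
}

empty_bsrs <- function() {
  out <- data.frame(entity = character(), chain = character(),
                    resno = integer(), resid = character(),
                    label = character(), shell = character(),
                    refpos = integer(), own_class = character(),
                    other_class = character(),
                    conservation_own = numeric(),
                    conservation_other = numeric(),
                    waived = logical(), n_evidence = integer(),
                    evidence = character(), stringsAsFactors = FALSE)
  class(out) <- c("bsr_calls", "data.frame")
  out
}

#' Family-swap mutant substitution table
#'
#' For each BSR of molecule A, looks up the corresponding position in
#' the paralogous family's reference sequence and emits a substitution
#' `wt` -> `other-family residue`, rendered in the conventional
#' `"E50R"` style.  Identity substitutions (both families carry the
#' same residue) are skipped; positions whose partner is a gap or
#' outside the other reference are omitted with a warning.
#'
#' @param bsrs either a `bsr_calls` data.frame (rows for one molecule)
#'   or a data.frame with columns `position` and `wt` (one-letter).
#' @param correspondence a `correspondence_map` with `pos_a` in the
#'   BSR numbering and `pos_b` in the other reference's numbering.
#' @param other_reference ungapped reference sequence of the other
#'   family (string), numbered from `other_start`.
#' @param molecule_id label stored on the result.
#' @param other_start first residue number of `other_reference`.
#' @return data.frame of class `mutant_spec` with columns `position`,
#'   `wt`, `mut`, `string`; `molecule_id` kept as an attribute.
#' @examples
#' bsrs <- data.frame(position = c(50, 103), wt = c("E", "E"))
#' make_mutant_spec(bsrs, identity_correspondence(c(50, 103)),
#'                  other_reference = paste(rep("Q", 110), collapse = ""),
#'                  molecule_id = "demo")
#' @export
make_mutant_spec <- function(bsrs, correspondence, other_reference,
                             molecule_id = "mutant", other_start = 1L) {
  tab <- normalize_bsr_positions(bsrs)
  if (anyDuplicated(tab$position))
    stop("duplicate BSR positions in mutant specification")
  other <- strsplit(toupper(other_reference), "")[[1L]]
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    p <- tab$position[i]
    q <- correspondence$pos_b[match(p, correspondence$pos_a)]
    if (is.na(q)) {
      warning("no correspondence partner for position ", p,
              "; substitution omitted")
      next
    }
    j <- q - other_start + 1L
    if (j < 1L || j > length(other) || other[j] %in% c("-", ".")) {
      warning("gap/out-of-range partner for position ", p,
              "; substitution omitted")
      next
    }
    mut <- other[j]
    if (identical(mut, tab$wt[i])) next   # identity substitution
    rows[[length(rows) + 1L]] <- data.frame(
      position = p, wt = tab$wt[i], mut = mut,
      string = paste0(tab$wt[i], p, mut), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(position = integer(), wt = character(),
                  mut = character(), string = character(),
                  stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "molecule_id") <- molecule_id
  class(out) <- c("mutant_spec", "data.frame")
  out
}

normalize_bsr_positions <- function(bsrs) {
  if (all(c("position", "wt") %in% names(bsrs))) {
    data.frame(position = as.integer(bsrs$position),
               wt = toupper(bsrs$wt), stringsAsFactors = FALSE)
  } else if (all(c("refpos", "resid") %in% names(bsrs))) {
    data.frame(position = as.integer(bsrs$refpos),
               wt = aa321(bsrs$resid), stringsAsFactors = FALSE)
  } else {
    stop("bsrs must have columns position/wt or refpos/resid")
  }
}

#' @export
print.mutant_spec <- function(x, ...) {
  cat("<mutant_spec> ", attr(x, "molecule_id"), ": ",
      paste(x$string, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Apply a mutant specification to a sequence
#'
#' @param sequence ungapped sequence (string) numbered from
#'   `ref_start`.
#' @param spec a `mutant_spec`.
#' @param ref_start first residue number of `sequence`.
#' @return the mutated sequence (string).  Errors if a wild-type
#'   residue in `spec` does not match `sequence`.
#' @export
apply_mutant_spec <- function(sequence, spec, ref_start = 1L) {
  s <- strsplit(toupper(sequence), "")[[1L]]
  for (i in seq_len(nrow(spec))) {
    j <- spec$position[i] - ref_start + 1L
    if (j < 1L || j > length(s))
      stop("position ", spec$position[i], " outside sequence")
    if (s[j] != spec$wt[i])
      stop("wild-type mismatch at ", spec$position[i], ": sequence has ",
           s[j], ", spec expects ", spec$wt[i])
    s[j] <- spec$mut[i]
  }
  paste(s, collapse = "")
}

#' Cross-species compatibility of a query sequence with a family's
#' BSR positions
#'
#' Checks, for every BSR position of a cognate family, whether a query
#' sequence (e.g. the paralogous hormone of another species) carries a
#' residue of the class conserved in that family.  A high score means
#' the query is class-compatible with the cognate family at its
#' specificity positions, the signature behind observed cross-species
#' cross-reactivity.
#'
#' @param query aligned query sequence: a string with the same columns
#'   as the family alignment used for `profiles`.
#' @param aln the cognate `family_alignment` (provides the
#'   column-to-position map the query is aligned to).
#' @param profiles `column_profiles` of the cognate family.
#' @param bsr_positions integer vector of BSR positions (family
#'   reference numbering).
#' @param alphabet a `reduced_alphabet`.
#' @param query_id label for the report.
#' @return object of class `compatibility_report`: list with
#'   `query_id`, `family_id`, `per_position` (data.frame: `position`,
#'   `cognate_class`, `query_residue`, `query_class`, `match`,
#'   `unresolved`) and `score` (matches / evaluated positions;
#'   unresolved positions excluded from the denominator).
#' @export
cross_react <- function(query, aln, profiles, bsr_positions,
                        alphabet = reduced_alphabet(),
                        query_id = "query") {
  stopifnot(inherits(aln, "family_alignment"))
  q <- strsplit(toupper(query), "")[[1L]]
  if (length(q) != aln$ncol)
    stop("query must be aligned to the family alignment (",
         aln$ncol, " columns)")
  lookup <- attr(alphabet, "lookup")
  rows <- lapply(sort(unique(as.integer(bsr_positions))), function(p) {
    j <- which(aln$col2ref == p)
    k <- match(p, profiles$refpos)
    cognate <- if (!is.na(k)) {
      if (!is.na(profiles$conserved_class[k]))
        profiles$conserved_class[k] else profiles$modal_class[k]
    } else NA_character_
    qr <- if (length(j) == 1L) q[j] else NA_character_
    qc <- if (!is.na(qr)) unname(lookup[qr]) else NA_character_
    unresolved <- is.na(qc) || is.na(cognate)
    data.frame(position = p, cognate_class = cognate,
               query_residue = qr, query_class = qc,
               match = if (unresolved) NA else qc == cognate,
               unresolved = unresolved, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  evaluated <- sum(!per$unresolved)
  structure(list(query_id = query_id, family_id = aln$family_id,
                 per_position = per,
                 score = if (evaluated > 0)
                   sum(per$match, na.rm = TRUE) / evaluated
                 else NA_real_),
            class = "compatibility_report")
}

#' @export
print.compatibility_report <- function(x, ...) {
  cat("<compatibility_report> ", x$query_id, " vs ", x$family_id,
      " BSR positions: score ",
      sprintf("%.2f", x$score), "\n", sep = "")
  print(x$per_position, row.names = FALSE)
  invisible(x)
}

# ring used as the pharmacophore AROMATIC anchor: the six-membered
# ring for TRP, the single ring otherwise
pharma_ring <- function(res) {
  nm <- res$resid[1L]
  rings <- c(AROMATIC_RINGS, AROMATIC_RINGS_HIS)[[nm]]
  if (is.null(rings)) return(NULL)
  ring <- rings[[length(rings)]]
  idx <- match(ring, res$elety)
  if (anyNA(idx)) return(NULL)
  colMeans(as.matrix(res[idx, c("x", "y", "z")]))
}

#' Extract a pharmacophore feature template from residue side chains
#'
#' Maps each residue of a peptidic stretch to abstract pharmacophore
#' features anchored at representative side-chain coordinates,
#' producing a template for peptidomimetic design: serine/threonine
#' hydroxyls give donor+acceptor points, carboxylates an anion point at
#' the O-O midpoint, lysine/arginine a cation point (NZ / CZ),
#' aromatics a ring-centroid point (tyrosine also a donor at OH),
#' aliphatics and proline a hydrophobe at the side-chain carbon
#' centroid, amides donor+acceptor, cysteine hydrophobe+donor at SG,
#' histidine donor+aromatic; glycine contributes nothing.
#'
#' @param model a `structure_model`.
#' @param chain chain identifier of the stretch.
#' @param range integer vector of residue numbers (e.g. `89:103`).
#' @param bsr_positions optional integer vector; when given and
#'   `include_non_bsr = FALSE`, only these residues contribute
#'   features.
#' @param include_non_bsr include non-BSR residues of the stretch.
#' @return data.frame of class `pharmacophore`: `chain`, `resno`,
#'   `resid`, `label`, `feature`, `x`, `y`, `z`, `anchor`
#'   (description of the anchoring atom(s)).
#' @export
extract_pharmacophore <- function(model, chain, range,
                                  bsr_positions = NULL,
                                  include_non_bsr = is.null(bsr_positions)) {
  sel <- model$chain == chain & model$resno %in% range &
    !model$is_hydrogen
  if (!any(sel)) stop("no residues in the requested stretch")
  if (!is.null(bsr_positions) && !include_non_bsr)
    sel <- sel & model$resno %in% bsr_positions
  sub <- model[sel, , drop = FALSE]
  rows <- list()
  for (key in unique(sub$reskey)) {
    res <- sub[sub$reskey == key, , drop = FALSE]
    feats <- PHARMACOPHORE_DICT[[res$resid[1L]]]
    if (is.null(feats)) next   # glycine or unknown
    for (f in feats) {
      anchor <- pharma_anchor(res, f[2L])
      if (is.null(anchor)) {
        warning("missing side-chain atoms for ", res$resid[1L], " ",
                res$resno[1L], " (", f[1L], " skipped)")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chain = res$chain[1L], resno = res$resno[1L],
        resid = res$resid[1L],
        label = residue_label(res$resno[1L], res$resid[1L]),
        feature = f[1L],
        x = anchor$xyz[1L], y = anchor$xyz[2L], z = anchor$xyz[3L],
        anchor = anchor$desc, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(chain = character(), resno = integer(),
                  resid = character(), label = character(),
                  feature = character(), x = numeric(), y = numeric(),
                  z = numeric(), anchor = character(),
                  stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pharmacophore", "data.frame")
  out
}

pharma_anchor <- function(res, spec) {
  if (spec == "ring_centroid") {
    xyz <- pharma_ring(res)
    if (is.null(xyz)) return(NULL)
    return(list(xyz = xyz, desc = "ring centroid"))
  }
  if (spec == "carboxylate_mid") {
    atoms <- if (res$resid[1L] == "ASP") c("OD1", "OD2")
    else c("OE1", "OE2")
    idx <- match(atoms, res$elety)
    if (anyNA(idx)) return(NULL)
    return(list(xyz = colMeans(as.matrix(res[idx, c("x", "y", "z")])),
                desc = paste(atoms, collapse = "/")))
  }
  if (spec == "sidechain_carbons") {
    idx <- which(res$is_sidechain & res$element == "C")
    if (!length(idx)) return(NULL)
    return(list(xyz = colMeans(as.matrix(res[idx, c("x", "y", "z"),
                                             drop = FALSE])),
                desc = "side-chain C centroid"))
  }
  idx <- match(spec, res$elety)
  if (is.na(idx)) return(NULL)
  list(xyz = as.numeric(res[idx, c("x", "y", "z")]), desc = spec)
}

#' Write a pharmacophore template as JSON
#'
#' @param ph a `pharmacophore` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pharmacophore_json <- function(ph, path) {
  jsonlite::write_json(
    lapply(seq_len(nrow(ph)), function(i)
      list(feature = ph$feature[i], x = ph$x[i], y = ph$y[i],
           z = ph$z[i], residue = ph$label[i], chain = ph$chain[i])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
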