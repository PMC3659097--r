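#' Read a PDB file into a structure model
#'
#' Parses a PDB file (via [bio3d::read.pdb()]) into a flat atom table
#' suitable for geometric interface analysis.  Waters and all other
#' HETATM records are removed, alternate locations are resolved, and
#' non-standard residues are dropped with a warning.  Hydrogens, if
#' deposited, are retained but flagged; the interaction detectors use
#' heavy-atom criteria by default.
#'
#' Residues keep their author (deposited) numbering throughout: all
#' residue labels produced by the package (e.g. `"50E"`) are in author
#' numbering, so they can be compared directly with labels used in the
#' structural literature.
#'
#' @param path path to a PDB file.
#' @param altloc_policy how to resolve alternate locations; currently
#'   only `"occupancy"` (keep the highest-occupancy conformer, ties
#'   broken by alt-loc label order) is implemented.
#' @return an object of class `structure_model`: a `data.frame` with one
#'   row per atom and columns `chain`, `resno`, `insert`, `resid`
#'   (3-letter code), `elety` (PDB atom name), `element`, `x`, `y`, `z`,
#'   `occ`, `is_sidechain`, `is_hydrogen`, and `reskey` (a unique
#'   `chain:resno:insert` residue identifier).  The structure id (file
#'   basename) is stored in the `"id"` attribute.
#' @seealso [select_entities()], [detect_interactions()]
#' @export
read_structure <- function(path, altloc_policy = c("occupancy")) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  std <- at$resid %in% AA3
  if (any(!std)) {
    bad <- unique(at$resid[!std])
    warning("dropping non-standard residue(s): ", paste(bad, collapse = ", "))
    at <- at[std, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("zero standard residues in '", path, "'")

  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  at$alt <- ifelse(is.na(at$alt), "", at$alt)
  at$occ <- ifelse(is.na(at$o), 1, at$o)

  # alt-loc resolution: within each (residue, atom name) group keep the
  # highest-occupancy record; ties break deterministically on the
  # alt-loc label, then file order.
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key, -at$occ, at$alt, seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                               sep = "\r")), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate atom records remain after alt-loc resolution")

  element <- at$elesy
  element[is.na(element) | element == ""] <-
    infer_element(at$elety[is.na(element) | element == ""])
  if (any(is.na(element) | element == ""))
    stop("could not infer element for atom(s): ",
         paste(unique(at$elety[is.na(element) | element == ""]),
               collapse = ", "))

  model <- data.frame(
    chain = at$chain,
    resno = at$resno,
    insert = at$insert,
    resid = at$resid,
    elety = at$elety,
    element = element,
    x = at$x, y = at$y, z = at$z,
    occ = at$occ,
    stringsAsFactors = FALSE
  )
  model$is_hydrogen <- model$element %in% c("H", "D")
  model$is_sidechain <- !(model$elety %in% BACKBONE_ATOMS) & !model$is_hydrogen
  model$reskey <- reskey(model$chain, model$resno, model$insert)
  if (!all(is.finite(c(model$x, model$y, model$z))))
    stop("non-finite coordinates in '", path, "'")
  structure_model(model, id = sub("\\.pdb$", "", basename(path),
                                  ignore.case = TRUE))
}

# Element inference from a PDB atom name when columns 77-78 are blank:
# strip digits/primes, first remaining letter (handles "NZ", "OD1",
# "1HB", "CA").
infer_element <- function(elety) {
  vapply(elety, function(nm) {
    nm <- gsub("[0-9']", "", nm)
    if (nchar(nm) == 0L) return(NA_character_)
    substr(nm, 1L, 1L)
  }, character(1), USE.NAMES = FALSE)
}

reskey <- function(chain, resno, insert = "") {
  paste0(chain, ":", resno, ifelse(insert == "", "", paste0(":", insert)))
}

structure_model <- function(df, id = "structure") {
  stopifnot(is.data.frame(df), nrow(df) >= 1L)
  attr(df, "id") <- id
  class(df) <- c("structure_model", "data.frame")
  df
}

#' @export
print.structure_model <- function(x, ...) {
  res <- residue_table(x)
  cat("<structure_model> ", attr(x, "id"), "\n", sep = "")
  cat("  ", nrow(x), " atoms, ", nrow(res), " residues, chains: ",
      paste(sort(unique(x$chain)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Residue-level summary of a structure model
#'
#' @param model a `structure_model`.
#' @return data.frame with one row per residue: `chain`, `resno`,
#'   `insert`, `resid`, `reskey`, `n_atoms`, and `label` (author number
#'   plus one-letter code, e.g. `"50E"`).
#' @export
residue_table <- function(model) {
  idx <- !duplicated(model$reskey) & !model$is_hydrogen
  res <- model[idx, c("chain", "resno", "insert", "resid", "reskey")]
  res$n_atoms <- as.integer(table(model$reskey)[res$reskey])
  res$label <- residue_label(res$resno, res$resid)
  rownames(res) <- NULL
  res
}

residue_label <- function(resno, resid) paste0(resno, aa321(resid))

#' Write a structure model back to PDB
#'
#' Normalized re-export of a parsed model (standard residues only,
#' alt-locs already resolved).  Round-tripping through
#' [read_structure()] preserves residue identities and coordinates to
#' the PDB format precision (1e-3 Angstrom).
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  xyz <- as.vector(t(as.matrix(model[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path,
                   xyz = xyz,
                   type = rep("ATOM", nrow(model)),
                   resno = model$resno,
                   resid = model$resid,
                   eleno = seq_len(nrow(model)),
                   elety = model$elety,
                   chain = model$chain,
                   insert = ifelse(model$insert == "", NA, model$insert),
                   o = model$occ,
                   b = rep(0, nrow(model)),
                   elesy = model$element)
  invisible(path)
}

#' Declare which chains are the hormone and which the receptor
#'
#' Entity assignment is always explicit: chain identities come from the
#' caller (typically a pipeline configuration), never guessed from the
#' file.  For a gonadotropin complex the hormone entity is normally the
#' beta-subunit chain and the receptor entity the ectodomain chain.
#'
#' @param model a `structure_model`.
#' @param hormone_chains,receptor_chains character vectors of chain
#'   identifiers; must be disjoint, non-empty and present in `model`.
#' @return an object of class `entity_selection` with elements
#'   `hormone_chains` and `receptor_chains`.
#' @examples
#' \dontrun{
#' sel <- select_entities(model, hormone_chains = "B",
#'                        receptor_chains = "X")
#' }
#' @export
select_entities <- function(model, hormone_chains, receptor_chains) {
  hormone_chains <- as.character(hormone_chains)
  receptor_chains <- as.character(receptor_chains)
  if (length(hormone_chains) == 0L || length(receptor_chains) == 0L)
    stop("hormone and receptor chain sets must be non-empty")
  present <- unique(model$chain)
  unknown <- setdiff(c(hormone_chains, receptor_chains), present)
  if (length(unknown))
    stop("unknown chain(s): ", paste(unknown, collapse = ", "))
  if (length(intersect(hormone_chains, receptor_chains)))
    stop("overlapping sets: hormone and receptor chains must be disjoint")
  structure(list(hormone_chains = hormone_chains,
                 receptor_chains = receptor_chains),
            class = "entity_selection")
}

#' @export
print.entity_selection <- function(x, ...) {
  cat("<entity_selection> hormone:",
      paste(x$hormone_chains, collapse = " "),
      "| receptor:", paste(x$receptor_chains, collapse = " "), "\n")
  invisible(x)
}

# Which entity does each atom belong to? Returns "hormone", "receptor"
# or NA.
entity_of <- function(model, selection) {
  out <- rep(NA_character_, nrow(model))
  out[model$chain %in% selection$hormone_chains] <- "hormone"
  out[model$chain %in% selection$receptor_chains] <- "receptor"
  out
}
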