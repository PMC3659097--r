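#' Assign first- and second-shell interface residues
#'
#' First-shell residues of the receptor are those that make at least
#' one direct inter-molecular interaction with the hormone.
#' Second-shell residues do not touch the hormone themselves but make
#' an intra-molecular interaction (any of the five types) with a
#' first-shell residue, stabilizing the binding epitope.  A residue in
#' both categories is first shell; the sets are disjoint.
#'
#' An optional proximity limit keeps the second shell within the
#' interface region: a second-shell candidate must additionally have at
#' least one atom within `proximity_limit` of any hormone atom
#' (default 8 Angstrom; set `NULL` to disable the filter).
#'
#' Hormone-side first-shell residues are reported too; a hormone-side
#' second shell can be enabled with `hormone_second_shell = TRUE`.
#'
#' @param inter inter-molecular interaction records
#'   ([detect_interactions()] with `scope = "inter"`).
#' @param intra intra-molecular records for the receptor (`scope =
#'   "intra"`); pass the hormone-internal records as `intra_hormone`
#'   when the hormone second shell is enabled.
#' @param selection an `entity_selection`.
#' @param model the `structure_model` (needed for the proximity
#'   filter).
#' @param proximity_limit Angstrom, or `NULL` for no proximity filter.
#' @param hormone_second_shell also compute the hormone-side second
#'   shell (off by default).
#' @param intra_hormone hormone-internal interaction records (only used
#'   when `hormone_second_shell = TRUE`).
#' @return data.frame with one row per assigned residue: `entity`
#'   (`"hormone"`/`"receptor"`), `chain`, `resno`, `insert`, `resid`,
#'   `label`, `shell` (`"FIRST"`/`"SECOND"`), `n_evidence` and
#'   `evidence` (summary string of supporting interactions; for a
#'   second-shell residue these are its intra-molecular links to
#'   first-shell residues).
#' @examples
#' toy <- make_toy_complex(list(c("LYS", "ASP", "SALT_BRIDGE", 3.5)))
#' sel <- select_entities(toy$model, "A", "B")
#' inter <- detect_interactions(toy$model, sel, scope = "inter")
#' intra <- detect_interactions(toy$model, sel, scope = "intra")
#' assign_shells(inter, intra, sel, toy$model)
#' @export
assign_shells <- function(inter, intra, selection, model,
                          proximity_limit = 8.0,
                          hormone_second_shell = FALSE,
                          intra_hormone = NULL) {
  stopifnot(inherits(selection, "entity_selection"))
  if (nrow(inter) == 0L) {
    warning("no inter-molecular interactions: empty shell assignment")
    return(empty_shells())
  }
  rec_side <- function(rec, suffix) {
    data.frame(chain = rec[[paste0("chain_", suffix)]],
               resno = rec[[paste0("resno_", suffix)]],
               insert = rec[[paste0("insert_", suffix)]],
               resid = rec[[paste0("resid_", suffix)]],
               label = rec[[paste0("label_", suffix)]],
               partner = rec[[paste0("label_", if (suffix == "a") "b"
                                     else "a")]],
               type = rec$type, distance = rec$distance,
               stringsAsFactors = FALSE)
  }
  both <- rbind(rec_side(inter, "a"), rec_side(inter, "b"))
  both$reskey <- reskey(both$chain, both$resno, both$insert)
  both$entity <- ifelse(both$chain %in% selection$receptor_chains,
                        "receptor",
                        ifelse(both$chain %in% selection$hormone_chains,
                               "hormone", NA))

  out <- list()
  for (ent in c("receptor", if (hormone_second_shell) "hormone")) {
    first <- both[both$entity == ent & !is.na(both$entity), ,
                  drop = FALSE]
    out[[length(out) + 1L]] <- shell_rows(first, ent, "FIRST")
    intra_ent <- if (ent == "receptor") intra else intra_hormone
    out[[length(out) + 1L]] <-
      second_shell(intra_ent, unique(first$reskey), first, ent,
                   selection, model, proximity_limit)
  }
  if (!hormone_second_shell) {
    first_h <- both[both$entity == "hormone" & !is.na(both$entity), ,
                    drop = FALSE]
    out[[length(out) + 1L]] <- shell_rows(first_h, "hormone", "FIRST")
  }
  res <- do.call(rbind, out)
  res <- res[order(res$entity, res$chain, res$resno, res$insert), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

shell_rows <- function(ev, entity, shell) {
  if (nrow(ev) == 0L) return(empty_shells())
  sp <- split(ev, ev$reskey)
  rows <- lapply(sp, function(e) {
    data.frame(entity = entity,
               chain = e$chain[1L], resno = e$resno[1L],
               insert = e$insert[1L], resid = e$resid[1L],
               label = e$label[1L], shell = shell,
               n_evidence = nrow(e),
               evidence = paste0(e$partner, "(", e$type, ",",
                                 sprintf("%.2f", e$distance), ")",
                                 collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

second_shell <- function(intra, first_keys, first_ev, entity,
                         selection, model, proximity_limit) {
  if (is.null(intra) || nrow(intra) == 0L) return(empty_shells())
  key_a <- reskey(intra$chain_a, intra$resno_a, intra$insert_a)
  key_b <- reskey(intra$chain_b, intra$resno_b, intra$insert_b)
  # links where exactly one end is first shell; the other end is a
  # second-shell candidate
  cand <- rbind(
    link_rows(intra[key_b %in% first_keys & !(key_a %in% first_keys), ,
                    drop = FALSE], "a"),
    link_rows(intra[key_a %in% first_keys & !(key_b %in% first_keys), ,
                    drop = FALSE], "b"))
  if (nrow(cand) == 0L) return(empty_shells())
  cand$reskey <- reskey(cand$chain, cand$resno, cand$insert)
  if (!is.null(proximity_limit)) {
    near <- near_hormone(model, selection, proximity_limit)
    cand <- cand[cand$reskey %in% near, , drop = FALSE]
    if (nrow(cand) == 0L) return(empty_shells())
  }
  shell_rows(cand, entity, "SECOND")
}

link_rows <- function(rec, suffix) {
  if (nrow(rec) == 0L)
    return(data.frame(chain = character(), resno = integer(),
                      insert = character(), resid = character(),
                      label = character(), partner = character(),
                      type = character(), distance = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(chain = rec[[paste0("chain_", suffix)]],
             resno = rec[[paste0("resno_", suffix)]],
             insert = rec[[paste0("insert_", suffix)]],
             resid = rec[[paste0("resid_", suffix)]],
             label = rec[[paste0("label_", suffix)]],
             partner = rec[[paste0("label_", if (suffix == "a") "b"
                                   else "a")]],
             type = rec$type, distance = rec$distance,
             stringsAsFactors = FALSE)
}

# residue keys with any heavy atom within `limit` of any hormone heavy
# atom
near_hormone <- function(model, selection, limit) {
  heavy <- model[!model$is_hydrogen, , drop = FALSE]
  hx <- as.matrix(heavy[heavy$chain %in% selection$hormone_chains,
                        c("x", "y", "z"), drop = FALSE])
  if (nrow(hx) == 0L) return(character())
  other <- heavy
  xyz <- as.matrix(other[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rep(1, nrow(hx))) +
    outer(rep(1, nrow(xyz)), rowSums(hx^2)) - 2 * xyz %*% t(hx)
  mind <- sqrt(pmax(apply(d2, 1L, min), 0))
  unique(other$reskey[mind <= limit])
}

empty_shells <- function() {
  data.frame(entity = character(), chain = character(),
             resno = integer(), insert = character(),
             resid = character(), label = character(),
             shell = character(), n_evidence = integer(),
             evidence = character(), stringsAsFactors = FALSE)
}

#' Write shell assignments as TSV
#'
#' @param shells data.frame from [assign_shells()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_shells_tsv <- function(shells, path) {
  utils::write.table(shells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
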