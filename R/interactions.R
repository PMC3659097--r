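#' Geometric criteria for interface interaction detection
#'
#' Bundles the distance/angle cutoffs used by [detect_interactions()].
#' The defaults follow the conventions of the classical interface
#' analysis tools: hydrogen bonds at donor-acceptor (heavy atom)
#' distance <= 3.5 Angstrom (3.9 Angstrom with an explicit hydrogen and
#' a D-H...A angle >= 90 degrees, the HBPLUS convention); salt bridges
#' at <= 4.0 Angstrom between side-chain charged-group nitrogens and
#' carboxylate oxygens (ESBRI convention); longer-range ionic
#' (electrostatic) pairs at <= 6.0 Angstrom between the same groups;
#' hydrophobic contacts at <= 5.0 Angstrom between apolar carbons; and
#' cation-pi contacts at cation-to-ring-centroid distance <= 6.0
#' Angstrom.  Every value is overridable.
#'
#' @param hbond_da_max heavy-atom donor-acceptor cutoff, Angstrom.
#' @param hbond_da_max_h donor-acceptor cutoff when an explicit donor
#'   hydrogen is present, Angstrom.
#' @param hbond_dha_min minimum D-H...A angle in degrees (used only
#'   with explicit hydrogens).
#' @param salt_bridge_max salt-bridge cutoff, Angstrom.
#' @param electrostatic_max ionic-interaction cutoff, Angstrom; must be
#'   >= `salt_bridge_max`.
#' @param hydrophobic_max apolar carbon-carbon cutoff, Angstrom.
#' @param cation_pi_max cation-to-ring-centroid cutoff, Angstrom.
#' @param his_cationic treat histidine imidazole nitrogens as cationic
#'   for salt-bridge/ionic detection.
#' @param his_aromatic treat the histidine ring as a cation-pi acceptor.
#' @param short_contact_min contacts shorter than this (Angstrom) are
#'   flagged `short_contact` but never dropped.
#' @return a validated list of class `geometry_config`.
#' @export
geometry_config <- function(hbond_da_max = 3.5,
                            hbond_da_max_h = 3.9,
                            hbond_dha_min = 90,
                            salt_bridge_max = 4.0,
                            electrostatic_max = 6.0,
                            hydrophobic_max = 5.0,
                            cation_pi_max = 6.0,
                            his_cationic = TRUE,
                            his_aromatic = FALSE,
                            short_contact_min = 2.2) {
  cfg <- list(hbond_da_max = hbond_da_max,
              hbond_da_max_h = hbond_da_max_h,
              hbond_dha_min = hbond_dha_min,
              salt_bridge_max = salt_bridge_max,
              electrostatic_max = electrostatic_max,
              hydrophobic_max = hydrophobic_max,
              hydrophobic_max = hydrophobic_max,
              cation_pi_max = cation_pi_max,
              his_cationic = isTRUE(his_cationic),
              his_aromatic = isTRUE(his_aromatic),
              short_contact_min = short_contact_min)
  cfg <- cfg[!duplicated(names(cfg))]
  num <- c("hbond_da_max", "hbond_da_max_h", "salt_bridge_max",
           "electrostatic_max", "hydrophobic_max", "cation_pi_max",
           "short_contact_min")
  if (!all(vapply(cfg[num], function(v) is.numeric(v) && v > 0, TRUE)))
    stop("all distance cutoffs must be positive numbers")
  if (cfg$salt_bridge_max > cfg$electrostatic_max)
    stop("salt_bridge_max must be <= electrostatic_max")
  class(cfg) <- "geometry_config"
  cfg
}

#' @export
print.geometry_config <- function(x, ...) {
  cat("<geometry_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

INTERACTION_TYPES <- c("HBOND", "SALT_BRIDGE", "ELECTROSTATIC",
                       "HYDROPHOBIC", "CATION_PI")

#' Detect stabilizing interactions in a complex
#'
#' Scans residue pairs of a structure for the five interaction types
#' that stabilize a ligand-receptor interface: hydrogen bonds, salt
#' bridges, longer-range ionic (electrostatic) pairs, hydrophobic
#' contacts and cation-pi interactions.  In `"inter"` scope
#' hormone-receptor residue pairs are scanned; in `"intra"` scope
#' residue pairs within one entity (default the receptor, as needed for
#' second-shell assignment).
#'
#' One record is emitted per (residue pair, type), carrying the closest
#' qualifying atom pair (set `verbose = TRUE` for all qualifying atom
#' pairs).  Two classification rules avoid double counting: (i) a
#' charged-group pair is typed `SALT_BRIDGE` when within
#' `salt_bridge_max` and `ELECTROSTATIC` when within the longer ionic
#' cutoff only, so a salt bridge is reported once even though it also
#' satisfies the ionic criterion; (ii) a donor-acceptor pair whose
#' donor belongs to a cationic side-chain group and whose acceptor to a
#' carboxylate is classified as ionic, not additionally as a hydrogen
#' bond.  Contacts shorter than `short_contact_min` are kept and
#' flagged.
#'
#' For intra-molecular scans, residue pairs adjacent in sequence only
#' count when at least one participating atom is a side-chain atom
#' (covalent backbone neighbours trivially satisfy any distance
#' criterion).
#'
#' @param model a `structure_model`.
#' @param selection an `entity_selection`.
#' @param config a `geometry_config`.
#' @param scope `"inter"` (hormone vs receptor) or `"intra"` (within
#'   `entity`).
#' @param entity for `scope = "intra"`: `"receptor"` or `"hormone"`.
#' @param method `"prune"` uses a centroid-radius spatial pruning before
#'   exact atom checks; `"brute"` scans every residue pair.  Both give
#'   identical results; `"brute"` exists as the reference path.
#' @param verbose return every qualifying atom pair instead of one
#'   record per (pair, type).
#' @return data.frame of interaction records with columns `chain_a`,
#'   `resno_a`, `resid_a`, `label_a`, `atom_a`, the `_b` equivalents,
#'   `type`, `distance`, `scope` and `short_contact`.  Records are
#'   canonically ordered (chain, residue number) so detection is
#'   symmetric in its arguments.
#' @examples
#' toy <- make_toy_complex(list(c("LYS", "ASP", "SALT_BRIDGE", 3.5)))
#' sel <- select_entities(toy$model, "A", "B")
#' detect_interactions(toy$model, sel)
#' @export
detect_interactions <- function(model, selection,
                                config = geometry_config(),
                                scope = c("inter", "intra"),
                                entity = "receptor",
                                method = c("prune", "brute"),
                                verbose = FALSE) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  stopifnot(inherits(selection, "entity_selection"))
  heavy <- model[!model$is_hydrogen, , drop = FALSE]
  ent <- entity_of(heavy, selection)

  if (scope == "inter") {
    keys_a <- unique(heavy$reskey[ent == "hormone" & !is.na(ent)])
    keys_b <- unique(heavy$reskey[ent == "receptor" & !is.na(ent)])
    if (length(keys_a) == 0L || length(keys_b) == 0L)
      stop("empty entity: both hormone and receptor must contain residues")
    pairs <- expand.grid(a = keys_a, b = keys_b,
                         stringsAsFactors = FALSE)
  } else {
    entity <- match.arg(entity, c("receptor", "hormone"))
    keys <- unique(heavy$reskey[ent == entity & !is.na(ent)])
    if (length(keys) < 2L)
      return(empty_interactions(scope))
    idx <- t(utils::combn(length(keys), 2L))
    pairs <- data.frame(a = keys[idx[, 1L]], b = keys[idx[, 2L]],
                        stringsAsFactors = FALSE)
  }

  atoms_by_res <- split(seq_len(nrow(heavy)), heavy$reskey)
  maxcut <- max(config$hbond_da_max, config$hbond_da_max_h,
                config$electrostatic_max, config$hydrophobic_max,
                config$cation_pi_max)

  if (method == "prune") {
    # exact spatial pruning: residue pairs can only interact if their
    # bounding spheres approach within the largest cutoff
    xyz <- as.matrix(heavy[, c("x", "y", "z")])
    keys_all <- names(atoms_by_res)
    cen <- t(vapply(atoms_by_res, function(i)
      colMeans(xyz[i, , drop = FALSE]), numeric(3)))
    rad <- vapply(seq_along(atoms_by_res), function(k) {
      i <- atoms_by_res[[k]]
      max(sqrt(rowSums((xyz[i, , drop = FALSE] -
                          matrix(cen[k, ], length(i), 3, byrow = TRUE))^2)))
    }, numeric(1))
    names(rad) <- keys_all
    ia <- match(pairs$a, keys_all); ib <- match(pairs$b, keys_all)
    dcen <- sqrt(rowSums((cen[ia, , drop = FALSE] -
                            cen[ib, , drop = FALSE])^2))
    pairs <- pairs[dcen <= maxcut + rad[pairs$a] + rad[pairs$b], ,
                   drop = FALSE]
  }

  recs <- vector("list", nrow(pairs))
  n <- 0L
  for (k in seq_len(nrow(pairs))) {
    ra <- heavy[atoms_by_res[[pairs$a[k]]], , drop = FALSE]
    rb <- heavy[atoms_by_res[[pairs$b[k]]], , drop = FALSE]
    # re-attach hydrogens for the D-H-A angle test where deposited
    ha <- model[model$reskey == pairs$a[k] & model$is_hydrogen, ,
                drop = FALSE]
    hb <- model[model$reskey == pairs$b[k] & model$is_hydrogen, ,
                drop = FALSE]
    r <- classify_pair(ra, rb, ha, hb, config,
                       adjacent = residues_adjacent(ra, rb) &&
                         scope == "intra",
                       verbose = verbose)
    if (!is.null(r) && nrow(r)) {
      r$scope <- toupper(scope)
      n <- n + 1L
      recs[[n]] <- r
    }
  }
  if (n == 0L) return(empty_interactions(scope))
  out <- do.call(rbind, recs[seq_len(n)])
  canonical_order(out)
}

residues_adjacent <- function(ra, rb) {
  ra$chain[1L] == rb$chain[1L] && ra$insert[1L] == rb$insert[1L] &&
    abs(ra$resno[1L] - rb$resno[1L]) == 1L
}

empty_interactions <- function(scope = "inter") {
  data.frame(chain_a = character(), resno_a = integer(),
             insert_a = character(), resid_a = character(),
             label_a = character(), atom_a = character(),
             chain_b = character(), resno_b = integer(),
             insert_b = character(), resid_b = character(),
             label_b = character(), atom_b = character(),
             type = character(), distance = numeric(),
             short_contact = logical(), scope = character(),
             stringsAsFactors = FALSE)
}

# Canonical record ordering: side "a" is the residue with the lower
# (chain, resno, insert); rows sorted by (chain_a, resno_a, type).
canonical_order <- function(rec) {
  if (nrow(rec) == 0L) return(rec)
  swap <- (rec$chain_b < rec$chain_a) |
    (rec$chain_b == rec$chain_a & rec$resno_b < rec$resno_a) |
    (rec$chain_b == rec$chain_a & rec$resno_b == rec$resno_a &
       rec$insert_b < rec$insert_a)
  a_cols <- c("chain_a", "resno_a", "insert_a", "resid_a", "label_a",
              "atom_a")
  b_cols <- sub("_a$", "_b", a_cols)
  tmp <- rec[swap, a_cols]
  rec[swap, a_cols] <- rec[swap, b_cols]
  rec[swap, b_cols] <- tmp
  rec <- rec[order(rec$chain_a, rec$resno_a, rec$insert_a,
                   rec$chain_b, rec$resno_b, rec$insert_b,
                   match(rec$type, INTERACTION_TYPES),
                   rec$distance), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

# --- per-pair classification --------------------------------------------

record_row <- function(ra, ia, rb, ib, type, dist, short_min,
                       atom_a = NULL, atom_b = NULL) {
  data.frame(
    chain_a = ra$chain[1L], resno_a = ra$resno[1L],
    insert_a = ra$insert[1L], resid_a = ra$resid[1L],
    label_a = residue_label(ra$resno[1L], ra$resid[1L]),
    atom_a = if (is.null(atom_a)) ra$elety[ia] else atom_a,
    chain_b = rb$chain[1L], resno_b = rb$resno[1L],
    insert_b = rb$insert[1L], resid_b = rb$resid[1L],
    label_b = residue_label(rb$resno[1L], rb$resid[1L]),
    atom_b = if (is.null(atom_b)) rb$elety[ib] else atom_b,
    type = type, distance = dist,
    short_contact = dist < short_min,
    stringsAsFactors = FALSE)
}

dist_mat <- function(ra, rb) {
  xa <- as.matrix(ra[, c("x", "y", "z")])
  xb <- as.matrix(rb[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rep(1, nrow(xb))) +
    outer(rep(1, nrow(xa)), rowSums(xb^2)) - 2 * xa %*% t(xb)
  sqrt(pmax(d2, 0))
}

donor_atoms <- function(res) {
  nm <- res$resid[1L]
  d <- HB_DONORS[[nm]]
  if (nm != "PRO") d <- c("N", d)
  which(res$elety %in% d)
}

acceptor_atoms <- function(res) {
  which(res$elety %in% c("O", "OXT", HB_ACCEPTORS[[res$resid[1L]]]))
}

cationic_atoms <- function(res, config) {
  dict <- CATIONIC_ATOMS
  if (config$his_cationic) dict <- c(dict, CATIONIC_ATOMS_HIS)
  which(res$elety %in% dict[[res$resid[1L]]])
}

anionic_atoms <- function(res) {
  which(res$elety %in% ANIONIC_ATOMS[[res$resid[1L]]])
}

apolar_atoms <- function(res) {
  which(res$elety %in% APOLAR_CARBONS[[res$resid[1L]]])
}

ring_centroids <- function(res, config) {
  dict <- AROMATIC_RINGS
  if (config$his_aromatic) dict <- c(dict, AROMATIC_RINGS_HIS)
  rings <- dict[[res$resid[1L]]]
  if (is.null(rings)) return(NULL)
  out <- list()
  for (i in seq_along(rings)) {
    idx <- match(rings[[i]], res$elety)
    if (anyNA(idx)) next   # incomplete ring: skip with no feature
    out[[length(out) + 1L]] <- list(
      name = paste0("RING", i),
      xyz = colMeans(as.matrix(res[idx, c("x", "y", "z")])))
  }
  if (length(out)) out else NULL
}

classify_pair <- function(ra, rb, ha, hb, config, adjacent = FALSE,
                          verbose = FALSE) {
  dm <- dist_mat(ra, rb)
  if (min(dm) > max(config$hbond_da_max_h, config$electrostatic_max,
                    config$hydrophobic_max, config$cation_pi_max))
    return(NULL)
  recs <- list()
  sidechain_ok <- function(i_a, i_b) {
    if (!adjacent) rep(TRUE, length(i_a))
    else ra$is_sidechain[i_a] | rb$is_sidechain[i_b]
  }

  # hydrogen bonds (both directions)
  hb_rows <- hbond_pairs(ra, rb, ha, hb, dm, config)
  if (!is.null(hb_rows) && nrow(hb_rows)) {
    keep <- sidechain_ok(hb_rows$ia, hb_rows$ib)
    hb_rows <- hb_rows[keep, , drop = FALSE]
    if (nrow(hb_rows)) {
      sel <- if (verbose) seq_len(nrow(hb_rows)) else which.min(hb_rows$d)
      for (s in sel)
        recs[[length(recs) + 1L]] <-
          record_row(ra, hb_rows$ia[s], rb, hb_rows$ib[s], "HBOND",
                     hb_rows$d[s], config$short_contact_min)
    }
  }

  # ionic: salt bridge within the short band, electrostatic in the
  # longer band
  for (dir in 1:2) {
    rc <- if (dir == 1L) ra else rb
    rn <- if (dir == 1L) rb else ra
    ic <- cationic_atoms(rc, config)
    ineg <- anionic_atoms(rn)
    if (length(ic) && length(ineg)) {
      d <- if (dir == 1L) dm[ic, ineg, drop = FALSE]
      else t(dm[ineg, ic, drop = FALSE])
      grid <- expand.grid(i = seq_along(ic), j = seq_along(ineg))
      dv <- d[cbind(grid$i, grid$j)]
      i_a <- if (dir == 1L) ic[grid$i] else ineg[grid$j]
      i_b <- if (dir == 1L) ineg[grid$j] else ic[grid$i]
      ok <- sidechain_ok(i_a, i_b) & dv <= config$electrostatic_max
      if (any(ok)) {
        dv <- dv[ok]; i_a <- i_a[ok]; i_b <- i_b[ok]
        sel <- if (verbose) order(dv) else which.min(dv)
        for (s in sel) {
          type <- if (dv[s] <= config$salt_bridge_max) "SALT_BRIDGE"
          else "ELECTROSTATIC"
          recs[[length(recs) + 1L]] <-
            record_row(ra, i_a[s], rb, i_b[s], type, dv[s],
                       config$short_contact_min)
        }
      }
    }
  }

  # hydrophobic
  iha <- apolar_atoms(ra); ihb <- apolar_atoms(rb)
  if (length(iha) && length(ihb)) {
    d <- dm[iha, ihb, drop = FALSE]
    grid <- expand.grid(i = seq_along(iha), j = seq_along(ihb))
    dv <- d[cbind(grid$i, grid$j)]
    i_a <- iha[grid$i]; i_b <- ihb[grid$j]
    ok <- sidechain_ok(i_a, i_b) & dv <= config$hydrophobic_max
    if (any(ok)) {
      dv <- dv[ok]; i_a <- i_a[ok]; i_b <- i_b[ok]
      sel <- if (verbose) order(dv) else which.min(dv)
      for (s in sel)
        recs[[length(recs) + 1L]] <-
          record_row(ra, i_a[s], rb, i_b[s], "HYDROPHOBIC", dv[s],
                     config$short_contact_min)
    }
  }

  # cation-pi (both directions); ring side reported as a centroid
  # pseudo-atom
  cp <- cation_pi_pairs(ra, rb, config)
  if (!is.null(cp) && nrow(cp)) {
    sel <- if (verbose) order(cp$d) else which.min(cp$d)
    for (s in sel)
      recs[[length(recs) + 1L]] <-
        record_row(ra, cp$ia[s], rb, 1L, "CATION_PI", cp$d[s],
                   config$short_contact_min,
                   atom_a = cp$atom_a[s], atom_b = cp$atom_b[s])
  }

  if (length(recs)) do.call(rbind, recs) else NULL
}

hbond_pairs <- function(ra, rb, ha, hb, dm, config) {
  rows <- list()
  for (dir in 1:2) {
    rd <- if (dir == 1L) ra else rb
    rc <- if (dir == 1L) rb else ra
    hd <- if (dir == 1L) ha else hb
    id <- donor_atoms(rd); ia <- acceptor_atoms(rc)
    if (!length(id) || !length(ia)) next
    d <- if (dir == 1L) dm[id, ia, drop = FALSE]
    else t(dm[ia, id, drop = FALSE])
    grid <- expand.grid(i = seq_along(id), j = seq_along(ia))
    dv <- d[cbind(grid$i, grid$j)]
    don <- id[grid$i]; acc <- ia[grid$j]
    # exclude charged-group pairs (classified as ionic)
    drop <- don %in% cationic_atoms(rd, config) &
      acc %in% anionic_atoms(rc)
    # explicit-H geometry where a hydrogen is bonded to the donor
    has_h <- rep(FALSE, length(don))
    ang <- rep(NA_real_, length(don))
    if (nrow(hd)) {
      hxyz <- as.matrix(hd[, c("x", "y", "z")])
      dxyz <- as.matrix(rd[, c("x", "y", "z")])
      axyz <- as.matrix(rc[, c("x", "y", "z")])
      for (q in seq_along(don)) {
        dh <- sqrt(colSums((t(hxyz) - dxyz[don[q], ])^2))
        bonded <- which(dh < 1.3)
        if (length(bonded)) {
          has_h[q] <- TRUE
          angs <- vapply(bonded, function(b) {
            v1 <- dxyz[don[q], ] - hxyz[b, ]
            v2 <- axyz[acc[q], ] - hxyz[b, ]
            acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) *
              180 / pi
          }, numeric(1))
          ang[q] <- max(angs)
        }
      }
    }
    cut <- ifelse(has_h, config$hbond_da_max_h, config$hbond_da_max)
    ok <- !drop & dv <= cut &
      (!has_h | is.na(ang) | ang >= config$hbond_dha_min)
    if (any(ok)) {
      i_a <- if (dir == 1L) don else acc
      i_b <- if (dir == 1L) acc else don
      rows[[length(rows) + 1L]] <-
        data.frame(ia = i_a[ok], ib = i_b[ok], d = dv[ok],
                   dha = ang[ok], donor_side = dir)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

cation_pi_pairs <- function(ra, rb, config) {
  rows <- list()
  for (dir in 1:2) {
    rc <- if (dir == 1L) ra else rb   # cation side
    rr <- if (dir == 1L) rb else ra   # ring side
    cat_names <- CATION_PI_CATIONS[[rc$resid[1L]]]
    ic <- which(rc$elety %in% cat_names)
    cens <- ring_centroids(rr, config)
    if (!length(ic) || is.null(cens)) next
    for (i in ic) {
      p <- as.numeric(rc[i, c("x", "y", "z")])
      for (cen in cens) {
        d <- sqrt(sum((p - cen$xyz)^2))
        if (d <= config$cation_pi_max) {
          rows[[length(rows) + 1L]] <- data.frame(
            ia = if (dir == 1L) i else 1L,
            d = d,
            atom_a = if (dir == 1L) rc$elety[i] else cen$name,
            atom_b = if (dir == 1L) cen$name else rc$elety[i],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$d), , drop = FALSE]
}

#' Qualifying hydrogen-bond donor/acceptor pairs for one residue pair
#'
#' Lower-level access to the hydrogen-bond detector: returns every
#' donor-acceptor atom pair of the two residues that satisfies the
#' criteria in `config`, with its geometry.  In heavy-atom mode (no
#' deposited hydrogens) the criterion is the donor-acceptor distance;
#' with explicit hydrogens the D-H...A angle is also required.
#'
#' @param model a `structure_model`.
#' @param reskey_a,reskey_b residue keys (`chain:resno` as in
#'   `model$reskey`).
#' @param config a `geometry_config`.
#' @return data.frame with columns `atom_a`, `atom_b`, `distance`,
#'   `dha_angle` (NA in heavy-atom mode), `donor_is_a`,
#'   `short_contact`; zero rows when nothing qualifies.
#' @export
hbond_candidates <- function(model, reskey_a, reskey_b,
                             config = geometry_config()) {
  ra <- model[model$reskey == reskey_a & !model$is_hydrogen, ,
              drop = FALSE]
  rb <- model[model$reskey == reskey_b & !model$is_hydrogen, ,
              drop = FALSE]
  if (!nrow(ra) || !nrow(rb))
    stop("unknown residue key(s): ",
         paste(setdiff(c(reskey_a, reskey_b), model$reskey),
               collapse = ", "))
  ha <- model[model$reskey == reskey_a & model$is_hydrogen, , drop = FALSE]
  hb <- model[model$reskey == reskey_b & model$is_hydrogen, , drop = FALSE]
  res <- hbond_pairs(ra, rb, ha, hb, dist_mat(ra, rb), config)
  if (is.null(res))
    return(data.frame(atom_a = character(), atom_b = character(),
                      distance = numeric(), dha_angle = numeric(),
                      donor_is_a = logical(), short_contact = logical()))
  data.frame(atom_a = ra$elety[res$ia], atom_b = rb$elety[res$ib],
             distance = res$d, dha_angle = res$dha,
             donor_is_a = res$donor_side == 1L,
             short_contact = res$d < config$short_contact_min,
             stringsAsFactors = FALSE)
}

#' Cation-pi record for one residue pair
#'
#' One residue must carry a cationic anchor (LYS NZ, or ARG CZ as
#' guanidinium centroid proxy), the other an aromatic ring (PHE/TYR
#' six-ring; TRP contributes both rings and the nearest is used).  A
#' record is returned iff the cation-to-centroid distance is within
#' `config$cation_pi_max`.
#'
#' @inheritParams hbond_candidates
#' @return a one-row data.frame (`atom_cation`, `ring`, `distance`) or a
#'   zero-row data.frame when no qualifying geometry exists.
#' @export
cation_pi <- function(model, reskey_a, reskey_b,
                      config = geometry_config()) {
  ra <- model[model$reskey == reskey_a & !model$is_hydrogen, , drop = FALSE]
  rb <- model[model$reskey == reskey_b & !model$is_hydrogen, , drop = FALSE]
  if (!nrow(ra) || !nrow(rb))
    stop("unknown residue key(s)")
  cp <- cation_pi_pairs(ra, rb, config)
  if (is.null(cp))
    return(data.frame(atom_cation = character(), ring = character(),
                      distance = numeric()))
  cp <- cp[which.min(cp$d), , drop = FALSE]
  is_cat_a <- cp$atom_a %in% unlist(CATION_PI_CATIONS)
  data.frame(atom_cation = if (is_cat_a) cp$atom_a else cp$atom_b,
             ring = if (is_cat_a) cp$atom_b else cp$atom_a,
             distance = cp$d, stringsAsFactors = FALSE)
}

#' Write interaction records as TSV
#'
#' @param records data.frame from [detect_interactions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
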