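#' Pipeline configuration
#'
#' Collects every input path and tunable of the end-to-end analysis:
#' structure and chain selection, the four family alignments (own and
#' paralogous family for each of hormone and receptor), optional
#' cross-family reference alignments, geometric cutoffs, conservation
#' thresholds and flags.  A configuration can be serialized to YAML
#' with [write_bsr_config()] and read back unchanged with
#' [read_bsr_config()].
#'
#' Each alignment entry is a list with `path` (aligned FASTA),
#' `family_id`, optional `reference_id` (default: first sequence) and
#' `ref_start` (author-numbering offset of the reference, default 1).
#'
#' @param pdb path to the complex PDB file.
#' @param hormone_chains,receptor_chains chain identifiers.
#' @param hormone_own,hormone_other,receptor_own,receptor_other
#'   alignment entries (see Details) for the hormone's own family, the
#'   paralogous hormone family, and likewise for the receptor.
#' @param cross_hormone,cross_receptor optional 2-row aligned FASTA
#'   paths mapping own-family to other-family reference numbering; by
#'   default numbering is assumed to agree (identity correspondence).
#' @param geometry a `geometry_config` (or a plain list of overrides).
#' @param cons_threshold,max_gap conservation threshold and column gap
#'   tolerance for [profile_columns()].
#' @param proximity_limit second-shell proximity limit in Angstrom
#'   (`NULL` disables it).
#' @param admit_structural_only permissive BSR mode (see
#'   [call_bsrs()]).
#' @param hormone_second_shell compute the hormone-side second shell.
#' @param seed integer seed recorded with the run (the analysis itself
#'   is deterministic).
#' @return list of class `bsr_config`.
#' @export
bsr_config <- function(pdb, hormone_chains, receptor_chains,
                       hormone_own, hormone_other,
                       receptor_own, receptor_other,
                       cross_hormone = NULL, cross_receptor = NULL,
                       geometry = geometry_config(),
                       cons_threshold = 1.0, max_gap = 0.3,
                       proximity_limit = 8.0,
                       admit_structural_only = FALSE,
                       hormone_second_shell = FALSE,
                       seed = 1L) {
  if (!inherits(geometry, "geometry_config"))
    geometry <- do.call(geometry_config, as.list(geometry))
  norm_aln <- function(a, what) {
    if (is.character(a)) a <- list(path = a, family_id = what)
    if (is.null(a$path)) stop("alignment entry '", what, "' lacks a path")
    if (is.null(a$family_id)) a$family_id <- what
    if (is.null(a$ref_start)) a$ref_start <- 1L
    a
  }
  cfg <- list(pdb = pdb,
              hormone_chains = as.character(hormone_chains),
              receptor_chains = as.character(receptor_chains),
              hormone_own = norm_aln(hormone_own, "hormone_own"),
              hormone_other = norm_aln(hormone_other, "hormone_other"),
              receptor_own = norm_aln(receptor_own, "receptor_own"),
              receptor_other = norm_aln(receptor_other, "receptor_other"),
              cross_hormone = cross_hormone,
              cross_receptor = cross_receptor,
              geometry = geometry,
              cons_threshold = cons_threshold, max_gap = max_gap,
              proximity_limit = proximity_limit,
              admit_structural_only = isTRUE(admit_structural_only),
              hormone_second_shell = isTRUE(hormone_second_shell),
              seed = as.integer(seed))
  class(cfg) <- "bsr_config"
  cfg
}

#' @rdname bsr_config
#' @param path YAML file path.
#' @export
read_bsr_config <- function(path) {
  raw <- yaml::read_yaml(path)
  geometry <- if (!is.null(raw$geometry))
    do.call(geometry_config, raw$geometry) else geometry_config()
  raw$geometry <- geometry
  cfg <- do.call(bsr_config, raw)
  cfg
}

#' @rdname bsr_config
#' @param config a `bsr_config`.
#' @export
write_bsr_config <- function(config, path) {
  out <- unclass(config)
  out$geometry <- unclass(out$geometry)
  yaml::write_yaml(out, path)
  invisible(path)
}

validate_config_paths <- function(config) {
  paths <- c(config$pdb,
             config$hormone_own$path, config$hormone_other$path,
             config$receptor_own$path, config$receptor_other$path,
             config$cross_hormone, config$cross_receptor)
  fields <- c("pdb", "hormone_own", "hormone_other", "receptor_own",
              "receptor_other", "cross_hormone",
              "cross_receptor")[seq_along(paths)]
  missing <- !vapply(paths, file.exists, TRUE)
  if (any(missing))
    stop("missing input file(s) for field(s): ",
         paste(fields[missing], collapse = ", "))
  invisible(TRUE)
}

#' Run the full binding-specificity analysis
#'
#' Executes the complete inference chain on one complex: parse the
#' structure, detect inter- and intra-molecular interactions, assign
#' interface shells, profile the four family alignments under the
#' reduced alphabet, call family-divergent positions via the
#' cross-family correspondence, intersect structural and sequence
#' evidence into BSR calls, and derive the family-swap mutant tables.
#' The run is deterministic given identical inputs and configuration.
#'
#' @param config a `bsr_config`.
#' @return object of class `bsr_analysis`: list with elements
#'   `config`, `model`, `selection`, `inter`, `intra`, `shells`,
#'   `profiles` (list of four `column_profiles`), `correspondence`
#'   (hormone and receptor maps), `divergent` (hormone and receptor),
#'   `bsrs`, and `mutants` (hormone and receptor `mutant_spec`s).
#' @seealso [write_report()] for exporting the result bundle.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "bsr_config"))
  validate_config_paths(config)
  model <- read_structure(config$pdb)
  selection <- select_entities(model, config$hormone_chains,
                               config$receptor_chains)
  inter <- detect_interactions(model, selection, config$geometry,
                               scope = "inter")
  intra <- detect_interactions(model, selection, config$geometry,
                               scope = "intra", entity = "receptor")
  intra_h <- if (config$hormone_second_shell)
    detect_interactions(model, selection, config$geometry,
                        scope = "intra", entity = "hormone")
  shells <- assign_shells(inter, intra, selection, model,
                          proximity_limit = config$proximity_limit,
                          hormone_second_shell = config$hormone_second_shell,
                          intra_hormone = intra_h)

  read_aln <- function(entry)
    read_family_alignment(entry$path, entry$family_id,
                          entry$reference_id, entry$ref_start)
  alns <- list(hormone_own = read_aln(config$hormone_own),
               hormone_other = read_aln(config$hormone_other),
               receptor_own = read_aln(config$receptor_own),
               receptor_other = read_aln(config$receptor_other))
  profiles <- lapply(alns, profile_columns,
                     cons_threshold = config$cons_threshold,
                     max_gap = config$max_gap)
  corr <- list(
    hormone = cross_correspondence(config$cross_hormone,
                                   alns$hormone_own,
                                   alns$hormone_other),
    receptor = cross_correspondence(config$cross_receptor,
                                    alns$receptor_own,
                                    alns$receptor_other))
  divergent <- list(
    hormone = call_divergent_positions(profiles$hormone_own,
                                       profiles$hormone_other,
                                       corr$hormone,
                                       on_missing = "skip"),
    receptor = call_divergent_positions(profiles$receptor_own,
                                        profiles$receptor_other,
                                        corr$receptor,
                                        on_missing = "skip"))
  bsrs <- call_bsrs(shells,
                    divergent_receptor = divergent$receptor,
                    divergent_hormone = divergent$hormone,
                    admit_structural_only = config$admit_structural_only)
  mutants <- list(
    receptor = bsr_mutant_spec(bsrs, "receptor", corr$receptor,
                               alns$receptor_other),
    hormone = bsr_mutant_spec(bsrs, "hormone", corr$hormone,
                              alns$hormone_other))
  structure(list(config = config, model = model, selection = selection,
                 inter = inter, intra = intra, shells = shells,
                 profiles = profiles, correspondence = corr,
                 divergent = divergent, bsrs = bsrs,
                 mutants = mutants),
            class = "bsr_analysis")
}

cross_correspondence <- function(path, aln_own, aln_other) {
  if (is.null(path)) return(NULL)   # identity correspondence
  build_correspondence(path = path,
                       ref_start_a = aln_own$ref_start,
                       ref_start_b = aln_other$ref_start)
}

bsr_mutant_spec <- function(bsrs, entity, corr, aln_other) {
  sub <- bsrs[bsrs$entity == entity & !is.na(bsrs$refpos), ,
              drop = FALSE]
  ref_row <- which(aln_other$ids == aln_other$reference_id)
  other_ref <- gsub("[-.]", "", aln_other$seqs[[ref_row]])
  if (nrow(sub) == 0L)
    return(make_mutant_spec(data.frame(position = integer(),
                                       wt = character()),
                            identity_correspondence(integer()),
                            other_ref, molecule_id = entity,
                            other_start = aln_other$ref_start))
  if (is.null(corr))
    corr <- identity_correspondence(sub$refpos)
  make_mutant_spec(data.frame(position = sub$refpos,
                              wt = aa321(sub$resid)),
                   corr, other_ref,
                   molecule_id = paste0(entity, "_swap"),
                   other_start = aln_other$ref_start)
}

#' @export
print.bsr_analysis <- function(x, ...) {
  cat("<bsr_analysis> ", attr(x$model, "id"), "\n", sep = "")
  cat("  interactions: ", nrow(x$inter), " inter, ", nrow(x$intra),
      " intra\n", sep = "")
  sh <- table(factor(x$shells$shell, levels = c("FIRST", "SECOND")),
              x$shells$entity)
  cat("  shells: ", paste(capture_table(sh), collapse = "; "), "\n",
      sep = "")
  cat("  divergent positions: ", nrow(x$divergent$receptor),
      " receptor, ", nrow(x$divergent$hormone), " hormone\n", sep = "")
  cat("  BSR calls: ", nrow(x$bsrs), "\n", sep = "")
  invisible(x)
}

capture_table <- function(tb) {
  vapply(colnames(tb), function(cn)
    paste0(cn, " ", paste0(rownames(tb), "=", tb[, cn],
                           collapse = "/")), character(1))
}

#' @export
summary.bsr_analysis <- function(object, ...) {
  x <- object
  cat("Binding-specificity analysis of ", attr(x$model, "id"), "\n\n",
      sep = "")
  print(x$config$geometry)
  cat("\nBSR calls:\n")
  print(x$bsrs[, c("entity", "label", "shell", "own_class",
                   "other_class", "waived")], row.names = FALSE)
  cat("\nMutant specifications:\n")
  print(x$mutants$receptor)
  print(x$mutants$hormone)
  invisible(x)
}

#' Write the analysis report bundle
#'
#' Exports an analysis as machine-readable tables plus a Markdown
#' report: interaction TSVs, shell TSV, per-column profile TSVs,
#' divergent-position TSV, BSR TSV and JSON evidence bundle, mutant
#' substitution lists (plain text, one `"E50R"` string per line, and
#' JSON), and `report.md` recording every parameter used (the
#' geometric cutoffs are always embedded, since published interface
#' analyses rarely state them).
#'
#' @param x a `bsr_analysis`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "bsr_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_interactions_tsv(x$inter, p("interactions_inter.tsv"))
  write_interactions_tsv(x$intra, p("interactions_intra.tsv"))
  write_shells_tsv(x$shells, p("shells.tsv"))
  for (nm in names(x$profiles)) {
    pr <- x$profiles[[nm]]
    pr$class_counts <- vapply(pr$class_counts, function(ct)
      paste0(names(ct), ":", as.integer(ct), collapse = ","),
      character(1))
    utils::write.table(pr, p(paste0("profile_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  div <- rbind(cbind(entity = "hormone", x$divergent$hormone),
               cbind(entity = "receptor", x$divergent$receptor))
  utils::write.table(div, p("divergent_positions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$bsrs, p("bsrs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(x$bsrs, p("bsrs.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  for (ent in names(x$mutants)) {
    writeLines(x$mutants[[ent]]$string, p(paste0("mutants_", ent, ".txt")))
    jsonlite::write_json(x$mutants[[ent]],
                         p(paste0("mutants_", ent, ".json")),
                         dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  writeLines(report_markdown(x), p("report.md"))
  invisible(dir)
}

report_markdown <- function(x) {
  g <- x$config$geometry
  fmt_tab <- function(df, cols) {
    if (nrow(df) == 0L) return("(none)")
    df <- df[, cols, drop = FALSE]
    c(paste0("| ", paste(cols, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"),
      vapply(seq_len(nrow(df)), function(i)
        paste0("| ", paste(vapply(df[i, ], format, character(1)),
                           collapse = " | "), " |"), character(1)))
  }
  c("# Binding-specificity analysis report",
    "",
    paste0("Structure: `", x$config$pdb, "` (hormone chains ",
           paste(x$config$hormone_chains, collapse = ","),
           "; receptor chains ",
           paste(x$config$receptor_chains, collapse = ","), ")"),
    "",
    "## Parameters",
    "",
    vapply(names(unclass(g)), function(nm)
      paste0("- geometry.", nm, ": ", format(g[[nm]])), character(1)),
    paste0("- cons_threshold: ", x$config$cons_threshold),
    paste0("- max_gap: ", x$config$max_gap),
    paste0("- proximity_limit: ",
           if (is.null(x$config$proximity_limit)) "none"
           else x$config$proximity_limit),
    paste0("- admit_structural_only: ",
           x$config$admit_structural_only),
    "",
    "## Inter-molecular interactions",
    "",
    fmt_tab(x$inter, c("label_a", "atom_a", "label_b", "atom_b",
                       "type", "distance")),
    "",
    "## Interface shells",
    "",
    fmt_tab(x$shells, c("entity", "label", "shell", "n_evidence")),
    "",
    "## Binding-specificity residues",
    "",
    fmt_tab(x$bsrs, c("entity", "label", "shell", "own_class",
                      "other_class", "waived")),
    "",
    "## Mutant substitutions",
    "",
    paste0("- receptor: ",
           paste(x$mutants$receptor$string, collapse = ", ")),
    paste0("- hormone: ",
           paste(x$mutants$hormone$string, collapse = ", ")))
}
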