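#' Construct a family alignment object
#'
#' Wraps a set of aligned sequences from one protein family (e.g. the
#' FSH beta-subunits of many species) together with a designated
#' reference sequence whose residue numbering anchors all reported
#' positions.  Column positions are mapped to reference numbering so
#' that profile and divergence output can be read against structure
#' residue labels (author numbering).
#'
#' @param sequences named character vector of aligned sequences (equal
#'   lengths; gaps as `-` or `.`).
#' @param family_id short family label (e.g. `"FSH"`).
#' @param reference_id name of the reference sequence; defaults to the
#'   first.
#' @param ref_start residue number of the first non-gap reference
#'   position (author numbering offset).
#' @return object of class `family_alignment`: list with `family_id`,
#'   `ids`, `seqs`, `reference_id`, `ref_start`, `ncol` and `col2ref`
#'   (integer vector mapping alignment columns to reference positions,
#'   `NA` at reference gaps).
#' @export
family_alignment <- function(sequences, family_id,
                             reference_id = NULL, ref_start = 1L) {
  if (length(sequences) == 0L) stop("empty alignment")
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("sequences must be named")
  seqs <- toupper(as.character(sequences))
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("aligned sequences must have equal length")
  if (is.null(reference_id)) reference_id <- names(sequences)[1L]
  if (!reference_id %in% names(sequences))
    stop("reference sequence '", reference_id, "' not in alignment")
  ref <- strsplit(seqs[[which(names(sequences) == reference_id)]],
                  "")[[1L]]
  nongap <- !(ref %in% c("-", "."))
  if (!any(nongap)) stop("reference sequence is all gaps")
  col2ref <- rep(NA_integer_, L)
  col2ref[nongap] <- ref_start + seq_len(sum(nongap)) - 1L
  structure(list(family_id = family_id,
                 ids = names(sequences),
                 seqs = stats::setNames(seqs, names(sequences)),
                 reference_id = reference_id,
                 ref_start = as.integer(ref_start),
                 ncol = L, col2ref = col2ref),
            class = "family_alignment")
}

#' @export
print.family_alignment <- function(x, ...) {
  cat("<family_alignment> ", x$family_id, ": ", length(x$ids),
      " sequences, ", x$ncol, " columns, reference ", x$reference_id,
      " (numbering from ", x$ref_start, ")\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file as a family alignment
#'
#' @param path aligned FASTA file.
#' @inheritParams family_alignment
#' @return a `family_alignment`.
#' @export
read_family_alignment <- function(path, family_id,
                                  reference_id = NULL, ref_start = 1L) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no sequences in '", path, "'")
  seqs <- stats::setNames(as.character(aa),
                          sub("\\s.*$", "", names(aa)))
  family_alignment(seqs, family_id, reference_id, ref_start)
}

#' Write a family alignment as aligned FASTA
#'
#' @param aln a `family_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_family_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(aln$seqs), path)
  invisible(path)
}

#' Reduced-alphabet conservation profile of alignment columns
#'
#' For every reference-anchored column (non-gap in the reference, gap
#' fraction at most `max_gap`) counts the physicochemical classes of
#' the residues and scores conservation as the modal class frequency
#' among non-gap residues.  A column is called conserved (its
#' `conserved_class` is set) iff conservation reaches
#' `cons_threshold`.  Non-standard residue codes (X, B, Z, ...) are
#' counted as gaps.
#'
#' @param aln a `family_alignment`.
#' @param alphabet a `reduced_alphabet`.
#' @param cons_threshold fraction in (0, 1]; default 1.0 calls only
#'   strictly class-conserved columns.  0.9 is a common relaxation for
#'   noisy families.
#' @param max_gap maximum tolerated gap fraction per column.
#' @return data.frame of class `column_profiles` with one row per
#'   profiled column: `refpos`, `column`, `n_seq`, `gap_fraction`,
#'   `modal_class`, `conservation`, `conserved_class` (`NA` when below
#'   threshold) and `class_counts` (list column of named counts).
#' @examples
#' aln <- family_alignment(c(a = "KR", b = "KK", c = "RD"), "toy")
#' profile_columns(aln, cons_threshold = 0.9)
#' @export
profile_columns <- function(aln, alphabet = reduced_alphabet(),
                            cons_threshold = 1.0, max_gap = 0.3) {
  stopifnot(inherits(aln, "family_alignment"))
  if (!(cons_threshold > 0 && cons_threshold <= 1))
    stop("cons_threshold must be in (0, 1]")
  mat <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  lookup <- attr(alphabet, "lookup")
  cols <- which(!is.na(aln$col2ref))
  rows <- lapply(cols, function(j) {
    cl <- lookup[mat[, j]]          # NA for gaps and non-standard
    n <- length(cl)
    gaps <- sum(is.na(cl))
    gap_fraction <- gaps / n
    if (gap_fraction > max_gap) return(NULL)
    counts <- table(factor(cl[!is.na(cl)], levels = names(alphabet)))
    counts <- counts[counts > 0]
    conservation <- if (n - gaps > 0) max(counts) / (n - gaps) else NA_real_
    modal <- if (length(counts)) names(counts)[which.max(counts)]
    else NA_character_
    data.frame(refpos = aln$col2ref[j], column = j, n_seq = n,
               gap_fraction = gap_fraction,
               modal_class = modal,
               conservation = conservation,
               conserved_class = if (!is.na(conservation) &&
                                     conservation >= cons_threshold)
                 modal else NA_character_,
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, TRUE)
  if (!any(keep))
    stop("no profilable columns (all exceed max_gap)")
  out <- do.call(rbind, rows[keep])
  counts_list <- lapply(cols[keep], function(j) {
    cl <- lookup[mat[, j]]
    tb <- table(factor(cl[!is.na(cl)], levels = names(alphabet)))
    tb[tb > 0]
  })
  out$class_counts <- counts_list
  rownames(out) <- NULL
  attr(out, "family_id") <- aln$family_id
  attr(out, "cons_threshold") <- cons_threshold
  attr(out, "alphabet") <- alphabet
  class(out) <- c("column_profiles", "data.frame")
  out
}

#' Build a cross-family position correspondence from a pairwise
#' alignment
#'
#' Given the two family reference sequences aligned to each other,
#' every column where both are non-gap yields a correspondence pair of
#' reference positions; gapped columns are excluded.
#'
#' @param seq_a,seq_b aligned reference sequences (equal-length
#'   strings), or pass `path` instead.
#' @param path optional 2-row aligned FASTA; overrides `seq_a`/`seq_b`.
#' @param ref_start_a,ref_start_b author-numbering offsets of the two
#'   references.
#' @return data.frame of class `correspondence_map` with columns
#'   `pos_a` and `pos_b` (one-to-one).
#' @examples
#' build_correspondence("AB-C", "A-DC")   # pairs (1,1) and (3,3)
#' @export
build_correspondence <- function(seq_a = NULL, seq_b = NULL,
                                 path = NULL,
                                 ref_start_a = 1L, ref_start_b = 1L) {
  if (!is.null(path)) {
    aa <- Biostrings::readAAStringSet(path)
    if (length(aa) != 2L)
      stop("cross-family alignment must contain exactly 2 sequences")
    seq_a <- as.character(aa[[1L]]); seq_b <- as.character(aa[[2L]])
  }
  if (is.null(seq_a) || is.null(seq_b))
    stop("provide seq_a and seq_b, or path")
  a <- strsplit(toupper(seq_a), "")[[1L]]
  b <- strsplit(toupper(seq_b), "")[[1L]]
  if (length(a) != length(b))
    stop("malformed alignment: unequal lengths")
  gap <- c("-", ".")
  pos_a <- cumsum(!(a %in% gap)) + ref_start_a - 1L
  pos_b <- cumsum(!(b %in% gap)) + ref_start_b - 1L
  keep <- !(a %in% gap) & !(b %in% gap)
  out <- data.frame(pos_a = pos_a[keep], pos_b = pos_b[keep])
  class(out) <- c("correspondence_map", "data.frame")
  out
}

#' Identity correspondence over a set of positions
#'
#' Convenience constructor for families whose reference numbering
#' already agrees position-by-position.
#'
#' @param positions integer vector of positions.
#' @return a `correspondence_map`.
#' @export
identity_correspondence <- function(positions) {
  out <- data.frame(pos_a = as.integer(positions),
                    pos_b = as.integer(positions))
  class(out) <- c("correspondence_map", "data.frame")
  out
}

#' Call family-divergent (specificity) positions
#'
#' A corresponding position pair is divergent iff both columns carry a
#' conserved class (conservation at or above the threshold used in
#' [profile_columns()]) and the two classes differ.  These are the
#' sequence-level signatures of binding-specificity residues:
#' conserved within each family, but on different chemistry.
#'
#' @param profiles_a,profiles_b `column_profiles` of the two families
#'   (computed with the same alphabet).
#' @param correspondence a `correspondence_map`; defaults to the
#'   identity map over positions present in both profile sets.
#' @param on_missing what to do when the correspondence references a
#'   position absent from a profile set: `"error"` (default) or
#'   `"skip"` (with a warning; useful when gap-heavy columns were
#'   dropped).
#' @return data.frame with one row per divergent pair: `pos_a`,
#'   `pos_b`, `class_a`, `class_b`, `conservation_a`,
#'   `conservation_b`.
#' @export
call_divergent_positions <- function(profiles_a, profiles_b,
                                     correspondence = NULL,
                                     on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  if (is.null(correspondence))
    correspondence <- identity_correspondence(
      intersect(profiles_a$refpos, profiles_b$refpos))
  ia <- match(correspondence$pos_a, profiles_a$refpos)
  ib <- match(correspondence$pos_b, profiles_b$refpos)
  miss <- is.na(ia) | is.na(ib)
  if (any(miss)) {
    msg <- paste0("correspondence references position(s) absent from ",
                  "profiles: ",
                  paste(utils::head(correspondence$pos_a[miss], 10L),
                        collapse = ", "))
    if (on_missing == "error") stop(msg) else warning(msg)
    correspondence <- correspondence[!miss, , drop = FALSE]
    ia <- ia[!miss]; ib <- ib[!miss]
  }
  ca <- profiles_a$conserved_class[ia]
  cb <- profiles_b$conserved_class[ib]
  div <- !is.na(ca) & !is.na(cb) & ca != cb
  data.frame(pos_a = correspondence$pos_a[div],
             pos_b = correspondence$pos_b[div],
             class_a = ca[div], class_b = cb[div],
             conservation_a = profiles_a$conservation[ia][div],
             conservation_b = profiles_b$conservation[ib][div],
             stringsAsFactors = FALSE)
}
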