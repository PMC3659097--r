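test_that("the default alphabet partitions the 20 standard residues", {
  ab <- reduced_alphabet()
  all_res <- unlist(ab, use.names = FALSE)
  expect_setequal(all_res, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_false(any(duplicated(all_res)))
  # mapping and re-expansion loses nothing
  cls <- residue_class(all_res, ab)
  expect_false(anyNA(cls))
  expect_setequal(unlist(ab[unique(cls)], use.names = FALSE), all_res)
  expect_equal(residue_class(c("K", "R"), ab), c("BASIC", "BASIC"))
  expect_equal(residue_class("P", ab), "P")
  expect_error(reduced_alphabet(list(A1 = c("K", "R"), A2 = "K")),
               "overlap")
})

test_that("column class counts and conservation match a hand count", {
  # column 'KKRRKDK' over 7 sequences: BASIC 6, ACIDIC 1
  seqs <- paste0(c("K", "K", "R", "R", "K", "D", "K"), "A")
  names(seqs) <- paste0("s", 1:7)
  aln <- family_alignment(seqs, "toy")
  pr <- profile_columns(aln, cons_threshold = 0.9)
  col1 <- pr[pr$refpos == 1, ]
  expect_equal(as.integer(col1$class_counts[[1]]["BASIC"]), 6L)
  expect_equal(as.integer(col1$class_counts[[1]]["ACIDIC"]), 1L)
  expect_equal(col1$conservation, 6 / 7, tolerance = 1e-12)
  expect_true(is.na(col1$conserved_class))   # 0.857 < 0.9
  expect_equal(col1$modal_class, "BASIC")
})

test_that("a single-sequence family is fully conserved", {
  aln <- family_alignment(c(only = "KDWP"), "solo")
  pr <- profile_columns(aln)
  expect_equal(pr$conservation, rep(1, 4))
  expect_equal(pr$conserved_class, c("BASIC", "ACIDIC", "AROMATIC", "P"))
})

test_that("a basic-only column is called BASIC at full conservation", {
  seqs <- c(ref = "KA", s2 = "RA", s3 = "KA", s4 = "RA")
  aln <- family_alignment(seqs, "fam", ref_start = 97L)
  pr <- profile_columns(aln)
  expect_equal(pr$refpos[1], 97L)
  expect_equal(pr$conserved_class[1], "BASIC")
  expect_equal(pr$conservation[1], 1.0)
})

test_that("profiles are invariant to sequence order", {
  fp <- make_family_pair(n_per_family = 10, L = 40, n_divergent = 4,
                         n_shared = 4, seed = 11)
  aln <- fp$aln_a
  perm <- c(1L, sample(2:10))   # keep the reference first
  aln2 <- family_alignment(aln$seqs[perm], aln$family_id,
                           reference_id = aln$reference_id)
  p1 <- profile_columns(aln)
  p2 <- profile_columns(aln2)
  expect_equal(p1$conservation, p2$conservation)
  expect_equal(p1$modal_class, p2$modal_class)
})

test_that("raising the threshold never adds conserved columns", {
  fp <- make_family_pair(n_per_family = 12, L = 60, n_divergent = 5,
                         n_shared = 5, noise_rate = 0.1, seed = 5)
  n_prev <- Inf
  for (th in c(0.7, 0.85, 1.0)) {
    pr <- profile_columns(fp$aln_a, cons_threshold = th)
    n <- sum(!is.na(pr$conserved_class))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("gaps and non-standard codes are excluded from conservation", {
  seqs <- c(ref = "KKK", s2 = "K-X", s3 = "KKK")
  aln <- family_alignment(seqs, "gappy")
  pr <- profile_columns(aln, max_gap = 0.5)
  expect_equal(pr$gap_fraction, c(0, 1 / 3, 1 / 3))
  expect_equal(pr$conservation, rep(1, 3))   # among non-gap residues
  pr2 <- profile_columns(aln, max_gap = 0.2)
  expect_equal(pr2$refpos, 1L)   # gappy columns filtered
})

test_that("correspondence building excludes gapped columns", {
  cm <- build_correspondence("AB-C", "A-DC")
  expect_equal(cm$pos_a, c(1L, 3L))
  expect_equal(cm$pos_b, c(1L, 3L))
  cm2 <- build_correspondence("KDE", "RNQ")
  expect_equal(cm2$pos_a, 1:3)
  expect_equal(cm2$pos_b, 1:3)
  expect_error(build_correspondence("AB", "ABC"), "malformed")
})

test_that("divergence calling recovers exactly the planted columns", {
  fp <- make_family_pair(n_per_family = 20, L = 120, n_divergent = 10,
                         n_shared = 10, noise_rate = 0, seed = 42)
  div <- call_divergent_positions(profile_columns(fp$aln_a),
                                  profile_columns(fp$aln_b))
  expect_identical(sort(div$pos_a), fp$truth$divergent_positions)
  expect_true(all(div$class_a != div$class_b))
})

test_that("identical families yield zero divergent pairs", {
  fp <- make_family_pair(n_per_family = 8, L = 50, n_divergent = 0,
                         n_shared = 5, seed = 9)
  pa <- profile_columns(fp$aln_a)
  div_self <- call_divergent_positions(pa, pa)
  expect_equal(nrow(div_self), 0L)
})

test_that("unknown correspondence positions error by default", {
  fp <- make_family_pair(n_per_family = 6, L = 30, n_divergent = 2,
                         n_shared = 2, seed = 3)
  pa <- profile_columns(fp$aln_a)
  pb <- profile_columns(fp$aln_b)
  cm <- identity_correspondence(c(1L, 999L))
  expect_error(call_divergent_positions(pa, pb, cm), "absent")
  expect_warning(call_divergent_positions(pa, pb, cm,
                                          on_missing = "skip"),
                 "absent")
})

test_that("aligned FASTA round trips through Biostrings", {
  fp <- make_family_pair(n_per_family = 5, L = 25, n_divergent = 2,
                         n_shared = 2, seed = 13)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_family_alignment(fp$aln_a, f)
  back <- read_family_alignment(f, "famA")
  expect_identical(back$seqs, fp$aln_a$seqs)
})
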