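# structural fixture with five hormone-receptor contact pairs; the
# receptor residues sit at positions 1..5
make_five_pair_fixture <- function() {
  toy <- make_toy_complex(list(c("LYS", "ASP", "SALT_BRIDGE", 3.5),
                               c("SER", "THR", "HBOND", 3.0),
                               c("ARG", "TYR", "CATION_PI", 5.0),
                               c("LEU", "VAL", "HYDROPHOBIC", 4.5),
                               c("SER", "GLU", "HBOND", 3.2)),
                          seed = 31)
  sel <- select_entities(toy$model, "A", "B")
  inter <- detect_interactions(toy$model, sel)
  intra <- detect_interactions(toy$model, sel, scope = "intra")
  list(model = toy$model, sel = sel,
       shells = assign_shells(inter, intra, sel, toy$model))
}

fake_divergent <- function(pos) {
  data.frame(pos_a = pos, pos_b = pos,
             class_a = rep("ACIDIC", length(pos)),
             class_b = rep("BASIC", length(pos)),
             conservation_a = rep(1, length(pos)),
             conservation_b = rep(1, length(pos)),
             stringsAsFactors = FALSE)
}

test_that("BSRs are the shell residues at divergent positions", {
  fx <- make_five_pair_fixture()
  calls <- call_bsrs(fx$shells,
                     divergent_receptor = fake_divergent(c(1L, 3L, 5L)))
  rc <- calls[calls$entity == "receptor", ]
  expect_equal(rc$resno, c(1L, 3L, 5L))
  expect_equal(rc$own_class, rep("ACIDIC", 3))
  expect_false(any(rc$waived))
  expect_true(all(rc$n_evidence >= 1))
  # BSR set is a subset of the shell set
  expect_true(all(paste(rc$chain, rc$resno) %in%
                    paste(fx$shells$chain, fx$shells$resno)))
  # no hormone divergence supplied: no hormone calls
  expect_equal(sum(calls$entity == "hormone"), 0L)
})

test_that("an empty divergent set yields zero BSRs", {
  fx <- make_five_pair_fixture()
  calls <- call_bsrs(fx$shells, divergent_receptor = fake_divergent(integer()))
  expect_equal(nrow(calls), 0L)
})

test_that("the structural-only waiver admits and labels non-divergent shells", {
  fx <- make_five_pair_fixture()
  calls <- call_bsrs(fx$shells,
                     divergent_receptor = fake_divergent(c(1L, 3L)),
                     admit_structural_only = TRUE)
  rc <- calls[calls$entity == "receptor", ]
  expect_setequal(rc$resno, 1:5)
  expect_equal(sort(rc$resno[rc$waived]), c(2L, 4L, 5L))
})

test_that("unmappable structure positions are skipped with a warning", {
  fx <- make_five_pair_fixture()
  map <- c("1" = 101L)   # only residue 1 mappable
  warns <- capture_warnings(
    calls <- call_bsrs(fx$shells,
                       divergent_receptor = fake_divergent(101L),
                       map_receptor = map))
  expect_gte(length(warns), 1L)
  expect_true(all(grepl("unmappable", warns)))
  expect_equal(calls$resno[calls$entity == "receptor"], 1L)
  expect_equal(calls$refpos[calls$entity == "receptor"], 101L)
})

test_that("curated receptor and hormone swap tables are reproduced", {
  ref <- gonadotropin_bsrs()
  swap_list <- function(tab, fam, L = 250L) {
    sub <- tab[tab$family == fam, ]
    other <- rep("G", L)
    other[sub$position] <- sub$partner
    make_mutant_spec(data.frame(position = sub$position, wt = sub$wt),
                     identity_correspondence(sub$position),
                     paste(other, collapse = ""), fam)
  }
  expect_equal(swap_list(ref$receptor, "FSHR")$string,
               c("E50R", "R52S", "V54A", "L55Y", "R101L", "E103Q",
                 "K104N", "K179G", "V221K"))
  expect_equal(swap_list(ref$hormone, "FSH")$string,
               c("P42V", "S89R", "D90S", "T95G", "V96G", "R97P",
                 "Y103T"))
  expect_equal(swap_list(ref$receptor, "LHR")$string,
               c("A54V", "Y55L", "L101R", "Q103E", "C128S", "Y178N",
                 "E199N"))
  lhm <- swap_list(ref$hormone, "LH")$string
  expect_length(lhm, 4L)
  expect_equal(lhm[1], "R89S")
})

test_that("identity substitutions are skipped and gaps omitted with warning", {
  bsrs <- data.frame(position = c(5L, 7L, 9L), wt = c("K", "A", "D"))
  other <- "AAAAKA-AE"   # pos 5 identical, pos 7 gap, pos 9 D->E
  expect_warning(
    spec <- make_mutant_spec(bsrs, identity_correspondence(c(5L, 7L, 9L)),
                             other),
    "gap")
  expect_equal(spec$string, "D9E")
})

test_that("wild-type mismatches are rejected when applying a spec", {
  spec <- make_mutant_spec(data.frame(position = 2L, wt = "K"),
                           identity_correspondence(2L), "ADA")
  expect_error(apply_mutant_spec("AAA", spec), "mismatch")
})

test_that("applying the swap spec reproduces the other reference", {
  for (s in 1:5) {
    fp <- make_family_pair(n_per_family = 10, L = 60, n_divergent = 6,
                           n_shared = 6, seed = 400 + s)
    div <- call_divergent_positions(profile_columns(fp$aln_a),
                                    profile_columns(fp$aln_b))
    ref_a <- unname(fp$aln_a$seqs[1])
    ref_b <- unname(fp$aln_b$seqs[1])
    wt <- substring(ref_a, div$pos_a, div$pos_a)
    spec <- make_mutant_spec(data.frame(position = div$pos_a, wt = wt),
                             identity_correspondence(div$pos_a), ref_b,
                             "swap")
    mutated <- apply_mutant_spec(ref_a, spec)
    for (p in spec$position)
      expect_equal(substring(mutated, p, p), substring(ref_b, p, p))
  }
})

test_that("cross-reactivity flags the compensating residues of other species", {
  sf <- synthetic_fsh_family()
  pr <- profile_columns(sf$aln)
  horse <- cross_react(sf$query_horse_lh, sf$aln, pr, sf$bsr_positions,
                       query_id = "horse_LH")
  chick <- cross_react(sf$query_chicken_lh, sf$aln, pr,
                       sf$bsr_positions, query_id = "chicken_LH")
  plain <- cross_react(sf$query_lh, sf$aln, pr, sf$bsr_positions,
                       query_id = "LH")
  expect_true(horse$per_position$match[horse$per_position$position == 96])
  expect_true(chick$per_position$match[chick$per_position$position == 42])
  expect_false(plain$per_position$match[plain$per_position$position == 96])
  expect_false(plain$per_position$match[plain$per_position$position == 42])
  # a member of the family itself is fully compatible
  member <- cross_react(unname(sf$aln$seqs[2]), sf$aln, pr,
                        sf$bsr_positions)
  expect_equal(member$score, 1.0)
})

test_that("a family member scores above shuffled sequences on average", {
  fp <- make_family_pair(n_per_family = 12, L = 60, n_divergent = 8,
                         n_shared = 4, seed = 77)
  pr <- profile_columns(fp$aln_a)
  bsr_pos <- fp$truth$divergent_positions
  member <- unname(fp$aln_a$seqs[3])
  s_member <- cross_react(member, fp$aln_a, pr, bsr_pos)$score
  withr::with_seed(99, {
    shuffled <- replicate(100, {
      q <- paste(sample(strsplit(member, "")[[1]]), collapse = "")
      cross_react(q, fp$aln_a, pr, bsr_pos)$score
    })
  })
  expect_gte(s_member, mean(shuffled))
})

test_that("pharmacophore features follow the residue dictionary", {
  stretch <- list(
    list(resname = "SER", chain = "P", resno = 89L),
    list(resname = "ASP", chain = "P", resno = 90L),
    list(resname = "GLY", chain = "P", resno = 93L),
    list(resname = "THR", chain = "P", resno = 95L),
    list(resname = "VAL", chain = "P", resno = 96L),
    list(resname = "ARG", chain = "P", resno = 97L),
    list(resname = "TYR", chain = "P", resno = 103L))
  m <- make_sparse_model(stretch)
  bsr_pos <- c(89L, 90L, 95L, 96L, 97L, 103L)
  ph <- extract_pharmacophore(m, "P", 89:103, bsr_positions = bsr_pos)
  got <- split(ph$feature, ph$resno)
  expect_setequal(got[["89"]], c("DONOR", "ACCEPTOR"))
  expect_setequal(got[["90"]], "ANION")
  expect_setequal(got[["95"]], c("DONOR", "ACCEPTOR"))
  expect_setequal(got[["96"]], "HYDROPHOBE")
  expect_setequal(got[["97"]], "CATION")
  expect_setequal(got[["103"]], c("AROMATIC", "DONOR"))
  expect_false("93" %in% names(got))   # non-BSR excluded by default
  # including non-BSR residues adds nothing for glycine
  ph_all <- extract_pharmacophore(m, "P", 89:103,
                                  bsr_positions = bsr_pos,
                                  include_non_bsr = TRUE)
  expect_false(93L %in% ph_all$resno)
})

test_that("an all-glycine stretch yields no features", {
  m <- make_sparse_model(list(list(resname = "GLY", chain = "G",
                                   resno = 1L),
                              list(resname = "GLY", chain = "G",
                                   resno = 2L)))
  ph <- extract_pharmacophore(m, "G", 1:2)
  expect_equal(nrow(ph), 0L)
})

test_that("a lone arginine gives one CATION feature anchored at CZ", {
  m <- make_sparse_model(list(list(resname = "ARG", chain = "R",
                                   resno = 1L)))
  ph <- extract_pharmacophore(m, "R", 1L)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$feature, "CATION")
  cz <- unlist(m[m$elety == "CZ", c("x", "y", "z")])
  expect_equal(unlist(ph[1, c("x", "y", "z")]), cz,
               ignore_attr = TRUE)
})

test_that("features are invariant under rigid-body motion", {
  stretch <- list(list(resname = "ASP", chain = "P", resno = 1L),
                  list(resname = "TYR", chain = "P", resno = 2L),
                  list(resname = "LYS", chain = "P", resno = 3L))
  m <- make_sparse_model(stretch)
  ph <- extract_pharmacophore(m, "P", 1:3)
  R <- bsrkit:::rotation_about(c(1, 2, 3), 1.1)
  t0 <- c(5, -7, 11)
  m2 <- m
  xyz <- as.matrix(m[, c("x", "y", "z")]) %*% t(R)
  m2$x <- xyz[, 1] + t0[1]; m2$y <- xyz[, 2] + t0[2]
  m2$z <- xyz[, 3] + t0[3]
  ph2 <- extract_pharmacophore(m2, "P", 1:3)
  expect_equal(nrow(ph2), nrow(ph))
  expect_equal(ph2$feature, ph$feature)
  moved <- as.matrix(ph[, c("x", "y", "z")]) %*% t(R) +
    matrix(t0, nrow(ph), 3, byrow = TRUE)
  expect_equal(as.matrix(ph2[, c("x", "y", "z")]), moved,
               tolerance = 1e-9, ignore_attr = TRUE)
})
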