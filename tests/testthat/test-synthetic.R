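test_that("toy complexes are deterministic under a fixed seed", {
  sp <- list(c("LYS", "ASP", "SALT_BRIDGE", 3.5),
             c("ARG", "TYR", "CATION_PI", 5.5))
  t1 <- make_toy_complex(sp, seed = 21)
  t2 <- make_toy_complex(sp, seed = 21)
  t3 <- make_toy_complex(sp, seed = 22)
  expect_identical(as.data.frame(t1$model), as.data.frame(t2$model))
  expect_false(identical(as.data.frame(t1$model),
                         as.data.frame(t3$model)))
})

test_that("family pair generation is deterministic and byte-identical", {
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  fp1 <- make_family_pair(n_per_family = 8, L = 40, n_divergent = 4,
                          n_shared = 4, noise_rate = 0.05, seed = 5)
  fp2 <- make_family_pair(n_per_family = 8, L = 40, n_divergent = 4,
                          n_shared = 4, noise_rate = 0.05, seed = 5)
  write_family_alignment(fp1$aln_a, f1)
  write_family_alignment(fp2$aln_a, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(fp1$truth, fp2$truth)
})

test_that("generated toy PDBs re-parse without warnings", {
  toy <- make_toy_complex(list(c("LYS", "ASP", "SALT_BRIDGE", 3.5),
                               c("TRP", "LYS", "CATION_PI", 4.5),
                               c("SER", "THR", "HBOND", 3.2)),
                          seed = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy$model, f)
  expect_no_warning(read_structure(f))
})

test_that("an empty spec yields two distant chains and no interactions", {
  toy <- make_toy_complex(list())
  sel <- select_entities(toy$model, "A", "B")
  expect_equal(nrow(detect_interactions(toy$model, sel)), 0L)
  xa <- as.matrix(toy$model[toy$model$chain == "A", c("x", "y", "z")])
  xb <- as.matrix(toy$model[toy$model$chain == "B", c("x", "y", "z")])
  dmin <- min(sqrt(outer(rowSums(xa^2), rep(1, nrow(xb))) +
                     outer(rep(1, nrow(xa)), rowSums(xb^2)) -
                     2 * xa %*% t(xb)))
  expect_gte(dmin, 10)
})

test_that("multi-pair toys plant each interaction independently", {
  toy <- make_toy_complex(list(c("ARG", "TYR", "CATION_PI", 5.5),
                               c("LEU", "VAL", "HYDROPHOBIC", 4.5)),
                          seed = 4)
  sel <- select_entities(toy$model, "A", "B")
  rec <- detect_interactions(toy$model, sel)
  expect_equal(nrow(rec), 2L)
  expect_setequal(rec$type, c("CATION_PI", "HYDROPHOBIC"))
  # pairs are isolated: no record couples different residue numbers
  expect_true(all(rec$resno_a == rec$resno_b))
})

test_that("infeasible or out-of-bound generator requests error", {
  expect_error(make_toy_complex(list(c("LYS", "ASP", "SALT_BRIDGE",
                                       -1))), "infeasible")
  expect_error(make_family_pair(L = 10, n_divergent = 8, n_shared = 8),
               "<= L")
  expect_error(make_family_pair(noise_rate = 0.7), "noise_rate")
})

test_that("residue templates carry the expected atom chemistry", {
  for (res in c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                "PRO", "SER", "THR", "TRP", "TYR", "VAL")) {
    xyz <- bsrkit:::build_residue_xyz(res)
    expect_true(all(c("N", "CA", "C", "O") %in% rownames(xyz)))
    expect_false(any(duplicated(rownames(xyz))))
    expect_true(all(is.finite(xyz)))
    # all bonded distances implied by the z-matrix stay physical
    d <- as.matrix(dist(xyz))
    expect_gt(min(d[upper.tri(d)]), 0.9)
  }
  # aromatic rings are near-planar and near-regular
  for (res in c("PHE", "TYR")) {
    xyz <- bsrkit:::build_residue_xyz(res)
    ring <- xyz[c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"), ]
    cen <- colMeans(ring)
    radii <- sqrt(rowSums(sweep(ring, 2, cen)^2))
    expect_lt(max(radii) - min(radii), 0.1)
  }
})
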