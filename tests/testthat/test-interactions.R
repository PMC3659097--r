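test_that("ionic band distinguishes salt bridge from electrostatic", {
  cases <- list(list(d = 3.5, type = "SALT_BRIDGE"),
                list(d = 4.5, type = "ELECTROSTATIC"),
                list(d = 7.0, type = NULL))
  for (cs in cases) {
    toy <- make_toy_complex(list(c("LYS", "ASP", "SALT_BRIDGE", cs$d)))
    sel <- select_entities(toy$model, "A", "B")
    rec <- detect_interactions(toy$model, sel)
    # independent check of the governing geometry
    expect_equal(atom_dist(toy$model, "A:1", "NZ", "B:1", "OD1"),
                 cs$d, tolerance = 1e-9)
    if (is.null(cs$type)) {
      expect_equal(nrow(rec), 0L)
    } else {
      expect_equal(nrow(rec), 1L)
      expect_equal(rec$type, cs$type)
      expect_equal(rec$distance, cs$d, tolerance = 1e-9)
    }
  }
})

test_that("a salt bridge is not double-reported as a hydrogen bond", {
  toy <- make_toy_complex(list(c("LYS", "ASP", "SALT_BRIDGE", 3.0)))
  sel <- select_entities(toy$model, "A", "B")
  rec <- detect_interactions(toy$model, sel)
  expect_equal(rec$type, "SALT_BRIDGE")
  expect_false("HBOND" %in% rec$type)
})

test_that("hydroxyl-to-carbonyl hydrogen bonds qualify in heavy-atom mode", {
  toy <- make_toy_complex(list(c("SER", "GLY", "HBOND", 2.9)))
  sel <- select_entities(toy$model, "A", "B")
  rec <- detect_interactions(toy$model, sel)
  expect_equal(rec$type, "HBOND")
  expect_equal(rec$atom_a, "OG")
  expect_equal(rec$atom_b, "O")
  hb <- hbond_candidates(toy$model, "A:1", "B:1")
  expect_gte(nrow(hb), 1L)
  expect_true(all(is.na(hb$dha_angle)))   # no hydrogens deposited
})

test_that("clash-range contacts are reported but flagged", {
  toy <- make_toy_complex(list(c("SER", "GLY", "HBOND", 2.0)))
  sel <- select_entities(toy$model, "A", "B")
  rec <- detect_interactions(toy$model, sel)
  expect_equal(rec$type, "HBOND")
  expect_true(rec$short_contact)
})

test_that("explicit donor hydrogens enforce the D-H-A angle", {
  # Ser donor with one hydrogen placed on the O-G..acceptor axis
  # (angle ~180, accepted) vs pointing away (angle ~0, rejected)
  base <- make_toy_complex(list(c("SER", "GLY", "HBOND", 3.7)))
  sel <- select_entities(base$model, "A", "B")
  # 3.7 exceeds the heavy-atom cutoff but is inside the with-H cutoff
  expect_equal(nrow(detect_interactions(base$model, sel)), 0L)
  add_h <- function(offset) {
    df <- as.data.frame(base$model)
    og <- unlist(df[df$elety == "OG", c("x", "y", "z")])
    h <- data.frame(chain = "A", resno = 1L, insert = "",
                    resid = "SER", elety = "HG", element = "H",
                    x = og[1] + offset[1], y = og[2] + offset[2],
                    z = og[3] + offset[3], occ = 1,
                    is_hydrogen = TRUE, is_sidechain = FALSE,
                    reskey = "A:1")
    df$reskey <- NULL; h$reskey <- NULL
    df <- rbind(df, h)
    df$reskey <- bsrkit:::reskey(df$chain, df$resno, df$insert)
    bsrkit:::structure_model(df, "ser_h")
  }
  # acceptor lies along +x from OG
  toward <- detect_interactions(add_h(c(0.96, 0, 0)), sel)
  away <- detect_interactions(add_h(c(-0.96, 0, 0)), sel)
  expect_true("HBOND" %in% toward$type)
  expect_false("HBOND" %in% away$type)
})

test_that("cation-pi triggers on centroid distance only", {
  near <- make_toy_complex(list(c("LYS", "PHE", "CATION_PI", 5.9)))
  far <- make_toy_complex(list(c("LYS", "PHE", "CATION_PI", 6.1)))
  off <- make_toy_complex(list(c("ARG", "PHE", "CATION_PI", 9.0)))
  for (cs in list(list(t = near, hit = TRUE), list(t = far, hit = FALSE),
                  list(t = off, hit = FALSE))) {
    sel <- select_entities(cs$t$model, "A", "B")
    rec <- detect_interactions(cs$t$model, sel)
    expect_equal("CATION_PI" %in% rec$type, cs$hit)
    cp <- cation_pi(cs$t$model, "A:1", "B:1")
    expect_equal(nrow(cp), as.integer(cs$hit))
  }
  cp <- cation_pi(near$model, "A:1", "B:1")
  expect_equal(cp$atom_cation, "NZ")
  expect_equal(cp$distance, 5.9, tolerance = 1e-9)
})

test_that("residue pairs beyond every cutoff yield nothing", {
  toy <- make_toy_complex(list(c("LYS", "ASP", "NONE", 12)))
  sel <- select_entities(toy$model, "A", "B")
  expect_equal(nrow(detect_interactions(toy$model, sel)), 0L)
})

test_that("pruned search equals brute-force scan on random systems", {
  for (s in 1:8) {
    m <- make_random_system(n_residues = 24, box = 22, seed = s)
    sel <- select_entities(m, "A", "B")
    for (sc in c("inter", "intra")) {
      a <- detect_interactions(m, sel, scope = sc, method = "prune")
      b <- detect_interactions(m, sel, scope = sc, method = "brute")
      expect_identical(record_set(a), record_set(b))
    }
  }
})

test_that("record sets are nested under increasing cutoffs", {
  scale_cfg <- function(f)
    geometry_config(hbond_da_max = 3.5 * f, hbond_da_max_h = 3.9 * f,
                    salt_bridge_max = 4.0 * f,
                    electrostatic_max = 6.0 * f,
                    hydrophobic_max = 5.0 * f, cation_pi_max = 6.0 * f)
  for (s in 1:5) {
    m <- make_random_system(n_residues = 20, box = 24, seed = 100 + s)
    sel <- select_entities(m, "A", "B")
    prev <- NULL
    for (f in c(0.6, 1.0, 1.4)) {
      rec <- detect_interactions(m, sel, config = scale_cfg(f))
      # salt bridges merge into the ionic class: the band boundary
      # moves with the cutoffs, the ionic union is what nests
      type <- sub("SALT_BRIDGE|ELECTROSTATIC", "IONIC", rec$type)
      cur <- paste(rec$label_a, rec$label_b, type)
      if (!is.null(prev)) expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("detection is symmetric under entity swap", {
  for (s in 1:5) {
    m <- make_random_system(n_residues = 20, box = 22, seed = 200 + s)
    ab <- detect_interactions(m, select_entities(m, "A", "B"))
    ba <- detect_interactions(m, select_entities(m, "B", "A"))
    expect_identical(record_set(ab), record_set(ba))
  }
})

test_that("every salt bridge also satisfies the ionic criterion", {
  cfg <- geometry_config()
  for (s in 1:5) {
    m <- make_random_system(n_residues = 24, box = 20, seed = 300 + s)
    rec <- detect_interactions(m, select_entities(m, "A", "B"),
                               config = cfg)
    sb <- rec[rec$type == "SALT_BRIDGE", ]
    expect_true(all(sb$distance <= cfg$salt_bridge_max))
    expect_true(all(sb$distance <= cfg$electrostatic_max))
  }
})

test_that("geometry config validates its cutoffs", {
  expect_error(geometry_config(salt_bridge_max = 7),
               "salt_bridge_max")
  expect_error(geometry_config(hydrophobic_max = -1), "positive")
})
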