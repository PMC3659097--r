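# Fixture builders shared across the test files.  Structures are
# assembled from the package's internal residue templates; expected
# geometric quantities are recomputed here from raw coordinates so the
# checks stay independent of the detector code paths.

# distance between two named atoms of a model
atom_dist <- function(model, key_a, atom_a, key_b, atom_b) {
  pa <- unlist(model[model$reskey == key_a & model$elety == atom_a,
                     c("x", "y", "z")])
  pb <- unlist(model[model$reskey == key_b & model$elety == atom_b,
                     c("x", "y", "z")])
  sqrt(sum((pa - pb)^2))
}

# hand-placed chain fixture for shell tests: hormone ASP (chain A,
# res 1) salt-bridged by receptor LYS (chain B, res 1); receptor GLU
# (chain B, res 2) linked to the LYS by an intra-molecular ionic
# contact at `link_dist`, placed on the +y side so the bodies stay
# clear of each other; receptor ARG (chain B, res 3) isolated far away.
make_shell_fixture <- function(link_dist = 3.5) {
  toy <- make_toy_complex(list(c("ASP", "LYS", "SALT_BRIDGE", 3.5)),
                          seed = 7)
  df <- as.data.frame(toy$model)
  df$reskey <- NULL
  lysnz <- unlist(df[df$resid == "LYS" & df$elety == "NZ",
                     c("x", "y", "z")])
  glu <- bsrkit:::build_residue_xyz("GLU")
  glu_p <- bsrkit:::orient_residue(glu, glu["OE1", ], c(0, -1, 0),
                                   spin = 0)
  glu_p <- sweep(glu_p, 2, lysnz + c(0, link_dist, 0), "+")
  arg <- bsrkit:::build_residue_xyz("ARG")
  arg_p <- sweep(arg, 2, c(60, 60, 60), "+")
  df2 <- rbind(df,
               bsrkit:::atom_rows(glu_p, "B", 2L, "GLU"),
               bsrkit:::atom_rows(arg_p, "B", 3L, "ARG"))
  df2$reskey <- bsrkit:::reskey(df2$chain, df2$resno, df2$insert)
  bsrkit:::structure_model(df2, "shell_fixture")
}

# place a list of residues (resname, chain, resno) on a wide grid so
# that nothing interacts; used for pharmacophore tests
make_sparse_model <- function(residues) {
  rows <- lapply(seq_along(residues), function(i) {
    r <- residues[[i]]
    xyz <- bsrkit:::build_residue_xyz(r$resname)
    xyz <- sweep(xyz, 2, c(0, 0, 25 * (i - 1)), "+")
    bsrkit:::atom_rows(xyz, r$chain, r$resno, r$resname)
  })
  df <- do.call(rbind, rows)
  df$reskey <- bsrkit:::reskey(df$chain, df$resno, df$insert)
  bsrkit:::structure_model(df, "sparse_fixture")
}

# canonical comparable view of an interaction record set
record_set <- function(rec) {
  sort(paste(rec$label_a, rec$atom_a, rec$label_b, rec$atom_b,
             rec$type, round(rec$distance, 6)))
}

# minimal hand-written PDB text (two residues, one CA each)
two_residue_pdb_text <- function() {
  c(paste0("ATOM      1  CA  ALA A   1       0.000   0.000   0.000",
           "  1.00  0.00           C"),
    paste0("ATOM      2  CA  GLY B   2      12.000   0.000   0.000",
           "  1.00  0.00           C"),
    "TER", "END")
}
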