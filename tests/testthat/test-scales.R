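test_that("residue atom counts exclude the peptide-bond backbone", {
  expect_equal(residue_atom_count("GLY"), 1)   # CA only
  expect_equal(residue_atom_count("ALA"), 2)   # CA, CB
  expect_equal(residue_atom_count("TRP"), 11)  # CA + 10 side-chain atoms
  expect_error(residue_atom_count("XYZ"), "no atom count")
})

test_that("per-atom scores divide the residue score by its atom count", {
  tab <- propensity_table("toy", stats::setNames(
    c(2.0, 1.0, rep(0.5, 18)), c("GLY", "ALA", setdiff(names(default_atom_counts()),
                                                        c("GLY", "ALA")))))
  expect_equal(per_atom_score("GLY", tab), 2.0)        # count 1
  expect_equal(per_atom_score("ALA", tab), 0.5)        # 1.0 / 2
  expect_equal(per_atom_score("TRP", tab), 0.5 / 11)
  expect_error(per_atom_score("XYZ", tab), "no score")
})

test_that("patch scores are linear per-atom sums", {
  hydro <- hydrophobicity_table()
  expect_equal(patch_score(toy_chain(numeric(0)), hydro), 0)

  ## k atoms of a single residue type score k * S / n
  p <- toy_chain(1:5, residue_type = "TRP")
  expect_equal(patch_score(p, hydro), 5 * 0.30 / 11)

  ## mixed patch equals an independent per-atom tally
  withr::local_seed(5)
  types <- sample(names(default_atom_counts()), 30, replace = TRUE)
  p2 <- toy_chain(1:30, residue_type = types)
  tally <- 0
  for (t in types) {
    tally <- tally + hydro$per_residue[[t]] / residue_atom_count(t)
  }
  expect_equal(patch_score(p2, hydro), tally, tolerance = 1e-12)
})

test_that("patch score is additive and reconstructs residue scores", {
  solv <- solvation_table()
  withr::local_seed(9)
  types <- sample(names(default_atom_counts()), 40, replace = TRUE)
  patch <- toy_chain(seq_len(40), residue_type = types)
  p1 <- patch[1:17, ]; p2 <- patch[18:40, ]
  expect_equal(patch_score(p1, solv) + patch_score(p2, solv),
               patch_score(patch, solv), tolerance = 1e-12)

  ## a full residue's per-atom scores sum back to the residue score
  for (t in c("GLY", "ALA", "ARG", "TRP")) {
    n <- residue_atom_count(t)
    full <- toy_chain(seq_len(n), residue_type = t, residue_seq = rep(1, n))
    expect_equal(patch_score(full, solv), solv$per_residue[[t]],
                 tolerance = 1e-12)
  }
})

test_that("derived RIP is a smoothed interface/reference frequency ratio", {
  aa <- names(default_atom_counts())
  ref <- toy_chain(seq_len(40), residue_type = rep(aa, 2), chain_id = "R")

  ## interface composition identical to the reference: all RIP = 1
  ifc <- manual_interface(ref[1:20, ], transform(ref[21:40, ], chain_id = "S"))
  rip <- derive_rip(list(ifc), list(ref), pseudocount = 0.5)
  expect_equal(unname(rip$per_residue), rep(1, 20))

  ## doubling every count leaves the ratio unchanged (pseudocount 0)
  rip1 <- derive_rip(list(ifc), list(ref), pseudocount = 0)
  rip2 <- derive_rip(list(ifc, ifc), list(ref, ref), pseudocount = 0)
  expect_equal(rip1$per_residue, rip2$per_residue)

  ## three-residue toy system against hand-computed ratios
  iface_types <- c("GLY", "GLY", "ALA")          # interface: 2 GLY, 1 ALA
  ref_types <- c("GLY", "ALA", "ALA", "SER")     # reference: 1/2/1
  toy_ifc <- manual_interface(
    toy_chain(1:3, residue_type = iface_types, chain_id = "A"),
    toy_chain(1, residue_type = "SER", chain_id = "B"))
  ## interface counts include both patches: GLY 2, ALA 1, SER 1 (N = 4)
  toy_rip <- derive_rip(list(toy_ifc),
                        list(toy_chain(1:4, residue_type = ref_types)),
                        pseudocount = 0.5)
  hand <- function(n_i, n_r) {
    ((n_i + 0.5) / (4 + 10)) / ((n_r + 0.5) / (4 + 10))
  }
  expect_equal(toy_rip$per_residue[["GLY"]], hand(2, 1))
  expect_equal(toy_rip$per_residue[["ALA"]], hand(1, 2))
  expect_equal(toy_rip$per_residue[["SER"]], hand(1, 1))
  expect_equal(toy_rip$per_residue[["TRP"]], hand(0, 0))

  ## strictly positive with pseudocount > 0; empty input errors
  expect_true(all(toy_rip$per_residue > 0))
  expect_error(derive_rip(list(), list(ref)), "at least one")
})

test_that("a residue interacting via many atoms counts once in RIP", {
  aa <- names(default_atom_counts())
  ref <- toy_chain(seq_len(20), residue_type = aa, chain_id = "R")
  multi <- toy_chain(1:3, residue_type = "GLY", residue_seq = c(1, 1, 1))
  single <- toy_chain(1, residue_type = "GLY")
  other <- toy_chain(1, residue_type = "ALA", chain_id = "B")
  r_multi <- derive_rip(list(manual_interface(multi, other)), list(ref))
  r_single <- derive_rip(list(manual_interface(single, other)), list(ref))
  expect_equal(r_multi$per_residue, r_single$per_residue)
})
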