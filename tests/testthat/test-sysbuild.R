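chain_tops <- function() {
  lapply(generate_chain_set(4, seed = 42), function(ch)
    assign_bonded_parameters(build_polymer_topology(ch)))
}

test_that("unimer placement respects the minimum-separation constraint", {
  fr <- place_unimers(10, chain_tops(), box = c(140, 140, 140), seed = 7)
  expect_equal(length(unique(fr$beads$mol_id)), 10L)
  # brute-force pairwise check under minimum image
  ids <- fr$beads$mol_id
  for (id in unique(ids)) {
    d <- pair_min_dist(fr$coords[ids == id, , drop = FALSE],
                       fr$coords[ids != id, , drop = FALSE], fr$box)
    expect_gte(min(d), 3.5)
  }
})

test_that("placement is deterministic under the seed and empty at n = 0", {
  tops <- chain_tops()
  a <- place_unimers(6, tops, box = c(120, 120, 120), seed = 3)
  b <- place_unimers(6, tops, box = c(120, 120, 120), seed = 3)
  expect_equal(a$coords, b$coords)
  expect_identical(a$beads, b$beads)
  e <- place_unimers(0, tops, box = c(50, 50, 50))
  expect_equal(nrow(e$coords), 0L)
  expect_equal(e$box, c(50, 50, 50))
})

test_that("chain types are apportioned 2:1:1:1", {
  fr <- place_unimers(40, chain_tops(), box = c(220, 220, 220), seed = 9)
  ct <- table(attr(fr, "chain_type"))
  expect_equal(as.integer(ct), 40L * c(2L, 1L, 1L, 1L) / 5L)
})

test_that("infeasible packing is rejected with a box suggestion", {
  expect_error(place_unimers(50, chain_tops(), box = c(30, 30, 30), seed = 1),
               "larger box")
})

test_that("placed centres are uniform over the box octants", {
  one_bead <- structure(list(
    molecule = "PT",
    beads = tibble::tibble(bead = "BB", type = "P2", size_class = "regular",
                           charge = 0, mass = 72, heavy_atoms = 4L,
                           role = "backbone", monomer = "M1",
                           monomer_index = 1L),
    bonds = tibble::tibble(i = integer(), j = integer(), length = double(),
                           kb = double()),
    angles = tibble::tibble(i = integer(), j = integer(), k = integer(),
                            theta = double(), ktheta = double()),
    dihedrals = tibble::tibble(i = integer(), j = integer(), k = integer(),
                               l = integer(), phi = double(), kphi = double(),
                               mult = integer()),
    exclusions = tibble::tibble(i = integer(), j = integer()),
    variant = "nonstandard"), class = "cg_topology")
  fr <- place_unimers(400, list(one_bead), box = c(100, 100, 100), seed = 5)
  oct <- 1 + (fr$coords[, 1] > 50) + 2 * (fr$coords[, 2] > 50) +
    4 * (fr$coords[, 3] > 50)
  p <- stats::chisq.test(table(factor(oct, levels = 1:8)))$p.value
  expect_gt(p, 1e-3)
})

test_that("cargo insertion preserves the frame and avoids the assembly", {
  mic <- make_micelle(8, seed = 4)
  dii <- assign_bonded_parameters(build_dii_topology())
  expect_identical(insert_cargo(mic, dii, 0), mic)
  fr <- insert_cargo(mic, dii, 5, seed = 6)
  expect_equal(sum(fr$beads$molecule == "DII") / nrow(dii$beads), 5)
  # existing molecules untouched
  expect_equal(fr$coords[seq_len(nrow(mic$coords)), ], mic$coords)
  # brute-force overlap check: every DiI bead >= min_sep from assembly beads
  dii_idx <- which(fr$beads$molecule == "DII")
  d <- pair_min_dist(fr$coords[dii_idx, , drop = FALSE],
                     fr$coords[-dii_idx, , drop = FALSE], fr$box)
  expect_gte(min(d), 3.5)
  # cargo starts outside the assembly's bounding sphere
  agg_com <- colMeans(mic$coords)
  agg_rad <- sqrt(max(rowSums(sweep(mic$coords, 2, agg_com)^2)))
  for (id in unique(fr$beads$mol_id[dii_idx])) {
    com <- colMeans(fr$coords[fr$beads$mol_id == id & fr$beads$molecule == "DII", ,
                              drop = FALSE])
    expect_gt(sqrt(sum((com - agg_com)^2)), agg_rad)
  }
})

test_that("proteins are placed with Zn in the 5-10 A ligand window", {
  mic <- make_micelle(12, seed = 2)
  prot <- make_synthetic_zn_protein()
  expect_identical(place_proteins_near_ligands(mic, prot, 0), mic)
  fr <- place_proteins_near_ligands(mic, prot, n = 4, seed = 3)
  zn <- which(fr$beads$bead == "ZN")
  expect_length(zn, 4L)
  anchors <- which(fr$beads$role == "ligand_anchor")
  d <- pair_min_dist(fr$coords[zn, , drop = FALSE],
                     fr$coords[anchors, , drop = FALSE], fr$box)
  nearest <- apply(d, 1, min)
  expect_true(all(nearest >= 5 & nearest <= 10))
  # each Zn sits near a distinct anchor
  expect_equal(length(unique(apply(d, 1, which.min))), 4L)
  # asking for more proteins than exposed anchors errors
  expect_error(place_proteins_near_ligands(mic, prot, n = 500, seed = 1),
               "exposed ligand")
})

test_that("run-parameter sets match the protocol field for field", {
  rp <- emit_run_parameters("production")
  expect_equal(rp$timestep_fs, 10)
  expect_equal(rp$nstlist, 20L)
  expect_equal(rp$vdw_cutoff_nm, 1.1)
  expect_equal(rp$coulomb_cutoff_nm, 1.1)
  expect_equal(rp$epsilon_r, 15)
  expect_equal(rp$ref_t_K, 303)
  expect_equal(rp$tau_t_ps, 0.5)
  expect_equal(rp$ref_p_bar, 1)
  expect_equal(rp$compressibility_bar, 4.5e-5)
  expect_equal(rp$tau_p_ps, 4.0)
  mdp <- write_mdp(rp)
  expect_true(any(grepl("^dt\\s+= 0.01$", mdp)))
  expect_true(any(grepl("epsilon_r\\s+= 15", mdp)))
  mn <- emit_run_parameters("minimize")
  expect_equal(mn$integrator, "steep")
  expect_equal(mn$nsteps, 5000L)
  eq <- emit_run_parameters("equilibrate")
  expect_equal(eq$posres_fc_kcal_A2, 0.1)
  expect_true(any(grepl("-DPOSRES", write_mdp(eq))))
  expect_error(emit_run_parameters("anneal"))
})

test_that("solvation bookkeeping neutralises the system", {
  mic <- make_micelle(6, seed = 1)
  dii <- assign_bonded_parameters(build_dii_topology())
  fr <- insert_cargo(mic, dii, 3, seed = 2)
  sv <- solvate_count(fr)
  expect_equal(sv$net_charge, 0)
  expect_equal(sv$n_cl, 3)  # three +1 DiI molecules
  expect_gt(sv$n_water, 0)
  top <- write_system_top(fr)
  expect_true(any(grepl("^DII\\s+3$", top)))
  expect_true(any(grepl("^CL\\s+3$", top)))
})
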