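single_m3_chain <- function() {
  generate_chain_set(1, constraints = list(m1 = c(5, 5), m2 = c(4, 4),
                                           m3 = c(1, 1)),
                     seed = 5, balanced = FALSE)[[1]]
}

test_that("P1 topology carries the ligand beads and zero net charge", {
  ch <- single_m3_chain()
  top <- build_polymer_topology(ch, "nonstandard")
  suf <- top$beads[top$beads$role == "binding_site", ]
  bsd <- top$beads[top$beads$role == "ligand_anchor", ]
  expect_equal(nrow(suf), 1L)
  expect_equal(suf$type, "P6")
  expect_equal(nrow(bsd), 1L)
  expect_equal(bsd$type, "TN6d")
  expect_equal(total_charge(top), 0)
})

test_that("all generated P1 topologies are charge neutral in both variants", {
  # independent brute-force summation over the raw per-bead charge column
  chains <- generate_chain_set(50, seed = 21, balanced = FALSE)
  for (v in c("nonstandard", "strict_standard")) {
    qs <- vapply(chains, function(ch) {
      b <- build_polymer_topology(ch, v)$beads
      sum(b$charge)
    }, numeric(1))
    expect_true(all(qs == 0))
  }
})

test_that("the two model variants differ only in the override table", {
  ch <- single_m3_chain()
  ns <- build_polymer_topology(ch, "nonstandard")
  ss <- build_polymer_topology(ch, "strict_standard")
  expect_identical(nrow(ns$beads), nrow(ss$beads))
  expect_identical(ns$bonds[c("i", "j")], ss$bonds[c("i", "j")])
  expect_identical(ns$angles[c("i", "j", "k")], ss$angles[c("i", "j", "k")])
  diff_idx <- which(ns$beads$type != ss$beads$type)
  ov <- variant_overrides()
  expect_setequal(ns$beads$bead[diff_idx],
                  ov$bead[ov$molecule %in% c("M1", "M2", "M3")])
  expect_identical(ns$beads$type[diff_idx],
                   ov$nonstandard[match(ns$beads$bead[diff_idx], ov$bead)])
  expect_identical(ss$beads$type[diff_idx],
                   ov$strict_standard[match(ss$beads$bead[diff_idx], ov$bead)])
  # everything except the type column is identical
  expect_identical(ns$beads[setdiff(names(ns$beads), "type")],
                   ss$beads[setdiff(names(ss$beads), "type")])
})

test_that("heavy-atom mapping follows size class with the single M3 amide exception", {
  ch <- single_m3_chain()
  b <- build_polymer_topology(ch)$beads
  expected <- c(regular = 4L, small = 3L, tiny = 2L)
  ok <- b$heavy_atoms == expected[b$size_class]
  exceptions <- b[!ok, ]
  expect_equal(nrow(exceptions), sum(ch$sequence == "M3"))
  expect_true(all(exceptions$bead == "AMD" & exceptions$heavy_atoms == 6L))
})

test_that("the polymer backbone is a linear path", {
  ch <- generate_chain_set(1, seed = 9, balanced = FALSE)[[1]]
  top <- build_polymer_topology(ch)
  bb <- which(top$beads$role == "backbone")
  is_bb_bond <- top$bonds$i %in% bb & top$bonds$j %in% bb
  expect_equal(sum(is_bb_bond), length(bb) - 1L)
  deg <- table(factor(c(top$bonds$i[is_bb_bond], top$bonds$j[is_bb_bond]),
                      levels = bb))
  expect_equal(sum(deg == 1), 2L)       # two chain ends
  expect_true(all(deg <= 2))            # no branching along the backbone
})

test_that("unknown monomer labels are rejected", {
  ch <- single_m3_chain()
  ch$sequence[1] <- "M9"
  expect_error(build_polymer_topology(ch), "M9")
})

test_that("DiI carries +1 as two +0.5 head beads and equal tails", {
  for (v in c("nonstandard", "strict_standard")) {
    dii <- build_dii_topology(v)
    expect_equal(total_charge(dii), 1)
    charged <- dii$beads[dii$beads$charge != 0, ]
    expect_equal(nrow(charged), 2L)
    expect_true(all(charged$charge == 0.5))
    expect_true(all(charged$role == "head"))
    tails <- dii$beads$bead[dii$beads$role == "tail"]
    expect_equal(sum(grepl("^TA", tails)), sum(grepl("^TB", tails)))
    expect_gt(sum(dii$beads$role == "head"), 0)
  }
  ns <- build_dii_topology("nonstandard")
  ss <- build_dii_topology("strict_standard")
  lnk <- which(ns$beads$bead == "LNK")
  expect_equal(ns$beads$type[lnk], "TN6d")
  expect_equal(ss$beads$type[lnk], "TC1")
  expect_identical(ns$beads$type[-lnk], ss$beads$type[-lnk])
})

test_that("bonded-parameter assignment fills every slot and honours references", {
  ch <- single_m3_chain()
  top <- assign_bonded_parameters(build_polymer_topology(ch))
  # independent exhaustive slot scan over all parameter columns
  expect_false(anyNA(top$bonds$length) || anyNA(top$bonds$kb) ||
               anyNA(top$angles$theta) || anyNA(top$angles$ktheta) ||
               anyNA(top$dihedrals$phi) || anyNA(top$dihedrals$kphi))
  # already parameterised -> identity
  expect_identical(assign_bonded_parameters(top), top)
  # named reference distance wins over the shipped default
  raw <- build_polymer_topology(ch)
  b1 <- raw$bonds$i[1]; b2 <- raw$bonds$j[1]
  key <- paste0(raw$beads$bead[b1], "-", raw$beads$bead[b2])
  ref <- stats::setNames(4.2, key)
  top2 <- assign_bonded_parameters(raw, reference = ref)
  expect_equal(top2$bonds$length[1], 4.2)
  # coordinate-matrix reference: bond lengths measured from geometry
  dii <- build_dii_topology()
  xyz <- matrix(seq_len(nrow(dii$beads) * 3), ncol = 3) * 1.0
  top3 <- assign_bonded_parameters(dii, reference = xyz)
  d17 <- sqrt(sum((xyz[dii$bonds$i[1], ] - xyz[dii$bonds$j[1], ])^2))
  expect_equal(top3$bonds$length[1], d17)
})

test_that("a bond with neither default nor reference is reported by name", {
  ch <- single_m3_chain()
  top <- build_polymer_topology(ch)
  top$beads$size_class[1] <- "colossal"  # no default for this class pair
  expect_error(assign_bonded_parameters(top), top$beads$bead[1])
})
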