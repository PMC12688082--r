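base_params <- function() nonbond_table(c("W", "P6", "TP1", "TP2", "ZN"),
                                        sigma = c(4.7, 4.7, 4.1, 4.1, 3.4),
                                        epsilon = c(1.0, 1.2, 0.9, 0.8, 0.5))

test_that("protein-water scaling duplicates bead types and scales only the W pair", {
  nb <- base_params()
  patched <- scale_protein_water(nb, c("TP1", "TP2"), factor = 1.10)
  fp <- function(p, a, b) {
    k <- paste(pmin(p$type_a, p$type_b), pmax(p$type_a, p$type_b), sep = "|")
    which(k == paste(min(a, b), max(a, b), sep = "|"))
  }
  # duplicated self and cross rows exist
  expect_length(fp(patched, "WTP1", "WTP1"), 1L)
  expect_length(fp(patched, "WTP1", "TP1"), 1L)
  # epsilon(WX-W) = 1.10 * epsilon(X-W), sigma untouched
  for (x in c("TP1", "TP2")) {
    wx <- paste0("W", x)
    expect_equal(patched$epsilon[fp(patched, wx, "W")],
                 1.10 * patched$epsilon[fp(patched, x, "W")])
    expect_equal(patched$sigma[fp(patched, wx, "W")],
                 patched$sigma[fp(patched, x, "W")])
    # every non-water cross term of WX matches X
    for (y in c("P6", "ZN")) {
      expect_equal(patched$epsilon[fp(patched, wx, y)],
                   patched$epsilon[fp(patched, x, y)])
    }
  }
  # base rows are untouched (conservation)
  expect_identical(patched[seq_len(nrow(nb)), ], nb)
  # idempotence
  expect_identical(scale_protein_water(patched, c("TP1", "TP2"), 1.10),
                   patched)
})

test_that("unit factor scaling equals the base set up to renaming", {
  nb <- base_params()
  p <- scale_protein_water(nb, "TP1", factor = 1.0)
  renamed <- p[p$type_a == "WTP1" | p$type_b == "WTP1", ]
  unW <- function(x) ifelse(x == "WTP1", "TP1", x)
  for (r in seq_len(nrow(renamed))) {
    a <- unW(renamed$type_a[r]); b <- unW(renamed$type_b[r])
    k <- paste(pmin(nb$type_a, nb$type_b), pmax(nb$type_a, nb$type_b), sep = "|")
    orig <- which(k == paste(min(a, b), max(a, b), sep = "|"))
    expect_equal(renamed$sigma[r], nb$sigma[orig])
    expect_equal(renamed$epsilon[r], nb$epsilon[orig])
  }
})

test_that("scaling rejects unknown types and non-positive factors", {
  expect_error(scale_protein_water(base_params(), "NOPE"), "NOPE")
  expect_error(scale_protein_water(base_params(), "TP1", factor = 0), "> 0")
})

test_that("the Zn-P6 cross term is written as 5 A / 15 kcal/mol (0.5 nm / 62.76 kJ/mol)", {
  p <- add_zn_ligand_crossterm(base_params())
  lines <- write_nonbond_params(p)
  znrow <- grep("^ZN\\s+P6|^P6\\s+ZN", lines, value = TRUE)
  expect_length(znrow, 1L)
  f <- strsplit(trimws(znrow), "\\s+")[[1]]
  expect_equal(as.numeric(f[4]), 0.5)      # nm
  expect_equal(as.numeric(f[5]), 62.76)    # kJ/mol = 15 * 4.184 exactly
  # parse back: unit round-trip within 1e-6 relative
  rt <- read_nonbond_params(lines)
  k <- paste(pmin(rt$type_a, rt$type_b), pmax(rt$type_a, rt$type_b), sep = "|")
  i <- which(k == "P6|ZN")
  expect_equal(rt$sigma[i], 5, tolerance = 1e-6)
  expect_equal(rt$epsilon[i], 15, tolerance = 1e-6)
})

test_that("the cross-term LJ minimum sits at 2^(1/6) sigma", {
  # independent numerical minimisation of the 12-6 potential
  lj <- function(r, sigma = 5, eps = 15) 4 * eps * ((sigma / r)^12 - (sigma / r)^6)
  rmin <- stats::optimize(lj, c(3, 12))$minimum
  expect_equal(rmin, 2^(1/6) * 5, tolerance = 1e-4)
  expect_equal(rmin, 5.612, tolerance = 1e-3)
})

test_that("cross-term patching is idempotent and rejects conflicts", {
  p <- add_zn_ligand_crossterm(base_params())
  p2 <- add_zn_ligand_crossterm(p)
  expect_equal(as.data.frame(p2), as.data.frame(p))
  expect_error(add_zn_ligand_crossterm(p, crossterm_spec(sigma = 6)),
               "conflict")
  expect_error(
    add_zn_ligand_crossterm(base_params(), crossterm_spec(bead_a = "XX")),
    "XX")
})

test_that("Zn coordination adds exactly three 2.4 A bonds and retypes Zn as SD", {
  top <- make_synthetic_zn_protein()
  n0 <- nrow(top$bonds)
  patched <- add_zn_coordination(top)
  new <- patched$bonds[(n0 + 1):nrow(patched$bonds), ]
  expect_equal(nrow(new), 3L)
  expect_true(all(new$length == 2.4))
  zn <- which(patched$beads$bead == "ZN")
  expect_equal(patched$beads$type[zn], "SD")
  expect_equal(patched$beads$mass[zn], 65.4)
  # the three bonds reach the three labelled histidine side chains
  his <- which(patched$beads$residue %in% c("H93", "H95", "H188"))
  expect_setequal(setdiff(c(new$i, new$j), zn), his)
  # idempotence
  expect_identical(add_zn_coordination(patched), patched)
})

test_that("missing coordination residues are reported by name", {
  top <- make_synthetic_zn_protein()
  keep <- top$beads$residue != "H95" & top$beads$residue != "H188"
  top$beads <- top$beads[keep, ]
  err <- tryCatch(add_zn_coordination(top), error = conditionMessage)
  expect_match(err, "H95")
  expect_match(err, "H188")
  expect_no_match(err, "H93")
  # and a topology without a Zn bead is rejected
  top2 <- make_synthetic_zn_protein()
  top2$beads <- top2$beads[top2$beads$bead != "ZN", ]
  expect_error(add_zn_coordination(top2), "Zn")
})
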