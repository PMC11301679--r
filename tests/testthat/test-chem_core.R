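# Elemental compositions, residue/protein bookkeeping, masses and
# isotope patterns.

test_that("composition arithmetic is valid, commutative and non-negative", {
  a <- composition(C = 2, H = 5)
  b <- composition(H = 1, O = 2)
  expect_equal(comp_add(a, b), comp_add(b, a))
  expect_equal(comp_add(comp_add(a, b), a),
               comp_add(a, comp_add(b, a)))
  expect_error(comp_add(composition(H = 1), c(H = -2)), "below zero")
  expect_error(composition(Xx = 1), "unknown element")
  expect_equal(parse_formula("C6H7NO2"),
               composition(C = 6, H = 7, N = 1, O = 2))
  expect_equal(parse_formula(""), composition())
})

test_that("composition_from_sequence sums residues plus water", {
  g <- protein_species("g", "G")
  expect_equal(composition_from_sequence(g),
               composition(C = 2, H = 5, N = 1, O = 2))
  expect_equal(monoisotopic_mass(composition_from_sequence(g)),
               75.0320, tolerance = 1e-4)
  gg <- protein_species("gg", "GG")
  expect_equal(monoisotopic_mass(composition_from_sequence(gg)),
               132.0535, tolerance = 1e-4)
  expect_error(protein_species("bad", "GXG"), "position 2")
})

test_that("the MT3 fixture has the documented sequence bookkeeping", {
  expect_equal(n_residues(mt3), 68L)
  expect_equal(n_cysteines(mt3), 20L)
  comp <- composition_from_sequence(mt3)
  # 20 Cys + 1 Met, each carrying one sulfur
  expect_equal(unclass(comp)[["S"]], 21)
  expect_equal(average_mass(comp), 6926.97, tolerance = 0.05)
  # first two labelable cysteines in Met-inclusive numbering
  expect_equal(cys_positions(mt3)[1:2], c(6L, 8L))
})

test_that("monoisotopic and average masses follow the standard tables", {
  h2o <- composition(H = 2, O = 1)
  expect_equal(monoisotopic_mass(h2o), 18.0106, tolerance = 1e-4)
  expect_equal(average_mass(h2o), 18.015, tolerance = 1e-3)
  expect_equal(monoisotopic_mass(composition()), 0)
  expect_equal(average_mass(composition()), 0)
  # Cd convention: most-abundant isotope (114) vs lightest (106)
  cd <- composition(Cd = 1)
  expect_equal(monoisotopic_mass(cd), 113.9034, tolerance = 1e-4)
  expect_equal(monoisotopic_mass(cd, convention = "lightest"),
               105.9065, tolerance = 1e-4)
})

test_that("single-atom isotope patterns equal the elemental table", {
  p <- isotope_pattern(composition(H = 1))
  iso <- metalloMS:::.ISOTOPES$H
  expect_equal(p$mass, iso$mass, tolerance = 1e-12)
  expect_equal(p$abundance, iso$abundance, tolerance = 1e-12)
})

test_that("patterns match brute-force enumeration on small molecules", {
  for (f in c("CH4", "C2H2O", "H2OS", "CHNO")) {
    comp <- parse_formula(f)
    p <- isotope_pattern(comp, prune = 1e-12)
    bf <- brute_force_pattern(comp)
    keep <- bf$abundance > max(bf$abundance) * 1e-12
    expect_equal(p$mass, bf$mass[keep], tolerance = 1e-9, info = f)
    expect_equal(p$abundance, bf$abundance[keep] / sum(bf$abundance[keep]),
                 tolerance = 1e-12, info = f)
  }
})

test_that("patterns are normalized, sorted and pruned", {
  p <- isotope_pattern(composition_from_sequence(mt3), prune = 1e-6)
  expect_equal(sum(p$abundance), 1, tolerance = 1e-9)
  expect_true(all(diff(p$mass) > 0))
  expect_true(all(p$abundance >= max(p$abundance) * 1e-6))
})

test_that("pattern of A+B equals the convolution of the two patterns", {
  set.seed(42)
  for (rep in 1:5) {
    a <- composition(C = sample(1:4, 1), H = sample(1:6, 1),
                     S = sample(0:1, 1))
    b <- composition(N = sample(1:3, 1), O = sample(1:3, 1))
    pa <- isotope_pattern(a, prune = 1e-10)
    pb <- isotope_pattern(b, prune = 1e-10)
    conv <- metalloMS:::.convolve_patterns(pa, pb, 1e-10, 0.2)
    conv$abundance <- conv$abundance / sum(conv$abundance)
    pab <- isotope_pattern(comp_add(a, b), prune = 1e-10)
    # align by mass: every direct-pattern entry must appear in the
    # convolution with the same abundance (up to pruning tolerance)
    # abundances must agree tightly; aggregated masses may shift by the
    # abundance-weighted-mean regrouping, well under the 0.2 Da width
    for (k in seq_along(pab$mass)) {
      j <- which.min(abs(conv$mass - pab$mass[k]))
      expect_lt(abs(conv$mass[j] - pab$mass[k]), 0.005)
      expect_lt(abs(conv$abundance[j] - pab$abundance[k]), 1e-8)
    }
  }
})

test_that("average mass equals the abundance-weighted pattern mean", {
  for (f in c("C6H7NO2", "C2H3NO", "C10H15N3O5S")) {
    comp <- parse_formula(f)
    p <- isotope_pattern(comp, prune = 1e-12)
    expect_equal(sum(p$mass * p$abundance), average_mass(comp),
                 tolerance = 0.01, info = f)
  }
})

test_that("adduct deltas match the stated chemistry and invert exactly", {
  expect_equal(adduct_delta("NEM")$formula,
               composition(C = 6, H = 7, N = 1, O = 2))
  expect_equal(adduct_delta("CAM")$formula,
               composition(C = 2, H = 3, N = 1, O = 1))
  expect_equal(adduct_delta("Cu_I")$h_displaced, 1L)
  expect_equal(adduct_delta("Zn_II")$h_displaced, 2L)
  expect_equal(adduct_delta("Cd_II")$h_displaced, 2L)
  expect_equal(adduct_delta("SS")$h_displaced, 2L)
  expect_equal(adduct_delta("SS")$cys_consumed, 2L)
  expect_equal(adduct_delta("NtermAcetyl")$formula,
               composition(C = 2, H = 2, O = 1))
  comp <- composition_from_sequence(mt3)
  for (ad in c("Cu_I", "Zn_II", "Cd_II", "NEM", "CAM", "SS")) {
    round_trip <- apply_adduct(apply_adduct(comp, ad, 2), ad, -2)
    expect_equal(round_trip, comp, info = ad)
  }
})

test_that("FASTA reading returns protein species with intact sequences", {
  fa <- system.file("extdata", "P25713_MT3_human.fasta",
                    package = "metalloMS")
  prots <- read_fasta(fa)
  expect_length(prots, 1)
  expect_equal(prots[[1]]$sequence, mt3$sequence)
  # multi-record
  tmp <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "GGC", ">b", "MKC"), tmp)
  two <- read_fasta(tmp)
  expect_length(two, 2)
  expect_equal(two$b$sequence, "MKC")
})

test_that("chemistry config round-trips through YAML with defaults", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("metals:", "  - Cu_I", "min_cys_per_metal: 2"), tmp)
  cfg <- read_chem_config(tmp)
  expect_equal(cfg$metals, "Cu_I")
  expect_equal(cfg$min_cys_per_metal, 2)
  expect_equal(cfg$ppm_tol, default_chem_config()$ppm_tol)
})
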