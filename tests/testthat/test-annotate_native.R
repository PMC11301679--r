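# Theoretical profiles, cosine fit scoring and isotope-pattern-based
# annotation with NNLS deconvolution.

test_that("high resolving power resolves the isotopologue apexes", {
  mfc <- metalloform(n_cu = 4, n_ss = 2, z = 5)
  prof <- theoretical_profile(mt3, mfc, resolving_power = 2e5)
  pat <- isotope_pattern(metalloform_composition(mt3, mfc))
  theo_mz <- (pat$mass + 5 * PROTON_MASS) / 5
  main <- theo_mz[pat$abundance > 0.2 * max(pat$abundance)]
  for (m in main) {
    j <- which(abs(prof$mz - m) < 0.02)
    expect_true(any(prof$intensity[j] > 0.1))
  }
})

test_that("low resolving power merges into one envelope at the average m/z", {
  mfc <- metalloform(n_cu = 4, n_zn = 4, n_ss = 2, z = 5)
  prof <- theoretical_profile(mt3, mfc, resolving_power = 800)
  # single envelope: intensity-weighted centroid near the average-mass m/z
  cen <- sum(prof$mz * prof$intensity) / sum(prof$intensity)
  expect_equal(cen, mz(mt3, mfc, "average"), tolerance = 0.05)
})

test_that("apex m/z follows charge arithmetic between 1+ and 2+", {
  mfc1 <- metalloform(n_cu = 1, z = 1)
  mfc2 <- metalloform(n_cu = 1, z = 2)
  p1 <- theoretical_profile(mt3, mfc1, resolving_power = 5000)
  p2 <- theoretical_profile(mt3, mfc2, resolving_power = 5000)
  M <- neutral_mass(mt3, mfc1, "monoisotopic")
  expected_ratio <- (M + PROTON_MASS) / ((M + 2 * PROTON_MASS) / 2)
  expect_equal(attr(p1, "apex_mz") / attr(p2, "apex_mz"), expected_ratio,
               tolerance = 1e-3)
})

test_that("score is 1 on itself, 0 off-support, and scale-invariant", {
  mfc <- metalloform(n_cu = 4, n_ss = 2, z = 5)
  prof <- theoretical_profile(mt3, mfc)
  expect_equal(score_fit(prof, prof), 1, tolerance = 1e-9)
  far <- mass_spectrum(prof$mz + 50, prof$intensity, "profile")
  expect_equal(score_fit(far, prof), 0)
  scaled <- mass_spectrum(prof$mz, prof$intensity * 737.3, "profile")
  expect_equal(score_fit(scaled, prof), score_fit(prof, prof),
               tolerance = 1e-12)
  expect_warning(s0 <- score_fit(prof, prof, window = c(1, 2)), "empty")
  expect_equal(s0, 0)
})

test_that("the true species outscores every candidate differing by a metal", {
  cands <- enumerate_candidates(mt3, list(cu = c(0, 6), zn = c(0, 4),
                                          ss = c(2, 2)), charges = 5L)
  truth <- metalloform(n_cu = 4, n_zn = 4, n_ss = 2, z = 5)
  sim <- simulate_native(simulation_spec(
    mt3, list(list(mfc = truth, abundance = 1)), snr = 20, seed = 101))
  res <- annotate(sim, cands)
  expect_gt(nrow(res), 0)
  true_score <- res$score[res$species == "Cu4Zn4SS2"]
  expect_length(true_score, 1)
  others <- res$score[res$species != "Cu4Zn4SS2"]
  if (length(others) > 0) expect_true(all(true_score > others))
})

test_that("a simulated seven-metalloform mixture is fully recovered", {
  seven <- list(c(4, 0), c(4, 1), c(4, 2), c(4, 3), c(4, 4), c(5, 4),
                c(6, 4))
  species <- lapply(seven, function(cz)
    list(mfc = metalloform(n_cu = cz[1], n_zn = cz[2], n_ss = 2, z = 5),
         abundance = 1))
  cands <- enumerate_candidates(mt3, list(cu = c(0, 6), zn = c(0, 4),
                                          ss = c(2, 2)), charges = 5L)
  sim <- simulate_native(simulation_spec(mt3, species, snr = 50,
                                         seed = 202))
  res <- annotate(sim, cands)
  labels <- vapply(species, function(sp) metalloform_label(sp$mfc),
                   character(1))
  for (lab in labels) {
    expect_true(lab %in% res$species, info = lab)
    expect_gt(res$abundance[res$species == lab], 0.3)
  }
})

test_that("annotating an empty spectrum or empty candidates yields nothing", {
  cands <- enumerate_candidates(mt3, list(cu = c(0, 2), ss = c(2, 2)),
                                charges = 5L)
  empty <- mass_spectrum(numeric(0), numeric(0), "profile")
  expect_equal(nrow(annotate(empty, cands)), 0L)
  none <- suppressWarnings(enumerate_candidates(mt3, list(nem = c(21, 22)),
                                                charges = 5L))
  s <- mass_spectrum(c(1486, 1486.2), c(1, 2), "centroid")
  expect_equal(nrow(annotate(s, none)), 0L)
})

test_that("overlapping oxidized species land in one ambiguity group", {
  cands <- enumerate_candidates(
    mt3, list(cu = c(4, 4), zn = c(0, 4), nem = c(0, 2), ss = c(2, 2)),
    charges = 5L)
  both <- list(
    list(mfc = metalloform(n_cu = 4, n_zn = 4, n_ss = 2, z = 5),
         abundance = 1),
    list(mfc = metalloform(n_cu = 4, n_nem = 2, n_ss = 2, z = 5),
         abundance = 0.8))
  sim <- simulate_native(simulation_spec(mt3, both, snr = 50, seed = 303))
  res <- annotate(sim, cands)
  a <- res[res$species == "Cu4Zn4SS2", ]
  b <- res[res$species == "Cu4NEM2SS2", ]
  expect_equal(nrow(a), 1L)
  expect_equal(nrow(b), 1L)
  expect_false(is.na(a$group_id))
  expect_equal(a$group_id, b$group_id)
})

test_that("NNLS abundances reproduce synthetic mixing proportions", {
  cands <- enumerate_candidates(mt3, list(cu = c(4, 4), zn = c(0, 4),
                                          ss = c(2, 2)), charges = 5L)
  truth <- c(Cu4Zn2SS2 = 1, Cu4Zn3SS2 = 0.6, Cu4Zn4SS2 = 0.3)
  species <- list(
    list(mfc = metalloform(n_cu = 4, n_zn = 2, n_ss = 2, z = 5),
         abundance = 1),
    list(mfc = metalloform(n_cu = 4, n_zn = 3, n_ss = 2, z = 5),
         abundance = 0.6),
    list(mfc = metalloform(n_cu = 4, n_zn = 4, n_ss = 2, z = 5),
         abundance = 0.3))
  sim <- simulate_native(simulation_spec(mt3, species, snr = 50,
                                         seed = 21))
  res <- annotate(sim, cands)
  est <- res$abundance[match(names(truth), res$species)]
  expect_true(all(!is.na(est)))
  expect_true(all(est >= 0))
  expect_true(all(abs(est - truth) / truth < 0.15))
})
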