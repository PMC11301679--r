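# b/y fragment generation with adduct partitions, matching,
# complementary-pair reconstruction, label localization and maps.

test_that("complementary partition pairs conserve mass and adduct totals", {
  parent <- metalloform(n_cu = 2, n_nem = 3, n_ss = 1, z = 5)
  fr <- generate_fragments(mt3, parent, charges = 1L)
  parent_apo_mass <- neutral_mass(
    mt3, metalloform(n_cu = 2, n_nem = 3, n_ss = 0, z = 5),
    "monoisotopic")
  n <- n_residues(mt3)
  set.seed(5)
  b_rows <- fr[fr$type == "b", ]
  for (r in sample(nrow(b_rows), 25)) {
    b <- b_rows[r, ]
    # complementary partition: whatever the b fragment does not carry
    y <- fr[fr$type == "y" & fr$index == n - b$index &
            fr$n_cu == parent$n_cu - b$n_cu &
            fr$n_nem == parent$n_nem - b$n_nem, ]
    expect_gt(nrow(y), 0)
    expect_equal(b$neutral_mono + y$neutral_mono[1], parent_apo_mass,
                 tolerance = 1e-6)
    rec <- complementary_reconstruction(b, y[1, ], mt3,
                                        n_ss = parent$n_ss)
    expect_equal(rec$n_cu, parent$n_cu)
    expect_equal(rec$n_nem, parent$n_nem)
  }
})

test_that("fragment label partitions respect both-side cysteine budgets", {
  parent <- metalloform(n_cu = 4, n_nem = 10, n_ss = 2, z = 5)
  fr <- generate_fragments(mt3, parent, charges = 1L)
  expect_true(all(fr$n_nem <= fr$cys_in_fragment))
  # residues 1-6 of MT3 contain 2 Cys, so b6 admits 0..2 NEM at most
  b6 <- fr[fr$type == "b" & fr$index == 6, ]
  expect_true(any(b6$n_nem == 1))
  expect_true(all(b6$n_nem <= 2))
  # y62 with 9 NEM and no metals exists for this parent
  y62 <- fr[fr$type == "y" & fr$index == 62 & fr$n_nem == 9 &
            fr$n_cu == 0, ]
  expect_gt(nrow(y62), 0)
  # a parent over budget is rejected
  expect_error(generate_fragments(mt3, metalloform(n_nem = 21, z = 5)),
               "budget")
})

test_that("matching recovers planted fragments with no false matches", {
  parent <- metalloform(n_nem = 2, z = 5)
  sim <- simulate_fragments(mt3, parent, nem_at = c(6, 8),
                            ppm_jitter = 1, seed = 17)
  truth <- attr(sim, "ground_truth")
  cands <- generate_fragments(mt3, parent, charges = 1L)
  ann <- match_fragments(sim, cands, tol = 20)
  expect_gte(nrow(ann) / nrow(truth), 0.95)
  expect_true(all(abs(ann$ppm) <= 20))
  # matched identities agree with the planted ions
  key <- function(df) paste(df$type, df$index, df$z)
  expect_true(all(key(ann) %in% key(truth)))
})

test_that("tolerance semantics pick the nearer candidate or nothing", {
  cand <- data.frame(type = c("b", "b"), index = c(2L, 3L),
                     n_cu = 0L, n_zn = 0L, n_cd = 0L, n_nem = 0L,
                     n_iam = 0L, z = 1L,
                     neutral_mono = c(999, 999.05),
                     mz_mono = c(1000.000, 1000.050),
                     cys_in_fragment = 0L)
  # a peak 20 ppm from one candidate and 30 ppm from the other
  peak <- mass_spectrum(1000.020, 100, "centroid")
  hit <- match_fragments(peak, cand, tol = 25)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$index, 2L)
  miss <- match_fragments(peak, cand, tol = 10)
  expect_equal(nrow(miss), 0L)
  empty <- mass_spectrum(numeric(0), numeric(0), "centroid")
  expect_equal(nrow(match_fragments(empty, cand)), 0L)
})

test_that("b6/y62 reconstruction returns the 10-NEM parent over 68 residues", {
  b6 <- data.frame(type = "b", index = 6L, n_cu = 0L, n_zn = 0L,
                   n_cd = 0L, n_nem = 1L, n_iam = 0L)
  y62 <- data.frame(type = "y", index = 62L, n_cu = 4L, n_zn = 0L,
                    n_cd = 0L, n_nem = 9L, n_iam = 0L)
  rec <- complementary_reconstruction(b6, y62, mt3, n_ss = 2, z = 5)
  expect_equal(rec$n_nem, 10L)
  expect_equal(rec$n_cu, 4L)
  expect_equal(b6$index + y62$index, n_residues(mt3))
  # non-complementary indices fail with a reason
  y61 <- y62; y61$index <- 61L
  expect_error(complementary_reconstruction(b6, y61, mt3),
               "not complementary")
  # b1 with no adducts plus y67 carrying everything
  b1 <- b6; b1$index <- 1L; b1$n_nem <- 0L
  y67 <- y62; y67$index <- 67L; y67$n_nem <- 10L
  rec2 <- complementary_reconstruction(b1, y67, mt3)
  expect_equal(rec2$n_nem, 10L)
  expect_equal(rec2$n_cu, 4L)
})

test_that("the b2-b8 NEM ladder localizes labels to Cys6 and Cys8", {
  ladder <- data.frame(
    type = "b", index = c(2L, 3L, 4L, 5L, 6L, 7L, 8L),
    n_cu = 0L, n_zn = 0L, n_cd = 0L,
    n_nem = c(0L, 0L, 0L, 0L, 1L, 1L, 2L), n_iam = 0L)
  loc <- localize_labels(ladder, mt3)
  expect_equal(loc$state[loc$position == 6], "labeled-NEM")
  expect_equal(loc$state[loc$position == 8], "labeled-NEM")
  expect_true(all(loc$state[!loc$position %in% c(6, 8)] ==
                  "undetermined"))
  # both numbering conventions are reported
  expect_equal(loc$position_noMet[loc$position == 6], 5L)
  expect_false(attr(loc, "conflict"))
})

test_that("an all-zero ladder marks covered cysteines unmodified", {
  ladder <- data.frame(type = "b", index = 2:9, n_cu = 0L, n_zn = 0L,
                       n_cd = 0L, n_nem = 0L, n_iam = 0L)
  loc <- localize_labels(ladder, mt3)
  expect_true(all(loc$state[loc$position <= 9] == "unmodified"))
  expect_true(all(loc$state[loc$position > 9] == "undetermined"))
})

test_that("an increment spanning two cysteines stays undetermined", {
  # b5 -> b8 brackets Cys6 and Cys8 together; +1 NEM cannot be placed
  ladder <- data.frame(type = "b", index = c(5L, 8L), n_cu = 0L,
                       n_zn = 0L, n_cd = 0L, n_nem = c(0L, 1L),
                       n_iam = 0L)
  loc <- localize_labels(ladder, mt3)
  expect_equal(loc$state[loc$position == 6], "undetermined")
  expect_equal(loc$state[loc$position == 8], "undetermined")
})

test_that("localization is invariant to annotation order", {
  parent <- metalloform(n_nem = 4, z = 5)
  sim <- simulate_fragments(mt3, parent, nem_at = c(6, 8, 64, 67),
                            ppm_jitter = 0.5, seed = 23)
  cands <- generate_fragments(mt3, parent, charges = 1L)
  ann <- match_fragments(sim, cands, tol = 20)
  loc1 <- localize_labels(ann, mt3)
  set.seed(31)
  loc2 <- localize_labels(ann[sample(nrow(ann)), ], mt3)
  expect_equal(loc1$state, loc2$state)
})

test_that("planted label placements are recovered end to end", {
  parent <- metalloform(n_nem = 3, z = 5)
  plant <- c(6L, 8L, 51L)
  sim <- simulate_fragments(mt3, parent, nem_at = plant,
                            ppm_jitter = 1, seed = 41)
  cands <- generate_fragments(mt3, parent, charges = 1L)
  ann <- match_fragments(sim, cands, tol = 20)
  loc <- localize_labels(ann, mt3)
  labeled <- loc$position[loc$state == "labeled-NEM"]
  expect_true(all(plant %in% labeled))
  # nothing outside the planted set may be called labeled
  expect_true(all(labeled %in% plant))
})

test_that("fragmentation maps compute coverage from informative cleavages", {
  none <- generate_fragments(mt3, metalloform(z = 5), charges = 1L)[0, ]
  fm0 <- fragmentation_map(none, mt3)
  expect_equal(fm0$coverage, 0)
  full_b <- data.frame(type = "b", index = 1:67, n_cu = 0L, n_zn = 0L,
                       n_cd = 0L, n_nem = 0L, n_iam = 0L)
  fm1 <- fragmentation_map(full_b, mt3)
  expect_equal(fm1$coverage, 100)
  # a simulated annotated ion list reproduces its own map
  parent <- metalloform(n_nem = 2, z = 5)
  sim <- simulate_fragments(mt3, parent, nem_at = c(6, 8),
                            indices = list(b = 2:8, y = c(30, 40, 62)),
                            ppm_jitter = 0.5, seed = 43)
  cands <- generate_fragments(mt3, parent, charges = 1L)
  ann <- match_fragments(sim, cands, tol = 20)
  fm <- fragmentation_map(ann, mt3)
  covered <- fm$map$site[fm$map$covered]
  expect_true(all(2:8 %in% covered))
  expect_true(all((68 - c(30, 40, 62)) %in% covered))
})
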