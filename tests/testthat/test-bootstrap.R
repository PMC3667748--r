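test_that("pairing predicates: allele, distance, mode = none", {
  test <- mk_sites(1, pos = 1000L, major = "G")
  ref_ok <- mk_sites(1, pos = 1500L, major = "G",
                     site_class = "SHORT_INTRON")
  ref_allele <- mk_sites(1, pos = 1500L, major = "A",
                         site_class = "SHORT_INTRON")
  ref_far <- mk_sites(1, pos = 2500L, major = "G",
                      site_class = "SHORT_INTRON")

  expect_equal(pair_index(test, ref_ok)$coverage$n_pairable, 1L)
  expect_error(pair_index(test, ref_allele), "no pairable")
  expect_error(pair_index(test, ref_far, max_dist = 1000), "no pairable")
  expect_equal(pair_index(test, ref_far, mode = "none")$coverage$n_pairable,
               1L)
  # inclusive distance boundary
  expect_equal(pair_index(test, mk_sites(1, pos = 2000L, major = "G")
                          )$coverage$n_pairable, 1L)
  # different arm blocks pairing under the distance modes
  ref_arm <- mk_sites(1, chrom = "3R", pos = 1500L, major = "G")
  expect_error(pair_index(test, ref_arm), "no pairable")

  # every indexed partner satisfies the matching predicate
  set.seed(1)
  tt <- mk_sites(200, pos = sample(1:20000, 200), major = sample(
    c("A", "C", "G", "T"), 200, replace = TRUE))
  rr <- mk_sites(500, pos = sample(1:20000, 500), major = sample(
    c("A", "C", "G", "T"), 500, replace = TRUE))
  idx <- pair_index(tt, rr)
  for (i in seq_len(nrow(idx$test))) {
    partners <- idx$ref[idx$lo[i]:idx$hi[i], ]
    expect_true(all(partners$major_allele == idx$test$major_allele[i]))
    expect_true(all(abs(partners$pos - idx$test$pos[i]) <= 1000))
  }
})

test_that("triplet mode matches the ordered major-allele 3-mer", {
  test <- mk_sites(1, pos = 1000L, major = "G", triplet = "AGT")
  ref_same <- mk_sites(1, pos = 1400L, major = "G", triplet = "AGT")
  ref_diff <- mk_sites(1, pos = 1400L, major = "G", triplet = "TGA")
  expect_equal(pair_index(test, ref_same, mode = "triplet"
                          )$coverage$n_pairable, 1L)
  expect_error(pair_index(test, ref_diff, mode = "triplet"), "no pairable")
  expect_error(pair_index(test, mk_sites(1, pos = 1400L), mode = "triplet"),
               "attr:triplet")
})

test_that("bootstrap deficit estimates its construction and is reproducible", {
  # paired toy: ref segregates w.p. 0.5, test w.p. 0.25 -> deficit 0.5
  N <- 4000L
  set.seed(10)
  test <- mk_sites(N, pos = seq_len(N) * 3000L,
                   minor = "A", minor_count = rbinom(N, 1, 0.25))
  ref <- mk_sites(N, pos = seq_len(N) * 3000L + 10L,
                  site_class = "SHORT_INTRON",
                  minor = "A", minor_count = rbinom(N, 1, 0.5))
  idx <- pair_index(test, ref)
  bd <- bootstrap_deficit(idx, n_boot = 10, seed = 3)
  expect_lt(abs(bd$mean - 0.5), 0.04)
  expect_equal(bd$n_pairs, N)

  # statistically identical streams: deficit compatible with zero
  ref2 <- mk_sites(N, pos = seq_len(N) * 3000L + 10L,
                   site_class = "SHORT_INTRON",
                   minor = "A", minor_count = rbinom(N, 1, 0.25))
  bd0 <- bootstrap_deficit(pair_index(test, ref2), n_boot = 10, seed = 3)
  expect_lt(abs(bd0$mean), 0.08)

  # identical seed, identical draws
  bd2 <- bootstrap_deficit(idx, n_boot = 10, seed = 3)
  expect_identical(bd$replicate_deficits, bd2$replicate_deficits)
})

test_that("paired spectra mirror the deficit draws and have equal L", {
  N <- 2000L
  set.seed(11)
  test <- mk_sites(N, pos = seq_len(N) * 3000L, minor = "A",
                   minor_count = rbinom(N, 1, 0.04))
  ref <- mk_sites(N, pos = seq_len(N) * 3000L + 7L,
                  site_class = "SHORT_INTRON", minor = "A",
                  minor_count = rbinom(N, 1, 0.06))
  idx <- pair_index(test, ref)
  bd <- bootstrap_deficit(idx, n_boot = 5, seed = 9)
  sp <- paired_spectra(idx, n_boot = 5, seed = 9)
  expect_length(sp, 5L)
  for (b in seq_along(sp)) {
    expect_equal(sp[[b]]$test$L, N)
    expect_equal(sp[[b]]$ref$L, N)
    # same draws as the deficit estimator under the same seed
    d_from_sp <- 1 - (sp[[b]]$test$m / N) / (sp[[b]]$ref$m / N)
    expect_equal(d_from_sp, bd$replicate_deficits[b])
  }
  # depth check
  bad <- mk_sites(N, pos = seq_len(N) * 3000L, depth = 168L)
  expect_error(paired_spectra(pair_index(bad, ref)), "depth-normalized")
})

test_that("slow-vs-fast pairing behaves under null and enriched fixtures", {
  N <- 40000L
  set.seed(12)
  # half slow (b1/b2), half fast (b7/b8), interleaved along the arm
  subst <- ifelse(seq_len(N) %% 2L == 0L, runif(N, 0, 1.4),
                  runif(N, 6.3, 12))
  sites <- mk_sites(N, pos = seq_len(N) * 200L, minor = "A",
                    minor_count = rbinom(N, 1, 0.06), subst = subst)
  # all neutral: deficit compatible with 0
  fs <- fast_slow_deficit(sites, slow_bins = c("b1", "b2"),
                          fast_bins = c("b7", "b8"), seed = 5)
  expect_lt(abs(fs$mean), 0.12)

  # slow bin depleted of polymorphism: clearly positive deficit
  slow <- bin_substitutions(sites$subst_count) %in% c("b1", "b2")
  sites2 <- sites
  sites2$minor_count[slow] <- rbinom(sum(slow), 1, 0.03)
  fs2 <- fast_slow_deficit(sites2, slow_bins = c("b1", "b2"),
                           fast_bins = c("b7", "b8"), seed = 5)
  expect_gt(fs2$mean, 0.3)

  # no substitution data is an error with diagnostics
  expect_error(fast_slow_deficit(mk_sites(5)), "subst_count")
})
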