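test_that("generator is deterministic: identical config+seed, identical TSV", {
  cfg <- sim_config(n_fourfold = 3000, n_intron = 3000)
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  write_site_table(simulate_sites(cfg, seed = 5)$sites, p1)
  write_site_table(simulate_sites(cfg, seed = 5)$sites, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  # different seed differs
  p3 <- withr::local_tempfile()
  write_site_table(simulate_sites(cfg, seed = 6)$sites, p3)
  expect_false(tools::md5sum(p1) == tools::md5sum(p3))
})

test_that("layout hosts the requested sites and nearly all test sites are pairable", {
  cfg <- sim_config(n_fourfold = 20000, n_intron = 20000)
  lay <- simulate_layout(cfg)
  expect_equal(nrow(lay$fourfold), 20000L)
  expect_equal(nrow(lay$intron_sites), 20000L)

  sim <- simulate_sites(cfg, seed = 3)
  s <- resample_sites(sim$sites, seed = 4)
  idx <- pair_index(s[s$site_class == "FOURFOLD", ],
                    s[s$site_class == "SHORT_INTRON", ])
  expect_gte(idx$coverage$fraction, 0.9)

  # no reference sites requested: explicit warning, empty reference
  expect_warning(lay0 <- simulate_layout(sim_config(n_fourfold = 1000,
                                                    n_intron = 0)),
                 "coverage")
  expect_equal(nrow(lay0$intron_sites), 0L)
})

test_that("generated marginals match their configured expectations", {
  cfg <- sim_config(n_fourfold = 30000, n_intron = 30000)
  sim <- simulate_sites(cfg, seed = 8)
  s4 <- sim$sites[sim$sites$site_class == "FOURFOLD", ]
  si <- sim$sites[sim$sites$site_class == "SHORT_INTRON", ]

  # GC composition of the two classes (ancestral alleles)
  gc4 <- mean(s4$major_allele %in% c("G", "C"))
  gcsi <- mean(si$major_allele %in% c("G", "C"))
  expect_lt(abs(gc4 - 0.64), 4 * sqrt(0.64 * 0.36 / nrow(s4)) + 0.003)
  expect_lt(abs(gcsi - 0.31), 4 * sqrt(0.31 * 0.69 / nrow(si)) + 0.003)

  # depth distribution spans the configured range
  expect_equal(range(sim$sites$called_depth), c(100L, 168L))

  # after depth normalization the reference segregating fraction matches
  # theta * H(129) scaled by the reference-class allele multiplier
  post <- resample_sites(sim$sites, seed = 9)
  ri <- post[post$site_class == "SHORT_INTRON", ]
  k <- cfg$gc_theta_ratio
  a_at <- 1 / ((1 - cfg$gc_fourfold) + cfg$gc_fourfold * k)
  mult_si <- (1 - cfg$gc_intron) * a_at + cfg$gc_intron * a_at * k
  expected <- cfg$theta * sum(1 / (1:129)) * mult_si
  pobs <- mean(ri$minor_count > 0)
  se <- sqrt(expected * (1 - expected) / nrow(ri))
  expect_lt(abs(pobs - expected), 4 * se)

  # singleton-class fraction among reference sites matches the folded
  # neutral spectrum (checks the depth-then-subsample path end to end)
  p1_exp <- cfg$theta * mult_si * (1 + 1 / 129)
  p1_obs <- mean(ri$minor_count == 1)
  se1 <- sqrt(p1_exp * (1 - p1_exp) / nrow(ri))
  expect_lt(abs(p1_obs - p1_exp), 4 * se1)

  # annotations: preference marginal consistent with GC target (only
  # C-ending codons are preferred except Valine's GTG)
  expect_true(all(classify_preference(s4$codon_anc) == s4$preference))
})

test_that("the generator can produce the GC confound the bootstrap removes", {
  # A/T sites mutate 1.5x faster, no selection anywhere: the naive
  # density comparison shows a deficit, the matched bootstrap does not
  cfg <- sim_config(n_fourfold = 1e5, n_intron = 1e5,
                    mixture = selection_mixture(c(1, 0, 0), c(0, -1, -283)),
                    gc_theta_ratio = 1 / 1.5, regional_sd = 0.5)
  sim <- simulate_sites(cfg, seed = 13)
  s <- resample_sites(sim$sites, seed = 14)
  test <- s[s$site_class == "FOURFOLD", ]
  ref <- s[s$site_class == "SHORT_INTRON", ]
  naive <- naive_deficit(test, ref)
  expect_gt(naive, 0.06)
  matched <- bootstrap_deficit(pair_index(test, ref), seed = 15)
  expect_lt(abs(matched$mean), 0.04)
})

test_that("per-gene heterogeneity feeds the ranking surrogate", {
  cfg <- sim_config(n_fourfold = 6e4, n_intron = 6e4, gene_dispersion = 4)
  sim <- simulate_sites(cfg, seed = 16)
  s <- resample_sites(sim$sites, seed = 17)
  s4 <- s[s$site_class == "FOURFOLD", ]
  r <- rank_genes(s4)
  expect_true(length(r$top) >= 1)
  # genes enriched in conserved-unpreferred sites carry more strong-class
  # sites, hence fewer SNPs: top-set density below the remainder's
  intop <- s4$gene_id %in% r$top
  eligible <- s4$gene_id %in% r$ranking$gene_id[r$ranking$eligible]
  expect_lt(mean(s4$minor_count[intop] > 0),
            mean(s4$minor_count[eligible & !intop] > 0))
})
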