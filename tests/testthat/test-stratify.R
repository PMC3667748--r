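test_that("substitution-rate bins partition with the published boundaries", {
  x <- c(0, 1.4, 1.92, 9.299, 9.3, 0.001, 6.2, 6.21)
  b <- bin_substitutions(x)
  expect_equal(as.character(b),
               c("b1", "b2", "b3", "b7", "b8", "b2", "b6", "b7"))
  # uniform draws are all assigned to exactly one bin
  set.seed(2)
  u <- runif(5000, 0, 12)
  bu <- bin_substitutions(u)
  expect_false(anyNA(bu))
  expect_error(bin_substitutions(-1), "non-negative")
})

test_that("codon preference classification follows the optimal-codon table", {
  expect_equal(classify_preference(c("GCC", "GTG")), c("P", "P"))
  expect_equal(classify_preference("CCA"), "U")
  expect_equal(classify_preference("GGA"), "U")
  # every family has exactly one preferred codon
  for (prefix in c("GC", "GG", "CC", "AC", "GT")) {
    codons <- paste0(prefix, c("A", "C", "G", "T"))
    expect_equal(sum(classify_preference(codons) == "P"), 1L)
  }
  expect_error(classify_preference("ATG"), "four-fold")
})

test_that("polarization by parsimony with major-allele fallback keeps all sites", {
  out <- polarize_sites(major = c("C", "C", "A"),
                        minor = c("T", "T", NA),
                        outgroup = c("C", "G", "A"))
  expect_equal(out$ancestral, c("C", "C", "A"))
  expect_equal(out$method,
               c("PARSIMONY", "MAJOR_FALLBACK", "PARSIMONY"))
  # outgroup matching the minor allele polarizes to the minor
  out2 <- polarize_sites("C", "T", "T")
  expect_equal(out2$ancestral, "T")

  # ten-species context refuses to guess
  out3 <- polarize_sites(c("C", "C"), c("T", "T"), c("G", "C"),
                         context = "ten_species")
  expect_true(is.na(out3$ancestral[1]))
  expect_equal(out3$method[1], "UNPOLARIZED")
  expect_equal(out3$ancestral[2], "C")

  expect_error(polarize_sites("C", "T", NA), "missing outgroup")
})

test_that("positional features: start/stop windows, splice distance, tertiles", {
  genes <- data.frame(
    gene_id = c("gA", "gB"),
    chrom = c("2L", "X"), strand = c("+", "+"),
    exon_starts = c("1001,1501", "5001"),
    exon_ends = c("1300,1800", "5400"),
    gene_length = c(800L, 400L), cds_length = c(600L, 400L),
    stringsAsFactors = FALSE)
  sites <- mk_sites(4, chrom = c("2L", "2L", "2L", "X"),
                    pos = c(1030L, 1076L, 1298L, 5200L),
                    gene_id = c("gA", "gA", "gA", "gB"))
  ann <- annotate_features(sites, genes)
  # site at CDS position 30 is near the start; CDS position 76 is not
  expect_equal(ann[["attr:near_start_75"]], c(TRUE, FALSE, FALSE, FALSE))
  # 1298 is 2 bp from the first splice junction
  expect_equal(ann[["attr:near_splice_48"]], c(FALSE, FALSE, TRUE, FALSE))
  # single-exon genes never flag splice proximity
  expect_true(ann[["attr:single_exon"]][4])
  expect_equal(ann[["attr:x_linked"]], c(FALSE, FALSE, FALSE, TRUE))

  # unknown gene ids warn and get NA attributes
  orphan <- mk_sites(1, gene_id = "gZ")
  expect_warning(a2 <- annotate_features(orphan, genes), "no matching gene")
  expect_true(is.na(a2[["attr:near_start_75"]]))

  # tertile groups over many genes differ in size by at most 1
  ng <- 100L
  genes2 <- data.frame(
    gene_id = sprintf("g%03d", 1:ng), chrom = "2L", strand = "+",
    exon_starts = "1", exon_ends = "300",
    gene_length = sample(300:5000, ng), cds_length = 300L,
    stringsAsFactors = FALSE)
  sites2 <- mk_sites(ng, pos = 1:ng, gene_id = genes2$gene_id)
  a3 <- suppressWarnings(annotate_features(sites2, genes2))
  tab <- table(a3[["attr:gene_len_class"]])
  expect_lte(diff(range(tab)), 1)
})

test_that("grouped deficits: identity with the global bootstrap, ordering, sign", {
  N <- 3000L
  set.seed(14)
  test <- mk_sites(N, pos = seq_len(N) * 2500L, minor = "A",
                   minor_count = rbinom(N, 1, 0.04))
  ref <- mk_sites(N, pos = seq_len(N) * 2500L + 11L,
                  site_class = "SHORT_INTRON", minor = "A",
                  minor_count = rbinom(N, 1, 0.08))
  # a single all-sites group equals the global estimator (same derived seed)
  gd <- group_deficit(test, ref, rep("all", N), seed = 100)
  global <- bootstrap_deficit(pair_index(test, ref), seed = 101)
  expect_equal(gd$mean_deficit, global$mean)

  # groups with different generated deficits are recovered in order
  grp <- rep(c("lo", "hi"), length.out = N)
  test2 <- test
  test2$minor_count[grp == "hi"] <- rbinom(sum(grp == "hi"), 1, 0.07)
  gd2 <- group_deficit(test2, ref, grp, seed = 7)
  expect_lt(gd2$mean_deficit[gd2$group == "hi"],
            gd2$mean_deficit[gd2$group == "lo"])

  # an excess of test polymorphism is reported as a negative deficit
  test3 <- test
  test3$minor_count <- rbinom(N, 1, 0.2)
  gd3 <- group_deficit(test3, ref, rep("x", N), seed = 8)
  expect_lt(gd3$mean_deficit, 0)
})

test_that("gene ranking surrogate: score arithmetic, eligibility, top sixth", {
  # one gene, 10 SNP-free conserved-AA sites, 4 unpreferred-and-conserved
  s <- mk_sites(12, pos = 1:12, gene_id = "gA",
                preference = c(rep("U", 6), rep("P", 6)),
                subst = c(rep(0, 4), rep(3, 2), rep(0, 3), rep(2, 3)),
                conserved_aa = 1L)
  s$minor_count <- c(rep(0L, 10), 1L, 1L)  # last two sites carry SNPs
  s$n_alleles <- ifelse(s$minor_count > 0, 2L, 1L)
  r <- rank_genes(s, min_conserved_frac = 0.2)
  expect_equal(r$ranking$score[r$ranking$gene_id == "gA"], 0.4)

  # gene below the conserved-amino-acid floor is ineligible
  s2 <- mk_sites(100, pos = 1:100, gene_id = "gB", preference = "U",
                 subst = 0, conserved_aa = rep(c(1L, 0L), c(19L, 81L)))
  r2 <- rank_genes(rbind(s, s2), min_conserved_frac = 0.2)
  expect_false(r2$ranking$eligible[r2$ranking$gene_id == "gB"])

  # 4877 eligible genes -> top set of 812
  ng <- 4877L
  s3 <- mk_sites(ng, pos = 1:ng, gene_id = sprintf("g%05d", 1:ng),
                 preference = rep(c("U", "P"), length.out = ng),
                 subst = 0, conserved_aa = 1L)
  r3 <- rank_genes(s3, min_conserved_frac = 0.2, top_frac = 1 / 6)
  expect_equal(sum(r3$ranking$eligible), ng)
  expect_length(r3$top, 812L)

  expect_error(rank_genes(s2, min_conserved_frac = 0.5), "eligible")
})
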