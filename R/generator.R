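# Synthetic site-table generator: emulates the statistical structure of a
# deep population panel (two site classes with different GC composition,
# shared regional mutation-rate variation, variable called depth, a
# selection mixture on the test class) so the whole pipeline is testable
# without any external data.

#' Generator configuration
#'
#' Defaults are the study conditions of the analysis the package
#' implements: 864,000 four-fold (test) sites and 870,000 short-intron
#' (reference) sites, `theta = 0.0132`, a mixture with 22.6% of test sites
#' under strong purifying selection at `gamma = -283`, GC composition 64%
#' (test) versus 31% (reference), and calling depth uniform over 100..168
#' chromosomes with downstream resampling to 130.  GC-major sites mutate
#' `gc_theta_ratio` times faster than A/T-major sites (multipliers
#' normalized so the test-class composition averages 1, anchoring theta on
#' the matched scale); a lognormal regional multiplier, piecewise constant
#' on 1-kb windows and shared by co-located sites of both classes,
#' emulates regional covariation of diversity.
#'
#' @param n_fourfold,n_intron target numbers of test / reference sites in
#'   the depth-filtered analysis set; [simulate_sites()] emits
#'   proportionally more so that, after [resample_sites()] removes sites
#'   called in fewer than `depth_target` chromosomes, the analyzed table
#'   has this size in expectation.
#' @param theta scaled mutation rate at the test-class composition.
#' @param mixture [selection_mixture()] for the test class (reference
#'   sites are always neutral).
#' @param gc_fourfold,gc_intron probability that a site's ancestral
#'   (major) allele is G or C.
#' @param gc_theta_ratio mutation-rate ratio of G/C-major to A/T-major
#'   sites (1 switches the GC confound off).
#' @param regional_sd lognormal sd of the per-window mutation multiplier
#'   (0 switches regional variation off).
#' @param window window width in bp for the regional multiplier.
#' @param depth_min,depth_max,depth_target called-depth model.
#' @param alpha optional shared folded-class distortion (length
#'   `floor(depth_target/2) + 1`, first element 1); when given, sites are
#'   emitted directly at `depth_target`, where the distortion is defined.
#' @param mutation_deficit replace the strong category by a zero-mutation
#'   category of the same fraction (confound experiments).
#' @param gene_dispersion Beta concentration of the per-gene strong-site
#'   fraction around its mean (NULL: homogeneous genes).
#' @param subst_correlation `"monotone"` draws fewer substitutions at
#'   strongly selected sites (so constraint declines across rate bins);
#'   `"none"` makes substitution counts independent of the site's class.
#' @param aa_conserved_prob probability that a test site's amino acid is
#'   flagged conserved.
#' @param seed default seed used by [simulate_sites()].
#' @return an object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_fourfold = 864000L, n_intron = 870000L,
                       theta = 0.0132,
                       mixture = selection_mixture(c(0.774, 0, 0.226),
                                                   c(0, -1, -283)),
                       gc_fourfold = 0.64, gc_intron = 0.31,
                       gc_theta_ratio = 1.65,
                       regional_sd = 0.3, window = 1000L,
                       depth_min = 100L, depth_max = 168L,
                       depth_target = 130L,
                       alpha = NULL, mutation_deficit = FALSE,
                       gene_dispersion = 15,
                       subst_correlation = c("monotone", "none"),
                       aa_conserved_prob = 0.5,
                       seed = 1L) {
  subst_correlation <- match.arg(subst_correlation)
  mixture <- .as_mixture(mixture)
  stopifnot(n_fourfold >= 0, n_intron >= 0,
            n_fourfold + n_intron > 0,
            theta > 0,
            gc_fourfold > 0, gc_fourfold < 1,
            gc_intron > 0, gc_intron < 1,
            gc_theta_ratio > 0, regional_sd >= 0, window >= 1,
            depth_min <= depth_target, depth_target <= depth_max,
            aa_conserved_prob >= 0, aa_conserved_prob <= 1)
  if (!is.null(alpha)) {
    stopifnot(length(alpha) == depth_target %/% 2L + 1L, alpha[1L] == 1,
              all(alpha >= 0))
  }
  structure(list(
    n_fourfold = as.integer(n_fourfold), n_intron = as.integer(n_intron),
    theta = theta, mixture = mixture,
    gc_fourfold = gc_fourfold, gc_intron = gc_intron,
    gc_theta_ratio = gc_theta_ratio,
    regional_sd = regional_sd, window = as.integer(window),
    depth_min = as.integer(depth_min), depth_max = as.integer(depth_max),
    depth_target = as.integer(depth_target),
    alpha = alpha, mutation_deficit = mutation_deficit,
    gene_dispersion = gene_dispersion,
    subst_correlation = subst_correlation,
    aa_conserved_prob = aa_conserved_prob,
    seed = as.integer(seed)), class = "sim_config")
}

# fixed gene template: 5 exons of 504 bp separated by 4 introns of 85 bp;
# four-fold sites at every third codon (56 per exon, 280 per gene),
# retained short-intron interiors 63 per intron (252 per gene)
.gene_template <- list(exon_len = 504L, n_exon = 5L, intron_len = 85L,
                       intergenic = 400L)

#' Lay out a synthetic genome scaffold
#'
#' Places genes (5 exons of 504 bp separated by 85-bp short introns) along
#' five chromosome arms, alternating strand, with enough genes to host the
#' configured numbers of four-fold and short-intron sites.  Four-fold
#' sites occupy the third position of every third codon; short-intron
#' positions are the [trim_short_intron()] interiors.  By construction
#' nearly every four-fold site has reference positions within 1 kb.
#'
#' @param config a [sim_config()].
#' @return an object of class `"sim_layout"`: list with `genes`,
#'   `fourfold`, `intron_sites` data frames and a `summary`.
#' @export
simulate_layout <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tpl <- .gene_template
  per_gene_4d <- (tpl$exon_len %/% 9L) * tpl$n_exon
  per_gene_si <- (tpl$intron_len - 22L) * (tpl$n_exon - 1L)
  n_genes <- max(ceiling(config$n_fourfold / per_gene_4d),
                 ceiling(config$n_intron / per_gene_si), 1L)
  arms <- c("2L", "2R", "3L", "3R", "X")
  tx_len <- tpl$n_exon * tpl$exon_len + (tpl$n_exon - 1L) * tpl$intron_len
  g <- seq_len(n_genes)
  arm <- arms[(g - 1L) %% length(arms) + 1L]
  slot <- (g - 1L) %/% length(arms)
  tx_start <- 1L + slot * (tx_len + tpl$intergenic)
  tx_end <- tx_start + tx_len - 1L
  strand <- ifelse(g %% 2L == 1L, "+", "-")
  gene_id <- sprintf("g%05d", g)

  step <- tpl$exon_len + tpl$intron_len
  exon_off <- (seq_len(tpl$n_exon) - 1L) * step          # 0-based starts
  exon_starts_str <- paste(exon_off + 1L, collapse = ",") # relative, 1-based
  exon_ends_str <- paste(exon_off + tpl$exon_len, collapse = ",")

  # 0-based within-gene offsets of the 3rd position of every 3rd codon
  codon3 <- seq(3L, tpl$exon_len %/% 3L, by = 3L)
  off_4d_fwd <- as.vector(outer(3L * codon3 - 1L, exon_off, `+`))
  off_4d_fwd <- sort(off_4d_fwd)
  # short-intron interiors via the trimming rule, per strand
  intron_off <- exon_off[-1L] - tpl$intron_len           # 0-based starts
  si_off <- function(strand) {
    sort(unlist(lapply(intron_off, function(o) {
      trim_short_intron(o + 1L, o + tpl$intron_len, strand) - 1L
    })))
  }
  off_si_fwd <- si_off("+")
  off_si_rev <- si_off("-")

  build_sites <- function(offs_fwd, offs_rev) {
    k_f <- length(offs_fwd)
    plus <- strand == "+"
    pos <- c(rep(tx_start[plus], each = k_f) + offs_fwd,
             rep(tx_start[!plus], each = length(offs_rev)) + offs_rev)
    gene <- c(rep(gene_id[plus], each = k_f),
              rep(gene_id[!plus], each = length(offs_rev)))
    chrom <- c(rep(arm[plus], each = k_f),
               rep(arm[!plus], each = length(offs_rev)))
    gnum <- as.integer(sub("^g", "", gene))
    o <- order(gnum, pos, method = "radix")
    data.frame(chrom = chrom[o], pos = pos[o], gene_id = gene[o],
               stringsAsFactors = FALSE)
  }
  # four-fold offsets: reverse-strand genes read the template from tx_end,
  # which maps offset x to tx_len - 1 - x
  off_4d_rev <- sort(tx_len - 1L - off_4d_fwd)
  fourfold <- build_sites(off_4d_fwd, off_4d_rev)
  fourfold <- head(fourfold, config$n_fourfold)
  intron_sites <- build_sites(off_si_fwd, off_si_rev)
  intron_sites <- head(intron_sites, config$n_intron)

  genes <- data.frame(
    gene_id = gene_id, chrom = arm, strand = strand,
    tx_start = tx_start, tx_end = tx_end,
    exon_starts = paste_offsets(exon_off + 1L, tx_start),
    exon_ends = paste_offsets(exon_off + tpl$exon_len, tx_start),
    gene_length = tx_len,
    cds_length = tpl$n_exon * tpl$exon_len,
    stringsAsFactors = FALSE)

  if (config$n_intron == 0L) {
    warning("no short-intron sites requested; pairing coverage will be 0")
  }
  structure(list(
    genes = genes, fourfold = fourfold, intron_sites = intron_sites,
    summary = list(n_genes = n_genes, arms = arms,
                   n_fourfold = nrow(fourfold),
                   n_intron = nrow(intron_sites),
                   per_gene_4d = per_gene_4d, per_gene_si = per_gene_si)),
    class = "sim_layout")
}

# absolute comma-separated coordinates per gene (vectorized over genes)
paste_offsets <- function(rel, tx_start) {
  vapply(tx_start, function(s) paste(s + rel - 1L, collapse = ","), "")
}

#' @export
print.sim_layout <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Synthetic layout: %d genes on %d arms; %s four-fold and %s short-intron sites\n",
    s$n_genes, length(s$arms), format(s$n_fourfold, big.mark = ","),
    format(s$n_intron, big.mark = ",")))
  invisible(x)
}

# sampling integrals for one depth without per-depth caching
.a_depth <- function(d, gammas) {
  key <- "gen_grid"
  grid <- get0(key, envir = .sfsmix_env)
  if (is.null(grid)) {
    grid <- .quad_grid()
    assign(key, grid, envir = .sfsmix_env)
  }
  i <- seq_len(d - 1L)
  B <- exp(outer(i, log(grid$x)) + outer(d - i, log1p(-grid$x)) +
             lchoose(d, i))
  vapply(gammas, function(g) {
    if (identical(g, -Inf)) rep(0, d - 1L)
    else as.vector(B %*% (grid$w * wright_sfs_density(grid$x, g, 1)))
  }, numeric(d - 1L))
}

.other_base <- function(base) {
  nt <- c("A", "C", "G", "T")
  alt <- matrix(c("C", "G", "T",  # A
                  "A", "G", "T",  # C
                  "A", "C", "T",  # G
                  "A", "C", "G"), # T
                nrow = 4L, byrow = TRUE,
                dimnames = list(nt, NULL))
  alt[cbind(match(base, nt), sample.int(3L, length(base), replace = TRUE))]
}

#' Generate a synthetic site table
#'
#' Runs the full generative model on the layout from [simulate_layout()]:
#' ancestral alleles drawn to the per-class GC targets; per-site scaled
#' mutation rate `theta * regional multiplier * allele multiplier`;
#' selection category assigned per test site from the mixture (reference
#' sites are neutral); called depth uniform over the configured range;
#' folded minor-allele counts drawn from the model sample SFS at that
#' depth, so that after [resample_sites()] the folded spectrum at
#' `depth_target` is exactly the model spectrum.  Test sites also receive codon, preference,
#' conservation and substitution-count annotations with the configured
#' class correlations, and each gene gets codon-bias and expression
#' attributes.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`); output is
#'   byte-identical given config and seed.
#' @return a list with `sites` (site-table data frame, both classes,
#'   ordered by class then gene), `genes` (gene-attribute table),
#'   `layout`, and `config`.
#' @export
simulate_sites <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  # n_fourfold / n_intron are analysis-set targets (sites surviving the
  # called-depth filter); emit proportionally more so the post-filter
  # table matches the configured study size in expectation
  keep_frac <- if (is.null(config$alpha)) {
    (config$depth_max - config$depth_target + 1) /
      (config$depth_max - config$depth_min + 1)
  } else {
    1
  }
  lay_cfg <- config
  lay_cfg$n_fourfold <- as.integer(ceiling(config$n_fourfold / keep_frac))
  lay_cfg$n_intron <- as.integer(ceiling(config$n_intron / keep_frac))
  layout <- suppressWarnings(simulate_layout(lay_cfg))
  n4 <- nrow(layout$fourfold)
  nsi <- nrow(layout$intron_sites)
  all_sites <- rbind(
    cbind(layout$fourfold, site_class = "FOURFOLD"),
    cbind(layout$intron_sites, site_class = "SHORT_INTRON"))
  ns <- nrow(all_sites)
  is4d <- all_sites$site_class == "FOURFOLD"

  # ancestral allele and allele-dependent mutation multiplier
  gc_p <- ifelse(is4d, config$gc_fourfold, config$gc_intron)
  is_gc <- runif(ns) < gc_p
  anc <- ifelse(is_gc,
                ifelse(runif(ns) < 0.5, "G", "C"),
                ifelse(runif(ns) < 0.5, "A", "T"))
  a_at <- 1 / ((1 - config$gc_fourfold) +
                 config$gc_fourfold * config$gc_theta_ratio)
  allele_mult <- ifelse(is_gc, a_at * config$gc_theta_ratio, a_at)

  # regional multiplier, piecewise constant on windows, shared by classes
  win <- paste(all_sites$chrom, all_sites$pos %/% config$window)
  uw <- unique(win)
  wmult <- if (config$regional_sd > 0) {
    setNames(rlnorm(length(uw), meanlog = -config$regional_sd^2 / 2,
                    sdlog = config$regional_sd), uw)
  } else {
    setNames(rep(1, length(uw)), uw)
  }
  theta_site <- config$theta * allele_mult * wmult[win]

  # selection category: 1 = neutral, 2 = weak, 3 = strong (test sites only)
  fr <- config$mixture$fractions
  gam <- config$mixture$gammas
  if (length(fr) != 3L) stop("generator expects a 3-category mixture")
  if (config$mutation_deficit) gam[3L] <- -Inf
  gene_fs <- setNames(rep(fr[3L], nrow(layout$genes)),
                      layout$genes$gene_id)
  if (!is.null(config$gene_dispersion) && fr[3L] > 0 && fr[3L] < 1) {
    gene_fs[] <- rbeta(length(gene_fs),
                       fr[3L] * config$gene_dispersion,
                       (1 - fr[3L]) * config$gene_dispersion)
  }
  ps <- ifelse(is4d, gene_fs[all_sites$gene_id], 0)
  pw <- if (fr[3L] < 1) fr[2L] * (1 - ps) / (1 - fr[3L]) else 0
  u <- runif(ns)
  cls <- ifelse(u < ps, 3L, ifelse(u < ps + pw, 2L, 1L))

  use_alpha <- !is.null(config$alpha)
  if (use_alpha) {
    depth <- rep(config$depth_target, ns)
  } else {
    depth <- sample(config$depth_min:config$depth_max, ns, replace = TRUE)
  }

  minor_count <- integer(ns)
  if (use_alpha) {
    # folded classes at depth_target with the shared distortion applied
    nt <- config$depth_target
    for (ci in unique(cls)) {
      af <- .fold_vec(.a_unfolded(nt, gam[ci]), nt)
      wts <- config$alpha[-1L] * af
      S <- sum(wts)
      A <- sum(af)
      sel <- which(cls == ci)
      th <- theta_site[sel]
      pseg <- th * S / (1 + th * (S - A))
      seg <- runif(length(sel)) < pseg
      if (any(seg) && S > 0) {
        minor_count[sel[seg]] <- sample.int(nt %/% 2L, sum(seg),
                                            replace = TRUE, prob = wts)
      }
    }
  } else {
    for (d in sort(unique(depth))) {
      gam_here <- sort(unique(cls[depth == d]))
      A <- .a_depth(d, gam[gam_here])
      for (j in seq_along(gam_here)) {
        ci <- gam_here[j]
        af <- .fold_vec(A[, j], d)
        sel <- which(depth == d & cls == ci)
        if (!length(sel)) next
        pseg <- pmin(theta_site[sel] * sum(af), 1)
        seg <- runif(length(sel)) < pseg
        if (any(seg) && sum(af) > 0) {
          minor_count[sel[seg]] <- sample.int(d %/% 2L, sum(seg),
                                              replace = TRUE, prob = af)
        }
      }
    }
  }

  # the mutation-rate class is keyed to the major (wild-type) allele; the
  # folded minor count never changes the major label (the rare depth-
  # resampling swaps are handled downstream by resample_sites)
  seg <- minor_count > 0L
  major <- anc
  minor <- ifelse(seg, .other_base(anc), NA)

  # codon annotations for test sites (ancestral codon from the ancestral
  # allele; preference from the optimal-codon table)
  aa <- rep(NA_character_, ns)
  codon <- rep(NA_character_, ns)
  pref <- rep(NA_character_, ns)
  subst <- rep(NA_real_, ns)
  cons_aa <- rep(NA, ns)
  idx4 <- which(is4d)
  aa_pool <- c(P = 0.13, A = 0.25, T = 0.17, G = 0.20, V = 0.25)
  aa[idx4] <- sample(names(aa_pool), length(idx4), replace = TRUE,
                     prob = aa_pool)
  prefix <- names(.fourfold_families)[match(aa[idx4], .fourfold_families)]
  codon[idx4] <- paste0(prefix, anc[idx4])
  pref[idx4] <- classify_preference(codon[idx4])
  cons_aa[idx4] <- runif(length(idx4)) < config$aa_conserved_prob
  strong4 <- cls[idx4] == 3L & config$subst_correlation == "monotone"
  n_str <- sum(strong4)
  n_oth <- length(idx4) - n_str
  sub_str <- ifelse(runif(n_str) < 0.5, 0,
                    rgamma(n_str, shape = 1.2, scale = 1.8))
  sub_oth <- ifelse(runif(n_oth) < 0.12, 0,
                    rgamma(n_oth, shape = 1.6, scale = 2.5))
  subst[idx4[strong4]] <- sub_str
  subst[idx4[!strong4]] <- sub_oth
  subst[idx4] <- round(subst[idx4], 3)

  # major-allele triplet context: 5' neighbour, site, 3' neighbour
  left <- character(ns)
  left[idx4] <- substr(prefix, 2L, 2L)
  gc_nb <- ifelse(is4d, config$gc_fourfold, config$gc_intron)
  rand_base <- function(p_gc) {
    g <- runif(ns) < p_gc
    ifelse(g, ifelse(runif(ns) < 0.5, "G", "C"),
           ifelse(runif(ns) < 0.5, "A", "T"))
  }
  left[!is4d] <- rand_base(gc_nb)[!is4d]
  right <- rand_base(gc_nb)
  triplet <- paste0(left, major, right)

  sites <- data.frame(
    chrom = all_sites$chrom, pos = all_sites$pos,
    site_class = all_sites$site_class,
    major_allele = major, minor_allele = minor,
    minor_count = minor_count, called_depth = depth,
    n_alleles = ifelse(seg, 2L, 1L),
    gene_id = all_sites$gene_id,
    codon_anc = codon, amino_acid = aa, preference = pref,
    subst_count = subst,
    check.names = FALSE, stringsAsFactors = FALSE)
  sites[["attr:triplet"]] <- triplet
  sites[["attr:conserved_aa"]] <- as.integer(cons_aa)

  # gene-level codon-bias and expression attributes, loaded on the gene's
  # strong-site fraction (constraint correlates with expression; codon
  # bias anti-correlates weakly)
  ng <- nrow(layout$genes)
  dev <- gene_fs - fr[3L]
  fop <- plogis(0.2 - 2 * dev + rnorm(ng, 0, 0.6))
  enc <- pmin(61, pmax(25, 61 - 20 * fop + rnorm(ng, 0, 3)))
  expr_of <- function(loading) {
    round(exp(rnorm(ng, 0, 1) + loading * dev * 8), 4)
  }
  genes <- layout$genes
  genes$fop <- round(fop, 4)
  genes$enc <- round(enc, 2)
  genes[["expr:embryo"]] <- expr_of(2)
  genes[["expr:larva"]] <- expr_of(0)
  genes[["expr:pupa"]] <- expr_of(2)
  genes[["expr:adult"]] <- expr_of(1.5)

  list(sites = sites, genes = genes, layout = layout, config = config)
}
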