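# Site and gene stratifications: substitution-rate bins, codon preference,
# polarization, genic features, grouped deficits, gene ranking.

#' Substitution-rate bins
#'
#' The eight rate classes over per-site substitution counts used to relate
#' within-species constraint to between-species divergence: `b1` is
#' exactly 0 (completely conserved), `b8` is `>= 9.3`, the rest partition
#' the intermediate range at fixed boundaries.
#'
#' @param boundaries increasing numeric boundaries between `b2..b7`
#'   (defaults 1.4, 1.92, 3.10, 4.40, 6.20, 9.30, the last opening `b8`).
#' @return an object of class `"rate_bins"`.
#' @export
rate_bins <- function(boundaries = c(1.4, 1.92, 3.10, 4.40, 6.20, 9.30)) {
  stopifnot(all(diff(boundaries) > 0), all(boundaries > 0))
  structure(list(boundaries = boundaries,
                 labels = paste0("b", seq_len(length(boundaries) + 2L))),
            class = "rate_bins")
}

#' Assign sites to substitution-rate bins
#'
#' `b1`: exactly 0 substitutions; `b2..b7`: half-open intervals
#' `(prev, bound]` except the last interior bin which is open above
#' (`6.20 < b7 < 9.30` under the defaults); `b8`: at or above the final
#' boundary.
#'
#' @param x numeric vector of per-site substitution counts (>= 0).
#' @param bins a [rate_bins()].
#' @return a factor with levels `b1..b8`.
#' @examples
#' bin_substitutions(c(0, 1.4, 9.299, 9.3))  # b1 b2 b7 b8
#' @export
bin_substitutions <- function(x, bins = rate_bins()) {
  if (any(is.na(x)) || any(x < 0)) {
    stop("substitution counts must be non-negative and non-missing")
  }
  b <- bins$boundaries
  k <- length(b)
  idx <- findInterval(x, c(0, b), left.open = TRUE) + 1L
  idx[x == 0] <- 1L
  idx[x >= b[k]] <- k + 2L
  factor(bins$labels[idx], levels = bins$labels)
}

#' Optimal (preferred) codons of the four-fold amino acids
#'
#' In *D. melanogaster* the translationally preferred codon of each
#' four-fold degenerate amino acid is G- or C-ending: Ala GCC, Gly GGC,
#' Pro CCC, Thr ACC, Val GTG.
#'
#' @return named character vector, amino acid (1-letter) -> codon.
#' @export
preferred_codons <- function() {
  c(A = "GCC", G = "GGC", P = "CCC", T = "ACC", V = "GTG")
}

# codon prefix -> amino acid for the five 4D families
.fourfold_families <- c(GC = "A", GG = "G", CC = "P", AC = "T", GT = "V")

#' Classify a four-fold codon as preferred or unpreferred
#'
#' @param codon character vector of 3-mers encoding a four-fold amino acid
#'   (Pro, Ala, Thr, Gly, Val).
#' @param table preference table as from [preferred_codons()].
#' @return character vector of `"P"` / `"U"`.
#' @examples
#' classify_preference(c("GCC", "CCA"))  # "P" "U"
#' @export
classify_preference <- function(codon, table = preferred_codons()) {
  codon <- toupper(codon)
  aa <- .fourfold_families[substr(codon, 1L, 2L)]
  if (any(is.na(aa))) {
    stop("not a four-fold degenerate codon: ",
         paste(unique(codon[is.na(aa)]), collapse = ", "))
  }
  unname(ifelse(codon == table[aa], "P", "U"))
}

#' Infer ancestral alleles by outgroup parsimony
#'
#' With a single outgroup (`context = "single_outgroup"`), the ancestral
#' allele is the allele shared with the outgroup; when the outgroup allele
#' matches neither the major nor the minor allele the site falls back to
#' its major allele (method `"MAJOR_FALLBACK"`) so that polarization never
#' removes sites.  With `context = "ten_species"` the outgroup consensus
#' must match one of the sample alleles, otherwise the site is returned
#' `UNPOLARIZED` (`NA` ancestral).  `context = "none"` assigns the major
#' allele throughout.
#'
#' @param major,minor character vectors of sample alleles (`minor` may be
#'   `NA` at monomorphic sites).
#' @param outgroup character vector of outgroup (consensus) alleles.
#' @param context polarization context.
#' @return data frame with columns `ancestral` (NA when unpolarized) and
#'   `method` (`"PARSIMONY"`, `"MAJOR_FALLBACK"`, `"MAJOR"`,
#'   `"UNPOLARIZED"`).
#' @export
polarize_sites <- function(major, minor = NA, outgroup,
                           context = c("single_outgroup", "ten_species",
                                       "none")) {
  context <- match.arg(context)
  k <- max(length(major), length(outgroup))
  major <- rep_len(major, k)
  minor <- rep_len(minor, k)
  if (context == "none") {
    return(data.frame(ancestral = major,
                      method = rep("MAJOR", k)))
  }
  outgroup <- rep_len(outgroup, k)
  if (context == "single_outgroup" && anyNA(outgroup)) {
    stop("missing outgroup allele(s) in single_outgroup mode")
  }
  hit_major <- !is.na(outgroup) & outgroup == major
  hit_minor <- !is.na(outgroup) & !is.na(minor) & outgroup == minor
  anc <- ifelse(hit_major, major, ifelse(hit_minor, minor, NA))
  method <- ifelse(hit_major | hit_minor, "PARSIMONY",
                   if (context == "single_outgroup") "MAJOR_FALLBACK"
                   else "UNPOLARIZED")
  if (context == "single_outgroup") {
    anc[is.na(anc)] <- major[is.na(anc)]
  }
  data.frame(ancestral = anc, method = method)
}

# descending-rank tertiles with stable id tie-breaking; sizes differ <= 1
.tertiles <- function(values, ids,
                      labels = c("high", "medium", "low")) {
  n <- length(values)
  ord <- order(-values, ids, method = "radix")
  sizes <- n %/% 3L + (seq_len(3L) <= n %% 3L)
  grp <- rep(labels, sizes)
  out <- character(n)
  out[ord] <- grp
  factor(out, levels = labels)
}

#' Annotate positional and gene-level features of test sites
#'
#' Adds boolean and tertile attributes used by the genic-feature
#' stratifications: `attr:near_start_75` / `attr:near_stop_75` (site
#' within 75 bp of the translation start / stop in CDS coordinates of the
#' longest transcript), `attr:near_splice_48` (within 48 bp of an
#' exon-intron junction; always FALSE in single-exon genes),
#' `attr:single_exon`, `attr:gene_len_class` and `attr:cds_len_class`
#' (long / medium / short tertiles over genes), and `attr:x_linked`.
#'
#' @param sites a site table (rows without a matching `gene_id` get `NA`
#'   attributes and are counted in a warning).
#' @param genes gene-model data frame with columns `gene_id`, `chrom`,
#'   `strand`, `exon_starts`, `exon_ends` (comma-separated coordinate
#'   strings), `gene_length`, `cds_length`.
#' @return the site table with the added `attr:` columns.
#' @export
annotate_features <- function(sites, genes) {
  need <- c("gene_id", "chrom", "strand", "exon_starts", "exon_ends",
            "gene_length", "cds_length")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table lacks column(s): ",
                         paste(miss, collapse = ", "))
  gi <- match(sites$gene_id, genes$gene_id)
  unmatched <- sum(is.na(gi) | is.na(sites$gene_id))
  if (unmatched > 0) {
    warning(unmatched, " site(s) have no matching gene model; ",
            "their positional attributes are NA")
  }
  ex_starts <- lapply(strsplit(genes$exon_starts, ",", fixed = TRUE),
                      as.integer)
  ex_ends <- lapply(strsplit(genes$exon_ends, ",", fixed = TRUE),
                    as.integer)
  n_ex <- lengths(ex_starts)

  cds_pos <- rep(NA_integer_, nrow(sites))
  splice_dist <- rep(NA_integer_, nrow(sites))
  for (g in unique(gi[!is.na(gi)])) {
    rows <- which(!is.na(gi) & gi == g)
    st <- ex_starts[[g]]
    en <- ex_ends[[g]]
    lens <- en - st + 1L
    pos <- sites$pos[rows]
    ei <- findInterval(pos, st)
    within <- ei >= 1L & pos <= en[pmax(ei, 1L)]
    before <- c(0L, cumsum(lens))[pmax(ei, 1L)]
    cp <- before + pos - st[pmax(ei, 1L)] + 1L
    if (genes$strand[g] == "-") cp <- sum(lens) - cp + 1L
    cds_pos[rows] <- ifelse(within, cp, NA_integer_)
    if (n_ex[g] > 1L) {
      junctions <- sort(c(en[-n_ex[g]], st[-1L]))
      sd_ <- vapply(pos, function(p) min(abs(p - junctions)), 0L)
      splice_dist[rows] <- as.integer(sd_)
    } else {
      splice_dist[rows] <- NA_integer_
    }
  }
  cds_len <- genes$cds_length[gi]
  sites[["attr:near_start_75"]] <- cds_pos <= 75L
  sites[["attr:near_stop_75"]] <- cds_pos >= cds_len - 74L
  single <- n_ex[gi] == 1L
  sites[["attr:single_exon"]] <- single
  sites[["attr:near_splice_48"]] <- ifelse(
    single, FALSE, !is.na(splice_dist) & splice_dist <= 48L)
  glen_class <- .tertiles(genes$gene_length, genes$gene_id,
                          labels = c("long", "medium", "short"))
  clen_class <- .tertiles(genes$cds_length, genes$gene_id,
                          labels = c("long", "medium", "short"))
  sites[["attr:gene_len_class"]] <- as.character(glen_class)[gi]
  sites[["attr:cds_len_class"]] <- as.character(clen_class)[gi]
  sites[["attr:x_linked"]] <- sites$chrom == "X"
  sites
}

#' Per-group matched-bootstrap deficits
#'
#' Splits the test sites by a grouping attribute and runs the matched
#' bootstrap within each group against the same reference stream — the
#' machinery behind deficits stratified by rate bin, codon, preference,
#' genic feature or expression class.  Groups with no pairable sites are
#' skipped with a diagnostic.  Negative deficits (an excess of test
#' polymorphism) are reported as such.
#'
#' @param test,ref site tables.
#' @param group either a vector (length `nrow(test)`) of group labels or
#'   the name of a column of `test`.
#' @param mode,max_dist passed to [pair_index()].
#' @param n_boot,seed passed to [bootstrap_deficit()]; each group uses a
#'   seed derived from `seed` and its index, so results are reproducible.
#' @return a data frame of class `"sfs_group_deficit"` with one row per
#'   group: `group`, `n_sites`, `n_pairable`, `mean_deficit`, `se`.
#'   Skipped groups carry `NA` estimates.
#' @export
group_deficit <- function(test, ref, group, mode = "major_allele",
                          max_dist = 1000, n_boot = 10L, seed = 1L) {
  if (is.character(group) && length(group) == 1L) {
    if (!group %in% names(test)) stop("no column '", group, "' in test")
    group <- test[[group]]
  }
  stopifnot(length(group) == nrow(test))
  levs <- if (is.factor(group)) levels(group) else sort(unique(group))
  out <- data.frame(group = as.character(levs),
                    n_sites = NA_integer_, n_pairable = NA_integer_,
                    mean_deficit = NA_real_, se = NA_real_)
  ests <- vector("list", length(levs))
  names(ests) <- as.character(levs)
  for (j in seq_along(levs)) {
    sel <- !is.na(group) & group == levs[j]
    out$n_sites[j] <- sum(sel)
    est <- tryCatch({
      idx <- pair_index(test[sel, , drop = FALSE], ref, mode = mode,
                        max_dist = max_dist)
      bootstrap_deficit(idx, n_boot = n_boot, seed = seed + j)
    }, error = function(e) {
      message("group '", levs[j], "' skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(est)) {
      out$n_pairable[j] <- est$n_pairs
      out$mean_deficit[j] <- est$mean
      out$se[j] <- est$se
      ests[[j]] <- est
    }
  }
  structure(out, estimates = ests, class = c("sfs_group_deficit",
                                             "data.frame"))
}

#' @export
print.sfs_group_deficit <- function(x, ...) {
  cat("Per-group matched-bootstrap polymorphism deficits:\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Rank genes by a surrogate for strong constraint
#'
#' Scores each gene by the fraction of its SNP-free four-fold sites in
#' conserved amino acids that are both unpreferred and themselves fully
#' conserved (0 substitutions) — a divergence-side surrogate for the
#' extent of strong constraint on the gene's synonymous sites.  Genes
#' whose fraction of four-fold sites in conserved amino acids is below
#' `min_conserved_frac` are ineligible.  The top `floor(top_frac *
#' eligible)` genes form the enriched set.
#'
#' @param sites a site table of test-class sites carrying `gene_id`,
#'   `preference`, `subst_count`, `minor_count` and the
#'   `attr:conserved_aa` flag.
#' @param min_conserved_frac minimum fraction of four-fold sites in
#'   conserved amino acids for a gene to be rankable (default 0.2).
#' @param top_frac fraction of eligible genes forming the top set
#'   (default 1/6).
#' @return a list with `ranking` (data frame: `gene_id`, `score`,
#'   `n_scored`, `eligible`, `rank`) and `top` (character vector of
#'   top-set gene ids).
#' @export
rank_genes <- function(sites, min_conserved_frac = 0.2, top_frac = 1 / 6) {
  cons_aa <- .attr_col(sites, "conserved_aa")
  keep <- !is.na(sites$gene_id)
  s <- sites[keep, , drop = FALSE]
  cons_aa <- as.logical(cons_aa[keep])
  gene <- s$gene_id
  frac_cons <- tapply(cons_aa, gene, mean)
  scored <- cons_aa & s$minor_count == 0
  hit <- scored & s$preference == "U" & !is.na(s$subst_count) &
    s$subst_count == 0
  n_scored <- tapply(scored, gene, sum)
  n_hit <- tapply(hit, gene, sum)
  ids <- names(frac_cons)
  score <- ifelse(n_scored > 0, n_hit / n_scored, NA_real_)
  eligible <- frac_cons >= min_conserved_frac & n_scored > 0
  if (!any(eligible)) stop("no genes eligible for ranking")
  ranking <- data.frame(gene_id = ids, score = as.numeric(score),
                        n_scored = as.integer(n_scored),
                        eligible = as.logical(eligible))
  ord <- order(-ranking$score, ranking$gene_id, method = "radix")
  ranking <- ranking[ord, , drop = FALSE]
  ranking$rank <- NA_integer_
  ranking$rank[ranking$eligible] <- seq_len(sum(ranking$eligible))
  n_top <- floor(top_frac * sum(ranking$eligible))
  top <- ranking$gene_id[ranking$eligible][seq_len(n_top)]
  rownames(ranking) <- NULL
  list(ranking = ranking, top = top)
}
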