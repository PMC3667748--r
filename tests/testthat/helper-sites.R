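# quick construction of site tables for unit tests
mk_sites <- function(n = 1L, chrom = "2L", pos = seq_len(n) * 10L,
                     site_class = "FOURFOLD", major = "G", minor = NA,
                     minor_count = 0L, depth = 130L, n_alleles = NULL,
                     gene_id = NA, subst = NA, preference = NA,
                     triplet = NULL, conserved_aa = NULL) {
  if (is.null(n_alleles)) n_alleles <- ifelse(minor_count > 0, 2L, 1L)
  df <- data.frame(
    chrom = rep_len(chrom, n), pos = rep_len(pos, n),
    site_class = rep_len(site_class, n),
    major_allele = rep_len(major, n), minor_allele = rep_len(minor, n),
    minor_count = rep_len(minor_count, n),
    called_depth = rep_len(depth, n),
    n_alleles = rep_len(n_alleles, n),
    gene_id = rep_len(gene_id, n), codon_anc = NA, amino_acid = NA,
    preference = rep_len(preference, n),
    subst_count = rep_len(subst, n),
    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(triplet)) df[["attr:triplet"]] <- rep_len(triplet, n)
  if (!is.null(conserved_aa)) {
    df[["attr:conserved_aa"]] <- rep_len(conserved_aa, n)
  }
  df
}

# write a site table as raw TSV text (exercises the parser, not the writer)
write_raw_site_tsv <- function(rows, path,
                               header = c("chrom", "pos", "site_class",
                                          "major_allele", "minor_allele",
                                          "minor_count", "called_depth",
                                          "n_alleles", "gene_id",
                                          "codon_anc", "amino_acid",
                                          "preference", "subst_count")) {
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  path
}
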