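# Site-table I/O and depth normalization.
#
# The site table is the package's exchange format: one row per candidate
# site, tab-separated with a header, '.' for absent values.  Mandatory
# columns are listed in .site_table_required; free annotation columns use
# an "attr:<name>" prefix and are kept verbatim.

.site_table_required <- c(
  "chrom", "pos", "site_class", "major_allele", "minor_allele",
  "minor_count", "called_depth", "n_alleles")

.site_table_optional <- c(
  "gene_id", "codon_anc", "amino_acid", "preference", "subst_count")

.site_classes <- c("FOURFOLD", "SHORT_INTRON")

#' Read a per-site polymorphism table
#'
#' Reads the tab-separated site table (header row, `.` for absent values)
#' and validates it: mandatory columns must be present, `site_class` must
#' be `FOURFOLD` or `SHORT_INTRON`, counts must be consistent
#' (`0 <= minor_count <= called_depth`).  Rows violating row-level
#' invariants that downstream filters handle (e.g. `n_alleles` > 2) are
#' loaded but reported in the `"flagged"` attribute with their line
#' numbers; structurally malformed rows are an error.
#'
#' @param path path to the TSV file.
#' @return a `data.frame` with one row per site; free `attr:` columns are
#'   preserved.  Attribute `"flagged"` holds a data frame of (line,
#'   reason) for rows left to downstream filters.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop("site table not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
                   check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.site_table_required, names(df))
  if (length(missing_cols)) {
    stop("site table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(.site_table_optional, names(df))) df[[col]] <- NA
  if (nrow(df) == 0L) {
    attr(df, "flagged") <- data.frame(line = integer(), reason = character())
    return(df)
  }
  line_no <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_class <- !(df$site_class %in% .site_classes)
  if (any(bad_class)) {
    stop("unknown site_class at line(s) ",
         paste(head(line_no[bad_class], 5L), collapse = ", "), ": ",
         paste(unique(df$site_class[bad_class]), collapse = ", "))
  }
  malformed <- !is.finite(df$pos) | df$pos < 1 |
    !is.finite(df$minor_count) | df$minor_count < 0 |
    !is.finite(df$called_depth) | df$called_depth < 1 |
    df$minor_count > df$called_depth |
    (df$minor_count > 0 & is.na(df$minor_allele)) |
    (df$minor_count == 0 & df$n_alleles > 1 & df$n_alleles <= 2)
  if (any(malformed)) {
    stop("malformed site rows at line(s): ",
         paste(head(line_no[malformed], 10L), collapse = ", "))
  }
  flag <- df$n_alleles > 2
  attr(df, "flagged") <- data.frame(
    line = line_no[flag],
    reason = rep("n_alleles > 2 (removed by resample_sites)", sum(flag)))
  df
}

#' @rdname read_site_table
#' @param sites a site-table data frame.
#' @export
write_site_table <- function(sites, path) {
  out <- sites
  for (col in names(out)) {
    v <- out[[col]]
    v <- as.character(v)
    v[is.na(v)] <- "."
    out[[col]] <- v
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Depth-normalize a site table by allele subsampling
#'
#' Applies the panel's depth filter and resampling rules: sites called in
#' fewer than `min_called` chromosomes and sites with more than two
#' alleles are removed; at the remaining sites a `depth_target`-allele
#' subset is drawn uniformly without replacement (hypergeometric on the
#' minor allele).  SNPs whose minor allele is lost in subsampling are
#' relabelled monomorphic; if the former minor allele ends up in the
#' majority the allele labels are swapped.  `minor_count` is re-folded so
#' that it never exceeds `floor(depth_target/2)`.
#'
#' @param sites site-table data frame.
#' @param depth_target number of chromosomes to resample to (default 130).
#' @param min_called minimum called depth for a site to be kept
#'   (default 130).
#' @param seed integer seed; the operation is deterministic given it.
#' @return the filtered, depth-normalized site table (all `called_depth`
#'   equal to `depth_target`).
#' @export
resample_sites <- function(sites, depth_target = 130L, min_called = 130L,
                           seed = NULL) {
  stopifnot(depth_target <= min_called)
  keep <- sites$called_depth >= min_called & sites$n_alleles <= 2
  out <- sites[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("no sites at called depth >= ", min_called, "; empty result")
    return(out)
  }
  if (!is.null(seed)) set.seed(seed)
  need <- out$called_depth > depth_target & out$minor_count > 0
  if (any(need)) {
    drawn <- rhyper(sum(need),
                    m = out$minor_count[need],
                    n = out$called_depth[need] - out$minor_count[need],
                    k = depth_target)
    swap <- drawn > depth_target - drawn
    folded <- pmin(drawn, depth_target - drawn)
    idx <- which(need)
    if (any(swap)) {
      i <- idx[swap]
      tmp <- out$major_allele[i]
      out$major_allele[i] <- out$minor_allele[i]
      out$minor_allele[i] <- tmp
    }
    out$minor_count[idx] <- folded
    lost <- idx[folded == 0L]
    out$minor_allele[lost] <- NA
    out$n_alleles[lost] <- 1L
  }
  # sites already monomorphic keep their major allele; depth is normalized
  out$called_depth <- as.integer(depth_target)
  out$minor_count <- pmin(out$minor_count, depth_target %/% 2L)
  out$n_alleles <- ifelse(out$minor_count > 0, 2L, 1L)
  out
}

#' Interior positions of a short intron
#'
#' Returns the genomic positions of a short intron retained as neutral
#' reference sites: introns must be shorter than 86 bp, and positions
#' within the first 16 bp after the 5' (donor) end or the last 6 bp before
#' the 3' (acceptor) end are removed, in transcription orientation, as
#' they may hold splicing signals.
#'
#' @param intron_start,intron_end 1-based inclusive genomic coordinates of
#'   the intron (start <= end).
#' @param strand `"+"` or `"-"`; determines which side is 5'.
#' @return an integer vector of retained genomic positions (possibly
#'   empty: introns of length >= 86 bp, or too short to have an interior,
#'   yield none).
#' @examples
#' length(trim_short_intron(101, 185))  # 85-bp intron -> 63 positions
#' @export
trim_short_intron <- function(intron_start, intron_end, strand = "+") {
  stopifnot(intron_start <= intron_end, strand %in% c("+", "-"))
  len <- intron_end - intron_start + 1L
  if (len >= 86L || len < 23L) {
    return(integer(0))
  }
  # retained within-intron indices (1-based from the 5' end): 17 .. len-6
  if (strand == "+") {
    seq.int(intron_start + 16L, intron_end - 6L)
  } else {
    seq.int(intron_start + 6L, intron_end - 16L)
  }
}
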