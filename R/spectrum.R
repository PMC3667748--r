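#' Observed folded site frequency spectrum with zero class
#'
#' Container for an observed folded SFS over minor-allele count classes
#' `0..floor(n/2)`, where class 0 counts monomorphic sites.  `L` is the
#' total number of sites and `m` the number of segregating sites.
#'
#' @param counts integer vector of per-class site counts, length
#'   `floor(n/2) + 1` (class 0 first).  Alternatively `NULL` if
#'   `minor_counts` is given.
#' @param n sample depth (chromosomes).
#' @param minor_counts optional vector of per-site folded minor-allele
#'   counts from which the class counts are tabulated.
#' @return an object of class `"sfs_spectrum"`: list with `n`, `counts`
#'   (named `0..floor(n/2)`), `L`, `m`.
#' @examples
#' sfs_spectrum(minor_counts = c(0, 0, 1, 3), n = 10)
#' @export
sfs_spectrum <- function(counts = NULL, n, minor_counts = NULL) {
  nf <- n %/% 2L
  if (is.null(counts)) {
    if (is.null(minor_counts)) stop("supply 'counts' or 'minor_counts'")
    if (any(minor_counts < 0 | minor_counts > nf)) {
      stop("minor-allele counts must lie in 0..floor(n/2)")
    }
    counts <- tabulate(minor_counts + 1L, nbins = nf + 1L)
  }
  if (length(counts) != nf + 1L) {
    stop("'counts' must have length floor(n/2) + 1 = ", nf + 1L)
  }
  if (any(counts < 0)) stop("class counts must be non-negative")
  counts <- setNames(as.numeric(counts), as.character(0:nf))
  structure(
    list(n = as.integer(n), counts = counts,
         L = sum(counts), m = sum(counts[-1L])),
    class = "sfs_spectrum")
}

#' @export
print.sfs_spectrum <- function(x, ...) {
  cat(sprintf(
    "Folded SFS: n = %d, L = %s sites, m = %s segregating (density %.4f)\n",
    x$n, format(x$L, big.mark = ","), format(x$m, big.mark = ","),
    if (x$L > 0) x$m / x$L else NA_real_))
  invisible(x)
}

#' Build an observed spectrum from a site table
#'
#' Tabulates the folded minor-allele counts of depth-normalized sites into
#' an [sfs_spectrum()].  All sites must be at the same depth `n`; run
#' [resample_sites()] first.
#'
#' @param sites a site table (data frame) with columns `minor_count` and
#'   `called_depth`.
#' @param n expected uniform depth (default 130).
#' @return an `"sfs_spectrum"`.
#' @export
site_spectrum <- function(sites, n = 130L) {
  if (nrow(sites) > 0 && any(sites$called_depth != n)) {
    stop("sites are not at uniform depth ", n,
         "; run resample_sites() first (depths seen: ",
         paste(sort(unique(sites$called_depth)), collapse = ", "), ")")
  }
  sfs_spectrum(minor_counts = sites$minor_count, n = as.integer(n))
}

#' Read / write a spectrum as two-column text
#'
#' Plain-text serialization: comment header lines `# key=value` carrying at
#' least `n`, then one `class <TAB> count` row per frequency class.
#'
#' @param x an `"sfs_spectrum"`.
#' @param path file path.
#' @param meta optional named character vector of extra header fields.
#' @return `read_spectrum` returns an `"sfs_spectrum"`;
#'   `write_spectrum` returns `path` invisibly.
#' @export
write_spectrum <- function(x, path, meta = NULL) {
  stopifnot(inherits(x, "sfs_spectrum"))
  hdr <- c(sprintf("# n=%d", x$n),
           if (!is.null(meta)) sprintf("# %s=%s", names(meta), meta))
  body <- sprintf("%s\t%s", names(x$counts),
                  format(x$counts, scientific = FALSE, trim = TRUE))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  nline <- grep("^# n=", hdr, value = TRUE)
  if (length(nline) != 1L) stop("spectrum file lacks a '# n=' header: ", path)
  n <- as.integer(sub("^# n=", "", nline))
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  cls <- as.integer(vapply(parts, `[`, "", 1L))
  cnt <- as.numeric(vapply(parts, `[`, "", 2L))
  counts <- numeric(n %/% 2L + 1L)
  counts[cls + 1L] <- cnt
  sfs_spectrum(counts, n = n)
}

# coerce counts vectors / spectra uniformly inside the fit
.as_spectrum <- function(x, n = NULL) {
  if (inherits(x, "sfs_spectrum")) return(x)
  if (is.numeric(x) && !is.null(n)) return(sfs_spectrum(x, n = n))
  stop("expected an 'sfs_spectrum' (or counts plus n)")
}
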