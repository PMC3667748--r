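# Matched-pair bootstrap: pair each test site with nearby reference sites
# that share its major allele (controlling GC content and regional
# variation in mutation rate / linked selection), then resample pairs.

.attr_col <- function(sites, name) {
  col <- paste0("attr:", name)
  if (!col %in% names(sites)) {
    stop("site table lacks the '", col, "' column required by this mode")
  }
  sites[[col]]
}

#' Build the test-to-reference pairing index
#'
#' For every test site, indexes the reference sites eligible to be its
#' bootstrap partner.  Eligibility under `mode = "major_allele"` (the
#' default): same chromosome arm, identical major allele, positions within
#' `max_dist` bp (inclusive).  `mode = "triplet"` matches the ordered
#' major-allele triplet (5' neighbour, site, 3' neighbour; read from the
#' `attr:triplet` column) instead of the single major allele, controlling
#' for context-dependent mutation.  `mode = "none"` keeps the major-allele
#' (GC) match but lifts the distance and chromosome restriction.
#'
#' @param test,ref site tables (data frames).
#' @param mode matching mode, see above.
#' @param max_dist maximum pair separation in bp (inclusive; default 1000).
#' @return an object of class `"pair_index"` carrying the pairable test
#'   sites, the ordered reference sites, per-test-site partner ranges, and
#'   coverage statistics (test sites with no eligible partner are
#'   excluded and counted).
#' @export
pair_index <- function(test, ref,
                       mode = c("major_allele", "triplet", "none"),
                       max_dist = 1000) {
  mode <- match.arg(mode)
  if (nrow(test) == 0L || nrow(ref) == 0L) {
    stop("empty test or reference site table")
  }
  key_of <- function(s) {
    base <- if (mode == "triplet") .attr_col(s, "triplet") else s$major_allele
    if (mode == "none") base else paste(s$chrom, base, sep = "/")
  }
  kT <- key_of(test)
  kR <- key_of(ref)
  ord <- order(kR, ref$pos, method = "radix")
  kRs <- kR[ord]
  posRs <- ref$pos[ord]
  block_start <- which(!duplicated(kRs))
  block_keys <- kRs[block_start]
  block_end <- c(block_start[-1L] - 1L, length(kRs))
  bi <- match(kT, block_keys)
  lo <- hi <- integer(nrow(test))
  ok <- !is.na(bi)
  sel_by_block <- split(which(ok), bi[ok])
  for (bname in names(sel_by_block)) {
    b <- as.integer(bname)
    sel <- sel_by_block[[bname]]
    rng <- block_start[b]:block_end[b]
    pv <- posRs[rng]
    if (mode == "none") {
      lo[sel] <- block_start[b]
      hi[sel] <- block_end[b]
    } else {
      lo[sel] <- block_start[b] +
        findInterval(test$pos[sel] - max_dist - 0.5, pv)
      hi[sel] <- block_start[b] - 1L +
        findInterval(test$pos[sel] + max_dist + 0.5, pv)
    }
  }
  pairable <- ok & hi >= lo
  if (!any(pairable)) {
    stop("no pairable test sites (test: ", nrow(test), ", ref: ", nrow(ref),
         ", mode: ", mode, ", max_dist: ", max_dist,
         "; shared strata: ", length(intersect(kT, kR)), ")")
  }
  structure(list(
    test = test[pairable, , drop = FALSE],
    ref = ref[ord, , drop = FALSE],
    lo = lo[pairable], hi = hi[pairable],
    mode = mode, max_dist = max_dist,
    coverage = list(n_test = nrow(test),
                    n_pairable = sum(pairable),
                    fraction = sum(pairable) / nrow(test))),
    class = "pair_index")
}

#' @export
print.pair_index <- function(x, ...) {
  cat(sprintf(
    "Pair index (mode %s%s): %s of %s test sites pairable (%.1f%%), mean %.1f partners\n",
    x$mode,
    if (x$mode == "none") "" else paste0(", max_dist ", x$max_dist),
    format(x$coverage$n_pairable, big.mark = ","),
    format(x$coverage$n_test, big.mark = ","),
    100 * x$coverage$fraction, mean(x$hi - x$lo + 1)))
  invisible(x)
}

# run fn(test_rows, ref_rows) once per bootstrap replicate; a test site
# drawn several times redraws its partner independently each time
.boot_reps <- function(index, n_boot, seed, fn) {
  if (!is.null(seed)) set.seed(seed)
  N <- index$coverage$n_pairable
  lapply(seq_len(n_boot), function(b) {
    ti <- sample.int(N, N, replace = TRUE)
    span <- index$hi[ti] - index$lo[ti] + 1L
    ri <- index$lo[ti] + floor(runif(N) * span)
    fn(ti, ri)
  })
}

#' Matched-bootstrap estimate of missing polymorphism
#'
#' Per replicate, draws as many test/reference pairs (with replacement)
#' as there are pairable test sites — first a test site, then one of its
#' eligible partners at random — and computes the polymorphism deficit
#' `1 - (segregating fraction of drawn test sites) / (segregating
#' fraction of drawn reference sites)`.  The estimate is the mean over
#' replicates, with the replicate standard deviation as its standard
#' error.
#'
#' @param index a [pair_index()].
#' @param n_boot number of bootstrap replicates (default 10).
#' @param seed integer seed; draws are reproducible given it.
#' @return an object of class `"sfs_bootstrap"`: `replicate_deficits`,
#'   `mean`, `se`, `n_pairs`, `coverage`.
#' @export
bootstrap_deficit <- function(index, n_boot = 10L, seed = NULL) {
  stopifnot(inherits(index, "pair_index"), n_boot >= 2L)
  segT <- index$test$minor_count > 0
  segR <- index$ref$minor_count > 0
  reps <- .boot_reps(index, n_boot, seed, function(ti, ri) {
    pr <- mean(segR[ri])
    if (pr == 0) NA_real_ else 1 - mean(segT[ti]) / pr
  })
  d <- unlist(reps)
  if (anyNA(d)) {
    warning(sum(is.na(d)), " replicate(s) had no segregating reference ",
            "sites and were excluded")
    d <- d[!is.na(d)]
  }
  structure(list(replicate_deficits = d,
                 mean = mean(d), se = sd(d),
                 n_pairs = index$coverage$n_pairable,
                 n_boot = n_boot,
                 coverage = index$coverage),
            class = "sfs_bootstrap")
}

#' @export
print.sfs_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Matched-bootstrap missing polymorphism: %.4f (se %.4f, %d replicates, %s pairs/replicate)\n",
    x$mean, x$se, length(x$replicate_deficits),
    format(x$n_pairs, big.mark = ",")))
  invisible(x)
}

#' Bootstrap-replicate spectra for the joint likelihood fit
#'
#' Runs the same pair resampling as [bootstrap_deficit()] (identical draws
#' under the same seed) but returns, for each replicate, the folded test
#' and reference spectra built from the drawn pairs.  Both spectra have
#' `L` equal to the number of pairs and, by the matching predicate,
#' identical major-allele (GC) composition.  Sites must be
#' depth-normalized.
#'
#' @inheritParams bootstrap_deficit
#' @param n depth at which to build the spectra (default 130).
#' @return a list of `n_boot` elements, each `list(test =, ref =)` of
#'   [sfs_spectrum()] objects.
#' @export
paired_spectra <- function(index, n_boot = 10L, seed = NULL, n = 130L) {
  stopifnot(inherits(index, "pair_index"))
  if (any(index$test$called_depth != n) || any(index$ref$called_depth != n)) {
    stop("paired_spectra needs sites depth-normalized to n = ", n)
  }
  mcT <- index$test$minor_count
  mcR <- index$ref$minor_count
  .boot_reps(index, n_boot, seed, function(ti, ri) {
    list(test = sfs_spectrum(minor_counts = mcT[ti], n = n),
         ref = sfs_spectrum(minor_counts = mcR[ri], n = n))
  })
}

#' Naive (unmatched) polymorphism deficit
#'
#' `1 - density(test) / density(ref)` without any pairing — the quantity
#' the matched bootstrap exists to correct, confounded by composition and
#' regional effects.
#'
#' @param test,ref site tables.
#' @return scalar deficit (negative = test excess).
#' @export
naive_deficit <- function(test, ref) {
  1 - mean(test$minor_count > 0) / mean(ref$minor_count > 0)
}

#' Slow- versus fast-evolving test sites as their own control
#'
#' Re-runs the matched bootstrap using slowly evolving test sites as the
#' "test" stream and nearby fast-evolving test sites as the neutral
#' reference, classifying sites by their per-site substitution count into
#' [rate_bins()].  A positive deficit of slow-bin sites that persists in
#' this comparison cannot be explained by a mutational difference between
#' the test class and the external reference class.
#'
#' @param sites a site table of test-class sites with `subst_count`.
#' @param slow_bins,fast_bins bin labels treated as slow (test) and fast
#'   (reference); defaults `b1` and `b7`/`b8`.
#' @param bins a [rate_bins()] definition.
#' @inheritParams pair_index
#' @inheritParams bootstrap_deficit
#' @return an `"sfs_bootstrap"`.
#' @export
fast_slow_deficit <- function(sites, slow_bins = "b1",
                              fast_bins = c("b7", "b8"),
                              bins = rate_bins(),
                              mode = "major_allele", max_dist = 1000,
                              n_boot = 10L, seed = NULL) {
  if (all(is.na(sites$subst_count))) {
    stop("sites carry no subst_count; cannot build rate bins")
  }
  sub <- sites[!is.na(sites$subst_count), , drop = FALSE]
  b <- bin_substitutions(sub$subst_count, bins)
  slow <- sub[b %in% slow_bins, , drop = FALSE]
  fast <- sub[b %in% fast_bins, , drop = FALSE]
  if (nrow(slow) == 0L || nrow(fast) == 0L) {
    stop("empty rate bins (slow: ", nrow(slow), " sites, fast: ",
         nrow(fast), " sites)")
  }
  idx <- pair_index(slow, fast, mode = mode, max_dist = max_dist)
  bootstrap_deficit(idx, n_boot = n_boot, seed = seed)
}
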