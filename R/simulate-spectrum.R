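#' Simulate an observed spectrum from the model
#'
#' Draws an observed folded spectrum (with zero class) of `L` sites from
#' the model-expected class distribution at depth `n`.  With
#' `noise = "multinomial"` the class counts are a multinomial draw; with
#' `noise = "none"` the expected counts `L * g` are returned after
#' largest-remainder rounding (floor everything, then hand out the
#' remaining sites to the classes with the largest fractional parts), so
#' the counts are integers summing exactly to `L`.
#'
#' @param n sample depth.
#' @param L number of sites.
#' @param theta scaled mutation rate.
#' @param mixture a [selection_mixture()] or single gamma (categories with
#'   `gamma = -Inf` carry no mutations and land in the zero class).
#' @param alpha optional shared class distortion (length
#'   `floor(n/2) + 1`, first element 1) applied to the class distribution
#'   before drawing.
#' @param noise `"multinomial"` (default) or `"none"`.
#' @param seed optional integer seed.
#' @return an [sfs_spectrum()].
#' @export
simulate_spectrum <- function(n, L, theta, mixture = 0, alpha = NULL,
                              noise = c("multinomial", "none"),
                              seed = NULL) {
  noise <- match.arg(noise)
  g <- expected_sfs(n, theta, mixture)$g
  g <- .apply_alpha(unname(g), alpha)
  if (noise == "multinomial") {
    if (!is.null(seed)) set.seed(seed)
    counts <- as.vector(rmultinom(1L, size = L, prob = g))
  } else {
    exact <- L * g
    counts <- floor(exact)
    left <- L - sum(counts)
    if (left > 0) {
      give <- order(exact - counts, decreasing = TRUE)[seq_len(left)]
      counts[give] <- counts[give] + 1
    }
  }
  sfs_spectrum(counts, n = n)
}
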