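# Multinomial likelihood of observed extended spectra, and the shared
# per-frequency-class correction (alpha) profiled out of the joint fit.

#' Multinomial log-likelihood of an observed spectrum
#'
#' `sum_x k_x log g(x)` over all frequency classes including the zero
#' class, dropping the data-only multinomial coefficient (so only
#' differences between parameter points are meaningful).  If any class has
#' positive observed count but zero expected probability the value is
#' `-Inf`, with attribute `"zero_class"` marking the offending classes.
#'
#' @param observed an [sfs_spectrum()] (or a counts vector over classes
#'   `0..floor(n/2)`).
#' @param expected an [expected_sfs()] (or a probability vector of the same
#'   length, summing to 1).
#' @return the log-likelihood (scalar), without the multinomial constant.
#' @export
sfs_loglik <- function(observed, expected) {
  k <- if (inherits(observed, "sfs_spectrum")) observed$counts else observed
  g <- if (inherits(expected, "expected_sfs")) expected$g else expected
  if (length(k) != length(g)) {
    stop("observed and expected spectra have different numbers of classes (",
         length(k), " vs ", length(g), "); depths must match")
  }
  bad <- g <= 0 & k > 0
  if (any(bad)) {
    return(structure(-Inf, zero_class = which(bad) - 1L))
  }
  pos <- k > 0
  sum(k[pos] * log(g[pos]))
}

# expected folded proportions (zero class first) for a parameter point
.g_folded <- function(n, theta, fractions, gammas) {
  fractions <- unname(fractions)
  gammas <- unname(gammas)
  seg <- 0
  acc <- numeric(n %/% 2L)
  for (j in seq_along(fractions)) {
    if (fractions[j] == 0) next
    a <- .a_unfolded(n, gammas[j])
    seg <- seg + fractions[j] * sum(a)
    acc <- acc + fractions[j] * .fold_vec(a, n)
  }
  c(1 - theta * seg, theta * acc)
}

# apply a shared class modifier alpha (alpha[1] is the zero class, fixed 1)
.apply_alpha <- function(g, alpha) {
  if (is.null(alpha)) return(g)
  if (all(alpha == 1)) return(g)
  ag <- alpha * g
  ag / sum(ag)
}

#' Joint negative log-likelihood of test and reference spectra
#'
#' The reference spectrum is modelled as fully neutral; the test spectrum
#' follows the selection mixture.  Both share `theta` and, when supplied,
#' the per-class modifiers `alpha` (`alpha[1]`, the zero class, must be 1;
#' modified probabilities are renormalized over all classes).  Returns
#' `+Inf` for invalid parameter points so it is safe inside an optimizer.
#'
#' @param theta scaled mutation rate.
#' @param mixture a [selection_mixture()] for the test sites.
#' @param observed_test,observed_ref [sfs_spectrum()] objects at the same
#'   depth.
#' @param alpha optional numeric vector of class modifiers, length
#'   `floor(n/2) + 1`, first element 1.
#' @return scalar negative log-likelihood.
#' @export
joint_negloglik <- function(theta, mixture, observed_test, observed_ref,
                            alpha = NULL) {
  stopifnot(inherits(observed_test, "sfs_spectrum"),
            inherits(observed_ref, "sfs_spectrum"))
  if (observed_test$n != observed_ref$n) {
    stop("test and reference spectra have different depths (",
         observed_test$n, " vs ", observed_ref$n, ")")
  }
  n <- observed_test$n
  mix <- .as_mixture(mixture)
  if (!is.null(alpha)) {
    if (length(alpha) != n %/% 2L + 1L) {
      stop("alpha must have one entry per folded class incl. the zero class")
    }
    if (alpha[1L] != 1) stop("alpha[1] (zero class) must be fixed at 1")
    if (any(alpha < 0)) stop("alpha must be non-negative")
  }
  val <- tryCatch({
    gt <- .g_folded(n, theta, mix$fractions, mix$gammas)
    gr <- .g_folded(n, theta, 1, 0)
    -(sfs_loglik(observed_test, .apply_alpha(gt, alpha)) +
        sfs_loglik(observed_ref, .apply_alpha(gr, alpha)))
  }, error = function(e) Inf)
  if (!is.finite(val)) Inf else val
}

# Profile the shared alpha out of the joint likelihood at fixed structural
# parameters.  Stationarity of the log-likelihood in alpha_x gives the
# fixed point
#   alpha_x <- (kT_x + kR_x) / (L_T gT_x / S_T + L_R gR_x / S_R),
# S = sum(alpha * g); the objective is invariant to rescaling alpha, so the
# iteration runs unanchored and the result is normalized to alpha[1] = 1.
.profile_alpha <- function(gT, gR, kT, kR, max_iter = 300L, tol = 1e-11) {
  LT <- sum(kT); LR <- sum(kR)
  nll_of <- function(alpha) {
    -(sfs_loglik(kT, .apply_alpha(gT, alpha)) +
        sfs_loglik(kR, .apply_alpha(gR, alpha)))
  }
  alpha <- rep(1, length(gT))
  best <- list(alpha = alpha, nll = nll_of(alpha))
  for (it in seq_len(max_iter)) {
    ST <- sum(alpha * gT); SR <- sum(alpha * gR)
    denom <- LT * gT / ST + LR * gR / SR
    new <- ifelse(denom > 0, (kT + kR) / denom, 1)
    step <- max(abs(log(pmax(new, 1e-300)) - log(pmax(alpha, 1e-300))))
    alpha <- new
    nll <- nll_of(alpha)
    if (nll < best$nll) best <- list(alpha = alpha, nll = nll)
    if (step < tol) break
  }
  alpha <- best$alpha
  if (alpha[1L] > 0) alpha <- alpha / alpha[1L]
  list(alpha = alpha, nll = best$nll, iterations = it,
       converged = it < max_iter)
}
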