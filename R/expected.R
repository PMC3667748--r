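#' Wright stationary density of a selected allele under mutation-selection
#' balance
#'
#' Expected density of derived-allele population frequency `q` for a site
#' under selection of scaled strength `gamma` = 4\*Ne\*s (negative =
#' deleterious) and scaled mutation rate `theta` = 4\*Ne\*mu:
#' \deqn{f(q) = \theta \frac{e^{\gamma q} - e^{\gamma}}{(1 - e^{\gamma})\,
#'   q(1-q)}.}
#' The neutral limit (gamma -> 0) is `theta / q`.  Evaluation uses the
#' algebraically equivalent form
#' `theta * exp(gamma*q) * expm1(gamma*(1-q)) / (expm1(gamma) * q * (1-q))`
#' which stays finite in double precision for |gamma| up to ~700; below
#' |gamma| = 1e-5 the neutral form is substituted.
#'
#' @param q population frequency, strictly inside (0, 1); vectorized.
#' @param gamma scaled selection coefficient 4\*Ne\*s (scalar).
#' @param theta scaled mutation rate 4\*Ne\*mu per site (scalar).
#' @return numeric vector of densities, same length as `q`.
#' @examples
#' wright_sfs_density(0.01, gamma = 0, theta = 0.0132)  # = theta / q = 1.32
#' @export
wright_sfs_density <- function(q, gamma, theta = 1) {
  if (any(q <= 0 | q >= 1)) {
    stop("'q' must lie strictly inside (0, 1)")
  }
  stopifnot(length(gamma) == 1L, is.finite(gamma), length(theta) == 1L,
            theta > 0)
  if (abs(gamma) < 1e-5) {
    return(theta / q)
  }
  theta * exp(gamma * q) * expm1(gamma * (1 - q)) /
    (expm1(gamma) * q * (1 - q))
}

# Composite Gauss-Legendre grid on (0,1).  Fixed panels concentrate nodes
# near q = 0, where the selected density has a boundary layer of width
# ~1/|gamma| (>= 1/700 for the supported gamma range); 256 nodes per panel
# resolve it to well below 1e-8.
.quad_grid <- function(nodes_per_panel = 256L,
                       breaks = c(0, 0.005, 0.03, 0.15, 0.5, 1)) {
  xs <- vector("list", length(breaks) - 1L)
  ws <- vector("list", length(breaks) - 1L)
  for (k in seq_len(length(breaks) - 1L)) {
    gl <- pracma::gaussLegendre(nodes_per_panel, breaks[k], breaks[k + 1L])
    xs[[k]] <- gl$x
    ws[[k]] <- gl$w
  }
  list(x = unlist(xs), w = unlist(ws))
}

# Quadrature engine for sample depth n: binomial sampling kernel evaluated
# on the fixed grid, cached per n.  B[i, j] = C(n,i) x_j^i (1-x_j)^(n-i).
.sfs_engine <- function(n) {
  key <- paste0("engine_", n)
  eng <- get0(key, envir = .sfsmix_env)
  if (!is.null(eng)) {
    return(eng)
  }
  stopifnot(n >= 2, n == round(n))
  grid <- .quad_grid()
  i <- seq_len(n - 1L)
  B <- exp(outer(i, log(grid$x)) + outer(n - i, log1p(-grid$x)) +
             lchoose(n, i))
  eng <- list(n = n, nf = n %/% 2L, x = grid$x, w = grid$w, B = B)
  assign(key, eng, envir = .sfsmix_env)
  eng
}

# theta-free sampling integrals a_i(gamma), i = 1..n-1, with
# g(i) = theta * a_i.  gamma = -Inf denotes a zero-mutation category.
.a_unfolded <- function(n, gamma) {
  if (identical(gamma, -Inf)) {
    return(rep(0, n - 1L))
  }
  eng <- .sfs_engine(n)
  h <- wright_sfs_density(eng$x, gamma, theta = 1)
  as.vector(eng$B %*% (eng$w * h))
}

.fold_vec <- function(a, n) {
  nf <- n %/% 2L
  out <- a[seq_len(nf)]
  upper <- if (n %% 2L == 0L) nf - 1L else nf
  out[seq_len(upper)] <- out[seq_len(upper)] + a[n - seq_len(upper)]
  out
}

.a_folded <- function(n, gamma) .fold_vec(.a_unfolded(n, gamma), n)

#' Fold an unfolded sample spectrum
#'
#' Folds derived-allele class proportions `g(1..n-1)` into minor-allele
#' classes: `G(j) = g(j) + g(n - j)` for `j < n/2` and `G(n/2) = g(n/2)`
#' when `n` is even.  The zero class, if supplied, is passed through
#' unchanged; total mass is preserved exactly.
#'
#' @param g numeric vector of unfolded proportions for derived-allele counts
#'   `1..n-1`.
#' @param n sample depth (number of chromosomes).
#' @param zero optional zero-class proportion to prepend to the result.
#' @return numeric vector of folded proportions for minor-allele counts
#'   `1..floor(n/2)` (preceded by the zero class when `zero` is given).
#' @examples
#' fold_sfs(c(0.5, 0.3, 0.2), n = 4)  # c(0.5 + 0.2, 0.3)
#' @export
fold_sfs <- function(g, n, zero = NULL) {
  stopifnot(length(g) == n - 1L)
  out <- .fold_vec(g, n)
  if (!is.null(zero)) out <- c(zero, out)
  out
}

#' Selection-category mixture
#'
#' Defines the distribution of fitness effects as a discrete mixture of
#' selection categories, each with a fraction of sites and a scaled
#' selection coefficient gamma = 4\*Ne\*s (<= 0; purifying or neutral).
#' `gamma = -Inf` marks a zero-mutation category: its sites never carry
#' SNPs and contribute only to the monomorphic class (used for
#' mutation-deficit power experiments).
#'
#' @param fractions numeric vector of per-category site fractions; must be
#'   non-negative and sum to 1.
#' @param gammas numeric vector of per-category gamma values, same length
#'   as `fractions`; each must be <= 0 (or -Inf).
#' @param labels optional category labels; defaults to
#'   `c("neutral", "weak", "strong")` when there are three categories.
#' @return an object of class `"selection_mixture"`.
#' @examples
#' selection_mixture(c(0.774, 0, 0.226), c(0, -1, -283))
#' @export
selection_mixture <- function(fractions, gammas, labels = NULL) {
  stopifnot(length(fractions) == length(gammas), length(fractions) >= 1L)
  if (any(fractions < 0)) stop("mixture fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("mixture fractions must sum to 1 (got ", sum(fractions), ")")
  }
  if (any(gammas > 0)) {
    stop("gamma values must be <= 0 (purifying or neutral)")
  }
  if (is.null(labels)) {
    labels <- if (length(fractions) == 3L) {
      c("neutral", "weak", "strong")
    } else {
      paste0("cat", seq_along(fractions))
    }
  }
  structure(
    list(fractions = setNames(as.numeric(fractions), labels),
         gammas = setNames(as.numeric(gammas), labels)),
    class = "selection_mixture")
}

#' @export
print.selection_mixture <- function(x, ...) {
  cat("Selection mixture (gamma = 4*Ne*s):\n")
  out <- data.frame(fraction = x$fractions, gamma = x$gammas)
  print(out, ...)
  invisible(x)
}

.as_mixture <- function(x) {
  if (inherits(x, "selection_mixture")) return(x)
  if (is.numeric(x) && length(x) == 1L) {
    return(selection_mixture(1, x, labels = "all"))
  }
  stop("expected a 'selection_mixture' or a single gamma value")
}

#' Model-predicted sample site frequency spectrum
#'
#' Computes the expected fraction of sites in each frequency class of a
#' sample of `n` chromosomes, including the zero-frequency (monomorphic)
#' class, under the Wright stationary density integrated against binomial
#' sampling:
#' \deqn{g(i) = \int_0^1 f(q)\, {n \choose i} q^i (1-q)^{n-i}\, dq,\qquad
#'   g(0) = 1 - \sum_{i \ge 1} g(i).}
#' For a mixture, `g(x) = sum_c f_c g(x | gamma_c)`.  Under neutrality the
#' closed form is `g(i) = theta / i`.  The quadrature is a fixed composite
#' Gauss-Legendre rule (1280 nodes) accurate to ~1e-8 relative over
#' |gamma| <= 700.
#'
#' @param n sample depth (chromosomes).
#' @param theta scaled mutation rate 4\*Ne\*mu per site.
#' @param mixture a [selection_mixture()], or a single gamma value.
#' @param folded fold to minor-allele classes (default) or keep the
#'   derived-allele spectrum.
#' @return an object of class `"expected_sfs"`: a list with `n`, `theta`,
#'   `mixture`, `folded`, `g` (named proportions over classes `0..`), and
#'   `per_category` (matrix of per-category spectra, same normalization).
#' @examples
#' e <- expected_sfs(10, theta = 0.01)
#' all.equal(unname(e$g[2]), 0.01)  # neutral singleton class = theta/1
#' @export
expected_sfs <- function(n, theta, mixture = 0, folded = TRUE) {
  stopifnot(theta > 0)
  mix <- .as_mixture(mixture)
  A <- vapply(mix$gammas, function(g) .a_unfolded(n, g),
              numeric(n - 1L))
  seg <- theta * colSums(A)
  if (any(seg > 1)) {
    stop("theta = ", theta, " implies a segregating fraction > 1 for some ",
         "category; model invalid at this parameter value")
  }
  per <- sweep(A, 2L, mix$fractions, `*`) * theta
  zero_per <- mix$fractions * (1 - seg)
  if (folded) {
    per <- apply(per, 2L, .fold_vec, n = n)
    if (is.null(dim(per))) per <- matrix(per, nrow = 1L)
  }
  per <- rbind(zero_per, per)
  g <- rowSums(per)
  names(g) <- as.character(seq_len(nrow(per)) - 1L)
  rownames(per) <- names(g)
  structure(
    list(n = n, theta = theta, mixture = mix, folded = folded,
         g = g, per_category = per),
    class = "expected_sfs")
}

#' @export
print.expected_sfs <- function(x, ...) {
  cat(sprintf(
    "Expected %s SFS: n = %d, theta = %g, %d categories\n",
    if (x$folded) "folded" else "unfolded", x$n, x$theta,
    length(x$mixture$fractions)))
  cat(sprintf("  monomorphic g(0) = %.5f, segregating = %.5f\n",
              x$g[1L], sum(x$g[-1L])))
  invisible(x)
}

#' Fraction of neutral polymorphism retained under selection
#'
#' The ratio of segregating-site density expected under selection `gamma`
#' to that expected under neutrality, at sample depth `n`; independent of
#' theta.  This links a fitted mixture to missing polymorphism: a category
#' with fraction `f` and selection `gamma` removes `f * (1 -
#' retention_ratio(n, gamma))` of the sites that would otherwise segregate.
#'
#' @param n sample depth.
#' @param gamma scaled selection coefficient (<= 0; `-Inf` gives 0).
#' @return a fraction in `[0, 1]`.
#' @export
retention_ratio <- function(n, gamma) {
  if (identical(gamma, -Inf)) return(0)
  sum(.a_unfolded(n, gamma)) / sum(.a_unfolded(n, 0))
}
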