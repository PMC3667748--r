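#' Fit the selection mixture to a test and a neutral reference spectrum
#'
#' Jointly fits a test-site folded spectrum (with zero class) and a
#' neutral-reference spectrum by maximum likelihood.  The model has five
#' free structural parameters: `theta` (shared by both spectra), the
#' category fractions `f_weak`, `f_strong` (with `f_neutral = 1 - f_weak -
#' f_strong`) and the category selection strengths `gamma_weak` in
#' `(-weak_bound, 0)` and `gamma_strong` in `(-gamma_limit,
#' -strong_lower)`.  Optionally a shared per-frequency-class modifier
#' `alpha_x` (zero class anchored at 1) absorbs demography and other
#' distortions common to both spectra; the alpha vector is profiled out at
#' each structural parameter point by its stationarity fixed-point, which
#' yields the same joint maximum as optimizing all parameters at once.
#'
#' Optimization is Nelder-Mead on transformed coordinates (log theta,
#' additive log-ratio fractions, bounded-logistic gammas) from several
#' deterministic and seeded starting points, keeping the best restart and
#' polishing it.  Because the weak category becomes exactly neutral as
#' `gamma_weak -> 0`, `f_weak` is unidentified on that ridge; the fit
#' therefore also maximizes the nested model without the weak category and
#' reports, by default, the model preferred by a 2-df likelihood-ratio
#' test at `lrt_level` (the full fit is always retained in the object).
#'
#' @param test,ref observed [sfs_spectrum()] objects at the same depth
#'   (test sites and neutral reference).
#' @param weak_bound upper bound on |gamma| for the weak category
#'   (default 5).
#' @param strong_lower lower bound on |gamma| for the strong category
#'   (default 100).
#' @param gamma_limit largest representable |gamma| (default 700, near the
#'   double-precision limit of the stationary density).
#' @param use_alpha fit the shared per-class correction (default FALSE).
#' @param restarts number of Nelder-Mead restarts (default 8).
#' @param maxit,reltol Nelder-Mead iteration cap and relative tolerance.
#' @param seed integer seed for the jittered restarts (deterministic).
#' @param select `"lrt"` (default) reports the weak category only when
#'   supported by the likelihood-ratio test; `"full"` always reports the
#'   5-parameter fit.
#' @param lrt_level significance level of the weak-category LRT.
#' @param profile_limit also profile the likelihood with `gamma_strong`
#'   fixed at `-gamma_limit`, storing a likelihood-ratio test of the
#'   boundary (used in power analyses; default FALSE).
#' @return an object of class `"sfs_fit"`; see Details.  Methods:
#'   `print`, `summary`, `coef`, `logLik`, `fitted`, `residuals`, `plot`,
#'   `predict`, `simulate`.
#' @details The returned object contains `theta`, `fractions` (neutral,
#'   weak, strong), `gammas` (weak, strong), `alpha` (or NULL), `logLik`
#'   with per-spectrum components, the `full` and `reduced` candidate
#'   fits, `lrt_weak`, boundary flags (`strong_at_limit`,
#'   `strong_at_lower`), convergence information and the fit
#'   configuration.  Estimates sit on the scale of the paper quantities:
#'   `fractions["strong"]` is the fraction of test sites under strong
#'   purifying selection and `gammas["strong"]` its 4\*Ne\*s.
#' @examples
#' g <- expected_sfs(20, theta = 0.01,
#'                   selection_mixture(c(0.8, 0, 0.2), c(0, -1, -200)))
#' test <- simulate_spectrum(20, L = 5e4, theta = 0.01,
#'                           mixture = selection_mixture(c(0.8, 0, 0.2),
#'                                                       c(0, -1, -200)),
#'                           noise = "none")
#' ref <- simulate_spectrum(20, L = 5e4, theta = 0.01, mixture = 0,
#'                          noise = "none")
#' fit <- sfs_selection_fit(test, ref, restarts = 4)
#' coef(fit)
#' @export
sfs_selection_fit <- function(test, ref,
                              weak_bound = 5, strong_lower = 100,
                              gamma_limit = 700,
                              use_alpha = FALSE,
                              restarts = 8L, maxit = 2000L, reltol = 1e-10,
                              seed = 1L,
                              select = c("lrt", "full"), lrt_level = 0.05,
                              profile_limit = FALSE) {
  select <- match.arg(select)
  stopifnot(0 < weak_bound, weak_bound <= strong_lower,
            strong_lower < gamma_limit)
  test <- .as_spectrum(test)
  ref <- .as_spectrum(ref)
  if (test$n != ref$n) {
    stop("test and reference spectra have different depths (", test$n,
         " vs ", ref$n, ")")
  }
  n <- test$n
  kT <- test$counts
  kR <- ref$counts
  a0f <- .a_folded(n, 0)
  A0 <- sum(a0f)

  # theta-free mixture integrals at structural parameters
  prep_mix <- function(fw, fs, gw, gs) {
    seg_mix <- function(gamma, f) {
      if (f == 0) return(list(seg = 0, acc = 0))
      if (gamma == 0) return(list(seg = f * A0, acc = f * a0f))
      a <- .a_unfolded(n, gamma)
      list(seg = f * sum(a), acc = f * .fold_vec(a, n))
    }
    parts <- list(seg_mix(0, 1 - fw - fs), seg_mix(gw, fw), seg_mix(gs, fs))
    list(seg = sum(vapply(parts, `[[`, 0, "seg")),
         acc = Reduce(`+`, lapply(parts, `[[`, "acc")))
  }
  nll_at_theta <- function(theta, mixp) {
    if (theta * mixp$seg >= 1 || theta * A0 >= 1) return(Inf)
    gT <- c(1 - theta * mixp$seg, theta * mixp$acc)
    gR <- c(1 - theta * A0, theta * a0f)
    if (use_alpha) {
      .profile_alpha(gT, gR, kT, kR)$nll
    } else {
      -(sfs_loglik(kT, gT) + sfs_loglik(kR, gR))
    }
  }
  # negative log-likelihood at structural parameters; under the alpha
  # model theta is confounded with the overall level of alpha (only
  # weakly identified through the zero class), so it is profiled out by a
  # 1-D search rather than left to the simplex
  core_nll <- function(theta, fw, fs, gw, gs) {
    nll_at_theta(theta, prep_mix(fw, fs, gw, gs))
  }
  prof_theta <- function(fw, fs, gw, gs) {
    mixp <- prep_mix(fw, fs, gw, gs)
    o <- stats::optimize(function(lt) {
      v <- nll_at_theta(exp(lt), mixp)
      if (is.finite(v)) v else 1e12
    }, interval = c(lt0 - 4, lt0 + 4), tol = 1e-7)
    list(nll = o$objective, theta = exp(o$minimum))
  }

  to_gs <- function(z) -(strong_lower + (gamma_limit - strong_lower) *
                           plogis(z))
  to_gw <- function(z) -weak_bound * plogis(z)
  frac_full <- function(z1, z2) {
    mx <- max(0, z1, z2)
    e <- exp(c(-mx, z1 - mx, z2 - mx))
    e / sum(e)  # (neutral, weak, strong)
  }

  if (use_alpha) {
    # simplex over mixture parameters only; theta profiled inside
    nll_full <- function(p) {
      fr <- frac_full(p[1L], p[2L])
      v <- prof_theta(fr[2L], fr[3L], to_gw(p[3L]), to_gs(p[4L]))$nll
      if (!is.finite(v)) 1e12 else v
    }
    nll_red <- function(p) {
      v <- prof_theta(0, plogis(p[1L]), -1, to_gs(p[2L]))$nll
      if (!is.finite(v)) 1e12 else v
    }
  } else {
    nll_full <- function(p) {
      fr <- frac_full(p[2L], p[3L])
      v <- core_nll(exp(p[1L]), fr[2L], fr[3L], to_gw(p[4L]), to_gs(p[5L]))
      if (!is.finite(v)) 1e12 else v
    }
    nll_red <- function(p) {
      v <- core_nll(exp(p[1L]), 0, plogis(p[2L]), -1, to_gs(p[3L]))
      if (!is.finite(v)) 1e12 else v
    }
  }

  # data-driven theta start from the reference density
  dens_ref <- max(ref$m / ref$L, 1 / (2 * ref$L))
  lt0 <- log(dens_ref / A0)

  run_best <- function(fn, starts) {
    best <- NULL
    codes <- integer(0)
    for (r in seq_len(nrow(starts))) {
      o <- optim(starts[r, ], fn, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol))
      codes <- c(codes, o$convergence)
      if (is.null(best) || o$value < best$value) best <- o
    }
    polish <- optim(best$par, fn, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = 1e-12))
    if (polish$value <= best$value) best <- polish
    best$restart_codes <- codes
    best
  }

  set.seed(seed)
  starts_full <- rbind(
    c(lt0, -2, -1, 0, 0),
    c(lt0, -2, -1, 0, -2),
    c(lt0, -2, -1, 0, 4),    # boundary probe for gamma_strong
    c(lt0, -1, -3, -1, 0),
    c(lt0 + 0.4, -3, 0, 0, 1),
    c(lt0 - 0.7, 0, -3, -1, -1))
  if (restarts > nrow(starts_full)) {
    extra <- matrix(rnorm((restarts - nrow(starts_full)) * 5, 0, 1.5),
                    ncol = 5L)
    extra <- sweep(extra, 2L, c(lt0, -2, -1, 0, 0), `+`)
    starts_full <- rbind(starts_full, extra)
  } else {
    starts_full <- starts_full[seq_len(max(restarts, 1L)), , drop = FALSE]
  }
  starts_red <- rbind(
    c(lt0, -1, 0),
    c(lt0, -1, -2),
    c(lt0, -1, 4),
    c(lt0, -3, 0))
  if (use_alpha) {  # theta column dropped (profiled)
    starts_full <- starts_full[, -1L, drop = FALSE]
    starts_red <- starts_red[, -1L, drop = FALSE]
  }

  best_full <- run_best(nll_full, starts_full)
  best_red <- run_best(nll_red, starts_red)

  unpack_full <- function(p, value) {
    if (use_alpha) p <- c(NA_real_, p)
    fr <- frac_full(p[2L], p[3L])
    theta <- if (use_alpha) {
      prof_theta(fr[2L], fr[3L], to_gw(p[4L]), to_gs(p[5L]))$theta
    } else {
      exp(p[1L])
    }
    list(theta = theta,
         fractions = setNames(fr, c("neutral", "weak", "strong")),
         gammas = c(weak = to_gw(p[4L]), strong = to_gs(p[5L])),
         nll = value, par = p)
  }
  unpack_red <- function(p, value) {
    if (use_alpha) p <- c(NA_real_, p)
    fs <- plogis(p[2L])
    theta <- if (use_alpha) {
      prof_theta(0, fs, -1, to_gs(p[3L]))$theta
    } else {
      exp(p[1L])
    }
    list(theta = theta,
         fractions = setNames(c(1 - fs, 0, fs),
                              c("neutral", "weak", "strong")),
         gammas = c(weak = NA_real_, strong = to_gs(p[3L])),
         nll = value, par = p)
  }
  full <- unpack_full(best_full$par, best_full$value)
  red <- unpack_red(best_red$par, best_red$value)

  lrt_stat <- max(0, 2 * (red$nll - full$nll))
  lrt_p <- pchisq(lrt_stat, df = 2, lower.tail = FALSE)
  use_full <- select == "full" || lrt_p < lrt_level
  est <- if (use_full) full else red

  alpha_hat <- NULL
  if (use_alpha) {
    gT <- .g_folded(n, est$theta,
                    est$fractions,
                    c(0, ifelse(is.na(est$gammas[["weak"]]), -1,
                                est$gammas[["weak"]]),
                      est$gammas[["strong"]]))
    gR <- .g_folded(n, est$theta, 1, 0)
    alpha_hat <- .profile_alpha(gT, gR, kT, kR)$alpha
    if (any(kT + kR == 0)) {
      warning("some frequency classes have zero total count; ",
              "their alpha is unidentified (set to 0)")
    }
  }

  limit_test <- NULL
  if (profile_limit) {
    nll_lim <- function(p) {  # gamma_strong pinned at -gamma_limit
      v <- if (use_alpha) {
        fr <- frac_full(p[1L], p[2L])
        prof_theta(fr[2L], fr[3L], to_gw(p[3L]), -gamma_limit)$nll
      } else {
        fr <- frac_full(p[2L], p[3L])
        core_nll(exp(p[1L]), fr[2L], fr[3L], to_gw(p[4L]), -gamma_limit)
      }
      if (!is.finite(v)) 1e12 else v
    }
    best_lim <- run_best(nll_lim,
                         starts_full[, seq_len(ncol(starts_full) - 1L),
                                     drop = FALSE])
    stat <- max(0, 2 * (best_lim$value - est$nll))
    limit_test <- list(nll = best_lim$value, stat = stat,
                       p = pchisq(stat, df = 1, lower.tail = FALSE))
  }

  gs_hat <- est$gammas[["strong"]]
  converged <- (if (use_full) best_full else best_red)$convergence == 0
  out <- structure(list(
    theta = est$theta,
    fractions = est$fractions,
    gammas = est$gammas,
    alpha = alpha_hat,
    selected = if (use_full) "full" else "reduced",
    full = full, reduced = red,
    lrt_weak = list(stat = lrt_stat, df = 2, p = lrt_p),
    strong_at_limit = abs(gs_hat) >= 0.99 * gamma_limit,
    strong_at_lower = abs(gs_hat) <= 1.01 * strong_lower,
    limit_test = limit_test,
    logLik = -est$nll,
    nll = est$nll,
    converged = converged,
    restart_codes = (if (use_full) best_full else best_red)$restart_codes,
    observed = list(test = test, ref = ref),
    n = n,
    config = list(weak_bound = weak_bound, strong_lower = strong_lower,
                  gamma_limit = gamma_limit, use_alpha = use_alpha,
                  restarts = restarts, maxit = maxit, reltol = reltol,
                  seed = seed, select = select, lrt_level = lrt_level)),
    class = "sfs_fit")
  if (!converged) {
    warning("optimizer iteration limit reached; estimates may not be at ",
            "the maximum (see $restart_codes)")
  }
  out
}

# expected probability vectors (alpha applied) at the fitted parameters
.fit_expected <- function(object) {
  gam_w <- object$gammas[["weak"]]
  gT <- .g_folded(object$n, object$theta, object$fractions,
                  c(0, ifelse(is.na(gam_w), -1, gam_w),
                    object$gammas[["strong"]]))
  gR <- .g_folded(object$n, object$theta, 1, 0)
  list(test = .apply_alpha(gT, object$alpha),
       ref = .apply_alpha(gR, object$alpha))
}

#' @export
print.sfs_fit <- function(x, digits = 4, ...) {
  cat("Extended-SFS selection mixture fit (n =", x$n, "chromosomes)\n")
  cat(sprintf("  theta (4*Ne*mu): %.*g\n", digits, x$theta))
  tab <- data.frame(
    fraction = round(x$fractions, digits),
    gamma = round(c(0, x$gammas), digits))
  rownames(tab) <- c("neutral", "weak", "strong")
  print(tab)
  cat(sprintf("  model: %s (weak-category LRT p = %.3g)\n",
              x$selected, x$lrt_weak$p))
  if (x$strong_at_limit) {
    cat("  NOTE: gamma_strong is pinned at the computational limit -",
        x$config$gamma_limit,
        "(consistent with a mutation deficit / unbounded selection)\n")
  }
  if (!is.null(x$alpha)) {
    cat("  shared alpha correction fitted (",
        length(x$alpha) - 1L, " free class modifiers)\n", sep = "")
  }
  cat(sprintf("  log-likelihood: %.2f%s\n", x$logLik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.sfs_fit <- function(object, ...) {
  exp_p <- .fit_expected(object)
  r_strong <- retention_ratio(object$n, object$gammas[["strong"]])
  missing_poly <- object$fractions[["strong"]] * (1 - r_strong)
  structure(list(
    fit = object,
    expected = exp_p,
    retention_strong = r_strong,
    missing_polymorphism = missing_poly,
    density = c(test = object$observed$test$m / object$observed$test$L,
                ref = object$observed$ref$m / object$observed$ref$L)),
    class = "summary.sfs_fit")
}

#' @export
print.summary.sfs_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  observed SNP density: test %.4f, reference %.4f\n",
              x$density[["test"]], x$density[["ref"]]))
  cat(sprintf("  retention ratio of the strong category: %.4f\n",
              x$retention_strong))
  cat(sprintf(
    "  implied missing polymorphism (f_strong * (1 - r)): %.4f\n",
    x$missing_polymorphism))
  invisible(x)
}

#' @export
coef.sfs_fit <- function(object, ...) {
  c(theta = object$theta,
    f_neutral = object$fractions[["neutral"]],
    f_weak = object$fractions[["weak"]],
    f_strong = object$fractions[["strong"]],
    gamma_weak = object$gammas[["weak"]],
    gamma_strong = object$gammas[["strong"]])
}

#' @export
logLik.sfs_fit <- function(object, ...) {
  df <- if (object$selected == "full") 5L else 3L
  if (!is.null(object$alpha)) df <- df + length(object$alpha) - 1L
  structure(object$logLik, df = df,
            nobs = object$observed$test$L + object$observed$ref$L,
            class = "logLik")
}

#' @export
fitted.sfs_fit <- function(object, ...) {
  exp_p <- .fit_expected(object)
  list(test = exp_p$test * object$observed$test$L,
       ref = exp_p$ref * object$observed$ref$L)
}

#' @export
residuals.sfs_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  f <- fitted(object)
  res <- function(obs, exp_counts) {
    d <- obs$counts - exp_counts
    if (type == "pearson") d / sqrt(pmax(exp_counts, .Machine$double.eps))
    else d
  }
  list(test = res(object$observed$test, f$test),
       ref = res(object$observed$ref, f$ref))
}

#' @export
predict.sfs_fit <- function(object, n = object$n, ...) {
  gam_w <- object$gammas[["weak"]]
  mix <- selection_mixture(object$fractions,
                           c(0, ifelse(is.na(gam_w), -1, gam_w),
                             object$gammas[["strong"]]))
  expected_sfs(n, object$theta, mix)
}

#' @export
simulate.sfs_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  gam_w <- object$gammas[["weak"]]
  mix <- selection_mixture(object$fractions,
                           c(0, ifelse(is.na(gam_w), -1, gam_w),
                             object$gammas[["strong"]]))
  lapply(seq_len(nsim), function(i) {
    list(test = simulate_spectrum(object$n, object$observed$test$L,
                                  object$theta, mix, alpha = object$alpha),
         ref = simulate_spectrum(object$n, object$observed$ref$L,
                                 object$theta, 0, alpha = object$alpha))
  })
}

#' @export
plot.sfs_fit <- function(x, log = "y", max_class = 30L, ...) {
  f <- fitted(x)
  cls <- seq_len(min(max_class, x$n %/% 2L))
  obs_t <- x$observed$test$counts[cls + 1L]
  obs_r <- x$observed$ref$counts[cls + 1L]
  ymax <- max(obs_t, obs_r, f$test[cls + 1L], f$ref[cls + 1L], 1)
  plot(cls, pmax(obs_t, 0.5), type = "p", pch = 1, log = log,
       xlab = "minor-allele count", ylab = "sites",
       ylim = c(0.5, ymax), col = "firebrick", ...)
  points(cls, pmax(obs_r, 0.5), pch = 2, col = "steelblue")
  lines(cls, pmax(f$test[cls + 1L], 0.5), col = "firebrick")
  lines(cls, pmax(f$ref[cls + 1L], 0.5), col = "steelblue")
  legend("topright", bty = "n",
         legend = c("test observed", "reference observed",
                    "test fitted", "reference fitted"),
         pch = c(1, 2, NA, NA), lty = c(NA, NA, 1, 1),
         col = rep(c("firebrick", "steelblue"), 2))
  invisible(x)
}
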