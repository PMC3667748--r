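# One-call reproducible pipeline: simulate -> prepare -> pair -> fit,
# writing plain-text artifacts and a provenance record.

#' Serialize a fit as key-value text
#'
#' @param fit an `"sfs_fit"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "sfs_fit"))
  kv <- c(
    sprintf("theta\t%.10g", fit$theta),
    sprintf("f_neutral\t%.10g", fit$fractions[["neutral"]]),
    sprintf("f_weak\t%.10g", fit$fractions[["weak"]]),
    sprintf("f_strong\t%.10g", fit$fractions[["strong"]]),
    sprintf("gamma_weak\t%.10g", fit$gammas[["weak"]]),
    sprintf("gamma_strong\t%.10g", fit$gammas[["strong"]]),
    sprintf("loglik\t%.6f", fit$logLik),
    sprintf("model\t%s", fit$selected),
    sprintf("lrt_weak_p\t%.6g", fit$lrt_weak$p),
    sprintf("strong_at_limit\t%s", fit$strong_at_limit),
    sprintf("converged\t%s", fit$converged))
  if (!is.null(fit$alpha)) {
    kv <- c(kv, sprintf("alpha_%d\t%.8g",
                        seq_along(fit$alpha) - 1L, fit$alpha))
  }
  writeLines(kv, path)
  invisible(path)
}

#' Run the simulate / prepare / pair / fit pipeline
#'
#' Generates (or loads) a site table, depth-normalizes it, builds the
#' matched pair index, estimates the missing-polymorphism deficit by
#' bootstrap, fits the selection mixture to each bootstrap-replicate pair
#' of spectra, and writes all artifacts as plain text together with a
#' provenance record (seed, configuration, package version).  Re-running
#' with the same configuration and seed reproduces the outputs.
#'
#' @param config a [sim_config()], or a path to an existing site-table
#'   TSV.
#' @param out_dir output directory (created if needed).
#' @param seed master seed for generation, resampling, bootstrap and fits.
#' @param n_boot bootstrap replicates.
#' @param mode,max_dist matching predicate, see [pair_index()].
#' @param n_fit how many replicate spectra to fit (default 1; the
#'   deficit uses all replicates).
#' @param fit_args list of extra arguments to [sfs_selection_fit()].
#' @return (invisibly) a list with `sites`, `deficit`, `fits`, `paths`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("sfsmix_"),
                         seed = 1L, n_boot = 10L,
                         mode = "major_allele", max_dist = 1000,
                         n_fit = 1L, fit_args = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    sites = file.path(out_dir, "sites.tsv"),
    genes = file.path(out_dir, "genes.tsv"),
    bootstrap = file.path(out_dir, "bootstrap.txt"),
    fit = file.path(out_dir, "fit.txt"),
    spectra = file.path(out_dir, c("spectrum_test.txt",
                                   "spectrum_ref.txt")),
    provenance = file.path(out_dir, "provenance.txt"))

  if (is.character(config)) {
    if (!file.exists(config)) stop("input site table not found: ", config)
    message("* loading site table ", config)
    sites <- read_site_table(config)
    cfg_text <- paste("input file:", config)
    depth_target <- 130L
  } else {
    message("* simulating site table (", config$n_fourfold, " + ",
            config$n_intron, " sites)")
    sim <- simulate_sites(config, seed = seed)
    sites <- sim$sites
    write_site_table(sim$sites, paths$sites)
    write_site_table(sim$genes, paths$genes)
    cfg_text <- paste(utils::capture.output(utils::str(config)),
                      collapse = "\n")
    depth_target <- config$depth_target
  }

  message("* depth-normalizing to ", depth_target, " chromosomes")
  sites <- resample_sites(sites, depth_target = depth_target,
                          min_called = depth_target, seed = seed + 1L)
  test <- sites[sites$site_class == "FOURFOLD", , drop = FALSE]
  ref <- sites[sites$site_class == "SHORT_INTRON", , drop = FALSE]
  if (nrow(test) == 0L || nrow(ref) == 0L) {
    stop("pipeline needs both FOURFOLD and SHORT_INTRON sites after ",
         "filtering (got ", nrow(test), " / ", nrow(ref), ")")
  }

  message("* building pair index (mode ", mode, ")")
  idx <- pair_index(test, ref, mode = mode, max_dist = max_dist)
  message("* bootstrap deficit (", n_boot, " replicates)")
  deficit <- bootstrap_deficit(idx, n_boot = n_boot, seed = seed + 2L)
  writeLines(c(
    sprintf("mean_deficit\t%.6f", deficit$mean),
    sprintf("se\t%.6f", deficit$se),
    sprintf("n_pairs\t%d", deficit$n_pairs),
    sprintf("replicates\t%s",
            paste(sprintf("%.6f", deficit$replicate_deficits),
                  collapse = ","))), paths$bootstrap)

  message("* fitting selection mixture on ", n_fit, " replicate(s)")
  spectra <- paired_spectra(idx, n_boot = n_boot, seed = seed + 2L,
                            n = depth_target)
  fits <- lapply(spectra[seq_len(min(n_fit, length(spectra)))],
                 function(sp) {
                   do.call(sfs_selection_fit,
                           c(list(test = sp$test, ref = sp$ref,
                                  seed = seed + 3L), fit_args))
                 })
  write_fit_report(fits[[1L]], paths$fit)
  write_spectrum(spectra[[1L]]$test, paths$spectra[1L],
                 meta = c(role = "test"))
  write_spectrum(spectra[[1L]]$ref, paths$spectra[2L],
                 meta = c(role = "reference"))

  writeLines(c(
    sprintf("package\tsfsmix %s", as.character(packageVersion("sfsmix"))),
    sprintf("seed\t%d", seed),
    sprintf("n_boot\t%d", n_boot),
    sprintf("mode\t%s", mode),
    sprintf("max_dist\t%g", max_dist),
    "config:", cfg_text), paths$provenance)

  message("* done: ", out_dir)
  invisible(list(sites = sites, deficit = deficit, fits = fits,
                 index = idx, paths = paths))
}
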