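## One-call orchestration of the full analysis. Stage outputs are files under
## the output directory, so any stage can be rerun in isolation; one master
## seed deterministically spawns per-stage seeds, all recorded in the run log.

#' Pipeline configuration
#'
#' Either `tps`/`metadata` paths (measured data) or `params`
#' (a [synthetic_params()]) must be supplied; `config` defaults to the
#' shipped cephalothorax configuration.
#'
#' @param out_dir output directory (created if needed).
#' @param tps,metadata paths to a TPS file and its sidecar metadata CSV.
#' @param params a [synthetic_params()] for generated input.
#' @param config analysis config path for [load_analysis_config()].
#' @param anova_permutations,mantel_iterations,cr_permutations,modularity_rounds
#'   per-stage iteration counts; each must be >= 100 (defaults 1000, 5000,
#'   999, 10000).
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, tps = NULL, metadata = NULL,
                            params = NULL, config = NULL,
                            anova_permutations = 1000L,
                            mantel_iterations = 5000L,
                            cr_permutations = 999L,
                            modularity_rounds = 10000L, seed = 1L) {
  counts <- c(anova_permutations = anova_permutations,
              mantel_iterations = mantel_iterations,
              cr_permutations = cr_permutations,
              modularity_rounds = modularity_rounds)
  if (any(counts < 100L))
    stop("validation error: iteration counts must be >= 100 (",
         paste(names(counts)[counts < 100L], collapse = ", "), ")")
  if (is.null(params) && is.null(tps))
    stop("validation error: supply either tps/metadata paths or generator params")
  structure(list(out_dir = out_dir, tps = tps, metadata = metadata,
                 params = params, config = config,
                 anova_permutations = as.integer(anova_permutations),
                 mantel_iterations = as.integer(mantel_iterations),
                 cr_permutations = as.integer(cr_permutations),
                 modularity_rounds = as.integer(modularity_rounds),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full symmetry + modularity analysis
#'
#' Stages, in order: data input (or synthetic generation), object-symmetry
#' decomposition, Procrustes ANOVA, per-sex L-R asymmetry profiles with
#' Z-tests and between-sex comparison, per-sex Mantel correlation of the
#' developmental modules' asymmetry with paired comparison, size regression,
#' per-sex CR / Z_CR for every multi-module hypothesis with pairwise signal
#' comparison, likelihood/AICc covariation-model selection, and modularity
#' tests (developmental + each sex's best-supported partition). All tables
#' are written as CSV under `out_dir`; `MANIFEST.txt` records completed
#' stages and `run_log.txt` the seeds.
#'
#' @param config a [pipeline_config()].
#' @return invisible list of all stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  note <- function(stage) {
    manifest <<- c(manifest, stage)
    writeLines(manifest, file.path(config$out_dir, "MANIFEST.txt"))
  }
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    note(name)
    res
  }
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 12L)
  writeLines(c(sprintf("master seed: %d", config$seed),
               sprintf("stage seeds: %s", paste(seeds, collapse = " ")),
               sprintf("R version: %s", getRversion())),
             file.path(config$out_dir, "run_log.txt"))

  cfg <- stage("config", {
    if (is.null(config$config)) load_analysis_config()
    else load_analysis_config(config$config)
  })
  scheme <- cfg$scheme; partitions <- cfg$partitions

  dat <- stage("data", {
    if (!is.null(config$params)) {
      gen <- generate_dataset(config$params, seed = seeds[1L])
      dir.create(file.path(config$out_dir, "data"), showWarnings = FALSE)
      write_tps(gen$dataset, file.path(config$out_dir, "data", "landmarks.tps"))
      write_specimen_metadata(gen$dataset,
                              file.path(config$out_dir, "data", "metadata.csv"))
      gen$dataset
    } else {
      md <- if (is.null(config$metadata)) NULL
            else read_specimen_metadata(config$metadata)
      read_tps(config$tps, md)
    }
  })

  comp <- stage("decompose_symmetry", decompose_symmetry(dat, scheme))

  anova <- stage("procrustes_anova", {
    a <- procrustes_anova(comp, permutations = config$anova_permutations,
                          seed = seeds[2L])
    utils::write.csv(as.data.frame(a),
                     file.path(config$out_dir, "procrustes_anova.csv"),
                     row.names = FALSE)
    writeLines(utils::capture.output(print(a)),
               file.path(config$out_dir, "procrustes_anova.txt"))
    a
  })

  profiles <- stage("lr_asym_profile", {
    by_sex <- lapply(c(F = "F", M = "M"), function(s)
      ztest_profile(lr_asym_profile(subset_components(comp, comp$sex == s))))
    fa_all <- ztest_profile(lr_asym_profile(comp, component = "fa"))
    cmp <- compare_profiles_between_sexes(by_sex$F, by_sex$M)
    for (s in c("F", "M"))
      utils::write.csv(by_sex[[s]]$summary,
                       file.path(config$out_dir,
                                 sprintf("lr_profile_%s.csv", s)),
                       row.names = FALSE)
    utils::write.csv(fa_all$summary,
                     file.path(config$out_dir, "lr_profile_fa.csv"),
                     row.names = FALSE)
    utils::write.csv(cmp, file.path(config$out_dir, "lr_profile_sex_ttest.csv"),
                     row.names = FALSE)
    list(by_sex = by_sex, fa = fa_all, sex_comparison = cmp)
  })

  mantel <- stage("mantel_modules", {
    res <- lapply(c(F = "F", M = "M"), function(s)
      mantel_modules(subset_components(comp, comp$sex == s),
                     partitions$developmental,
                     iterations = config$mantel_iterations,
                     seed = seeds[3L]))
    cmp <- compare_mantel_distributions(res$F, res$M)
    utils::write.csv(data.frame(sex = c("F", "M"),
                                r = c(res$F$r_point, res$M$r_point),
                                p_perm = c(res$F$p_perm, res$M$p_perm),
                                t_between = cmp$t_stat, p_between = cmp$p),
                     file.path(config$out_dir, "mantel_developmental.csv"),
                     row.names = FALSE)
    list(by_sex = res, comparison = cmp)
  })

  multi <- Filter(function(p) p$module_count >= 2L, partitions)
  modsig <- stage("modular_signal", {
    out <- list()
    for (s in c("F", "M")) {
      resid <- regress_out_size(subset_components(comp, comp$sex == s))
      sig <- lapply(multi, function(p)
        cr_effect_size(resid, p, permutations = config$cr_permutations,
                       seed = seeds[4L]))
      cmp <- compare_modular_signal(sig)
      tab <- data.frame(model = names(sig),
                        cr = vapply(sig, `[[`, 0, "cr"),
                        z_cr = vapply(sig, `[[`, 0, "z_cr_mean"),
                        ci_lo = vapply(sig, function(x) x$ci95[1L], 0),
                        ci_hi = vapply(sig, function(x) x$ci95[2L], 0),
                        group = cmp$grouping[names(sig)])
      utils::write.csv(tab, file.path(config$out_dir,
                                      sprintf("modular_signal_%s.csv", s)),
                       row.names = FALSE)
      writeLines(utils::capture.output(print(cmp)),
                 file.path(config$out_dir,
                           sprintf("modular_signal_groups_%s.txt", s)))
      out[[s]] <- list(signals = sig, comparison = cmp, residuals = resid)
    }
    out
  })

  emmli <- stage("emmli", {
    registry <- enumerate_covariation_variants(unname(partitions))
    out <- list()
    for (s in c("F", "M")) {
      fit <- emmli_fit(modsig[[s]]$residuals, registry)
      utils::write.csv(fit$models,
                       file.path(config$out_dir, sprintf("emmli_%s.csv", s)),
                       row.names = FALSE)
      out[[s]] <- fit
    }
    out
  })

  modtest <- stage("modularity_test", {
    out <- list()
    for (s in c("F", "M")) {
      best_base <- setdiff(unique(emmli[[s]]$models$base), "uniform")[1L]
      targets <- unique(c("developmental", best_base))
      tests <- lapply(targets, function(nm)
        modularity_test(modsig[[s]]$residuals, partitions[[nm]],
                        rounds = config$modularity_rounds, seed = seeds[5L]))
      names(tests) <- targets
      utils::write.csv(data.frame(model = targets,
                                  cr = vapply(tests, `[[`, 0, "cr"),
                                  p = vapply(tests, `[[`, 0, "p")),
                       file.path(config$out_dir,
                                 sprintf("modularity_test_%s.csv", s)),
                       row.names = FALSE)
      out[[s]] <- tests
    }
    out
  })

  note("complete")
  invisible(list(config = cfg, dataset = dat, components = comp,
                 anova = anova, profiles = profiles, mantel = mantel,
                 modular_signal = modsig, emmli = emmli,
                 modularity_tests = modtest, seeds = seeds))
}
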