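## Modularity statistics and covariation-model selection.
##
## The exchangeable unit everywhere is the landmark: both coordinates of a
## landmark always travel together in permutations and reassignments.

#' Covariance ratio (CR) of a landmark partition
#'
#' For two modules, `CR = sqrt( S_b / sqrt(S_w1 * S_w2) )` where `S_b` sums
#' the squared between-module covariances of the sample covariance matrix of
#' the coordinate columns and `S_wm` sums the squared off-diagonal
#' within-module covariances. For more than two modules, the mean of all
#' pairwise CRs. Values toward 0 indicate stronger modularity (weak
#' between-module covariation relative to within-module covariation).
#'
#' @param shape `n x 2K` coordinate (or residual) matrix, columns ordered
#'   `lm1_x, lm1_y, ...` as produced by [flatten_configs()] /
#'   [regress_out_size()].
#' @param partition a [module_partition()] (>= 2 modules, each with >= 2
#'   landmarks).
#' @return scalar CR.
#' @export
covariance_ratio <- function(shape, partition) {
  stopifnot(is.matrix(shape), nrow(shape) >= 3L)
  cr_from_cov(stats::cov(shape), partition$assignment)
}

## CR from a precomputed covariance matrix and a landmark->module assignment
cr_from_cov <- function(V, assignment) {
  mods <- unique(assignment)
  if (length(mods) < 2L) stop("partition must have at least 2 modules")
  cols <- lapply(mods, function(m) landmark_columns(which(assignment == m)))
  sw <- vapply(cols, function(cc) {
    W <- V[cc, cc, drop = FALSE]
    s <- sum(W^2) - sum(diag(W)^2)
    if (s <= 0) stop("undefined CR: a module has all-zero within covariances")
    s
  }, 0)
  pairs <- utils::combn(length(mods), 2L)
  crs <- apply(pairs, 2L, function(pr) {
    B <- V[cols[[pr[1L]]], cols[[pr[2L]]], drop = FALSE]
    sqrt(sum(B^2) / sqrt(sw[pr[1L]] * sw[pr[2L]]))
  })
  mean(crs)
}

## random size-preserving reassignment of landmarks to modules
shuffle_assignment <- function(assignment) assignment[sample.int(length(assignment))]

#' CR permutation effect size (Z_CR)
#'
#' Null distribution of CR from random size-preserving reassignments of
#' landmarks to modules; `Z = (CR_obs - mean_null) / sd_null`. The reported
#' Z_CR distribution (whose mean and 95% CI the modular-signal plots show)
#' comes from re-standardizing against bootstrap resamples of the
#' permutation set (RRPP-style), one Z value per resampling.
#'
#' @inheritParams covariance_ratio
#' @param permutations number of null permutations and of resampled Z values
#'   (default 999).
#' @param seed integer seed.
#' @return Object of class `modular_signal`: `partition_name`, `cr`,
#'   `z_cr_mean`, `z_cr_distribution`, `ci95`, `permutations`, `seed`,
#'   `null_cr`.
#' @export
cr_effect_size <- function(shape, partition, permutations = 999L, seed = 1L) {
  V <- stats::cov(shape)
  cr_obs <- cr_from_cov(V, partition$assignment)
  set.seed(seed)
  null_cr <- vapply(seq_len(permutations), function(b)
    cr_from_cov(V, shuffle_assignment(partition$assignment)), 0)
  if (stats::sd(null_cr) == 0)
    stop("degenerate null: permutation CRs have zero variance")
  zdist <- vapply(seq_len(permutations), function(b) {
    nb <- null_cr[sample.int(permutations, replace = TRUE)]
    s <- stats::sd(nb)
    if (s == 0) NA_real_ else (cr_obs - mean(nb)) / s
  }, 0)
  zdist <- zdist[is.finite(zdist)]
  structure(list(partition_name = partition$name, cr = cr_obs,
                 z_cr = (cr_obs - mean(null_cr)) / stats::sd(null_cr),
                 z_cr_mean = mean(zdist), z_cr_distribution = zdist,
                 ci95 = unname(stats::quantile(zdist, c(0.025, 0.975))),
                 permutations = permutations, seed = seed,
                 null_cr = null_cr),
            class = "modular_signal")
}

#' @export
print.modular_signal <- function(x, ...) {
  cat("modular signal '", x$partition_name, "': CR = ",
      format(x$cr, digits = 4), ", Z_CR = ", format(x$z_cr_mean, digits = 4),
      " [", format(x$ci95[1L], digits = 4), ", ",
      format(x$ci95[2L], digits = 4), "] (", x$permutations,
      " permutations)\n", sep = "")
  invisible(x)
}

## Bron-Kerbosch maximal cliques of a small undirected graph (adjacency
## matrix); returns a list of vertex vectors.
max_cliques <- function(adj) {
  out <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      out[[length(out) + 1L]] <<- sort(R)
      return()
    }
    for (v in P) {
      nb <- which(adj[v, ])
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(nrow(adj)), integer(0))
  out
}

#' Pairwise comparison of modular signals
#'
#' For each pair of hypotheses fitted on the same data, the absolute
#' difference of the mean Z_CR values (`|Z12|`) and an overlap p-value of
#' the two Z_CR distributions: with distributions ordered so that
#' `mean(Z_lo) <= mean(Z_hi)`, `p = min(1, 2 min(P(Z_lo >= mean Z_hi),
#' P(Z_hi <= mean Z_lo)))`. Models are grouped into letters by maximal
#' cliques of the non-significant pairs (compact letter display), so shared
#' letters mark statistically similar modular signal.
#'
#' @param results list of [cr_effect_size()] results on the same shape data
#'   with equal permutation counts.
#' @param alpha significance level for the letter grouping (0.05).
#' @return Object of class `signal_comparison`: `pairs` data.frame
#'   (`model_1`, `model_2`, `delta`, `p_overlap`), `grouping` (named letter
#'   strings), `alpha`.
#' @export
compare_modular_signal <- function(results, alpha = 0.05) {
  stopifnot(length(results) >= 2L,
            all(vapply(results, inherits, TRUE, "modular_signal")))
  perms <- vapply(results, function(x) as.numeric(x$permutations), 0)
  if (length(unique(perms)) > 1L)
    stop("permutation counts differ across results")
  nm <- vapply(results, `[[`, "", "partition_name")
  k <- length(results)
  prs <- utils::combn(k, 2L)
  rows <- apply(prs, 2L, function(pr) {
    z1 <- results[[pr[1L]]]$z_cr_distribution
    z2 <- results[[pr[2L]]]$z_cr_distribution
    if (isTRUE(all.equal(z1, z2))) return(c(0, 1))
    if (mean(z1) > mean(z2)) { tmp <- z1; z1 <- z2; z2 <- tmp }
    p <- min(1, 2 * min(mean(z1 >= mean(z2)), mean(z2 <= mean(z1))))
    c(abs(mean(results[[pr[1L]]]$z_cr_distribution) -
          mean(results[[pr[2L]]]$z_cr_distribution)), p)
  })
  pairs_df <- data.frame(model_1 = nm[prs[1L, ]], model_2 = nm[prs[2L, ]],
                         delta = rows[1L, ], p_overlap = rows[2L, ])
  adj <- matrix(FALSE, k, k)
  for (j in seq_len(ncol(prs)))
    adj[prs[1L, j], prs[2L, j]] <- adj[prs[2L, j], prs[1L, j]] <-
      rows[2L, j] >= alpha
  cl <- max_cliques(adj)
  cl <- cl[order(vapply(cl, min, 0L))]
  letters_by_model <- vapply(seq_len(k), function(i)
    paste0(letters[which(vapply(cl, function(cc) i %in% cc, TRUE))],
           collapse = ""), "")
  names(letters_by_model) <- nm
  structure(list(pairs = pairs_df, grouping = letters_by_model,
                 alpha = alpha),
            class = "signal_comparison")
}

#' @export
print.signal_comparison <- function(x, ...) {
  cat("modular-signal comparison (alpha =", x$alpha, ")\n")
  print.data.frame(format(x$pairs, digits = 4), row.names = FALSE)
  cat("letter groups:\n")
  for (nm in names(x$grouping)) cat("  ", nm, ": ", x$grouping[[nm]], "\n",
                                    sep = "")
  invisible(x)
}

#' Modularity test against arbitrary partitions
#'
#' Compares the CR of a hypothesized partition with CR values of arbitrary
#' partitions having the same number of landmarks per module. The arbitrary
#' distribution contains one CR per random size-preserving reassignment of
#' landmarks across modules. CR is exactly invariant to relabeling landmarks
#' within modules, so shuffling within the hypothesized modules leaves the
#' observed statistic unchanged: the default observed distribution
#' (`"within"`) is that constant, and the p-value reduces to the exact
#' permutation form `p = (#\{CR_arb <= CR_obs\} + 1) / (rounds + 1)`.
#' `observed = "bootstrap"` instead resamples specimens with replacement to
#' show the sampling spread of the observed CR (the red-box display of the
#' test); the p-value then uses the mean of that distribution.
#'
#' @param shape size-regressed residual matrix ([regress_out_size()]).
#' @param partition hypothesized [module_partition()].
#' @param rounds permutation rounds for both distributions (default 10000).
#' @param seed integer seed.
#' @param observed `"within"` (default) or `"bootstrap"`.
#' @return Object of class `modularity_test`: `partition_name`,
#'   `cr_observed_mean`, `cr_observed_distribution`,
#'   `cr_arbitrary_distribution`, `p`, `rounds`, `seed`.
#' @export
modularity_test <- function(shape, partition, rounds = 10000L, seed = 1L,
                            observed = c("within", "bootstrap")) {
  observed <- match.arg(observed)
  if (rounds < 100L) warning("fewer than 100 rounds: p estimate is unstable")
  V <- stats::cov(shape)
  cr_obs <- cr_from_cov(V, partition$assignment)
  n <- nrow(shape)
  set.seed(seed)
  obs_dist <- if (observed == "within") rep(cr_obs, rounds) else
    vapply(seq_len(rounds), function(b) {
      idx <- sample.int(n, replace = TRUE)
      cr_from_cov(stats::cov(shape[idx, , drop = FALSE]),
                  partition$assignment)
    }, 0)
  arb_dist <- vapply(seq_len(rounds), function(b)
    cr_from_cov(V, shuffle_assignment(partition$assignment)), 0)
  m_obs <- mean(obs_dist)
  p <- (sum(arb_dist <= m_obs) + 1L) / (rounds + 1L)
  structure(list(partition_name = partition$name, cr_observed_mean = m_obs,
                 cr = cr_obs, cr_observed_distribution = obs_dist,
                 cr_arbitrary_distribution = arb_dist, p = p,
                 rounds = rounds, seed = seed, observed = observed),
            class = "modularity_test")
}

#' @export
print.modularity_test <- function(x, ...) {
  cat("modularity test '", x$partition_name, "': CR = ",
      format(x$cr, digits = 4), " (observed mean ",
      format(x$cr_observed_mean, digits = 4), ", arbitrary mean ",
      format(mean(x$cr_arbitrary_distribution), digits = 4), ")\n  p = ",
      format(x$p, digits = 4), " (", x$rounds, " rounds)\n", sep = "")
  invisible(x)
}

## ---- likelihood / AICc covariation-model selection --------------------------

#' Landmark-level congruence correlation matrix
#'
#' Correlation between the coordinate blocks of each landmark pair:
#' `phi_ab = (cov(xa, xb) + cov(ya, yb)) /
#'   sqrt((var(xa) + var(ya)) (var(xb) + var(yb)))`, bounded in `[-1, 1]`.
#'
#' @param shape `n x 2K` coordinate matrix.
#' @return `K x K` symmetric matrix with unit diagonal.
#' @export
congruence_matrix <- function(shape) {
  V <- stats::cov(shape)
  K <- ncol(shape) / 2L
  xi <- 2L * seq_len(K) - 1L; yi <- xi + 1L
  num <- V[xi, xi] + V[yi, yi]
  tot <- diag(V)[xi] + diag(V)[yi]
  phi <- num / sqrt(outer(tot, tot))
  diag(phi) <- 1
  phi
}

#' Enumerate covariation-model variants of the modularity hypotheses
#'
#' From each landmark partition, the standard likelihood-model expansions:
#' a shared or module-specific within-module correlation crossed with a
#' shared or module-pair-specific between-module correlation. Variants with
#' identical pair groupings are deduplicated (for 2-module partitions the
#' two between choices coincide); a 1-module partition yields the single
#' uniform-correlation model. The shipped 7-hypothesis configuration expands
#' to 19 distinct variants.
#'
#' @param base_partitions list of [module_partition()] over the same K.
#' @param dedup drop duplicate pair groupings (default TRUE).
#' @return list of models, each `list(name, base, k_params, pair_group)`
#'   where `pair_group` labels each unordered landmark pair (columns of
#'   `combn(K, 2)`).
#' @export
enumerate_covariation_variants <- function(base_partitions, dedup = TRUE) {
  stopifnot(length(base_partitions) >= 1L)
  K <- length(base_partitions[[1L]]$assignment)
  prs <- utils::combn(K, 2L)
  build <- function(part, sep_within, sep_between) {
    a <- part$assignment
    vapply(seq_len(ncol(prs)), function(j) {
      m1 <- a[prs[1L, j]]; m2 <- a[prs[2L, j]]
      if (m1 == m2) {
        if (sep_within) paste0("within.", m1) else "within"
      } else {
        mm <- sort(c(m1, m2))
        if (sep_between) paste0("between.", mm[1L], ".", mm[2L])
        else "between"
      }
    }, "")
  }
  models <- list()
  for (part in base_partitions) {
    if (length(part$assignment) != K)
      stop("partitions must share the same landmark count")
    if (part$module_count == 1L) {
      models[[length(models) + 1L]] <-
        list(name = part$name, base = part$name,
             pair_group = rep("all", ncol(prs)))
      next
    }
    for (sw in c(FALSE, TRUE)) for (sb in c(FALSE, TRUE)) {
      nm <- paste0(part$name, ".",
                   if (sw) "within_sep" else "within_same", ".",
                   if (sb) "between_sep" else "between_same")
      models[[length(models) + 1L]] <-
        list(name = nm, base = part$name,
             pair_group = build(part, sw, sb))
    }
  }
  for (i in seq_along(models))
    models[[i]]$k_params <- length(unique(models[[i]]$pair_group))
  if (dedup) {
    sig <- vapply(models, function(m)
      paste(match(m$pair_group, unique(m$pair_group)), collapse = ","), "")
    models <- models[!duplicated(sig)]
  }
  models
}

#' Likelihood/AICc selection over covariation models
#'
#' Each model assigns every unordered landmark pair to a correlation
#' parameter group. Group estimates are the inverse Fisher transform of the
#' mean Fisher z of the member correlations of the congruence matrix; the
#' log-likelihood treats each pair's z as normal with mean `z(rho_group)`
#' and variance `1 / (n_eff - 3)`. `AICc = -2 logL + 2k + 2k(k+1)/(N-k-1)`
#' with `k` the number of correlation parameters and `N` the number of
#' correlations (set `aicc_n = "neff"` to use the specimen count instead);
#' posterior model weights are proportional to `exp(-delta_AICc / 2)`.
#'
#' @param shape `n x 2K` coordinate matrix (or pass `phi` directly).
#' @param model_registry list from [enumerate_covariation_variants()].
#' @param n_eff effective sample size (number of specimens); must exceed 3.
#' @param phi optional precomputed congruence matrix.
#' @param aicc_n `"ncorr"` (default) or `"neff"`.
#' @return Object of class `emmli_result`: data.frame `models` (`name`,
#'   `base`, `k_params`, `logL`, `aicc`, `delta_aicc`, `posterior_weight`)
#'   sorted by AICc, plus `rho_estimates` (named list per model).
#' @export
emmli_fit <- function(shape, model_registry, n_eff = nrow(shape),
                      phi = congruence_matrix(shape),
                      aicc_n = c("ncorr", "neff")) {
  aicc_n <- match.arg(aicc_n)
  if (n_eff <= 3L) stop("n_eff must exceed 3")
  K <- nrow(phi)
  prs <- utils::combn(K, 2L)
  r <- phi[cbind(prs[1L, ], prs[2L, ])]
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- atanh(r)
  sdz <- 1 / sqrt(n_eff - 3)
  Ncorr <- length(r)
  Nait <- if (aicc_n == "ncorr") Ncorr else n_eff
  rows <- list(); rhos <- list()
  for (m in model_registry) {
    if (length(m$pair_group) != Ncorr)
      stop("model '", m$name, "' labels ", length(m$pair_group),
           " pairs but data has ", Ncorr)
    k <- length(unique(m$pair_group))
    if (k >= Nait - 1L) {
      warning("model '", m$name, "' skipped: k >= N - 1")
      next
    }
    zbar <- tapply(z, m$pair_group, mean)
    mu <- zbar[m$pair_group]
    logL <- sum(stats::dnorm(z, mu, sdz, log = TRUE))
    aicc <- -2 * logL + 2 * k + 2 * k * (k + 1) / (Nait - k - 1)
    rows[[length(rows) + 1L]] <- data.frame(name = m$name,
                                            base = m$base %||% m$name,
                                            k_params = k, logL = logL,
                                            aicc = aicc)
    rhos[[m$name]] <- tanh(zbar)
  }
  if (!length(rows)) stop("no fittable models in the registry")
  tab <- do.call(rbind, rows)
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  w <- exp(-tab$delta_aicc / 2)
  tab$posterior_weight <- w / sum(w)
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL
  structure(list(models = tab, rho_estimates = rhos, n_eff = n_eff,
                 aicc_n = aicc_n),
            class = "emmli_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.emmli_result <- function(x, ...) {
  cat("covariation-model selection (n_eff =", x$n_eff, ")\n")
  print.data.frame(format(x$models, digits = 4), row.names = FALSE)
  invisible(x)
}
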