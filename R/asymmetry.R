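## Inference on bilateral asymmetry: Procrustes ANOVA with RRPP, the
## triangle-area left-right asymmetry profile, and Mantel correlation of
## module-wise asymmetry.

#' Subset shape components by specimen
#' @param components a [decompose_symmetry()] result.
#' @param which logical or integer index over specimens.
#' @return `shape_components` restricted to those specimens (records included).
#' @export
subset_components <- function(components, which) {
  stopifnot(inherits(components, "shape_components"))
  idx <- seq_along(components$specimen_id)[which]
  keep_ids <- components$specimen_id[idx]
  rec <- components$record_specimen %in% keep_ids
  out <- components
  out$aligned <- components$aligned[rec, , , drop = FALSE]
  out$sym <- components$sym[rec, , , drop = FALSE]
  out$asym <- components$asym[rec, , , drop = FALSE]
  out$record_specimen <- components$record_specimen[rec]
  out$record_replicate <- components$record_replicate[rec]
  out$record_sex <- components$record_sex[rec]
  out$specimen_id <- keep_ids
  out$sex <- components$sex[idx]
  out$sym_spec <- components$sym_spec[idx, , , drop = FALSE]
  out$asym_spec <- components$asym_spec[idx, , , drop = FALSE]
  out$centroid_size <- components$centroid_size[idx]
  out
}

## Sequential (type-I) multivariate sums of squares via orthonormal bases.
## Returns list of Q matrices for the nested model sequence.
nested_bases <- function(factors) {
  N <- length(factors[[1L]])
  X <- matrix(1, N, 1L)
  Qs <- list(qr.Q(qr(X)))
  for (f in factors) {
    X <- cbind(X, stats::model.matrix(~f)[, -1L, drop = FALSE])
    qr_ <- qr(X)
    Qs <- c(Qs, list(qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]))
  }
  Qs
}

#' Two-way Procrustes ANOVA of the symmetry decomposition
#'
#' Distance-based ANOVA over the `2 n r` aligned copies (each digitized
#' replicate plus its reflected-relabeled counterpart), with sex nested in
#' the symmetric and asymmetric effects: terms are sex (among-individual,
#' symmetric component), side (within-individual, directional asymmetry) and
#' sex x side (fluctuations of individual asymmetry), each with
#' `nlevels(sex) - 1 = 1` df in the two-sex design; the residual term
#' absorbs the remaining variation including the digitization replicates.
#' Sums of squares are summed squared Procrustes distances (sequential
#' decomposition; parts sum exactly to the total). P-values come from
#' randomization of reduced-model residuals (RRPP): for each term, residuals
#' of the model without it are permuted, the term's F recomputed, and
#' `p = (#\{F* >= F\} + 1) / (B + 1)`. Residuals are permuted over each
#' term's exchangeable units, not free rows: whole-specimen blocks for the
#' sex and sex x side terms (the four copies of a specimen are mutually
#' correlated through its individual shape), and within-copy side swaps for
#' the directional-asymmetry term.
#'
#' @param components a [decompose_symmetry()] result (2 replicates needed).
#' @param sex optional per-record sex labels; defaults to those stored in
#'   `components`.
#' @param permutations RRPP permutations B (default 1000).
#' @param seed integer seed for the permutations.
#' @return Object of class `procrustes_anova`: a data.frame with rows
#'   `symmetric (sex)`, `directional asymmetry (sex)`,
#'   `fluctuating asymmetry (sex)`, `error` and columns `df`, `SS`, `MS`,
#'   `F`, `p_rrpp`; attributes `permutations`, `seed`.
#' @export
procrustes_anova <- function(components, sex = NULL, permutations = 1000L,
                             seed = 1L) {
  stopifnot(inherits(components, "shape_components"))
  if (is.null(sex)) sex <- components$record_sex
  if (anyNA(sex)) stop("missing sex labels")
  if (max(table(components$record_specimen)) < 2L)
    stop("error term undefined: need at least 2 digitization replicates per specimen")
  n_rec <- dim(components$aligned)[1L]
  refl <- array(NA_real_, dim(components$aligned))
  for (i in seq_len(n_rec))
    refl[i, , ] <- reflect_relabel(components$aligned[i, , , drop = TRUE],
                                   components$scheme)
  Y <- rbind(flatten_configs(components$aligned), flatten_configs(refl))
  Y <- scale(Y, scale = FALSE)
  sexf <- factor(rep(as.character(sex), 2L))
  side <- factor(rep(c("original", "reflected"), each = n_rec))
  inter <- interaction(sexf, side)
  Qs <- nested_bases(list(sexf, side, inter))
  N <- nrow(Y)
  totSS <- sum(Y^2)
  fitSS <- vapply(Qs, function(Q) sum(crossprod(Q, Y)^2), 0)
  rks <- vapply(Qs, ncol, 0L)
  SS <- diff(fitSS)
  df <- diff(rks)
  SS_err <- totSS - fitSS[length(fitSS)]
  df_err <- N - rks[length(rks)]
  MS <- SS / df
  MS_err <- SS_err / df_err
  Fs <- MS / MS_err
  ## RRPP over each term's exchangeable units: specimen blocks for the sex
  ## and interaction terms, per-copy side swaps for the side term
  ids <- unique(components$record_specimen)
  n_spec <- length(ids)
  block_rows <- lapply(ids, function(id) {
    w <- which(components$record_specimen == id)
    w <- w[order(components$record_replicate[w])]
    c(w, w + n_rec)
  })
  rows_per_block <- lengths(block_rows)
  if (length(unique(rows_per_block)) > 1L)
    stop("structure error: specimens differ in replicate counts")
  block_mat <- do.call(rbind, block_rows)        # n_spec x (2 r_rep) row ids
  perm_rows <- list(
    block = function() as.vector(t(block_mat[sample.int(n_spec), ,
                                             drop = FALSE]))[
      order(as.vector(t(block_mat)))],
    side = function() {
      swap <- sample(c(TRUE, FALSE), n_rec, replace = TRUE)
      prm <- seq_len(N)
      prm[swap] <- which(swap) + n_rec
      prm[which(swap) + n_rec] <- which(swap)
      prm
    })
  schemes <- c("block", "side", "block")
  set.seed(seed)
  counts <- rep(0L, 3L)
  fit0s <- lapply(Qs[1:3], function(Q) Q %*% crossprod(Q, Y))
  for (b in seq_len(permutations)) {
    prm_b <- perm_rows$block(); prm_s <- perm_rows$side()
    for (j in 1:3) {
      prm <- if (schemes[j] == "block") prm_b else prm_s
      Q0 <- Qs[[j]]; Q1 <- Qs[[j + 1L]]
      Ystar <- fit0s[[j]] + (Y - fit0s[[j]])[prm, , drop = FALSE]
      ss1 <- sum(crossprod(Q1, Ystar)^2)
      ss0 <- sum(crossprod(Q0, Ystar)^2)
      sse <- sum(Ystar^2) - sum(crossprod(Qs[[4L]], Ystar)^2)
      Fstar <- ((ss1 - ss0) / df[j]) / (sse / df_err)
      if (Fstar >= Fs[j] - 1e-12) counts[j] <- counts[j] + 1L
    }
  }
  p <- (counts + 1L) / (permutations + 1L)
  tab <- data.frame(
    term = c("symmetric (sex)", "directional asymmetry (sex)",
             "fluctuating asymmetry (sex)", "error"),
    df = c(df, df_err),
    SS = c(SS, SS_err),
    MS = c(MS, MS_err),
    F = c(Fs, NA_real_),
    p_rrpp = c(p, NA_real_))
  attr(tab, "permutations") <- permutations
  attr(tab, "seed") <- seed
  attr(tab, "total_SS") <- totSS
  class(tab) <- c("procrustes_anova", "data.frame")
  tab
}

#' @export
print.procrustes_anova <- function(x, ...) {
  cat("Procrustes ANOVA (object symmetry; RRPP with",
      attr(x, "permutations"), "permutations)\n")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  invisible(x)
}

## ---- triangle-area left-right asymmetry profile -----------------------------

#' Left-right asymmetry profile from triangle areas
#'
#' For each bilateral pair and specimen, the area of the right triangle with
#' legs parallel and perpendicular to the symmetry axis, spanned by the
#' axis-reference landmark and the side landmark:
#' `A = |x_side - x_ref| * |y_side - y_ref| / 2`. The descriptor is the
#' percentage difference between the sides,
#' `LR = 100 (A_R - A_L) / ((A_L + A_R) / 2)`, negative when asymmetry is
#' skewed to the left (larger left-side area). Coordinates are the grand
#' mean plus each specimen's asymmetric component, so individual symmetric
#' variation does not enter; with `component = "fa"` the sex-mean asymmetry
#' is first removed (fluctuating part only).
#'
#' @param components a [decompose_symmetry()] result.
#' @param scheme pairing scheme; defaults to the one stored in `components`.
#' @param component `"total"` (directional + fluctuating, the default) or
#'   `"fa"` (per-sex centered).
#' @return Object of class `asymmetry_profile`: `values` (specimens x pairs,
#'   longitudinal order), `pair_labels`, `specimen_id`, `sex`, `degenerate`
#'   (pairs with zero summed area), and a `summary` data.frame with per-pair
#'   mean and 95% CI. Z-test columns are filled by [ztest_profile()].
#' @export
lr_asym_profile <- function(components, scheme = components$scheme,
                            component = c("total", "fa")) {
  stopifnot(inherits(components, "shape_components"))
  component <- match.arg(component)
  asym <- components$asym_spec
  n <- dim(asym)[1L]
  if (component == "fa") {
    for (lv in levels(components$sex)) {
      w <- which(components$sex == lv)
      if (length(w))
        asym[w, , ] <- sweep(asym[w, , , drop = FALSE], c(2L, 3L),
                             apply(asym[w, , , drop = FALSE], c(2L, 3L), mean))
    }
  }
  ord <- scheme$longitudinal_order
  P <- nrow(scheme$pairs)
  vals <- matrix(NA_real_, n, P)
  degenerate <- logical(P)
  ref <- scheme$axis_reference
  for (i in seq_len(n)) {
    M <- components$grand_mean + asym[i, , , drop = TRUE]
    for (j in seq_len(P)) {
      pr <- scheme$pairs[ord[j], ]
      aL <- abs(M[pr[1L], 1L] - M[ref, 1L]) * abs(M[pr[1L], 2L] - M[ref, 2L]) / 2
      aR <- abs(M[pr[2L], 1L] - M[ref, 1L]) * abs(M[pr[2L], 2L] - M[ref, 2L]) / 2
      if (aL + aR == 0) {
        vals[i, j] <- 0; degenerate[j] <- TRUE
      } else vals[i, j] <- 100 * (aR - aL) / ((aL + aR) / 2)
    }
  }
  labels <- scheme$pair_labels[ord]
  colnames(vals) <- labels
  mu <- colMeans(vals)
  se <- apply(vals, 2L, stats::sd) / sqrt(n)
  structure(list(values = vals, pair_labels = labels,
                 specimen_id = components$specimen_id, sex = components$sex,
                 component = component, degenerate = degenerate,
                 summary = data.frame(pair = labels, mean = mu,
                                      ci_lo = mu - 1.96 * se,
                                      ci_hi = mu + 1.96 * se,
                                      z_stat = NA_real_, p_z = NA_real_,
                                      row.names = NULL)),
            class = "asymmetry_profile")
}

#' @export
print.asymmetry_profile <- function(x, ...) {
  cat("L-R asymmetry profile (", x$component, "): ", nrow(x$values),
      " specimens x ", ncol(x$values), " pairs\n",
      "sign convention: negative = skewed to the left (larger left-side area)\n",
      sep = "")
  print.data.frame(format(x$summary, digits = 4), row.names = FALSE)
  invisible(x)
}

#' One-sample Z-test of each pair's deviation from perfect symmetry
#'
#' Per pair, `z = mean / (sigma / sqrt(n))` against LR = 0, two-sided p from
#' the standard normal. By default sigma is the sample standard deviation
#' (the classical z.test requires a known sigma the study design does not
#' provide); a fixed `sigma` can be supplied.
#'
#' @param profile an [lr_asym_profile()] result (>= 3 specimens).
#' @param sigma optional fixed population SD (scalar or per-pair vector).
#' @return the profile with `z_stat`, `p_z` and a `degenerate_z` flag filled
#'   in `summary`.
#' @export
ztest_profile <- function(profile, sigma = NULL) {
  stopifnot(inherits(profile, "asymmetry_profile"))
  n <- nrow(profile$values)
  if (n < 3L) stop("need at least 3 specimens for the Z-test")
  mu <- colMeans(profile$values)
  sd_ <- if (is.null(sigma)) apply(profile$values, 2L, stats::sd)
         else rep_len(sigma, ncol(profile$values))
  z <- p <- numeric(length(mu))
  flag <- logical(length(mu))
  for (j in seq_along(mu)) {
    if (sd_[j] == 0) {
      flag[j] <- TRUE
      z[j] <- if (mu[j] == 0) 0 else sign(mu[j]) * Inf
      p[j] <- if (mu[j] == 0) 1 else 0
    } else {
      z[j] <- mu[j] / (sd_[j] / sqrt(n))
      p[j] <- 2 * stats::pnorm(-abs(z[j]))
    }
  }
  profile$summary$z_stat <- z
  profile$summary$p_z <- p
  profile$summary$degenerate_z <- flag
  profile
}

#' Between-sex comparison of asymmetry profiles
#'
#' Per bilateral pair, a two-sample t-test (Welch by default) of the
#' per-specimen LR values of the two sexes. A literally paired test is not
#' defined for unequal sample sizes; `var_equal = TRUE` gives the pooled
#' Student variant.
#'
#' @param profile_f,profile_m [lr_asym_profile()] results over the same
#'   pairing scheme.
#' @param var_equal pooled-variance Student's t instead of Welch.
#' @return data.frame with per-pair `t_stat`, `df`, `p_t`.
#' @export
compare_profiles_between_sexes <- function(profile_f, profile_m,
                                           var_equal = FALSE) {
  stopifnot(inherits(profile_f, "asymmetry_profile"),
            inherits(profile_m, "asymmetry_profile"))
  if (!identical(profile_f$pair_labels, profile_m$pair_labels))
    stop("profiles computed over different pairing schemes")
  if (nrow(profile_f$values) < 2L || nrow(profile_m$values) < 2L)
    stop("need at least 2 specimens per sex")
  res <- lapply(seq_along(profile_f$pair_labels), function(j) {
    tt <- stats::t.test(profile_f$values[, j], profile_m$values[, j],
                        var.equal = var_equal)
    data.frame(pair = profile_f$pair_labels[j], t_stat = unname(tt$statistic),
               df = unname(tt$parameter), p_t = tt$p.value)
  })
  do.call(rbind, res)
}

## ---- Mantel correlation of module asymmetries -------------------------------

lower_tri <- function(D) D[lower.tri(D)]

#' Mantel correlation between the asymmetric components of two modules
#'
#' Builds, per module, the specimen x specimen Euclidean distance matrix over
#' that module's asymmetric Procrustes coordinates; the point statistic is
#' the Pearson correlation of the two matrices' lower triangles. Significance
#' comes from joint row/column permutations of one matrix; the bootstrap
#' distribution (for between-sex comparison) from re-computing r over random
#' subsamples of the specimens (90% without replacement, so no degenerate
#' zero distances enter).
#'
#' @param components a [decompose_symmetry()] result (subset to one sex with
#'   [subset_components()] for per-sex tests).
#' @param partition a 2-module [module_partition()].
#' @param iterations bootstrap iterations (default 5000).
#' @param permutations permutations for the point test (default 999).
#' @param seed integer seed.
#' @param boot_prop subsample proportion for the bootstrap (default 0.9).
#' @return Object of class `mantel_result`: `r_point`, `r_distribution`,
#'   `p_perm`, `iterations`, `permutations`, `seed`, `n`.
#' @export
mantel_modules <- function(components, partition, iterations = 5000L,
                           permutations = 999L, seed = 1L, boot_prop = 0.9) {
  stopifnot(inherits(components, "shape_components"),
            inherits(partition, "module_partition"))
  if (partition$module_count != 2L)
    stop("partition has ", partition$module_count,
         " modules; compare modules pairwise with 2-module partitions")
  X <- flatten_configs(components$asym_spec)
  n <- nrow(X)
  if (n < 5L) stop("need at least 5 specimens")
  mods <- partition$modules
  cols1 <- landmark_columns(which(partition$assignment == mods[1L]))
  cols2 <- landmark_columns(which(partition$assignment == mods[2L]))
  X1 <- X[, cols1, drop = FALSE]; X2 <- X[, cols2, drop = FALSE]
  D1 <- as.matrix(stats::dist(X1)); D2 <- as.matrix(stats::dist(X2))
  r_point <- stats::cor(lower_tri(D1), lower_tri(D2))
  set.seed(seed)
  v1 <- lower_tri(D1)
  hits <- 0L
  for (b in seq_len(permutations)) {
    prm <- sample.int(n)
    if (stats::cor(v1, lower_tri(D2[prm, prm])) >= r_point - 1e-12)
      hits <- hits + 1L
  }
  p_perm <- (hits + 1L) / (permutations + 1L)
  m <- max(5L, floor(boot_prop * n))
  r_boot <- vapply(seq_len(iterations), function(b) {
    idx <- sample.int(n, m)
    stats::cor(lower_tri(as.matrix(stats::dist(X1[idx, , drop = FALSE]))),
               lower_tri(as.matrix(stats::dist(X2[idx, , drop = FALSE]))))
  }, 0)
  structure(list(r_point = r_point, r_distribution = r_boot, p_perm = p_perm,
                 iterations = iterations, permutations = permutations,
                 seed = seed, n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("Mantel r =", format(x$r_point, digits = 4), " (n =", x$n,
      "); permutation p =", format(x$p_perm, digits = 4), "\n  bootstrap:",
      x$iterations, "iterations, mean r =",
      format(mean(x$r_distribution), digits = 4), "\n")
  invisible(x)
}

#' Paired comparison of two bootstrap Mantel-r distributions
#'
#' Paired Student's t-test over the two distributions, paired by iteration
#' index (equal iteration counts required).
#'
#' @param result_1,result_2 [mantel_modules()] results.
#' @return list with `t_stat`, `df`, `p`, `mean_diff`, `degenerate` (zero
#'   variance of the differences).
#' @export
compare_mantel_distributions <- function(result_1, result_2) {
  stopifnot(inherits(result_1, "mantel_result"),
            inherits(result_2, "mantel_result"))
  if (result_1$iterations != result_2$iterations)
    stop("iteration counts differ; distributions cannot be paired")
  d <- result_1$r_distribution - result_2$r_distribution
  if (stats::sd(d) < 1e-9 * max(abs(mean(d)), .Machine$double.eps)) {
    return(list(t_stat = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = length(d) - 1L,
                p = if (mean(d) == 0) 1 else 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(result_1$r_distribution, result_2$r_distribution,
                      paired = TRUE)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
}
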