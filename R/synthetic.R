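## Synthetic landmark data with known structure.
##
## The generator emulates the study design the analyses assume: bilaterally
## paired 2D landmarks digitized twice per specimen, block-structured
## symmetric shape covariance over two developmental modules, sex-specific
## directional asymmetry, individually fluctuating asymmetry whose module-wise
## expression can be correlated, digitization noise, and an arbitrary
## similarity transform per digitized copy (so the Procrustes stage is
## genuinely exercised). Asymmetry is injected in the template's symmetric
## frame *before* the nuisance transform.

#' Deterministic symmetric template configuration
#'
#' Builds a bilaterally symmetric template conforming to a pairing scheme:
#' midline landmarks on the x-axis (the axis_reference landmark
#' anteriormost), pairs mirrored across it at positions monotone in x along
#' the longitudinal order, centroid size 1.
#'
#' @param scheme a [pairing_scheme()].
#' @return `K x 2` matrix; exact fixed point of [reflect_relabel()].
#' @export
make_template <- function(scheme) {
  K <- scheme$K
  P <- nrow(scheme$pairs)
  tmpl <- matrix(0, K, 2L)
  ## pairs from anterior (large x) to posterior, half-width varying smoothly
  xs <- seq(0.9, -0.9, length.out = P)
  ws <- 0.35 + 0.25 * sin(pi * seq_len(P) / (P + 1))
  for (j in seq_len(P)) {
    pr <- scheme$pairs[scheme$longitudinal_order[j], ]
    tmpl[pr[1L], ] <- c(xs[j], ws[j])    # left: positive y
    tmpl[pr[2L], ] <- c(xs[j], -ws[j])   # right: mirrored
  }
  mid <- scheme$midline
  other <- setdiff(mid, scheme$axis_reference)
  tmpl[scheme$axis_reference, ] <- c(1.05, 0)
  if (length(other))
    tmpl[other, 1L] <- seq(-0.5, -1.05, length.out = length(other))
  tmpl <- scale(tmpl, scale = FALSE)
  tmpl / centroid_size(tmpl)
}

#' Parameters of the synthetic landmark generator
#'
#' Defaults follow the emulated study design: 55 females and 48 males, each
#' digitized twice. Magnitudes are in units of the unit-centroid-size
#' template (shape units).
#'
#' @param scheme a [pairing_scheme()].
#' @param modules a 2-module [module_partition()] defining the developmental
#'   blocks of the shape covariance; default splits the pairs at the
#'   longitudinal midpoint (for the shipped configuration, pass the
#'   `developmental` partition).
#' @param n_female,n_male specimens per sex (55, 48).
#' @param replicates digitizations per specimen (2).
#' @param template symmetric mean shape; default [make_template()].
#' @param rho_within,rho_between landmark-level correlations of the symmetric
#'   individual deviations within / between modules (0.5, 0.2).
#' @param sigma_shape SD of individual symmetric shape deviations (0.01).
#' @param da_vector_by_sex named list (`F`, `M`) of `K x 2` matrices added to
#'   the *left-side* landmark rows (midline rows ignored); default skews
#'   females left (+y on the left side) and males right.
#' @param sigma_fa SD of the individual fluctuating-asymmetry field (0.003).
#' @param sigma_digit SD of per-replicate digitization noise (0.001).
#' @param asym_module_corr correlation of the module-wise expression of
#'   fluctuating asymmetry (drives the Mantel correlation; 0.5).
#' @param seed integer seed used by [generate_dataset()].
#' @return list of class `synthetic_params`.
#' @export
synthetic_params <- function(scheme, modules = NULL,
                             n_female = 55L, n_male = 48L, replicates = 2L,
                             template = make_template(scheme),
                             rho_within = 0.5, rho_between = 0.2,
                             sigma_shape = 0.01,
                             da_vector_by_sex = NULL,
                             sigma_fa = 0.003, sigma_digit = 0.001,
                             asym_module_corr = 0.5, seed = 1L) {
  stopifnot(inherits(scheme, "pairing_scheme"),
            rho_within >= 0, rho_within < 1, rho_between >= 0,
            rho_between < 1, sigma_shape > 0, sigma_fa >= 0,
            sigma_digit >= 0, asym_module_corr >= 0, asym_module_corr <= 1,
            n_female >= 1L, n_male >= 1L, replicates >= 1L)
  if (max(abs(template - reflect_relabel(template, scheme))) > 1e-9)
    stop("template must be an exact fixed point of reflect_relabel")
  if (is.null(modules)) {
    P <- nrow(scheme$pairs)
    half <- scheme$longitudinal_order[seq_len(ceiling(P / 2))]
    assign <- rep("m2", scheme$K)
    assign[c(scheme$pairs[half, ], scheme$axis_reference)] <- "m1"
    modules <- module_partition("generator_default", assign)
  }
  if (modules$module_count != 2L)
    stop("generator modules must form a 2-module partition")
  if (is.null(da_vector_by_sex)) {
    daF <- daM <- matrix(0, scheme$K, 2L)
    daF[scheme$pairs[, 1L], 2L] <- 0.004    # left side outward: skew left
    daM[scheme$pairs[, 1L], 2L] <- -0.003   # left side inward: skew right
    da_vector_by_sex <- list(F = daF, M = daM)
  }
  structure(list(scheme = scheme, modules = modules, n_female = n_female,
                 n_male = n_male, replicates = as.integer(replicates),
                 template = template, rho_within = rho_within,
                 rho_between = rho_between, sigma_shape = sigma_shape,
                 da_vector_by_sex = da_vector_by_sex, sigma_fa = sigma_fa,
                 sigma_digit = sigma_digit,
                 asym_module_corr = asym_module_corr, seed = as.integer(seed)),
            class = "synthetic_params")
}

## Exchangeable block correlation over units; shrunk toward the identity if a
## numerically non-PSD matrix sneaks through.
block_correlation <- function(unit_module, rho_within, rho_between) {
  same <- outer(unit_module, unit_module, `==`)
  R <- ifelse(same, rho_within, rho_between)
  diag(R) <- 1
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-10) {
    lam <- abs(ev) + 1e-8
    R <- (R + lam * diag(nrow(R))) / (1 + lam)
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 0)
      stop("block correlation matrix not positive semi-definite after shrinkage")
  }
  R
}

#' Generate a synthetic landmark dataset
#'
#' Per specimen: a symmetric individual deviation with block correlation
#' (`rho_within` within each module, `rho_between` across) at the level of
#' bilateral units (pairs + midline points), applied mirror-symmetrically;
#' the sex's directional-asymmetry vector and an individual
#' fluctuating-asymmetry field added to the left-side landmarks; per
#' replicate, digitization noise and a random similarity transform
#' (rotation, scale, translation). Every drawn effect is returned in the
#' truth record for recovery tests.
#'
#' @param params a [synthetic_params()].
#' @param seed optional override of `params$seed`.
#' @return list with `dataset` (a [landmark_dataset()]) and `truth` (list:
#'   per-specimen symmetric deviations and asymmetry fields, the parameters).
#' @export
generate_dataset <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(seed)
  scheme <- params$scheme
  K <- scheme$K; P <- nrow(scheme$pairs)
  ## bilateral units: pairs (represented by their left landmark) + midline
  unit_lm <- c(scheme$pairs[, 1L], scheme$midline)
  U <- length(unit_lm)
  is_pair_unit <- c(rep(TRUE, P), rep(FALSE, length(scheme$midline)))
  unit_module <- params$modules$assignment[unit_lm]
  R <- block_correlation(unit_module, params$rho_within, params$rho_between)
  cholR <- chol(R)
  ## fixed unit-norm fluctuating-asymmetry pattern over pair units
  fa_pattern <- sin(seq_len(P)) ; fa_pattern <- fa_pattern / sqrt(sum(fa_pattern^2))
  c_fa <- params$asym_module_corr
  n <- params$n_female + params$n_male
  sexes <- rep(c("F", "M"), c(params$n_female, params$n_male))
  ids <- sprintf("%s%03d", sexes, c(seq_len(params$n_female),
                                    seq_len(params$n_male)))
  configs <- list(); rec_id <- character(); rec_rep <- integer()
  sym_dev_truth <- array(0, c(n, K, 2L))
  fa_truth <- matrix(0, n, P)                 # y-displacement per pair unit
  rec <- 0L
  for (i in seq_len(n)) {
    ## symmetric individual deviation, drawn at unit level per axis
    dx <- params$sigma_shape * drop(crossprod(cholR, stats::rnorm(U)))
    dy <- params$sigma_shape * drop(crossprod(cholR, stats::rnorm(U)))
    dev <- matrix(0, K, 2L)
    dev[scheme$pairs[, 1L], ] <- cbind(dx[seq_len(P)], dy[seq_len(P)])
    dev[scheme$pairs[, 2L], ] <- cbind(dx[seq_len(P)], -dy[seq_len(P)])
    dev[scheme$midline, 1L] <- dx[!is_pair_unit]
    sym_dev_truth[i, , ] <- dev
    ## fluctuating asymmetry: common-factor coupling across modules
    g <- stats::rnorm(1L)
    eps <- stats::rnorm(P)
    fa_y <- params$sigma_fa * (sqrt(c_fa) * g * fa_pattern * sqrt(P) +
                               sqrt(1 - c_fa) * eps)
    fa_truth[i, ] <- fa_y
    base <- params$template + dev
    da <- params$da_vector_by_sex[[sexes[i]]]
    base[scheme$pairs[, 1L], ] <- base[scheme$pairs[, 1L], ] +
      da[scheme$pairs[, 1L], , drop = FALSE]
    base[scheme$pairs[, 1L], 2L] <- base[scheme$pairs[, 1L], 2L] + fa_y
    for (r in seq_len(params$replicates)) {
      X <- base + matrix(stats::rnorm(2L * K, sd = params$sigma_digit), K, 2L)
      th <- stats::runif(1L, 0, 2 * pi)
      rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
      X <- X %*% rot * exp(stats::rnorm(1L, 0, 0.1))
      X <- sweep(X, 2L, stats::runif(2L, -1, 1), `+`)
      rec <- rec + 1L
      configs[[rec]] <- X; rec_id[rec] <- ids[i]; rec_rep[rec] <- r
    }
  }
  dataset <- landmark_dataset(configs, rec_id,
                              sex = rep(sexes, each = params$replicates),
                              replicate = rec_rep)
  list(dataset = dataset,
       truth = list(sym_dev = sym_dev_truth, fa_y = fa_truth,
                    specimen_id = ids, sex = sexes, params = params,
                    seed = seed))
}

#' Generate a correlation-structured shape matrix directly
#'
#' Draws an `n x 2K` matrix whose landmark-level correlation follows an
#' exchangeable block structure: `rho_within` between landmarks of the same
#' module and `rho_between` across modules, independently for x and y, so
#' the congruence correlation between two landmarks equals the block value
#' in expectation. This bypasses superimposition entirely: it is the
#' reference input for validating the covariance-ratio and likelihood
#' machinery against a known covariation model, free of the cross-side
#' sign structure that bilateral (object-symmetry) coordinates carry.
#'
#' @param n specimens.
#' @param partition a [module_partition()] (K landmarks).
#' @param rho_within,rho_between block correlations.
#' @param sigma coordinate SD (default 1).
#' @param seed integer seed.
#' @return `n x 2K` matrix in [flatten_configs()] column order.
#' @export
generate_shape_matrix <- function(n, partition, rho_within, rho_between,
                                  sigma = 1, seed = 1L) {
  set.seed(seed)
  K <- length(partition$assignment)
  R <- block_correlation(partition$assignment, rho_within, rho_between)
  cholR <- chol(R)
  X <- matrix(NA_real_, n, 2L * K)
  for (i in seq_len(n)) {
    X[i, 2L * seq_len(K) - 1L] <- sigma * drop(crossprod(cholR, stats::rnorm(K)))
    X[i, 2L * seq_len(K)] <- sigma * drop(crossprod(cholR, stats::rnorm(K)))
  }
  colnames(X) <- as.vector(rbind(paste0("lm", seq_len(K), "_x"),
                                 paste0("lm", seq_len(K), "_y")))
  X
}
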