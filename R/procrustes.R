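## Superimposition and object-symmetry decomposition.
##
## Conventions: full Procrustes fitting (configurations scaled to unit
## centroid size), rotation-only alignment (determinant +1; reflection is
## handled explicitly by reflect_relabel), consensus rotated so the best-fit
## line through the midline landmarks is the x-axis with the axis_reference
## landmark at positive x.

#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of the landmarks from their
#' centroid; invariant to translation and rotation, homogeneous of degree 1
#' under isotropic scaling.
#'
#' @param config `K x 2` numeric matrix.
#' @return positive scalar.
#' @export
centroid_size <- function(config) {
  stopifnot(is.matrix(config), ncol(config) == 2L, nrow(config) >= 2L,
            all(is.finite(config)))
  cs <- sqrt(sum(scale(config, scale = FALSE)^2))
  if (cs < .Machine$double.eps^0.5 * nrow(config))
    stop("degenerate configuration: all landmarks coincident")
  cs
}

#' Reflect and relabel a configuration under object symmetry
#'
#' Mirrors the configuration across the symmetry axis (the x-axis by
#' convention) and exchanges the left/right landmark labels; midline
#' landmarks keep their labels. This map is an involution, and a perfectly
#' symmetric configuration is its fixed point.
#'
#' @param config `K x 2` matrix in the axis-aligned frame.
#' @param scheme a [pairing_scheme()].
#' @return `K x 2` matrix.
#' @export
reflect_relabel <- function(config, scheme) {
  if (nrow(config) != scheme$K)
    stop("structure error: configuration has ", nrow(config),
         " landmarks but scheme expects ", scheme$K)
  out <- config
  out[, 2L] <- -out[, 2L]
  perm <- seq_len(scheme$K)
  perm[scheme$pairs[, 1L]] <- scheme$pairs[, 2L]
  perm[scheme$pairs[, 2L]] <- scheme$pairs[, 1L]
  out[perm, , drop = FALSE]
}

## Optimal rotation (det +1) of X onto Y, both centered: X %*% rot
opa_rotation <- function(X, Y) {
  M <- crossprod(X, Y)
  sv <- svd(M)
  d <- sign(det(sv$u) * det(sv$v))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

## Rotation matrix sending the midline best-fit direction to the x-axis,
## with the axis_reference landmark at positive x.
axis_rotation <- function(mean_config, scheme) {
  mid <- mean_config[scheme$midline, , drop = FALSE]
  ctr <- colMeans(mid)
  v <- eigen(crossprod(sweep(mid, 2L, ctr)), symmetric = TRUE)$vectors[, 1L]
  rot <- cbind(v, c(-v[2L], v[1L]))          # v -> e1, proper rotation
  if ((mean_config %*% rot)[scheme$axis_reference, 1L] < 0)
    rot <- -rot                              # 180 degrees, still proper
  rot
}

#' Generalized Procrustes alignment
#'
#' Iterative superimposition: each configuration is centered, scaled to unit
#' centroid size and rotated (no reflection) to the current consensus; the
#' consensus is the normalized mean of the aligned copies. Iteration stops
#' when the consensus moves by less than `tol` (root summed squared
#' difference) or after `max_iter` iterations. With
#' `include_reflections = TRUE` every configuration's reflected-relabeled
#' copy joins the alignment set (object symmetry), and the consensus is
#' rotated to the symmetry-axis convention.
#'
#' @param dataset a [landmark_dataset()] (or a `n x K x 2` array).
#' @param scheme a [pairing_scheme()]; required when `include_reflections`.
#' @param include_reflections logical; add reflect-relabel copies.
#' @param tol convergence tolerance on the consensus (default 1e-10).
#' @param max_iter iteration cap (default 100).
#' @return list with `aligned` (`m x K x 2` array: originals first, then, if
#'   requested, their reflected copies), `grand_mean` (`K x 2`, unit centroid
#'   size) and `meta` (iterations, final delta, objective trace, convention).
#' @export
gpa_align <- function(dataset, scheme = NULL, include_reflections = FALSE,
                      tol = 1e-10, max_iter = 100L) {
  coords <- if (inherits(dataset, "landmark_dataset")) dataset$coords
            else dataset
  n <- dim(coords)[1L]; K <- dim(coords)[2L]
  if (n < 2L) stop("need at least 2 configurations for alignment")
  if (include_reflections && is.null(scheme))
    stop("include_reflections requires a pairing scheme")
  configs <- lapply(seq_len(n), function(i) {
    X <- coords[i, , , drop = TRUE]
    X <- scale(X, scale = FALSE)
    X / centroid_size(X)
  })
  if (include_reflections)
    configs <- c(configs, lapply(configs, reflect_relabel, scheme = scheme))
  m <- length(configs)
  ref <- configs[[1L]]
  objective <- numeric(0)
  delta <- Inf; it <- 0L
  while (it < max_iter && delta > tol) {
    it <- it + 1L
    aligned <- lapply(configs, function(X) X %*% opa_rotation(X, ref))
    newref <- Reduce(`+`, aligned) / m
    newref <- newref / sqrt(sum(newref^2))    # centered already; unit size
    objective <- c(objective,
                   sum(vapply(aligned, function(A) sum((A - newref)^2), 0)))
    delta <- sqrt(sum((newref - ref)^2))
    ref <- newref
  }
  if (delta > tol)
    warning("GPA did not converge in ", max_iter,
            " iterations (final delta ", format(delta), ")")
  aligned <- lapply(configs, function(X) X %*% opa_rotation(X, ref))
  if (!is.null(scheme)) {
    rot <- axis_rotation(ref, scheme)
    ref <- ref %*% rot
    aligned <- lapply(aligned, function(A) A %*% rot)
    if (include_reflections) {
      ## force the consensus to exact bilateral symmetry (it is symmetric up
      ## to the convergence tolerance because the alignment set is closed
      ## under reflect_relabel) and refresh the alignment against it, so the
      ## downstream decomposition is exact to machine precision
      ref <- (ref + reflect_relabel(ref, scheme)) / 2
      ref <- ref / sqrt(sum(ref^2))
      aligned <- lapply(aligned, function(A) A %*% opa_rotation(A, ref))
    }
  }
  out <- array(NA_real_, c(m, K, 2L))
  for (i in seq_len(m)) out[i, , ] <- aligned[[i]]
  list(aligned = out, grand_mean = ref,
       meta = list(iterations = it, delta = delta, objective = objective,
                   axis = if (is.null(scheme)) NA_character_ else "x",
                   include_reflections = include_reflections))
}

#' Decompose shape variation into symmetric and asymmetric components
#'
#' Joint generalized Procrustes alignment of all digitized copies together
#' with their reflected-relabeled counterparts (2 x n x r configurations in
#' total), followed by the object-symmetry decomposition in the axis-aligned
#' frame: for each aligned copy `A`, the symmetric component is
#' `(A + RR(A)) / 2` and the asymmetric component `(A - RR(A)) / 2`, where
#' `RR` is [reflect_relabel()]. The identities `A = sym + asym` and
#' `RR(A) = sym - asym` hold exactly; the symmetric component is an exact
#' fixed point of `RR` and the asymmetric component flips sign under it.
#'
#' @param dataset a [landmark_dataset()] (>= 1 replicate per specimen).
#' @param scheme a [pairing_scheme()].
#' @param ... passed to [gpa_align()].
#' @return Object of class `shape_components`: record-level arrays `aligned`,
#'   `sym`, `asym` (`n_rec x K x 2`, dataset record order) plus replicate
#'   metadata; specimen-level (replicate-averaged) arrays `sym_spec`,
#'   `asym_spec`, vectors `specimen_id`, `sex`, `centroid_size` (original
#'   units); `grand_mean`; `alignment_meta`; the `scheme`.
#' @export
decompose_symmetry <- function(dataset, scheme, ...) {
  stopifnot(inherits(dataset, "landmark_dataset"),
            inherits(scheme, "pairing_scheme"))
  if (dataset$K != scheme$K)
    stop("structure error: dataset K=", dataset$K, " does not match scheme K=",
         scheme$K)
  fit <- gpa_align(dataset, scheme, include_reflections = TRUE, ...)
  n_rec <- dataset$n
  A <- fit$aligned[seq_len(n_rec), , , drop = FALSE]
  sym <- asym <- array(NA_real_, dim(A))
  for (i in seq_len(n_rec)) {
    ai <- A[i, , , drop = TRUE]
    ri <- reflect_relabel(ai, scheme)
    sym[i, , ] <- (ai + ri) / 2
    asym[i, , ] <- (ai - ri) / 2
  }
  ## centroid sizes in original units (scale applied when digitized with one)
  cs_rec <- vapply(seq_len(n_rec), function(i) {
    s <- dataset$scale[i]
    centroid_size(dataset$coords[i, , , drop = TRUE]) * ifelse(is.na(s), 1, s)
  }, 0)
  ids <- unique(dataset$specimen_id)
  n_spec <- length(ids)
  K <- dataset$K
  sym_spec <- asym_spec <- array(0, c(n_spec, K, 2L))
  cs_spec <- numeric(n_spec)
  sex_spec <- factor(rep(NA_character_, n_spec), levels = c("F", "M"))
  for (s in seq_len(n_spec)) {
    w <- which(dataset$specimen_id == ids[s])
    sym_spec[s, , ] <- apply(sym[w, , , drop = FALSE], c(2L, 3L), mean)
    asym_spec[s, , ] <- apply(asym[w, , , drop = FALSE], c(2L, 3L), mean)
    cs_spec[s] <- mean(cs_rec[w])
    sex_spec[s] <- dataset$sex[w[1L]]
  }
  structure(list(aligned = A, sym = sym, asym = asym,
                 record_specimen = dataset$specimen_id,
                 record_replicate = dataset$replicate,
                 record_sex = dataset$sex,
                 specimen_id = ids, sex = sex_spec,
                 sym_spec = sym_spec, asym_spec = asym_spec,
                 centroid_size = cs_spec,
                 grand_mean = fit$grand_mean,
                 alignment_meta = fit$meta, scheme = scheme),
            class = "shape_components")
}

#' @export
print.shape_components <- function(x, ...) {
  cat("shape_components:", length(x$specimen_id), "specimens,",
      dim(x$aligned)[1L], "aligned records,", dim(x$aligned)[2L],
      "landmarks\n  GPA:", x$alignment_meta$iterations,
      "iterations, delta", format(x$alignment_meta$delta, digits = 3), "\n")
  invisible(x)
}

#' Flatten a record array to a coordinate matrix
#'
#' @param a `n x K x 2` array.
#' @return `n x 2K` matrix with columns `lm1_x, lm1_y, ..., lmK_x, lmK_y`.
#' @export
flatten_configs <- function(a) {
  n <- dim(a)[1L]; K <- dim(a)[2L]
  m <- matrix(aperm(a, c(1L, 3L, 2L)), n, 2L * K)
  colnames(m) <- as.vector(rbind(paste0("lm", seq_len(K), "_x"),
                                 paste0("lm", seq_len(K), "_y")))
  m
}

#' Columns of the flattened matrix belonging to given landmarks
#' @param landmarks integer landmark indices.
#' @return integer column indices into a [flatten_configs()] matrix.
#' @export
landmark_columns <- function(landmarks) {
  as.vector(rbind(2L * landmarks - 1L, 2L * landmarks))
}

#' Regress shape on centroid size and return residuals
#'
#' Multivariate least squares of the flattened symmetric-component
#' coordinates on centroid size (intercept included). The residuals have
#' zero column means and zero sample covariance with size; they are the
#' input for the modularity analyses.
#'
#' @param components a [decompose_symmetry()] result.
#' @param log_size regress on `log(centroid size)` instead of raw size.
#' @return `n x 2K` residual matrix (one row per specimen).
#' @export
regress_out_size <- function(components, log_size = FALSE) {
  stopifnot(inherits(components, "shape_components"))
  Y <- flatten_configs(components$sym_spec)
  if (nrow(Y) < 3L) stop("need at least 3 specimens for the size regression")
  x <- components$centroid_size
  if (log_size) x <- log(x)
  if (stats::var(x) < .Machine$double.eps) {
    warning("constant centroid size: regression skipped, returning centered coordinates")
    return(scale(Y, scale = FALSE))
  }
  res <- stats::lm.fit(cbind(1, x), Y)$residuals
  dimnames(res) <- dimnames(Y)
  res
}
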