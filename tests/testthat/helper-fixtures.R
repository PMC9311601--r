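# Shared fixtures: a small 12-landmark bilateral scheme (5 pairs + 2 midline)
# and its developmental-style split, plus convenience wrappers.

small_scheme <- function() {
  pairing_scheme(cbind(left = c(8, 9, 10, 11, 12), right = c(2, 3, 4, 5, 6)),
                 midline = c(1, 7), axis_reference = 1)
}

small_modules <- function() {
  module_partition("dev", c("a", "a", "a", "b", "b", "b", "b",
                            "a", "a", "b", "b", "b"))
}

zero_da <- function(K = 12L) list(F = matrix(0, K, 2L), M = matrix(0, K, 2L))

small_params <- function(...) {
  synthetic_params(small_scheme(), modules = small_modules(), ...)
}

## shipped full-size configuration, loaded once
shipped_config <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_analysis_config()
    cache
  }
})

## independent brute-force covariance ratio: literal double loop over
## coordinate-column index pairs
brute_cr <- function(X, assignment) {
  V <- stats::cov(X)
  mods <- unique(assignment)
  cols <- lapply(mods, function(m) {
    lm <- which(assignment == m)
    sort(c(2L * lm - 1L, 2L * lm))
  })
  sw <- numeric(length(mods))
  for (m in seq_along(mods)) {
    s <- 0
    for (i in cols[[m]]) for (j in cols[[m]]) if (i != j) s <- s + V[i, j]^2
    sw[m] <- s
  }
  crs <- c()
  for (m1 in seq_along(mods)) for (m2 in seq_along(mods)) if (m1 < m2) {
    sb <- 0
    for (i in cols[[m1]]) for (j in cols[[m2]]) sb <- sb + V[i, j]^2
    crs <- c(crs, sqrt(sb / sqrt(sw[m1] * sw[m2])))
  }
  mean(crs)
}
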