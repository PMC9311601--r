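test_that("Procrustes ANOVA decomposes sums of squares exactly with the
           design degrees of freedom", {
  p <- small_params(n_female = 6, n_male = 6, seed = 21)
  comp <- decompose_symmetry(generate_dataset(p)$dataset, small_scheme())
  a <- procrustes_anova(comp, permutations = 49, seed = 1)
  N <- 2 * dim(comp$aligned)[1]           # copies = 2 * n * r
  expect_equal(sum(a$df), N - 1L)
  expect_equal(a$df[1:3], c(1L, 1L, 1L))
  expect_equal(sum(a$SS), attr(a, "total_SS"), tolerance = 1e-8)
  expect_equal(a$MS, a$SS / a$df, tolerance = 1e-12)
  expect_true(all(a$p_rrpp[1:3] > 0 & a$p_rrpp[1:3] <= 1))
})

test_that("zero injected asymmetry gives exactly zero DA and FA sums of
           squares", {
  p0 <- small_params(n_female = 5, n_male = 5, sigma_fa = 0, sigma_digit = 0,
                     da_vector_by_sex = zero_da(), seed = 8)
  comp0 <- decompose_symmetry(generate_dataset(p0)$dataset, small_scheme())
  a0 <- procrustes_anova(comp0, permutations = 19, seed = 2)
  expect_lt(a0$SS[2], 1e-12)   # directional asymmetry
  expect_lt(a0$SS[3], 1e-12)   # fluctuating asymmetry
})

test_that("increasing directional asymmetry increases the DA F-statistic", {
  sch <- small_scheme()
  Fs <- vapply(c(0.003, 0.008, 0.02), function(m) {
    da <- matrix(0, 12, 2); da[sch$pairs[, 1], 2] <- m
    p <- small_params(n_female = 15, n_male = 15,
                      da_vector_by_sex = list(F = da, M = da), seed = 3)
    comp <- decompose_symmetry(generate_dataset(p)$dataset, sch)
    procrustes_anova(comp, permutations = 19, seed = 4)$F[2]
  }, 0)
  expect_true(all(diff(Fs) > 0))
})

test_that("single-replicate data and missing sex labels are rejected", {
  p <- small_params(n_female = 4, n_male = 4, replicates = 1, seed = 5)
  comp <- decompose_symmetry(generate_dataset(p)$dataset, small_scheme())
  expect_error(procrustes_anova(comp, permutations = 9), "replicate")
  p2 <- small_params(n_female = 4, n_male = 4, seed = 5)
  comp2 <- decompose_symmetry(generate_dataset(p2)$dataset, small_scheme())
  expect_error(procrustes_anova(comp2, sex = rep(NA, 16), permutations = 9),
               "sex")
})

test_that("the triangle-area descriptor follows its defining formula", {
  ## constructed configuration with known areas: A_L = 0.25, A_R = 0.20
  sch <- pairing_scheme(cbind(3, 2), midline = c(1, 4), axis_reference = 1)
  M <- rbind(c(0, 0),          # axis reference
             c(0.8, -0.5),     # right: A_R = 0.8 * 0.5 / 2 = 0.20
             c(1.0, 0.5),      # left:  A_L = 1.0 * 0.5 / 2 = 0.25
             c(-1, 0))
  comp <- structure(list(grand_mean = M,
                         asym_spec = array(0, c(1, 4, 2)),
                         specimen_id = "s1",
                         sex = factor("F", levels = c("F", "M")),
                         scheme = sch),
                    class = "shape_components")
  pr <- lr_asym_profile(comp)
  expect_equal(unname(pr$values[1, 1]), 100 * (0.20 - 0.25) / 0.225,
               tolerance = 1e-10)
  expect_equal(unname(pr$values[1, 1]), -22.2222, tolerance = 1e-4)
})

test_that("profiles vanish for symmetric shapes, are scale-free, and track
           the injected skew direction", {
  sch <- small_scheme()
  p0 <- small_params(n_female = 4, n_male = 4, sigma_fa = 0, sigma_digit = 0,
                     da_vector_by_sex = zero_da(), seed = 12)
  comp0 <- decompose_symmetry(generate_dataset(p0)$dataset, sch)
  expect_lt(max(abs(lr_asym_profile(comp0)$values)), 1e-9)

  ## scale invariance: multiplying all input coordinates leaves the profile
  g <- generate_dataset(small_params(n_female = 6, n_male = 6, seed = 13))
  d10 <- g$dataset; d10$coords <- d10$coords * 10
  pr1 <- lr_asym_profile(decompose_symmetry(g$dataset, sch))
  pr2 <- lr_asym_profile(decompose_symmetry(d10, sch))
  expect_equal(pr1$values, pr2$values, tolerance = 1e-9)

  ## default generator: females skewed left (negative), males right
  gd <- generate_dataset(small_params(n_female = 25, n_male = 25, seed = 14))
  comp <- decompose_symmetry(gd$dataset, sch)
  prF <- lr_asym_profile(subset_components(comp, comp$sex == "F"))
  prM <- lr_asym_profile(subset_components(comp, comp$sex == "M"))
  expect_true(all(prF$summary$mean < 0))
  expect_true(all(prM$summary$mean > 0))
})

test_that("Z-test matches the formula and handles degenerate pairs", {
  pr <- list(values = cbind(p1 = rep(0, 5), p2 = rep(1, 5)),
             pair_labels = c("p1", "p2"),
             summary = data.frame(pair = c("p1", "p2"), mean = c(0, 1),
                                  ci_lo = NA, ci_hi = NA,
                                  z_stat = NA_real_, p_z = NA_real_))
  class(pr) <- "asymmetry_profile"
  z <- ztest_profile(pr)
  expect_equal(z$summary$z_stat[1], 0)
  expect_equal(z$summary$p_z[1], 1)
  expect_equal(z$summary$p_z[2], 0)           # sd 0, mean 1: forced
  expect_true(z$summary$degenerate_z[2])

  set.seed(30)
  v <- rnorm(100, 0.5, 1)
  pr2 <- pr
  pr2$values <- cbind(p1 = v, p2 = v)
  z2 <- ztest_profile(pr2)
  expect_equal(z2$summary$z_stat[1], mean(v) / (sd(v) / 10),
               tolerance = 1e-10)
  expect_equal(z2$summary$p_z[1], 2 * pnorm(-abs(mean(v) / (sd(v) / 10))),
               tolerance = 1e-10)
})

test_that("between-sex profile comparison equals the textbook Welch t", {
  mk <- function(vals) {
    structure(list(values = vals, pair_labels = colnames(vals)),
              class = "asymmetry_profile")
  }
  set.seed(31)
  a <- cbind(p1 = rnorm(30, -1, 0.1)); b <- cbind(p1 = rnorm(30, 1, 0.1))
  out <- compare_profiles_between_sexes(mk(a), mk(b))
  expect_lt(out$p_t, 1e-6)
  ## textbook Welch statistic
  s2a <- var(a[, 1]) / 30; s2b <- var(b[, 1]) / 30
  expect_equal(out$t_stat, (mean(a[, 1]) - mean(b[, 1])) / sqrt(s2a + s2b),
               tolerance = 1e-10)
  ## identical samples: t = 0, p = 1
  same <- compare_profiles_between_sexes(mk(a), mk(a))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_t, 1)
})

test_that("Mantel r equals brute-force correlation of the lower triangles
           and the vegan implementation", {
  sch <- small_scheme(); mp <- small_modules()
  p <- small_params(n_female = 10, n_male = 10, seed = 40)
  comp <- decompose_symmetry(generate_dataset(p)$dataset, sch)
  mm <- mantel_modules(comp, mp, iterations = 20, permutations = 99,
                       seed = 7)
  X <- flatten_configs(comp$asym_spec)
  c1 <- landmark_columns(which(mp$assignment == "a"))
  c2 <- landmark_columns(which(mp$assignment == "b"))
  D1 <- as.matrix(dist(X[, c1])); D2 <- as.matrix(dist(X[, c2]))
  expect_equal(mm$r_point,
               cor(D1[lower.tri(D1)], D2[lower.tri(D2)]),
               tolerance = 1e-10)
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(dist(X[, c1]), dist(X[, c2]), permutations = 99)
  expect_equal(mm$r_point, unname(vg$statistic), tolerance = 1e-10)
  expect_equal(length(mm$r_distribution), 20L)
})

test_that("a module duplicating the other's coordinates gives r = 1 and
           partitions with more than two modules are refused", {
  sch <- small_scheme(); mp <- small_modules()
  p <- small_params(n_female = 5, n_male = 5, seed = 41)
  comp <- decompose_symmetry(generate_dataset(p)$dataset, sch)
  ## copy module a's asymmetric coordinates onto module b landmarks
  la <- which(mp$assignment == "a"); lb <- which(mp$assignment == "b")
  comp$asym_spec[, lb[seq_along(la)], ] <- comp$asym_spec[, la, ]
  comp$asym_spec[, lb[-seq_along(la)], ] <- 0   # identical distance matrices
  mm <- mantel_modules(comp, mp, iterations = 10, permutations = 19, seed = 1)
  expect_equal(mm$r_point, 1, tolerance = 1e-9)
  mp3 <- module_partition("three", rep(c("a", "b", "c"), 4))
  expect_error(mantel_modules(comp, mp3, iterations = 10), "pairwise")
})

test_that("Mantel r grows with the generator's module-asymmetry coupling", {
  sch <- small_scheme(); mp <- small_modules()
  rs <- vapply(c(0, 0.5, 0.9), function(cc) {
    mean(vapply(1:5, function(s) {
      p <- small_params(n_female = 30, n_male = 30, asym_module_corr = cc,
                        seed = s * 11)
      comp <- decompose_symmetry(generate_dataset(p)$dataset, sch)
      mantel_modules(comp, mp, iterations = 10, permutations = 19,
                     seed = s)$r_point
    }, 0))
  }, 0)
  expect_true(all(diff(rs) > 0))
})

test_that("paired comparison of Mantel distributions matches direct
           computation and flags degenerate differences", {
  r1 <- structure(list(r_distribution = seq(0.1, 0.6, length.out = 50),
                       iterations = 50L), class = "mantel_result")
  set.seed(5)
  r2 <- r1; r2$r_distribution <- r1$r_distribution + rnorm(50, 0.05, 0.02)
  out <- compare_mantel_distributions(r1, r2)
  d <- r1$r_distribution - r2$r_distribution
  expect_equal(out$t_stat, mean(d) / (sd(d) / sqrt(50)), tolerance = 1e-10)
  ## identical distributions
  same <- compare_mantel_distributions(r1, r1)
  expect_equal(same$t_stat, 0); expect_equal(same$p, 1)
  ## constant offset: zero-variance differences, flagged degenerate
  r3 <- r1; r3$r_distribution <- r1$r_distribution + 0.2
  off <- compare_mantel_distributions(r1, r3)
  expect_true(off$degenerate)
  expect_equal(off$p, 0)
  r4 <- r1; r4$iterations <- 49L
  expect_error(compare_mantel_distributions(r1, r4), "iteration")
})
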