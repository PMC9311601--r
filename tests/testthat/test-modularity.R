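test_that("CR hits its closed-form anchors on constructed covariances", {
  ## two modules of 2 landmarks each: 8 coordinate columns
  assign <- c("a", "a", "b", "b")
  ## zero between-module covariance: CR = 0
  V <- diag(8)
  V[1, 2] <- V[2, 1] <- 0.5   # within a (off-diagonal)
  V[5, 6] <- V[6, 5] <- 0.5   # within b
  expect_equal(symmod:::cr_from_cov(V, assign), 0)
  ## all off-diagonal covariances equal: the sums reduce to entry counts,
  ## sqrt(n_between / sqrt(n_w1 * n_w2)) = sqrt(16 / 12) for 4+4 columns
  V1 <- matrix(0.3, 8, 8); diag(V1) <- 1
  expect_equal(symmod:::cr_from_cov(V1, assign), sqrt(16 / 12),
               tolerance = 1e-12)
  ## a module with no within covariance is undefined
  V2 <- diag(8); V2[1, 5] <- V2[5, 1] <- 0.2
  expect_error(symmod:::cr_from_cov(V2, assign), "undefined CR")
})

test_that("CR equals a brute-force index-pair summation and is invariant to
           landmark order and module labels", {
  set.seed(50)
  mp <- small_modules()
  for (s in 1:3) {
    X <- generate_shape_matrix(25, mp, 0.5, 0.2, seed = s)
    expect_equal(covariance_ratio(X, mp), brute_cr(X, mp$assignment),
                 tolerance = 1e-10)
  }
  ## three modules: mean of pairwise CRs, still matching brute force
  mp3 <- module_partition("three", rep(c("a", "b", "c"), each = 4))
  X3 <- generate_shape_matrix(30, mp3, 0.4, 0.1, seed = 9)
  expect_equal(covariance_ratio(X3, mp3), brute_cr(X3, mp3$assignment),
               tolerance = 1e-10)
  ## reordering landmarks together with their assignment leaves CR unchanged
  X <- generate_shape_matrix(25, mp, 0.5, 0.2, seed = 4)
  perm <- sample(12)
  Xp <- X[, landmark_columns(perm)]
  mpp <- module_partition("p", mp$assignment[perm])
  expect_equal(covariance_ratio(Xp, mpp), covariance_ratio(X, mp),
               tolerance = 1e-12)
  ## swapping module labels is immaterial
  swapped <- module_partition("s", ifelse(mp$assignment == "a", "b", "a"))
  expect_equal(covariance_ratio(X, swapped), covariance_ratio(X, mp),
               tolerance = 1e-12)
})

test_that("CR effect size is negative under modular structure and its null
           permutation reproduces a fresh CR evaluation", {
  mp <- small_modules()
  X <- generate_shape_matrix(100, mp, 0.7, 0.05, seed = 60)
  sig <- cr_effect_size(X, mp, permutations = 199, seed = 3)
  expect_lt(sig$z_cr_mean, 0)
  expect_equal(length(sig$z_cr_distribution), 199L)
  expect_lt(sig$ci95[1], sig$ci95[2])
  ## the permutation null is by definition CR of a relabeled partition
  set.seed(77)
  shuffled <- symmod:::shuffle_assignment(mp$assignment)
  expect_equal(symmod:::cr_from_cov(cov(X), shuffled),
               covariance_ratio(X, module_partition("shuf", shuffled)),
               tolerance = 1e-12)
})

test_that("expected CR decreases as between-module correlation drops", {
  mp <- small_modules()
  df <- do.call(rbind, lapply(c(0.4, 0.2, 0.05), function(rb) {
    data.frame(rb = rb, cr = vapply(1:30, function(s)
      covariance_ratio(generate_shape_matrix(60, mp, 0.5, rb,
                                             seed = s + round(rb * 1e4)),
                       mp), 0))
  }))
  expect_gt(cor(df$rb, df$cr, method = "spearman"), 0)
  m <- tapply(df$cr, df$rb, mean)
  expect_true(all(diff(m[order(as.numeric(names(m)))]) > 0))
})

test_that("modular-signal comparison handles self-comparison, separation,
           and compact letter grouping", {
  mk <- function(nm, z) structure(list(partition_name = nm,
                                       z_cr_distribution = z,
                                       permutations = length(z)),
                                  class = "modular_signal")
  base <- seq(-0.5, 0.5, length.out = 101)
  self <- compare_modular_signal(list(mk("m1", base), mk("m2", base)))
  expect_equal(self$pairs$delta, 0)
  expect_equal(self$pairs$p_overlap, 1)
  ## separation by ~10 SDs forces a tiny overlap p
  far <- compare_modular_signal(list(mk("m1", base), mk("m2", base + 3)))
  expect_lt(far$pairs$p_overlap, 0.001)
  ## chain where only (1,2) and (2,3) are similar: groups a{1,2}, b{2,3}
  cmp <- compare_modular_signal(list(mk("m1", base), mk("m2", base + 0.4),
                                     mk("m3", base + 0.8)))
  expect_lt(cmp$pairs$p_overlap[cmp$pairs$model_1 == "m1" &
                                cmp$pairs$model_2 == "m3"], 0.05)
  expect_equal(unname(cmp$grouping), c("a", "ab", "b"))
  bad <- mk("m4", base[1:51])
  expect_error(compare_modular_signal(list(mk("m1", base), bad)),
               "permutation counts")
})

test_that("modularity test rejects modular structure, accepts its absence,
           and is stable across seed streams", {
  mp <- small_modules()
  Xmod <- generate_shape_matrix(100, mp, 0.7, 0.05, seed = 70)
  t1 <- modularity_test(Xmod, mp, rounds = 499, seed = 1)
  expect_lt(t1$p, 0.05)
  expect_equal(length(t1$cr_arbitrary_distribution), 499L)
  set.seed(71)
  Xnull <- matrix(rnorm(60 * 24), 60, 24)
  t0 <- modularity_test(Xnull, mp, rounds = 499, seed = 2)
  expect_gt(t0$p, 0.05)
  ## iid arbitrary draws: the p estimate is exchangeable across seed streams
  t1b <- modularity_test(Xmod, mp, rounds = 999, seed = 5)
  t1c <- modularity_test(Xmod, mp, rounds = 999, seed = 6)
  expect_lt(abs(t1b$p - t1c$p), 2 / sqrt(999))
  expect_warning(modularity_test(Xnull, mp, rounds = 50, seed = 1),
                 "unstable")
})

test_that("covariation-variant enumeration expands and deduplicates as the
           block structure dictates", {
  uni <- module_partition("uniform", rep("u", 12))
  two <- small_modules()
  three <- module_partition("three", rep(c("a", "b", "c"), each = 4))
  expect_equal(length(enumerate_covariation_variants(list(uni))), 1L)
  ## 2 modules: separate-between collapses onto single-between
  expect_equal(length(enumerate_covariation_variants(list(two))), 2L)
  expect_equal(length(enumerate_covariation_variants(list(two),
                                                     dedup = FALSE)), 4L)
  ## >= 3 modules: all four within/between combinations are distinct
  expect_equal(length(enumerate_covariation_variants(list(three))), 4L)
  ## the shipped seven hypotheses expand to 19 variants
  cfg <- shipped_config()
  reg <- enumerate_covariation_variants(unname(cfg$partitions))
  expect_equal(length(reg), 19L)
  expect_equal(sort(unique(vapply(reg, `[[`, "", "base"))),
               sort(names(cfg$partitions)))
})

test_that("likelihood fit matches a literal pair-by-pair summation and
           respects model nesting", {
  mp6 <- module_partition("m6", c("a", "a", "a", "b", "b", "b"))
  uni6 <- module_partition("u6", rep("u", 6))
  X <- generate_shape_matrix(40, mp6, 0.6, 0.1, seed = 80)
  reg <- enumerate_covariation_variants(list(uni6, mp6))
  fit <- emmli_fit(X, reg, n_eff = 40)
  ## independent oracle: literal summation of normal log-densities
  phi <- congruence_matrix(X)
  prs <- combn(6, 2)
  r <- phi[cbind(prs[1, ], prs[2, ])]
  z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  sdz <- 1 / sqrt(40 - 3)
  for (m in reg) {
    want <- 0
    for (g in unique(m$pair_group)) {
      zg <- z[m$pair_group == g]
      want <- want + sum(dnorm(zg, mean(zg), sdz, log = TRUE))
    }
    got <- fit$models$logL[fit$models$name == m$name]
    expect_equal(got, want, tolerance = 1e-8)
  }
  ## saturated grouping (each pair its own parameter) bounds every logL
  sat_logL <- sum(dnorm(z, z, sdz, log = TRUE))
  expect_true(all(fit$models$logL <= sat_logL + 1e-10))
  ## weights normalize and the best model has delta 0
  expect_equal(sum(fit$models$posterior_weight), 1, tolerance = 1e-8)
  expect_equal(min(fit$models$delta_aicc), 0)
  expect_error(emmli_fit(X, reg, n_eff = 3), "n_eff")
})

test_that("model selection recovers the generating correlation structure", {
  mp <- small_modules()
  uni <- module_partition("uniform", rep("u", 12))
  reg <- enumerate_covariation_variants(list(uni, mp))
  wins_mod <- vapply(1:20, function(s)
    emmli_fit(generate_shape_matrix(100, mp, 0.6, 0.1, seed = s),
              reg)$models$base[1] == "dev", TRUE)
  expect_gte(mean(wins_mod), 0.9)
  wins_uni <- vapply(1:20, function(s)
    emmli_fit(generate_shape_matrix(100, uni, 0.3, 0.3, seed = s + 500),
              reg)$models$base[1] == "uniform", TRUE)
  expect_gte(mean(wins_uni), 0.85)
})

test_that("Z_CR is approximately standard under the no-modularity null", {
  mp <- small_modules()
  z <- vapply(1:30, function(s) {
    set.seed(s)
    X <- matrix(rnorm(40 * 24), 40, 24)
    cr_effect_size(X, mp, permutations = 199, seed = s + 900)$z_cr_mean
  }, 0)
  expect_gte(mean(abs(z) <= 1.96), 0.85)
})
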