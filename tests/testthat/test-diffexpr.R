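test_that("exact test equals brute-force conditional enumeration", {
  set.seed(21)
  for (disp in c(0, 0.05, 0.2, 1.0)) {
    for (rep in 1:25) {
      n_a <- sample(2:4, 1)
      n_b <- sample(2:4, 1)
      a <- rpois(n_a, sample(3:25, 1))
      b <- rpois(n_b, sample(3:25, 1))
      p <- nb_exact_test(a, b, dispersion = disp)
      p_oracle <- oracle_nb_exact_p(sum(a), sum(a) + sum(b), n_a, n_b, disp)
      expect_equal(p, p_oracle, tolerance = 1e-9)
    }
  }
})

test_that("dispersion-zero limit equals the exact binomial test", {
  set.seed(22)
  for (rep in 1:40) {
    n_a <- sample(2:5, 1)
    n_b <- sample(2:5, 1)
    a <- rpois(n_a, 20)
    b <- rpois(n_b, 20)
    p <- nb_exact_test(a, b, dispersion = 0)
    p_binom <- stats::binom.test(sum(a), sum(a) + sum(b),
                                 n_a / (n_a + n_b))$p.value
    expect_equal(p, p_binom, tolerance = 1e-9)
  }
})

test_that("exact test degenerate and invariance properties hold", {
  # identical group sums: the observed outcome is the most probable one
  expect_equal(nb_exact_test(c(5, 5), c(5, 5), 0.1), 1.0)
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), 0.1), 1.0)
  expect_error(nb_exact_test(c(1, 2), c(3, 4), -0.1), "non-negative")

  # label-swap invariance
  set.seed(23)
  for (rep in 1:20) {
    a <- rpois(3, 15)
    b <- rpois(3, 25)
    expect_equal(nb_exact_test(a, b, 0.1), nb_exact_test(b, a, 0.1),
                 tolerance = 1e-12)
  }
})

test_that("library-size equalization makes the test scale-aware", {
  # same RPM signal, very different libraries: must not be called different
  a <- c(100, 110)
  b <- c(10, 11)
  p_unscaled <- nb_exact_test(a, b, 0)
  p_scaled <- nb_exact_test(a, b, 0, lib_sizes = c(1e6, 1e6, 1e5, 1e5))
  expect_lt(p_unscaled, 0.01)
  expect_gt(p_scaled, 0.5)
})

test_that("common dispersion estimation recovers simulation truth", {
  set.seed(31)
  libs <- rep(1e6, 8)
  mu <- rlnorm(300, log(60), 1)
  pois <- sapply(1:8, function(j) rpois(300, mu))
  rownames(pois) <- paste0("f", 1:300)
  est0 <- estimate_dispersion(pois, 1:4, 5:8, lib_sizes = libs)
  expect_lt(est0$common, 0.05)

  nb <- sapply(1:8, function(j) rnbinom(500, mu = rep(mu, 2)[1:500] + 20,
                                        size = 1 / 0.2))
  rownames(nb) <- paste0("f", 1:500)
  est <- estimate_dispersion(nb, 1:4, 5:8, lib_sizes = libs)
  expect_gt(est$common, 0.1)
  expect_lt(est$common, 0.3)
})

test_that("tagwise dispersion shrinks toward common and degenerates cleanly", {
  set.seed(32)
  m <- matrix(rnbinom(400, mu = 50, size = 10), 100, 4,
              dimnames = list(paste0("f", 1:100), paste0("s", 1:4)))
  full <- estimate_dispersion(m, 1:2, 3:4, shrinkage_weight = 1)
  expect_equal(unname(full$tagwise), rep(full$common, 100))

  single <- estimate_dispersion(m[1, , drop = FALSE], 1:2, 3:4)
  expect_equal(unname(single$tagwise), single$common)

  expect_error(estimate_dispersion(matrix(0, 5, 4,
    dimnames = list(paste0("f", 1:5), paste0("s", 1:4))), 1:2, 3:4),
    "all-zero")
})

test_that("BH adjustment matches the closed-form step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(33)
  p <- runif(200)^2
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
})

test_that("DEM calling uses a strict FDR threshold and has power at 1.5-fold", {
  de <- data.frame(feature_id = c("a", "b"), logFC = c(1, -1),
                   log_mean = 1, p = c(0.01, 0.012),
                   fdr = c(0.049, 0.05), direction = c("up", "ns"))
  dems <- call_dems(de, alpha = 0.05)
  expect_equal(dems$dems$feature_id, "a")
  expect_equal(dems$n_up, 1)
  expect_equal(dems$n_down, 0)

  # power simulation: 20 true features among 80 nulls, dispersion 0.05,
  # 3 reps; expected calling rates frozen from the simulation itself
  # (biological replication bounds per-feature power at small fold changes)
  set.seed(34)
  run_power <- function(fc) {
    replicate(20, {
      n_null <- 80
      mu <- rlnorm(n_null + 20, log(80), 0.8)
      f <- c(rep(1, n_null), rep(fc, 20))
      m <- cbind(sapply(1:3, function(j) rnbinom(100, mu = mu * f, size = 20)),
                 sapply(1:3, function(j) rnbinom(100, mu = mu, size = 20)))
      dimnames(m) <- list(paste0("f", 1:100), paste0("s", 1:6))
      cm <- count_matrix(m, data.frame(sample_id = paste0("s", 1:6),
                                       genotype_id = rep(c("e", "c"), each = 3)))
      nm <- rpm_normalize(cm)
      de <- de_exact(cm, nm, paste0("s", 1:3), paste0("s", 4:6),
                     dispersion = 0.05)
      sum(de$fdr[81:100] < 0.05)
    })
  }
  called_25 <- run_power(2.5)
  called_15 <- run_power(1.5)
  expect_gte(mean(called_25), 10)          # strong effects are found
  expect_gt(mean(called_25), mean(called_15))  # power grows with effect size
})

test_that("ratio t-test matches the pooled closed form and its degenerate cases", {
  expect_equal(ratio_t_test(c(0.1, 0.2), c(0.1, 0.2))$p, 1.0)

  a <- c(0.1, 0.2, 0.15)
  b <- c(0.5, 0.6, 0.55)
  res <- ratio_t_test(a, b)
  # pooled two-sample t with 4 df, computed from first principles
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  expect_lt(res$p, 0.01)

  expect_error(ratio_t_test(0.1, c(0.2, 0.3)), "at least 2")
})

test_that("ratio t-test holds its nominal type-I error under the null", {
  set.seed(35)
  p <- replicate(2000, ratio_t_test(rnorm(3), rnorm(3))$p)
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("exact-test p-values are calibrated under a simulated NB null", {
  set.seed(36)
  mu <- rlnorm(400, log(60), 1)
  m <- sapply(1:6, function(j) rnbinom(400, mu = mu, size = 1 / 0.1))
  dimnames(m) <- list(paste0("f", 1:400), paste0("s", 1:6))
  cm <- count_matrix(m, data.frame(sample_id = paste0("s", 1:6),
                                   genotype_id = rep(c("e", "c"), each = 3)))
  nm <- rpm_normalize(cm)
  de <- de_exact(cm, nm, paste0("s", 1:3), paste0("s", 4:6),
                 dispersion = "common")
  rate <- mean(de$p < 0.05)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
  # no-signal data: BH should call (essentially) nothing
  expect_lte(sum(de$fdr < 0.05), 1)
})

test_that("power increases with fold change and replicate number", {
  set.seed(37)
  power_at <- function(fc, reps) {
    mean(replicate(40, {
      a <- rnbinom(reps, mu = 60 * fc, size = 20)
      b <- rnbinom(reps, mu = 60, size = 20)
      nb_exact_test(a, b, 0.05) < 0.05
    }))
  }
  expect_lte(power_at(1.5, 3), power_at(2.5, 3) + 0.05)
  expect_lte(power_at(1.5, 3), power_at(1.5, 6) + 0.05)
})
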