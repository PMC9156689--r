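small_cfg <- function(...) {
  sim_config(n_lines = 2, n_mirnas = 110, n_genes = 40, replicates = 3,
             lib_size_mean = 1e6, seed = 101, ...)
}

test_that("simulated designs carry the full genotype nomenclature", {
  cfg <- small_cfg()
  d <- simulate_design(cfg)
  genos <- d$design$info$genotype_id
  expect_true(all(c("2D", "h1D", "1X", "2X", "3X", "4X", "0B", "1B") %in% genos))
  for (l in d$segments$line_id) {
    expect_true(all(paste0(l, "_", c("1D", "3D", "4D", "h2D")) %in% genos))
    # every segment holds at least one cis locus
    expect_gt(sum(d$loci$line_id == l & d$loci$chrom ==
                    d$segments$chrom[d$segments$line_id == l], na.rm = TRUE), 0)
  }
  expect_equal(segment_dosage(d$design, paste0(d$segments$line_id[1], "_3D"),
                              d$segments$line_id[1]), 3)
  expect_equal(segment_dosage(d$design, "2D", d$segments$line_id[1]), 2)
  expect_equal(segment_dosage(d$design, paste0(d$segments$line_id[1], "_h2D"),
                              d$segments$line_id[2]), 1)
})

test_that("the same seed reproduces the simulation byte for byte", {
  cfg <- small_cfg()
  d1 <- simulate_design(cfg); s1 <- simulate_counts(cfg, d1)
  d2 <- simulate_design(cfg); s2 <- simulate_counts(cfg, d2)
  expect_identical(d1, d2)
  expect_identical(s1$cm$counts, s2$cm$counts)
  t1 <- simulate_targets(cfg, d1, s1)
  t2 <- simulate_targets(cfg, d2, s2)
  expect_identical(t1$gene_cm$counts, t2$gene_cm$counts)
  expect_identical(t1$interactions, t2$interactions)

  dir1 <- tempfile(); dir2 <- tempfile()
  p1 <- write_simulation(d1, s1, dir1, t1)
  p2 <- write_simulation(d2, s2, dir2, t2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("archetype means follow their closed forms in every genotype", {
  mu <- 10
  delta <- log(1.5)
  # diploid background, segment dosages 1..4
  for (d in c(1, 3, 4)) {
    expect_equal(archetype_mean("direct_dosage", mu, d, 2), mu * d / 2)
    expect_equal(archetype_mean("negative_dosage", mu, d, 2), mu * 2 / d)
    expect_equal(archetype_mean("compensation", mu, d, 2), mu)
    expect_equal(archetype_mean("trans_inverse", mu, d, 2), mu * 2 / d)
    expect_equal(archetype_mean("trans_positive", mu, d, 2), mu * d / 2)
    expect_equal(archetype_mean("increased", mu, d, 2, delta), mu * exp(delta))
    expect_equal(archetype_mean("decreased", mu, d, 2, delta), mu * exp(-delta))
  }
  # haploid background disomy: direct expectation 2.0, inverse 0.5
  expect_equal(archetype_mean("direct_dosage", mu, 2, 1), mu * 2)
  expect_equal(archetype_mean("trans_inverse", mu, 2, 1), mu / 2)
  # euploid dosage leaves every archetype at baseline
  for (a in c("direct_dosage", "negative_dosage", "increased", "mixed")) {
    expect_equal(archetype_mean(a, mu, 2, 2), mu)
  }
  # B-responsive features scale with B count only
  expect_equal(archetype_mean("b_responsive", mu, NA, 2, b_count = 1,
                              b_effect = 3), 30)
  expect_equal(archetype_mean("b_responsive", mu, NA, 2, b_count = 0,
                              b_effect = 3), mu)
  expect_error(archetype_mean("nonsense", mu, 1, 2), "unknown archetype")
})

test_that("expected RPM is ploidy-invariant (transcriptome-size cancellation)", {
  cfg <- small_cfg()
  d <- simulate_design(cfg)
  s <- simulate_counts(cfg, d)
  for (g in c("1X", "3X", "4X")) {
    expect_equal(s$expected_rpm[, g], s$expected_rpm[, "2X"])
  }
})

test_that("simulated counts match their NB targets at large n", {
  set.seed(71)
  mu <- 40
  phi <- 0.1
  x <- rnbinom(10000, mu = mu, size = 1 / phi)
  se_mean <- sqrt(mu * (1 + phi * mu) / 10000)
  expect_lt(abs(mean(x) - mu), 4 * se_mean)
  phi_hat <- (var(x) - mean(x)) / mean(x)^2
  expect_lt(abs(phi_hat - phi), 0.03)

  # the generator's sampling path reproduces expected RPM on average
  cfg <- small_cfg()
  d <- simulate_design(cfg)
  s <- simulate_counts(cfg, d)
  nm <- rpm_normalize(s$cm, library_sizes = s$lib_sizes)
  gm <- genotype_means(nm)
  hi <- s$truth$baseline_rpm > 5      # abundant features: stable ratio
  obs <- gm[hi, "2D"]
  expect_gt(cor(obs, s$expected_rpm[hi, "2D"]), 0.98)
})

test_that("fold-change expectations surface in a low-noise simulation", {
  cfg <- sim_config(n_lines = 1, n_mirnas = 400, replicates = 4,
                    dispersion = 0.005, lib_size_mean = 5e6,
                    baseline_meanlog = log(50), baseline_sdlog = 0.5,
                    seed = 77)
  d <- simulate_design(cfg)
  s <- simulate_counts(cfg, d)
  nm <- rpm_normalize(s$cm, library_sizes = s$lib_sizes)
  gm <- genotype_means(nm)
  l <- d$segments$line_id[1]
  fc_3d <- gm[, paste0(l, "_3D")] / gm[, "2D"]
  direct <- s$truth$feature_id[s$truth$archetype == "direct_dosage"]
  comp <- s$truth$feature_id[s$truth$archetype == "compensation"]
  inv <- s$truth$feature_id[s$truth$archetype == "trans_inverse" &
                              s$truth$line_id == l]
  expect_equal(median(fc_3d[direct]), 1.5, tolerance = 0.05)
  expect_equal(median(fc_3d[comp]), 1.0, tolerance = 0.05)
  expect_equal(median(fc_3d[inv]), 2 / 3, tolerance = 0.05)
})

test_that("written simulations round-trip through the package readers", {
  cfg <- small_cfg()
  d <- simulate_design(cfg)
  s <- simulate_counts(cfg, d)
  tg <- simulate_targets(cfg, d, s)
  dir <- tempfile()
  paths <- write_simulation(d, s, dir, tg)

  cm <- read_count_matrix(paths["counts"], paths["samples"])
  expect_equal(cm$counts, s$cm$counts)
  expect_equal(cm$samples$genotype_id, d$samples$genotype_id)

  seg <- read_segments(paths["segments"])
  expect_equal(seg, d$segments)

  loci <- read_loci(paths["loci"], dialect = "bed")
  expect_equal(loci$start, d$loci$start)
  expect_equal(loci$end, d$loci$end)
  expect_equal(loci$feature_id, d$loci$feature_id)

  gd <- read_genotype_design(paths["genotypes"])
  for (g in gd$info$genotype_id) {
    for (l in d$segments$line_id) {
      expect_equal(segment_dosage(gd, g, l), segment_dosage(d$design, g, l))
    }
  }

  ia <- load_interactions(paths["interactions"])
  expect_false(any(!ia$src_prediction & !ia$src_degradome))
  expect_gt(nrow(ia), 0)
})

test_that("cis locus placement induces a positive count-size correlation", {
  cfg <- sim_config(n_lines = 6, n_mirnas = 900, seed = 88)
  d <- simulate_design(cfg)
  labels <- partition_all_lines(
    d$loci[, c("feature_id", "chrom", "start", "end", "feature_class")],
    d$segments)
  res <- cis_count_size_correlation(labels, d$segments)
  expect_gt(res$R, 0.5)
})

test_that("misconfigured archetype proportions are rejected", {
  expect_error(sim_config(archetype_mix = c(direct_dosage = 0.6,
                                            trans_inverse = 0.3)),
               "sum to 1")
  expect_error(sim_config(archetype_mix = c(wibble = 1)), "unknown archetype")
  expect_error(sim_config(dispersion = -1), ">= 0")
})
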