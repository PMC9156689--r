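test_that("expected ratios reproduce every printed reference line", {
  # (d_e, d_c) -> (inverse, direct) after 2-decimal rounding
  cases <- list(
    list(pair = c(1, 2), inverse = 2.00, direct = 0.50),   # 1D/2D, 1X/2X
    list(pair = c(3, 2), inverse = 0.67, direct = 1.50),   # 3D/2D, 3X/2X
    list(pair = c(4, 2), inverse = 0.50, direct = 2.00),   # 4D/2D, 4X/2X
    list(pair = c(4, 3), inverse = 0.75, direct = 1.33),   # 4D/3D, 4X/3X
    list(pair = c(2, 1), inverse = 0.50, direct = 2.00)    # h2D/h1D
  )
  for (cs in cases) {
    er <- expected_ratios(cs$pair)
    expect_equal(er$inverse_label, cs$inverse)
    expect_equal(er$direct_label, cs$direct)
    expect_equal(er$direct_fc * er$inverse_fc, 1.0, tolerance = 1e-12)
    expect_equal(er$no_change, 1.0)
  }
  expect_warning(er <- expected_ratios(c(2, 2)), "degenerate")
  expect_equal(er$direct_fc, 1.0)
})

test_that("per-feature ratios use group means and guard zero controls", {
  m <- rbind(f1 = c(10, 10, 5, 5), f2 = c(5, 5, 0, 0))
  colnames(m) <- paste0("s", 1:4)
  nm <- tiny_rpm(m)
  nm$rpm <- m
  rt <- compute_ratios(nm, c("s1", "s2"), c("s3", "s4"))
  expect_equal(rt$fc[rt$feature_id == "f1"], 2.0)
  expect_true(is.na(rt$fc[rt$feature_id == "f2"]))
  expect_false(rt$defined[rt$feature_id == "f2"])
})

test_that("median trans ratio summarizes defined trans fold changes only", {
  rt <- data.frame(feature_id = c("a", "b", "c", "d", "e"),
                   fc = c(0.5, 0.67, 2.0, NA, 9),
                   defined = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(median_trans_ratio(rt, c("a", "b", "c", "d")), 0.67)
  expect_equal(median_trans_ratio(rt, c("a")), 0.5)
  expect_error(median_trans_ratio(rt, "d"), "no defined")
})

test_that("1-D k-means separates well-separated groups deterministically", {
  x <- c(2.0, 0.9, 1.9, 1.0, 2.1, 1.1)
  km1 <- kmeans_1d(x, 2)
  km2 <- kmeans_1d(x, 2)
  expect_identical(km1, km2)
  expect_equal(km1$cluster, c(2, 1, 2, 1, 2, 1))
  expect_equal(km1$centers, c(1.0, 2.0))
  expect_error(kmeans_1d(rep(1, 5), 2), "degenerate")
  expect_error(kmeans_1d(c(1, 2), 3), "at least k")
})

test_that("1-D k-means attains the exhaustive-search optimum", {
  set.seed(51)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    x <- round(rnorm(n), 3)
    if (length(unique(x)) < 2) next
    km <- kmeans_1d(x, 2)
    expect_equal(km$tot_withinss, oracle_kmeans2_sse(x), tolerance = 1e-9)
  }
})

test_that("1-D k-means never loses to random-restart Lloyd iterations", {
  set.seed(52)
  for (rep in 1:50) {
    x <- rnorm(sample(5:40, 1))
    km <- kmeans_1d(x, 2)
    lloyd <- stats::kmeans(x, centers = 2, nstart = 25)
    expect_lte(km$tot_withinss, lloyd$tot.withinss + 1e-9)
  }
})

test_that("B-control exclusion removes flagged features and nothing else", {
  feats <- paste0("m", 1:5)
  expect_equal(apply_control_exclusion(feats, c("m1", "m2")),
               c("m3", "m4", "m5"))
  expect_equal(apply_control_exclusion(feats, character(0)), feats)
})

make_ev <- function(...) {
  # rows: list(comparison, series, d_e, d_c, fdr, logfc)
  rows <- list(...)
  if (!length(rows)) {
    return(data.frame(comparison = character(), series = character(),
                      d_e = numeric(), d_c = numeric(), fdr = numeric(),
                      logfc = numeric(), fc = numeric()))
  }
  do.call(rbind, lapply(rows, function(r) {
    data.frame(comparison = r[[1]], series = r[[2]], d_e = r[[3]],
               d_c = r[[4]], fdr = r[[5]], logfc = r[[6]], fc = 2^r[[6]],
               stringsAsFactors = FALSE)
  }))
}

test_that("cis classifier follows the decision table on canonical patterns", {
  # cis RPM ~ {1D: 5, 2D: 10, 3D: 15}, both comparisons significant
  ev <- make_ev(list("1D/2D", "diploid_aneuploid", 1, 2, 0.001, log2(0.5)),
                list("3D/2D", "diploid_aneuploid", 3, 2, 0.001, log2(1.5)))
  expect_equal(classify_cis_response(ev)$label, "direct_dosage")

  # all significant changes oppose dosage
  ev <- make_ev(list("1D/2D", "diploid_aneuploid", 1, 2, 0.001, 1),
                list("3D/2D", "diploid_aneuploid", 3, 2, 0.001, -0.6))
  expect_equal(classify_cis_response(ev)$label, "negative_dosage")

  # up in both a dosage-decreased and a dosage-increased comparison
  ev <- make_ev(list("1D/2D", "diploid_aneuploid", 1, 2, 0.01, 0.8),
                list("3D/2D", "diploid_aneuploid", 3, 2, 0.01, 0.7))
  expect_equal(classify_cis_response(ev)$label, "increased")
  ev$logfc <- -ev$logfc
  ev$fc <- 2^ev$logfc
  expect_equal(classify_cis_response(ev)$label, "decreased")

  # nothing significant, every FC inside the band -> compensation
  ev <- make_ev(list("1D/2D", "diploid_aneuploid", 1, 2, 0.4, log2(0.9)),
                list("3D/2D", "diploid_aneuploid", 3, 2, 0.7, log2(1.1)))
  expect_equal(classify_cis_response(ev)$label, "compensation")
  ev$fc[1] <- 0.6  # band violated
  expect_equal(classify_cis_response(ev)$label, "unclassified")

  # conflicting significant calls across the two backgrounds -> mixed
  ev <- make_ev(list("3D/2D", "diploid_aneuploid", 3, 2, 0.01, 0.8),
                list("h2D/h1D", "haploid_aneuploid", 2, 1, 0.01, -0.8))
  expect_equal(classify_cis_response(ev)$label, "mixed")

  # same conflict confined to one series is not called mixed
  ev <- make_ev(list("3D/2D", "diploid_aneuploid", 3, 2, 0.01, 0.8),
                list("4D/2D", "diploid_aneuploid", 4, 2, 0.01, -0.8))
  expect_equal(classify_cis_response(ev)$label, "unclassified")

  expect_equal(classify_cis_response(make_ev())$label, "unclassified")
})

test_that("trans classifier matches the hand-enumerated 27-case truth table", {
  # comparisons: 1D/2D (dosage down), 3D/2D (up), h2D/h1D (up)
  # frozen expectation for every direction pattern (up/down/ns)^3
  expected <- c(
    "up.up.up" = "increased",      "up.up.down" = "mixed",
    "up.up.ns" = "increased",      "up.down.up" = "mixed",
    "up.down.down" = "inverse_trans", "up.down.ns" = "inverse_trans",
    "up.ns.up" = "increased",      "up.ns.down" = "inverse_trans",
    "up.ns.ns" = "unclassified",   "down.up.up" = "positive_trans",
    "down.up.down" = "mixed",      "down.up.ns" = "positive_trans",
    "down.down.up" = "mixed",      "down.down.down" = "decreased",
    "down.down.ns" = "decreased",  "down.ns.up" = "positive_trans",
    "down.ns.down" = "decreased",  "down.ns.ns" = "unclassified",
    "ns.up.up" = "positive_trans", "ns.up.down" = "mixed",
    "ns.up.ns" = "unclassified",   "ns.down.up" = "mixed",
    "ns.down.down" = "inverse_trans", "ns.down.ns" = "unclassified",
    "ns.ns.up" = "unclassified",   "ns.ns.down" = "unclassified",
    "ns.ns.ns" = "unclassified"
  )
  dirs <- c("up", "down", "ns")
  to_row <- function(dir, cmp, series, d_e, d_c) {
    fdr <- if (dir == "ns") 0.5 else 0.01
    lfc <- switch(dir, up = 0.9, down = -0.9, ns = 0.05)
    list(cmp, series, d_e, d_c, fdr, lfc)
  }
  for (s1 in dirs) for (s2 in dirs) for (s3 in dirs) {
    ev <- make_ev(to_row(s1, "1D/2D", "diploid_aneuploid", 1, 2),
                  to_row(s2, "3D/2D", "diploid_aneuploid", 3, 2),
                  to_row(s3, "h2D/h1D", "haploid_aneuploid", 2, 1))
    key <- paste(s1, s2, s3, sep = ".")
    expect_equal(classify_trans_response(ev)$label, unname(expected[key]),
                 label = paste("pattern", key))
  }
})

test_that("classifier output is invariant to evidence row order", {
  ev <- make_ev(list("1D/2D", "diploid_aneuploid", 1, 2, 0.01, 0.9),
                list("3D/2D", "diploid_aneuploid", 3, 2, 0.01, -0.9),
                list("h2D/h1D", "haploid_aneuploid", 2, 1, 0.01, -0.9))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(classify_trans_response(ev[perm, ])$label,
                 classify_trans_response(ev)$label)
    expect_equal(classify_cis_response(ev[perm, ])$label,
                 classify_cis_response(ev)$label)
  }
})
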