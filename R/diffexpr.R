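# Library-size equalization: linearly scale each sample's counts to the
# geometric mean library size (rounded). Keeps the conditional exact test
# and the dispersion estimator on a common footing.
equalize_libraries <- function(counts, lib_sizes) {
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  ref <- round(exp(mean(log(lib_sizes))))
  sweep_fac <- ref / lib_sizes
  if (is.matrix(counts)) {
    sweep(counts, 2, sweep_fac, "*")
  } else {
    counts * sweep_fac
  }
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Log conditional mass of the group-A total given the grand total, for
# nA and nB replicates per group with common per-replicate NB mean after
# library equalization. Free of the mean: depends only on the dispersion
# through r = 1/dispersion (beta-binomial-like weights); the dispersion-0
# limit is binomial(t, nA/(nA+nB)).
cond_log_mass <- function(a, t, n_a, n_b, dispersion) {
  if (dispersion == 0) {
    return(stats::dbinom(a, t, n_a / (n_a + n_b), log = TRUE))
  }
  r <- 1 / dispersion
  ra <- n_a * r
  rb <- n_b * r
  lw <- lgamma(a + ra) - lgamma(a + 1) - lgamma(ra) +
    lgamma(t - a + rb) - lgamma(t - a + 1) - lgamma(rb)
  lw - logsumexp(lgamma(0:t + ra) - lgamma(0:t + 1) - lgamma(ra) +
                   lgamma(t - 0:t + rb) - lgamma(t - 0:t + 1) - lgamma(rb))
}

#' Negative-binomial exact test for a two-group count comparison
#'
#' Conditional exact test of differential abundance between two replicate
#' groups. Counts are linearly scaled to a common (geometric-mean) library
#' size, summed per group, and the two-sided p-value is computed by summing,
#' over the conditional distribution of the group-A total given the grand
#' total, the probabilities of all outcomes at most as probable as the one
#' observed (minimum-likelihood two-sidedness). In the dispersion-to-zero
#' limit the conditional distribution is binomial in the group-A share of
#' replicates.
#'
#' @param counts_a,counts_b Non-negative count vectors (one entry per
#'   replicate).
#' @param dispersion Negative-binomial dispersion (>= 0; 0 = Poisson).
#' @param lib_sizes Optional library sizes for `c(counts_a, counts_b)`;
#'   default: equal libraries (no rescaling).
#' @return Two-sided p-value.
#' @export
nb_exact_test <- function(counts_a, counts_b, dispersion, lib_sizes = NULL) {
  if (length(dispersion) != 1 || is.na(dispersion) || dispersion < 0) {
    stop("dispersion must be a single non-negative number")
  }
  if (!length(counts_a) || !length(counts_b)) stop("both groups must be non-empty")
  if (any(c(counts_a, counts_b) < 0)) stop("counts must be non-negative")
  n_a <- length(counts_a)
  n_b <- length(counts_b)
  if (!is.null(lib_sizes)) {
    if (length(lib_sizes) != n_a + n_b) {
      stop("lib_sizes must have one entry per replicate")
    }
    eq <- equalize_libraries(c(counts_a, counts_b), lib_sizes)
    counts_a <- eq[seq_len(n_a)]
    counts_b <- eq[n_a + seq_len(n_b)]
  }
  s_a <- round(sum(counts_a))
  t <- s_a + round(sum(counts_b))
  if (t == 0) return(1)
  lp <- cond_log_mass(0:t, t, n_a, n_b, dispersion)
  obs <- lp[s_a + 1]
  p <- sum(exp(lp[lp <= obs + 1e-8]))
  min(1, p)
}

#' Estimate negative-binomial dispersion from a two-group count matrix
#'
#' Common dispersion by maximizing the summed conditional log-likelihood of
#' within-group counts given group totals (on library-size-equalized
#' pseudo-counts), a quantile-free qCML analogue. Tagwise values are
#' empirical-Bayes shrinkage of per-feature method-of-moments estimates
#' toward the common value.
#'
#' @param counts Count matrix (features x samples) or a `count_matrix`.
#' @param group_a,group_b Column names or indices of the two groups.
#' @param lib_sizes Optional library sizes (default column sums).
#' @param shrinkage_weight Weight on the common value in the tagwise
#'   shrinkage, in `[0, 1]` (default 0.7; 1 collapses tagwise to common).
#' @return list with `common`, `tagwise` (named per feature),
#'   `shrinkage_weight`.
#' @export
estimate_dispersion <- function(counts, group_a, group_b, lib_sizes = NULL,
                                shrinkage_weight = 0.7) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (shrinkage_weight < 0 || shrinkage_weight > 1) {
    stop("shrinkage_weight must be in [0, 1]")
  }
  y <- counts[, c(group_a, group_b), drop = FALSE]
  if (all(y == 0)) stop("all-zero count matrix: dispersion is unidentifiable")
  if (is.null(lib_sizes)) lib_sizes <- colSums(y)
  n_a <- length(group_a)
  if (max(n_a, ncol(y) - n_a) < 2) {
    stop("need >= 2 replicates in at least one group")
  }
  pseudo <- equalize_libraries(y, lib_sizes)
  ga <- seq_len(n_a)
  gb <- n_a + seq_len(ncol(y) - n_a)

  group_cll <- function(m, r) {
    # conditional log-likelihood of each row given its total, for n iid
    # NB(size r) replicates; constant terms in r omitted
    n <- ncol(m)
    if (n < 2) return(0)
    tot <- rowSums(m)
    sum(lgamma(m + r)) - nrow(m) * n * lgamma(r) +
      sum(lgamma(n * r) - lgamma(tot + n * r))
  }
  keep <- rowSums(pseudo) > 0
  pa <- pseudo[keep, ga, drop = FALSE]
  pb <- pseudo[keep, gb, drop = FALSE]
  nll <- function(log_phi) {
    r <- exp(-log_phi)
    -(group_cll(pa, r) + group_cll(pb, r))
  }
  opt <- stats::optimize(nll, interval = c(log(1e-6), log(20)))
  common <- exp(opt$minimum)
  if (nll(log(1e-6)) <= opt$objective) common <- 1e-6

  # per-feature moment estimate from pooled within-group mean/variance
  mom_one <- function(m) {
    mu <- rowMeans(m)
    v <- apply(m, 1, stats::var)
    phi <- (v - mu) / pmax(mu, 1e-8)^2
    pmax(phi, 0)
  }
  phi_mom <- rep(0, nrow(counts))
  w_a <- if (length(ga) >= 2) 1 else 0
  w_b <- if (length(gb) >= 2) 1 else 0
  pa_all <- equalize_libraries(y, lib_sizes)
  mom <- (w_a * (if (w_a) mom_one(pa_all[, ga, drop = FALSE]) else 0) +
            w_b * (if (w_b) mom_one(pa_all[, gb, drop = FALSE]) else 0)) /
    (w_a + w_b)
  # with a single feature there is nothing to shrink between: collapse to common
  tagwise <- if (nrow(counts) == 1) common
             else shrinkage_weight * common + (1 - shrinkage_weight) * mom
  names(tagwise) <- rownames(counts)
  list(common = common, tagwise = tagwise,
       shrinkage_weight = shrinkage_weight)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment with monotonicity enforcement, mapped back to the
#' input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NAs propagate).
#' @return Vector of FDR values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Exact-test differential expression for one comparison
#'
#' Runs the NB exact test per kept feature on raw counts (library sizes from
#' the normalized matrix), with log2 fold change computed from RPM group
#' means and BH-adjusted p-values over the tested set.
#'
#' @param cm A `count_matrix` of raw counts.
#' @param nm The matching `rpm_matrix`.
#' @param exp_samples,ctl_samples Sample ids of the experimental and control
#'   replicates.
#' @param kept Features to test (from [filter_low_expression()]); default all.
#' @param dispersion `"tagwise"` (default; per-feature shrinkage estimates,
#'   robust to dispersion outliers), `"common"`, or a fixed numeric value.
#' @param alpha Significance level for the `direction` column (default 0.05).
#' @param shrinkage_weight Passed to [estimate_dispersion()].
#' @return data.frame with `feature_id`, `logFC`, `log_mean`, `p`, `fdr`,
#'   `direction` (`up`/`down`/`ns`).
#' @export
de_exact <- function(cm, nm, exp_samples, ctl_samples, kept = NULL,
                     dispersion = "tagwise", alpha = 0.05,
                     shrinkage_weight = 0.7) {
  stopifnot(inherits(cm, "count_matrix"), inherits(nm, "rpm_matrix"))
  if (is.null(kept)) kept <- rownames(cm$counts)
  kept <- intersect(rownames(cm$counts), kept)
  if (!length(kept)) {
    return(data.frame(feature_id = character(), logFC = numeric(),
                      log_mean = numeric(), p = numeric(), fdr = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  libs <- nm$library_sizes[c(exp_samples, ctl_samples)]
  y <- cm$counts[kept, c(exp_samples, ctl_samples), drop = FALSE]
  if (is.character(dispersion)) {
    mode <- match.arg(dispersion, c("common", "tagwise"))
    est <- estimate_dispersion(y, exp_samples, ctl_samples, lib_sizes = libs,
                               shrinkage_weight = shrinkage_weight)
    phi <- if (mode == "common") rep(est$common, length(kept)) else est$tagwise[kept]
  } else {
    phi <- rep(dispersion, length(kept))
  }
  n_e <- length(exp_samples)
  p <- vapply(seq_along(kept), function(i) {
    nb_exact_test(y[i, seq_len(n_e)], y[i, n_e + seq_len(length(ctl_samples))],
                  dispersion = phi[i], lib_sizes = libs)
  }, numeric(1))
  mu_e <- rowMeans(nm$rpm[kept, exp_samples, drop = FALSE])
  mu_c <- rowMeans(nm$rpm[kept, ctl_samples, drop = FALSE])
  fdr <- bh_adjust(p)
  logfc <- log2(mu_e / mu_c)
  data.frame(
    feature_id = kept,
    logFC = logfc,
    log_mean = log2((mu_e + mu_c) / 2),
    p = p,
    fdr = fdr,
    direction = ifelse(fdr < alpha & logfc > 0, "up",
                       ifelse(fdr < alpha & logfc < 0, "down", "ns")),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Call differentially expressed features at an FDR threshold
#'
#' Features with FDR strictly below `alpha` are differentially expressed
#' (DEMs for miRNA input).
#'
#' @param de A data.frame from [de_exact()] or [de_ratio_t()].
#' @param alpha FDR threshold (default 0.05, strict inequality).
#' @return list with `dems` (subset data.frame), `n_up`, `n_down`.
#' @export
call_dems <- function(de, alpha = 0.05) {
  hit <- !is.na(de$fdr) & de$fdr < alpha
  dems <- de[hit, , drop = FALSE]
  list(dems = dems,
       n_up = sum(dems$logFC > 0),
       n_down = sum(dems$logFC < 0))
}

#' Two-sample t-test on per-replicate log2 ratios
#'
#' Two-sided Student's t-test (pooled variance) of whether the mean log2
#' ratio of one genotype over a shared control differs between two
#' genotypes. Used where the exact test is inappropriate, e.g. comparing
#' tetraploids (4X/2X ratios) against triploids (3X/2X ratios) of different
#' genetic background.
#'
#' @param log2_ratios_a,log2_ratios_b Per-replicate log2 ratios (>= 2 each).
#' @return list with `t`, `p`, `df`.
#' @export
ratio_t_test <- function(log2_ratios_a, log2_ratios_b) {
  if (length(log2_ratios_a) < 2 || length(log2_ratios_b) < 2) {
    stop("each group needs at least 2 log2 ratios")
  }
  if (stats::var(log2_ratios_a) == 0 && stats::var(log2_ratios_b) == 0) {
    if (mean(log2_ratios_a) == mean(log2_ratios_b)) {
      return(list(t = 0, p = 1,
                  df = length(log2_ratios_a) + length(log2_ratios_b) - 2))
    }
    return(list(t = Inf * sign(mean(log2_ratios_a) - mean(log2_ratios_b)),
                p = 0, df = length(log2_ratios_a) + length(log2_ratios_b) - 2))
  }
  tt <- stats::t.test(log2_ratios_a, log2_ratios_b, var.equal = TRUE,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Ratio t-test differential expression for one comparison
#'
#' Per feature, forms per-replicate log2 ratios of each experimental group's
#' RPM to the shared control group mean, runs [ratio_t_test()], and adjusts
#' p-values with BH. The reported fold change compares group A to group B.
#'
#' @param nm An `rpm_matrix`.
#' @param samples_a,samples_b Replicates of the two experimental genotypes.
#' @param ctl_samples Replicates of the shared control genotype.
#' @param kept Features to test (default all).
#' @param alpha Significance level for `direction`.
#' @return data.frame shaped like [de_exact()] output.
#' @export
de_ratio_t <- function(nm, samples_a, samples_b, ctl_samples, kept = NULL,
                       alpha = 0.05) {
  stopifnot(inherits(nm, "rpm_matrix"))
  if (is.null(kept)) kept <- rownames(nm$rpm)
  kept <- intersect(rownames(nm$rpm), kept)
  ctl_mean <- rowMeans(nm$rpm[kept, ctl_samples, drop = FALSE])
  ra <- nm$rpm[kept, samples_a, drop = FALSE]
  rb <- nm$rpm[kept, samples_b, drop = FALSE]
  res <- lapply(seq_along(kept), function(i) {
    if (ctl_mean[i] <= 0 || any(ra[i, ] <= 0) || any(rb[i, ] <= 0)) {
      return(c(p = NA_real_))
    }
    la <- log2(ra[i, ] / ctl_mean[i])
    lb <- log2(rb[i, ] / ctl_mean[i])
    c(p = ratio_t_test(la, lb)$p)
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  mu_a <- rowMeans(ra)
  mu_b <- rowMeans(rb)
  fdr <- bh_adjust(p)
  logfc <- log2(mu_a / mu_b)
  data.frame(
    feature_id = kept,
    logFC = logfc,
    log_mean = log2((mu_a + mu_b) / 2),
    p = p,
    fdr = fdr,
    direction = ifelse(!is.na(fdr) & fdr < alpha & logfc > 0, "up",
                       ifelse(!is.na(fdr) & fdr < alpha & logfc < 0,
                              "down", "ns")),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
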