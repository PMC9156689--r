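#' Construct a comparison specification
#'
#' Describes one experimental-vs-control contrast of a dosage series, e.g.
#' monosomy vs diploid control ("1D/2D") of a given translocation line,
#' disomy vs haploid control ("h2D/h1D"), a ploidy contrast ("3X/2X"), or
#' the B-chromosome control pair ("1B/0B").
#'
#' @param name Comparison name, conventionally "exp/ctl".
#' @param experimental,control Genotype ids of the two groups.
#' @param dosage_pair Integer pair `c(d_e, d_c)`: the cis-segment (or
#'   whole-genome) dosage of experimental and control genotypes.
#' @param series One of `"diploid_aneuploid"`, `"haploid_aneuploid"`,
#'   `"ploidy"`, `"b_control"`.
#' @param line_id Translocation line (required for aneuploid series).
#' @return An object of class `comparison_spec`.
#' @export
comparison_spec <- function(name, experimental, control, dosage_pair,
                            series = c("diploid_aneuploid", "haploid_aneuploid",
                                       "ploidy", "b_control"),
                            line_id = NULL) {
  series <- match.arg(series)
  if (series %in% c("diploid_aneuploid", "haploid_aneuploid") &&
      is.null(line_id)) {
    stop("line_id is required for aneuploid series comparisons")
  }
  if (series != "b_control" && any(dosage_pair < 1)) {
    stop("dosages must be >= 1 for aneuploid/ploidy comparisons")
  }
  structure(list(name = name, experimental = experimental, control = control,
                 dosage_pair = dosage_pair, series = series,
                 line_id = line_id),
            class = "comparison_spec")
}

#' Analytically expected fold-change ratios for a comparison
#'
#' For a dosage pair (d_e, d_c), a pure gene-dosage (direct) effect predicts
#' FC = d_e/d_c and an inverse dosage effect predicts FC = d_c/d_e; no
#' change is 1.0. The rounded values reproduce the reference lines used in
#' the scatter plots: e.g. inverse 2.0 and direct 0.5 for 1D/2D, inverse
#' 0.67 and direct 1.5 for 3D/2D, inverse 0.75 and direct 1.33 for 4D/3D.
#'
#' @param cmp A `comparison_spec`, or an integer pair `c(d_e, d_c)`.
#' @return list with `direct_fc`, `inverse_fc`, `no_change` (exact values)
#'   and `direct_label`, `inverse_label` (2-decimal presentation values).
#' @export
expected_ratios <- function(cmp) {
  pair <- if (inherits(cmp, "comparison_spec")) cmp$dosage_pair else cmp
  if (length(pair) != 2 || any(pair < 1)) stop("need a dosage pair (d_e, d_c) >= 1")
  d_e <- pair[1]
  d_c <- pair[2]
  if (d_e == d_c) {
    warning("degenerate comparison: equal dosages, both expected ratios 1.0")
  }
  direct <- d_e / d_c
  inverse <- d_c / d_e
  list(direct_fc = direct, inverse_fc = inverse, no_change = 1,
       direct_label = round(direct, 2), inverse_label = round(inverse, 2))
}

#' Per-feature fold changes for one comparison
#'
#' FC = mean RPM(experimental) / mean RPM(control), on replicate-averaged
#' normalized counts. Features with a zero control mean are marked
#' undefined and are excluded from median computations downstream.
#'
#' @param nm An `rpm_matrix`.
#' @param exp_samples,ctl_samples Replicate sample ids of the two groups.
#' @param kept Features passing the expression filter (default all).
#' @return data.frame with `feature_id`, `fc`, `defined`.
#' @export
compute_ratios <- function(nm, exp_samples, ctl_samples, kept = NULL) {
  stopifnot(inherits(nm, "rpm_matrix"))
  if (is.null(kept)) kept <- rownames(nm$rpm)
  kept <- intersect(rownames(nm$rpm), kept)
  if (!length(kept)) {
    return(data.frame(feature_id = character(), fc = numeric(),
                      defined = logical(), stringsAsFactors = FALSE))
  }
  mu_e <- rowMeans(nm$rpm[kept, exp_samples, drop = FALSE])
  mu_c <- rowMeans(nm$rpm[kept, ctl_samples, drop = FALSE])
  data.frame(
    feature_id = kept,
    fc = ifelse(mu_c > 0, mu_e / mu_c, NA_real_),
    defined = mu_c > 0,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Median trans ratio of one comparison
#'
#' Median fold change over trans-labeled features with a defined FC; the
#' summary statistic whose position relative to the expected inverse ratio
#' indicates the overall direction of trans modulation.
#'
#' @param ratios data.frame from [compute_ratios()].
#' @param trans_features Character vector of feature ids that are trans for
#'   the comparison's line.
#' @return Median FC (numeric scalar).
#' @export
median_trans_ratio <- function(ratios, trans_features) {
  x <- ratios$fc[ratios$feature_id %in% trans_features & ratios$defined]
  if (!length(x)) stop("no defined trans fold changes")
  stats::median(x)
}

#' Globally optimal one-dimensional k-means
#'
#' Exact 1-D k-means by dynamic programming on the sorted values (optimal
#' clusters are contiguous in sorted order), so the result is deterministic
#' and attains the global minimum of the within-cluster sum of squares --
#' unlike Lloyd iterations from random starts.
#'
#' @param values Numeric vector (length >= k, with >= k distinct values).
#' @param k Number of clusters (default 2).
#' @return list with `cluster` (assignment in input order, clusters numbered
#'   by increasing center), `centers`, `withinss`, `tot_withinss`.
#' @export
kmeans_1d <- function(values, k = 2) {
  n <- length(values)
  if (k < 1) stop("k must be >= 1")
  if (n < k) stop("need at least k values")
  if (length(unique(values)) < k) {
    stop("degenerate input: fewer than k distinct values")
  }
  ord <- order(values)
  x <- values[ord]
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  # sse of x[i..j]
  sse <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)
  split <- matrix(0L, k, n)
  for (j in 1:n) cost[1, j] <- sse(1, j)
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        best <- Inf
        arg <- m - 1L
        for (i in (m - 1):(j - 1)) {
          v <- cost[m - 1, i] + sse(i + 1, j)
          if (v < best) {
            best <- v
            arg <- i
          }
        }
        cost[m, j] <- best
        split[m, j] <- arg
      }
    }
  }
  bounds <- integer(k + 1)
  bounds[k + 1] <- n
  if (k > 1) {
    for (m in k:2) bounds[m] <- split[m, bounds[m + 1]]
  }
  bounds[1] <- 0L
  assign_sorted <- integer(n)
  centers <- numeric(k)
  wss <- numeric(k)
  for (m in 1:k) {
    idx <- (bounds[m] + 1):bounds[m + 1]
    assign_sorted[idx] <- m
    centers[m] <- mean(x[idx])
    wss[m] <- sse(bounds[m] + 1, bounds[m + 1])
  }
  cluster <- integer(n)
  cluster[ord] <- assign_sorted
  list(cluster = cluster, centers = centers, withinss = wss,
       tot_withinss = cost[k, n])
}

#' Remove features responsive to the B-chromosome control
#'
#' Some aneuploid genotypes carry B-chromosome material that their controls
#' lack; features differentially expressed in the 1B/0B control comparison
#' cannot be attributed to A-segment dosage and are excluded from all
#' aneuploidy interpretation.
#'
#' @param features Character vector of feature ids.
#' @param b_control_dems Feature ids called DE in the B-control comparison.
#' @return `features` minus `b_control_dems`, order preserved.
#' @export
apply_control_exclusion <- function(features, b_control_dems) {
  features[!features %in% b_control_dems]
}

# Shared per-feature evidence validation for the classifiers. Evidence has
# one row per available comparison of the feature's line:
# comparison, series, d_e, d_c, fdr, logfc, fc.
check_evidence <- function(evidence) {
  need <- c("comparison", "series", "d_e", "d_c", "fdr", "logfc", "fc")
  if (!all(need %in% names(evidence))) {
    stop("evidence must have columns: ", paste(need, collapse = ", "))
  }
  evidence[!is.na(evidence$fdr), , drop = FALSE]
}

#' Classify the dosage response of a cis feature
#'
#' Decision table over the feature's available comparisons (e.g. 1D/2D,
#' 3D/2D, 4D/2D on the diploid background; h2D/h1D on the haploid
#' background). With S = the comparisons significant at FDR < `alpha`:
#' \itemize{
#'   \item `direct_dosage`: every significant fold change tracks the dosage
#'     direction (sign(logFC) = sign(log(d_e/d_c))), |S| >= 1;
#'   \item `negative_dosage`: every significant fold change opposes dosage;
#'   \item `increased` / `decreased`: all significant changes up (resp.
#'     down), with at least one in a dosage-decreased and one in a
#'     dosage-increased comparison;
#'   \item `compensation`: S empty and every defined FC within the
#'     no-change band `fc_band`;
#'   \item `mixed`: conflicting significant patterns between the diploid and
#'     haploid aneuploid series;
#'   \item `unclassified`: no usable evidence, or S empty with the FC band
#'     violated, or a conflict confined to a single series.
#' }
#'
#' @param evidence data.frame, one row per comparison: `comparison`,
#'   `series`, `d_e`, `d_c`, `fdr`, `logfc`, `fc`.
#' @param alpha FDR threshold (default 0.05).
#' @param fc_band Two-sided no-change band for compensation (default
#'   `c(0.8, 1.25)`).
#' @return list with `label`, `n_significant`, `n_comparisons`.
#' @export
classify_cis_response <- function(evidence, alpha = 0.05,
                                  fc_band = c(0.8, 1.25)) {
  ev <- check_evidence(evidence)
  out <- function(lab, sig_n) list(label = lab, n_significant = sig_n,
                                   n_comparisons = nrow(ev))
  if (!nrow(ev)) return(out("unclassified", 0L))
  sig <- ev[ev$fdr < alpha, , drop = FALSE]
  if (!nrow(sig)) {
    fcs <- ev$fc[!is.na(ev$fc)]
    if (length(fcs) && all(fcs >= fc_band[1] & fcs <= fc_band[2])) {
      return(out("compensation", 0L))
    }
    return(out("unclassified", 0L))
  }
  dose_sign <- sign(log(sig$d_e / sig$d_c))
  fc_sign <- sign(sig$logfc)
  lab <- if (all(fc_sign == dose_sign)) {
    "direct_dosage"
  } else if (all(fc_sign == -dose_sign)) {
    "negative_dosage"
  } else if (all(fc_sign == 1) && any(dose_sign < 0) && any(dose_sign > 0)) {
    "increased"
  } else if (all(fc_sign == -1) && any(dose_sign < 0) && any(dose_sign > 0)) {
    "decreased"
  } else if (length(unique(sig$series)) > 1) {
    "mixed"
  } else {
    "unclassified"
  }
  out(lab, nrow(sig))
}

#' Classify the trans response of a feature for one line
#'
#' Eligibility mirrors the selection applied to trans DEMs: the feature must
#' be significant in all available aneuploidy comparisons of the line except
#' at most `max_missing` (and in at least one). Significant directions that
#' track segment dosage give `positive_trans`; directions that oppose it
#' give `inverse_trans`; same-direction changes in both dosage-decreased and
#' dosage-increased comparisons give `increased`/`decreased`; anything else
#' significant is `mixed`.
#'
#' @param evidence As in [classify_cis_response()].
#' @param alpha FDR threshold (default 0.05).
#' @param max_missing Maximum number of non-significant comparisons allowed
#'   (default 1).
#' @return list with `label`, `n_significant`, `n_comparisons`.
#' @export
classify_trans_response <- function(evidence, alpha = 0.05, max_missing = 1) {
  ev <- check_evidence(evidence)
  out <- function(lab, sig_n) list(label = lab, n_significant = sig_n,
                                   n_comparisons = nrow(ev))
  if (!nrow(ev)) return(out("unclassified", 0L))
  sig <- ev[ev$fdr < alpha, , drop = FALSE]
  if (!nrow(sig) || nrow(ev) - nrow(sig) > max_missing) {
    return(out("unclassified", nrow(sig)))
  }
  dose_sign <- sign(log(sig$d_e / sig$d_c))
  fc_sign <- sign(sig$logfc)
  lab <- if (all(fc_sign == dose_sign)) {
    "positive_trans"
  } else if (all(fc_sign == -dose_sign)) {
    "inverse_trans"
  } else if (all(fc_sign == 1) && any(dose_sign < 0) && any(dose_sign > 0)) {
    "increased"
  } else if (all(fc_sign == -1) && any(dose_sign < 0) && any(dose_sign > 0)) {
    "decreased"
  } else {
    "mixed"
  }
  out(lab, nrow(sig))
}
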