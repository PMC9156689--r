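#' Construct a count matrix with sample-to-genotype mapping
#'
#' @param counts Integer matrix, features x samples, with rownames
#'   (feature ids) and colnames (sample ids).
#' @param samples data.frame with columns `sample_id`, `genotype_id` (and
#'   optionally `replicate`, `include_flag`).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry feature ids as rownames and sample ids as colnames")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!all(c("sample_id", "genotype_id") %in% names(samples))) {
    stop("samples must have columns sample_id and genotype_id")
  }
  miss <- setdiff(colnames(counts), samples$sample_id)
  if (length(miss)) {
    stop("samples with no genotype mapping: ", paste(miss, collapse = ", "))
  }
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples (", length(unique(x$samples$genotype_id)), "genotypes )\n")
  invisible(x)
}

#' Read a count matrix and sample sheet from TSV files
#'
#' The counts TSV has `feature_id` in the first column and one column per
#' sample; the sample sheet maps samples to genotypes. Samples with
#' `include_flag` FALSE (if the column is present) are dropped, mirroring
#' upstream exclusion of low-quality libraries.
#'
#' @param counts_path Path to the counts TSV.
#' @param samples_path Path to the sample sheet TSV (`sample_id`,
#'   `genotype_id`, optional `replicate`, `include_flag`).
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "feature_id") {
    stop("first column of the counts file must be feature_id")
  }
  if (anyDuplicated(tab$feature_id)) stop("duplicate feature_id in counts file")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$feature_id
  storage.mode(m) <- "double"
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  if ("include_flag" %in% names(samples)) {
    keep <- samples$sample_id[as.logical(samples$include_flag)]
    m <- m[, colnames(m) %in% keep, drop = FALSE]
    samples <- samples[samples$sample_id %in% keep, , drop = FALSE]
  }
  count_matrix(m, samples)
}

#' Reads-per-million normalization
#'
#' value = count / library_size * 1e6. Library sizes default to per-sample
#' column sums of the analyzed matrix; externally supplied totals of mapped
#' reads take precedence when given. Note that RPM does not reflect
#' expression per cell: a whole-ploidy series with jointly scaled
#' transcriptomes is RPM-invariant by construction.
#'
#' @param cm A `count_matrix`.
#' @param library_sizes Optional named numeric vector of per-sample library
#'   sizes (total mapped reads).
#' @return An object of class `rpm_matrix`: list with `rpm` (matrix),
#'   `library_sizes`, `samples`.
#' @export
rpm_normalize <- function(cm, library_sizes = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(library_sizes)) {
    library_sizes <- colSums(cm$counts)
  } else {
    if (is.null(names(library_sizes))) {
      stop("library_sizes must be named by sample_id")
    }
    miss <- setdiff(colnames(cm$counts), names(library_sizes))
    if (length(miss)) stop("missing library sizes for: ", paste(miss, collapse = ", "))
    library_sizes <- library_sizes[colnames(cm$counts)]
  }
  if (any(library_sizes <= 0)) {
    stop("zero or negative library size for sample(s): ",
         paste(colnames(cm$counts)[library_sizes <= 0], collapse = ", "))
  }
  rpm <- sweep(cm$counts, 2, library_sizes, "/") * 1e6
  structure(list(rpm = rpm, library_sizes = library_sizes,
                 samples = cm$samples),
            class = "rpm_matrix")
}

#' @export
print.rpm_matrix <- function(x, ...) {
  cat("rpm_matrix:", nrow(x$rpm), "features x", ncol(x$rpm), "samples\n")
  invisible(x)
}

#' Filter lowly expressed features for one comparison
#'
#' A feature is kept iff its mean RPM over the union of experimental and
#' control replicates is at least `threshold` (strictly-below-threshold
#' features are excluded). Filtering is per-comparison: the same feature can
#' be tested in one comparison and excluded in another.
#'
#' @param nm An `rpm_matrix`.
#' @param sample_ids Samples of the comparison (experimental plus control
#'   replicates).
#' @param threshold Mean-RPM threshold; default 0.5.
#' @return Character vector of kept feature ids.
#' @export
filter_low_expression <- function(nm, sample_ids, threshold = 0.5) {
  stopifnot(inherits(nm, "rpm_matrix"))
  miss <- setdiff(sample_ids, colnames(nm$rpm))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  if (length(sample_ids) < 2) stop("a comparison needs at least 2 samples")
  m <- rowMeans(nm$rpm[, sample_ids, drop = FALSE])
  rownames(nm$rpm)[m >= threshold]
}

#' Replicate QC by principal components
#'
#' PCA on centered (not scaled) RPM profiles of the given samples; a sample
#' is flagged as an outlier iff its PC1 or PC2 score deviates from the group
#' mean by more than 2 standard deviations. Flagged samples are reported,
#' never dropped automatically.
#'
#' @param nm An `rpm_matrix`.
#' @param sample_ids Samples of one comparison set (>= 3).
#' @param n_sd Flagging threshold in SD units (default 2).
#' @return list with `scores` (data.frame sample_id, PC1, PC2) and
#'   `outlier_flags` (named logical), or NULL with a warning when fewer than
#'   3 samples are given.
#' @export
replicate_qc_pca <- function(nm, sample_ids, n_sd = 2) {
  stopifnot(inherits(nm, "rpm_matrix"))
  if (length(sample_ids) < 3) {
    warning("fewer than 3 samples; PCA QC skipped")
    return(NULL)
  }
  x <- t(nm$rpm[, sample_ids, drop = FALSE])
  if (all(apply(x, 2, stats::var) == 0)) {
    warning("zero variance across samples; no outliers flaggable")
    scores <- data.frame(sample_id = sample_ids, PC1 = 0, PC2 = 0)
    flags <- stats::setNames(rep(FALSE, length(sample_ids)), sample_ids)
    return(list(scores = scores, outlier_flags = flags))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  sc <- pc$x[, seq_len(k), drop = FALSE]
  if (k < 2) sc <- cbind(sc, PC2 = 0)
  flags <- rep(FALSE, length(sample_ids))
  for (j in 1:2) {
    s <- stats::sd(sc[, j])
    if (s > 0) flags <- flags | abs(sc[, j] - mean(sc[, j])) > n_sd * s
  }
  list(
    scores = data.frame(sample_id = sample_ids,
                        PC1 = unname(sc[, 1]), PC2 = unname(sc[, 2])),
    outlier_flags = stats::setNames(flags, sample_ids)
  )
}

#' Replicate QC by pairwise Pearson correlation
#'
#' Pearson R and two-sided P for every pair of samples; pairs whose
#' expression profiles are not significantly correlated (P >= 0.05) are
#' flagged, as are pairs involving a constant profile (R undefined).
#'
#' @param nm An `rpm_matrix`.
#' @param sample_ids Samples to compare pairwise (>= 2).
#' @param alpha Flagging threshold on P (default 0.05).
#' @return data.frame with `sample_a`, `sample_b`, `r`, `p`, `flagged`.
#' @export
replicate_qc_pcc <- function(nm, sample_ids, alpha = 0.05) {
  stopifnot(inherits(nm, "rpm_matrix"))
  if (length(sample_ids) < 2) stop("need at least 2 samples")
  pairs <- utils::combn(sample_ids, 2)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- nm$rpm[, pairs[1, i]]
    b <- nm$rpm[, pairs[2, i]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      data.frame(sample_a = pairs[1, i], sample_b = pairs[2, i],
                 r = NA_real_, p = NA_real_, flagged = TRUE)
    } else {
      ct <- stats::cor.test(a, b, method = "pearson")
      data.frame(sample_a = pairs[1, i], sample_b = pairs[2, i],
                 r = unname(ct$estimate), p = ct$p.value,
                 flagged = ct$p.value >= alpha)
    }
  })
  do.call(rbind, out)
}
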