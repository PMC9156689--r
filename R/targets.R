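#' Load a miRNA-target interaction table
#'
#' Reads interactions from target prediction and/or degradome evidence and
#' applies the analysis filters: interactions acting through translational
#' inhibition are dropped (only target cleavage leaves an expression
#' signature readable from RNA-seq), prediction records with an expectation
#' score above `max_expectation` are dropped, and duplicate miRNA-target
#' pairs are merged with the union of their evidence sources.
#'
#' @param path TSV with columns `mirna_id`, `target_id`, `source`
#'   (`prediction`/`degradome`), `mode` (`cleavage`/`inhibition`), and
#'   optional `expectation_score`.
#' @param max_expectation Maximum psRNATarget-style expectation score kept
#'   for prediction records (default 3).
#' @return data.frame with `mirna_id`, `target_id`, logical
#'   `src_prediction`, `src_degradome`, and `expectation_score` (NA when no
#'   scored prediction record remains).
#' @export
load_interactions <- function(path, max_expectation = 3) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("mirna_id", "target_id", "source", "mode")
  if (!all(need %in% names(tab))) {
    stop("interaction file must have columns: ", paste(need, collapse = ", "))
  }
  if (!"expectation_score" %in% names(tab)) tab$expectation_score <- NA_real_
  bad <- setdiff(unique(tab$mode), c("cleavage", "inhibition"))
  if (length(bad)) stop("unknown interaction mode: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(tab$source), c("prediction", "degradome"))
  if (length(bad)) stop("unknown interaction source: ", paste(bad, collapse = ", "))
  tab <- tab[tab$mode == "cleavage", , drop = FALSE]
  drop <- !is.na(tab$expectation_score) &
    tab$expectation_score > max_expectation
  tab <- tab[!drop, , drop = FALSE]
  if (!nrow(tab)) {
    return(data.frame(mirna_id = character(), target_id = character(),
                      src_prediction = logical(), src_degradome = logical(),
                      expectation_score = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(tab$mirna_id, tab$target_id, sep = "\r")
  agg <- lapply(split(seq_len(nrow(tab)), key), function(i) {
    data.frame(
      mirna_id = tab$mirna_id[i[1]],
      target_id = tab$target_id[i[1]],
      src_prediction = any(tab$source[i] == "prediction"),
      src_degradome = any(tab$source[i] == "degradome"),
      expectation_score = if (all(is.na(tab$expectation_score[i]))) NA_real_
        else min(tab$expectation_score[i], na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$mirna_id, out$target_id), , drop = FALSE]
}

#' Per-genotype mean expression
#'
#' Averages replicate RPM values within each genotype class.
#'
#' @param nm An `rpm_matrix`.
#' @param genotypes Optional subset of genotype ids (default all in the
#'   sample sheet).
#' @return Matrix features x genotypes of mean RPM.
#' @export
genotype_means <- function(nm, genotypes = NULL) {
  stopifnot(inherits(nm, "rpm_matrix"))
  gmap <- nm$samples$genotype_id
  if (is.null(genotypes)) genotypes <- unique(gmap)
  miss <- setdiff(genotypes, gmap)
  if (length(miss)) stop("genotype(s) without samples: ", paste(miss, collapse = ", "))
  out <- vapply(genotypes, function(g) {
    rowMeans(nm$rpm[, nm$samples$sample_id[gmap == g], drop = FALSE])
  }, numeric(nrow(nm$rpm)))
  dimnames(out) <- list(rownames(nm$rpm), genotypes)
  out
}

# Pearson correlation between two genotype-mean series with explicit
# exclusion reasons; P is the standard two-sided t-transform with n-2 df.
pearson_pair <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) {
    return(list(r = NA_real_, p = NA_real_, n = n, significant = FALSE,
                exclusion_reason = "fewer than 3 genotype classes"))
  }
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, significant = FALSE,
                exclusion_reason = "constant expression series"))
  }
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n,
       significant = ct$p.value < alpha, exclusion_reason = NA_character_)
}

#' Correlate miRNA and target expression across genotypes
#'
#' Pearson correlation between genotype-mean expression of each interaction's
#' miRNA and target. `scope = "global"` uses all supplied genotype classes;
#' for the local mode (one segment's dosage series) pass the restricted
#' genotype set and a `scope` label such as `"local:TB-1Sb"`. No
#' multiple-testing adjustment is applied (by design); interactions that
#' cannot yield a p-value (fewer than 3 genotype classes, constant series,
#' unexpressed feature) are returned with an explicit exclusion reason.
#'
#' @param interactions data.frame from [load_interactions()].
#' @param mirna_means,target_means Genotype-mean matrices from
#'   [genotype_means()] (miRNA and gene expression respectively).
#' @param genotypes Optional genotype subset (columns) used for the
#'   correlation; default: all columns shared by both matrices.
#' @param scope Scope label recorded in the output (default `"global"`).
#' @param alpha Significance threshold on the unadjusted P (default 0.05).
#' @return data.frame with `scope`, `mirna_id`, `target_id`,
#'   `src_prediction`, `src_degradome`, `r`, `p`, `n`, `significant`,
#'   `exclusion_reason`.
#' @export
correlate_interactions <- function(interactions, mirna_means, target_means,
                                   genotypes = NULL, scope = "global",
                                   alpha = 0.05) {
  if (is.null(genotypes)) {
    genotypes <- intersect(colnames(mirna_means), colnames(target_means))
  }
  if (length(genotypes) < 1) stop("no shared genotype classes")
  if (!nrow(interactions)) {
    return(data.frame(scope = character(), mirna_id = character(),
                      target_id = character(), src_prediction = logical(),
                      src_degradome = logical(), r = numeric(), p = numeric(),
                      n = integer(), significant = logical(),
                      exclusion_reason = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(interactions)), function(i) {
    m <- interactions$mirna_id[i]
    t <- interactions$target_id[i]
    if (!m %in% rownames(mirna_means) || !t %in% rownames(target_means)) {
      pr <- list(r = NA_real_, p = NA_real_, n = 0L, significant = FALSE,
                 exclusion_reason = "feature filtered from expression matrix")
    } else {
      pr <- pearson_pair(mirna_means[m, genotypes],
                         target_means[t, genotypes], alpha = alpha)
    }
    data.frame(scope = scope, mirna_id = m, target_id = t,
               src_prediction = interactions$src_prediction[i],
               src_degradome = interactions$src_degradome[i],
               r = pr$r, p = pr$p, n = pr$n, significant = pr$significant,
               exclusion_reason = pr$exclusion_reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Local correlation along one segment's dosage series
#'
#' Restricts the correlation to genotypes in which the given line's segment
#' dosage varies (plus its controls), the local mode asking whether a cis
#' miRNA's dosage response propagates to its trans targets. Interactions
#' whose miRNA is not cis or whose target is not trans for the line are
#' dropped when labels are supplied; series with fewer than 3 genotype
#' classes are excluded with a reason, mirroring series for which a
#' correlation P cannot be produced.
#'
#' @param interactions data.frame from [load_interactions()].
#' @param mirna_means,target_means Genotype-mean matrices.
#' @param genotypes Genotype ids of the line's dosage series (experimental
#'   genotypes plus controls).
#' @param line_id Line label recorded in `scope` as `"local:<line_id>"`.
#' @param labels Optional cis/trans labels (data.frame from
#'   [partition_cis_trans()]) used to enforce cis-miRNA / trans-target.
#' @param alpha Significance threshold (default 0.05).
#' @return As [correlate_interactions()].
#' @export
correlate_local <- function(interactions, mirna_means, target_means,
                            genotypes, line_id, labels = NULL, alpha = 0.05) {
  if (!is.null(labels)) {
    lab <- labels[labels$line_id == line_id, , drop = FALSE]
    cis_ids <- lab$feature_id[lab$label == "cis"]
    trans_ids <- lab$feature_id[lab$label == "trans"]
    interactions <- interactions[
      interactions$mirna_id %in% cis_ids &
        (!interactions$target_id %in% cis_ids |
           interactions$target_id %in% trans_ids), , drop = FALSE]
  }
  correlate_interactions(interactions, mirna_means, target_means,
                         genotypes = genotypes,
                         scope = paste0("local:", line_id), alpha = alpha)
}

#' Intersect significant interactions across evidence sources
#'
#' Summarizes interactions that are significant and supported by both
#' target prediction and degradome evidence, with the split of negative and
#' positive correlation signs.
#'
#' @param results data.frame from [correlate_interactions()].
#' @return list with `n_both` (significant, both sources), `n_negative`,
#'   `n_positive`, and `interactions` (the subset data.frame).
#' @export
intersect_sources <- function(results) {
  hit <- results$significant & results$src_prediction & results$src_degradome
  hit[is.na(hit)] <- FALSE
  sub <- results[hit, , drop = FALSE]
  list(n_both = nrow(sub),
       n_negative = sum(sub$r < 0),
       n_positive = sum(sub$r > 0),
       interactions = sub)
}
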