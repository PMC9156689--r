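#' MA-style scatter table for one comparison
#'
#' One row per tested feature with the quantities behind the differential
#' expression scatter plots: x = log2 fold change, y = log2 mean normalized
#' count, and the color class (`magenta` for FDR < 0.05 with logFC > 0,
#' `green` for FDR < 0.05 with logFC < 0, `black` otherwise). The expected
#' direct/inverse fold changes plus 1.0 are attached as reference lines.
#'
#' @param de data.frame from [de_exact()] or [de_ratio_t()].
#' @param cmp The `comparison_spec` the results came from.
#' @param alpha FDR threshold for coloring (default 0.05).
#' @return data.frame with `feature_id`, `x`, `y`, `color_class`; the FC
#'   reference values are in `attr(, "reference_fc")`.
#' @export
ma_table <- function(de, cmp, alpha = 0.05) {
  er <- expected_ratios(cmp)
  out <- data.frame(
    feature_id = de$feature_id,
    x = de$logFC,
    y = de$log_mean,
    color_class = ifelse(!is.na(de$fdr) & de$fdr < alpha & de$logFC > 0,
                         "magenta",
                         ifelse(!is.na(de$fdr) & de$fdr < alpha & de$logFC < 0,
                                "green", "black")),
    stringsAsFactors = FALSE
  )
  attr(out, "reference_fc") <- sort(unique(c(er$direct_label, 1,
                                             er$inverse_label)))
  out
}

#' Standard comparisons for a genotype design
#'
#' Derives the comparison set from a genotype design: each aneuploid
#' genotype against the euploid control of its background (d vs background
#' ploidy, per line), the ploidy series against the diploid euploid
#' (including the 4X/3X contrast, flagged for the ratio t-test), and the
#' B-chromosome control pair.
#'
#' @param design A `genotype_design`.
#' @param diploid_control,haploid_control,ploidy_control,b0_control Genotype
#'   ids of the euploid diploid, euploid haploid, ploidy-series diploid and
#'   zero-B controls (defaults match [simulate_design()] naming).
#' @return Named list of `comparison_spec` objects; the 4X/3X entry carries
#'   `test = "ratio_t"` and its shared-control genotype in `ratio_control`.
#' @export
comparisons_for_design <- function(design, diploid_control = "2D",
                                   haploid_control = "h1D",
                                   ploidy_control = "2X",
                                   b0_control = "0B") {
  info <- design$info
  dos <- design$dosages
  cmps <- list()
  for (i in seq_len(nrow(dos))) {
    g <- dos$genotype_id[i]
    d <- dos$segment_dosage[i]
    bg <- info$background_ploidy[match(g, info$genotype_id)]
    if (d == bg) next
    ctl <- if (bg == 2) diploid_control else haploid_control
    if (!ctl %in% info$genotype_id) next
    name <- if (bg == 2) sprintf("%s %dD/2D", dos$line_id[i], d)
            else sprintf("%s h%dD/h1D", dos$line_id[i], d)
    cmps[[name]] <- comparison_spec(
      name, experimental = g, control = ctl, dosage_pair = c(d, bg),
      series = if (bg == 2) "diploid_aneuploid" else "haploid_aneuploid",
      line_id = dos$line_id[i]
    )
  }
  euploid <- setdiff(info$genotype_id, dos$genotype_id)
  for (p in c(1, 3, 4)) {
    g <- euploid[info$background_ploidy[match(euploid, info$genotype_id)] == p &
                   info$b_count[match(euploid, info$genotype_id)] == 0]
    g <- setdiff(g, c(diploid_control, haploid_control, b0_control))
    g <- grep("X$", g, value = TRUE)
    if (length(g) == 1 && ploidy_control %in% info$genotype_id) {
      name <- sprintf("%dX/2X", p)
      cmps[[name]] <- comparison_spec(name, experimental = g,
                                      control = ploidy_control,
                                      dosage_pair = c(p, 2),
                                      series = "ploidy")
    }
  }
  if (all(c("4X", "3X", ploidy_control) %in% info$genotype_id)) {
    cmp <- comparison_spec("4X/3X", experimental = "4X", control = "3X",
                           dosage_pair = c(4, 3), series = "ploidy")
    cmp$test <- "ratio_t"
    cmp$ratio_control <- ploidy_control
    cmps[["4X/3X"]] <- cmp
  }
  b1 <- info$genotype_id[info$b_count > 0]
  if (length(b1) == 1 && b0_control %in% info$genotype_id) {
    cmps[["1B/0B"]] <- comparison_spec("1B/0B", experimental = b1,
                                       control = b0_control,
                                       dosage_pair = c(1, 1),
                                       series = "b_control")
  }
  cmps
}

samples_of <- function(samples, genotypes) {
  samples$sample_id[samples$genotype_id %in% genotypes]
}

# Per-(feature, line) evidence table from the line's aneuploid DE results.
line_evidence <- function(feature, line_cmps, de_tables) {
  rows <- lapply(names(line_cmps), function(nm) {
    de <- de_tables[[nm]]
    i <- match(feature, de$feature_id)
    if (is.na(i)) return(NULL)
    cmp <- line_cmps[[nm]]
    data.frame(comparison = nm, series = cmp$series,
               d_e = cmp$dosage_pair[1], d_c = cmp$dosage_pair[2],
               fdr = de$fdr[i], logfc = de$logFC[i],
               fc = 2^de$logFC[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full dosage-response pipeline
#'
#' Orchestrates qc, filtering, differential expression, B-control
#' exclusion, trans-ratio trends with k-means, cis/trans response
#' classification, and (when target data are supplied) miRNA-target
#' correlation, over all comparisons derivable from the design.
#'
#' @param cm `count_matrix` of miRNA counts.
#' @param design A `genotype_design`.
#' @param segments Segment definitions data.frame.
#' @param loci Feature loci data.frame (miRNA clusters).
#' @param gene_cm Optional `count_matrix` of target-gene counts.
#' @param interactions Optional interaction data.frame from
#'   [load_interactions()] (or the raw table columns accepted by it written
#'   to disk first).
#' @param alpha FDR / significance threshold (default 0.05).
#' @param threshold Mean-RPM expression filter (default 0.5).
#' @param dispersion Dispersion mode for [de_exact()] (default "tagwise").
#' @param out_dir Optional directory; when given, all result tables are
#'   written as TSV with a header row.
#' @return list with `summary` (one row per comparison), `de` (named list of
#'   DE tables), `dems`, `b_excluded`, `trend` (medians plus k-means
#'   cluster), `cis_calls`, `trans_calls`, `correlations`, `qc`, `labels`.
#' @export
run_pipeline <- function(cm, design, segments, loci, gene_cm = NULL,
                         interactions = NULL, alpha = 0.05, threshold = 0.5,
                         dispersion = "tagwise", out_dir = NULL) {
  nm <- rpm_normalize(cm)
  labels <- partition_all_lines(loci, segments)
  cmps <- comparisons_for_design(design)
  if (!length(cmps)) stop("pipeline stage 'design': no comparisons derivable")

  qc <- lapply(cmps, function(cmp) {
    ids <- samples_of(nm$samples, c(cmp$experimental, cmp$control))
    list(pcc = replicate_qc_pcc(nm, ids),
         pca = suppressWarnings(replicate_qc_pca(nm, ids)))
  })

  de_tables <- list()
  kept_sets <- list()
  for (nm_c in names(cmps)) {
    cmp <- cmps[[nm_c]]
    exp_s <- samples_of(nm$samples, cmp$experimental)
    ctl_s <- samples_of(nm$samples, cmp$control)
    if (!length(exp_s) || !length(ctl_s)) {
      stop("pipeline stage 'de': comparison ", nm_c, " has empty groups")
    }
    if (identical(cmp$test, "ratio_t")) {
      ctl2 <- samples_of(nm$samples, cmp$ratio_control)
      kept <- filter_low_expression(nm, c(exp_s, ctl_s, ctl2), threshold)
      de_tables[[nm_c]] <- de_ratio_t(nm, exp_s, ctl_s, ctl2, kept = kept,
                                      alpha = alpha)
    } else {
      kept <- filter_low_expression(nm, c(exp_s, ctl_s), threshold)
      de_tables[[nm_c]] <- de_exact(cm, nm, exp_s, ctl_s, kept = kept,
                                    dispersion = dispersion, alpha = alpha)
    }
    kept_sets[[nm_c]] <- kept
  }

  b_dems <- character(0)
  if ("1B/0B" %in% names(cmps)) {
    b_dems <- call_dems(de_tables[["1B/0B"]], alpha)$dems$feature_id
  }

  is_aneu <- vapply(cmps, function(c) {
    c$series %in% c("diploid_aneuploid", "haploid_aneuploid")
  }, logical(1))

  summary_rows <- list()
  trend_rows <- list()
  for (nm_c in names(cmps)) {
    cmp <- cmps[[nm_c]]
    de <- de_tables[[nm_c]]
    de_kept <- de[!de$feature_id %in% b_dems, , drop = FALSE]
    dem <- call_dems(de_kept, alpha)
    med <- NA_real_
    if (is_aneu[[nm_c]]) {
      exp_s <- samples_of(nm$samples, cmp$experimental)
      ctl_s <- samples_of(nm$samples, cmp$control)
      rt <- compute_ratios(nm, exp_s, ctl_s,
                           kept = apply_control_exclusion(kept_sets[[nm_c]],
                                                          b_dems))
      trans_f <- labels$feature_id[labels$line_id == cmp$line_id &
                                     labels$label == "trans"]
      med <- tryCatch(median_trans_ratio(rt, trans_f), error = function(e) NA_real_)
      trend_rows[[nm_c]] <- data.frame(
        comparison = nm_c, series = cmp$series, line_id = cmp$line_id,
        median_trans_fc = med, stringsAsFactors = FALSE)
    }
    er <- suppressWarnings(expected_ratios(cmp))
    summary_rows[[nm_c]] <- data.frame(
      comparison = nm_c, series = cmp$series,
      line_id = if (is.null(cmp$line_id)) NA_character_ else cmp$line_id,
      n_tested = nrow(de), n_dem = nrow(dem$dems),
      n_up = dem$n_up, n_down = dem$n_down,
      expected_direct_fc = er$direct_label,
      expected_inverse_fc = er$inverse_label,
      median_trans_fc = med, stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  trend <- if (length(trend_rows)) do.call(rbind, trend_rows) else NULL
  if (!is.null(trend)) {
    rownames(trend) <- NULL
    trend$cluster <- NA_integer_
    for (s in unique(trend$series)) {
      i <- which(trend$series == s & !is.na(trend$median_trans_fc))
      if (length(i) >= 2 &&
          length(unique(trend$median_trans_fc[i])) >= 2) {
        trend$cluster[i] <- kmeans_1d(trend$median_trans_fc[i], k = 2)$cluster
      }
    }
  }

  # per-line response classification over the aneuploid comparisons
  cis_calls <- list()
  trans_calls <- list()
  for (l in segments$line_id) {
    line_cmps <- cmps[is_aneu & vapply(cmps, function(c) {
      identical(c$line_id, l)
    }, logical(1))]
    if (!length(line_cmps)) next
    tested <- unique(unlist(lapply(names(line_cmps), function(n) {
      de_tables[[n]]$feature_id
    })))
    tested <- apply_control_exclusion(tested, b_dems)
    lab_l <- labels[labels$line_id == l, ]
    cis_f <- intersect(tested, lab_l$feature_id[lab_l$label == "cis"])
    trans_f <- intersect(tested, lab_l$feature_id[lab_l$label == "trans"])
    for (f in cis_f) {
      ev <- line_evidence(f, line_cmps, de_tables)
      cl <- classify_cis_response(ev, alpha = alpha)
      cis_calls[[paste(l, f)]] <- data.frame(
        feature_id = f, line_id = l, context = "cis", label = cl$label,
        n_significant = cl$n_significant,
        n_comparisons = cl$n_comparisons, stringsAsFactors = FALSE)
    }
    # only trans features DE somewhere in this line are worth classifying
    de_any <- unique(unlist(lapply(names(line_cmps), function(n) {
      call_dems(de_tables[[n]], alpha)$dems$feature_id
    })))
    for (f in intersect(trans_f, de_any)) {
      ev <- line_evidence(f, line_cmps, de_tables)
      cl <- classify_trans_response(ev, alpha = alpha)
      trans_calls[[paste(l, f)]] <- data.frame(
        feature_id = f, line_id = l, context = "trans", label = cl$label,
        n_significant = cl$n_significant,
        n_comparisons = cl$n_comparisons, stringsAsFactors = FALSE)
    }
  }
  cis_calls <- if (length(cis_calls)) do.call(rbind, c(cis_calls, make.row.names = FALSE)) else NULL
  trans_calls <- if (length(trans_calls)) do.call(rbind, c(trans_calls, make.row.names = FALSE)) else NULL

  correlations <- NULL
  if (!is.null(gene_cm) && !is.null(interactions)) {
    gnm <- rpm_normalize(gene_cm)
    mir_means <- genotype_means(nm)
    tgt_means <- genotype_means(gnm)
    expressed_m <- rownames(mir_means)[rowMeans(mir_means) >= threshold]
    expressed_t <- rownames(tgt_means)[rowMeans(tgt_means) >= threshold]
    ia <- interactions[!interactions$mirna_id %in% b_dems, , drop = FALSE]
    glob <- correlate_interactions(
      ia, mir_means[expressed_m, , drop = FALSE],
      tgt_means[expressed_t, , drop = FALSE], alpha = alpha)
    loc <- lapply(segments$line_id, function(l) {
      genos <- unique(c(
        design$dosages$genotype_id[design$dosages$line_id == l],
        "2D", "h1D"))
      genos <- intersect(genos, colnames(mir_means))
      correlate_local(ia, mir_means[expressed_m, , drop = FALSE],
                      tgt_means[expressed_t, , drop = FALSE],
                      genotypes = genos, line_id = l, labels = labels,
                      alpha = alpha)
    })
    correlations <- list(global = glob, local = do.call(rbind, loc),
                         intersection = intersect_sources(glob))
  }

  res <- list(summary = summary, de = de_tables, b_excluded = b_dems,
              trend = trend, cis_calls = cis_calls,
              trans_calls = trans_calls, correlations = correlations,
              qc = qc, labels = labels, comparisons = cmps)
  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

#' Write pipeline result tables to a directory
#'
#' All writers emit TSV with a header row.
#'
#' @param res Result list from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_pipeline_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  w(res$summary, "summary.tsv")
  w(res$trend, "trend.tsv")
  w(res$cis_calls, "cis_calls.tsv")
  w(res$trans_calls, "trans_calls.tsv")
  for (nm in names(res$de)) {
    w(res$de[[nm]], paste0("de_", gsub("[^A-Za-z0-9]+", "_", nm), ".tsv"))
  }
  if (!is.null(res$correlations)) {
    w(res$correlations$global, "correlations_global.tsv")
    w(res$correlations$local, "correlations_local.tsv")
  }
  invisible(out_dir)
}
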