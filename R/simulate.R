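# Response archetypes recognized by the simulator. Cis archetypes sit on a
# varied segment; trans archetypes respond to one line's dosage from
# elsewhere in the genome; "null" features track nothing.
CIS_ARCHETYPES <- c("direct_dosage", "negative_dosage", "compensation",
                    "increased", "decreased", "mixed")
TRANS_ARCHETYPES <- c("trans_positive", "trans_inverse", "trans_increased",
                      "trans_decreased", "null")

#' Simulation configuration
#'
#' Defines the study conditions the simulator emulates: a set of B-A
#' translocation lines each with a segmental dosage series of 1-4 copies on
#' the diploid background and 1-2 copies on the haploid background, one
#' whole-genome ploidy series (1X-4X), one B-chromosome control pair
#' (0B/1B), negative-binomial counts with replicate libraries of log-normal
#' size, per-feature response archetypes, and miRNA-to-target cleavage
#' coupling of tunable sign and strength.
#'
#' @param n_lines Number of translocation lines (default 3).
#' @param n_mirnas Number of miRNA cluster features; default 2200 = 200 per
#'   archetype (10 responsive archetypes plus a null class).
#' @param n_genes Number of protein-coding target genes (default 600; half
#'   coupled to miRNAs, half decoys).
#' @param replicates Biological replicates per genotype (default 3).
#' @param dispersion NB dispersion of simulated counts (default 0.05).
#' @param lib_size_mean,lib_size_cv Log-normal library size model; defaults
#'   2e7 mapped reads with CV 0.3, typical of small-RNA libraries.
#' @param archetype_mix Named proportions over the archetypes (must sum
#'   to 1); default uniform over the 11 classes.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline RPM of
#'   features; defaults put ~15% of features below the 0.5-RPM filter so
#'   the filtering path is exercised.
#' @param effect_delta Log-scale magnitude of increased/decreased effects
#'   (default log(1.5)).
#' @param coupling_fraction_negative Fraction of miRNA-target couplings with
#'   negative sign (default 0.6).
#' @param coupling_exponent Coupling strength gamma: the target mean scales
#'   as (miRNA mean / baseline)^(sign * gamma) (default 0.8).
#' @param b_effect Fold change of B-responsive decoy features in 1B vs 0B
#'   (default 3).
#' @param n_b_responsive Number of injected B-responsive decoys (default 2).
#' @param seed Integer seed; fully determines all simulator output.
#' @return list of validated settings, class `sim_config`.
#' @export
sim_config <- function(n_lines = 3,
                       n_mirnas = 2200,
                       n_genes = 600,
                       replicates = 3,
                       dispersion = 0.05,
                       lib_size_mean = 2e7,
                       lib_size_cv = 0.3,
                       archetype_mix = NULL,
                       baseline_meanlog = log(0.5) + stats::qnorm(0.85) * 2,
                       baseline_sdlog = 2,
                       effect_delta = log(1.5),
                       coupling_fraction_negative = 0.6,
                       coupling_exponent = 0.8,
                       b_effect = 3,
                       n_b_responsive = 2,
                       seed = 1L) {
  if (is.null(archetype_mix)) {
    labs <- c(CIS_ARCHETYPES, TRANS_ARCHETYPES)
    archetype_mix <- stats::setNames(rep(1 / length(labs), length(labs)), labs)
  }
  if (abs(sum(archetype_mix) - 1) > 1e-8) {
    stop("archetype_mix proportions must sum to 1")
  }
  bad <- setdiff(names(archetype_mix), c(CIS_ARCHETYPES, TRANS_ARCHETYPES))
  if (length(bad)) stop("unknown archetype(s): ", paste(bad, collapse = ", "))
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (replicates < 2) stop("need >= 2 replicates per genotype")
  structure(list(
    n_lines = n_lines, n_mirnas = n_mirnas, n_genes = n_genes,
    replicates = replicates, dispersion = dispersion,
    lib_size_mean = lib_size_mean, lib_size_cv = lib_size_cv,
    archetype_mix = archetype_mix,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    effect_delta = effect_delta,
    coupling_fraction_negative = coupling_fraction_negative,
    coupling_exponent = coupling_exponent,
    b_effect = b_effect, n_b_responsive = n_b_responsive,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Deterministic integer allocation of n features over proportions
# (largest-remainder rounding).
allocate_counts <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Simulate the experimental design
#'
#' Builds segment definitions (one per line, sizes spread over 50-150 Mb),
#' feature loci (cis loci placed uniformly inside segments, allocated to
#' lines proportionally to segment size; trans loci on an unvaried
#' chromosome), the genotype design, and the sample sheet. Genotypes per
#' line are 1D/3D/4D (diploid background) and h2D (haploid background) with
#' shared 2D and h1D controls, plus the 1X-4X ploidy series and the 0B/1B
#' pair.
#'
#' @param cfg A `sim_config`.
#' @return list with `segments`, `loci` (including truth archetype and
#'   responding line), `design` (a `genotype_design`), `samples`.
#' @export
simulate_design <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_lines <- cfg$n_lines
  line_ids <- paste0("TB-", seq_len(n_lines), "L")
  sizes <- round(seq(5e7, 1.5e8, length.out = n_lines))
  segments <- data.frame(
    line_id = line_ids,
    chrom = paste0("chr", seq_len(n_lines)),
    start = 1e6,
    end = 1e6 + sizes - 1,
    kind = "distal",
    stringsAsFactors = FALSE
  )

  n_arch <- allocate_counts(cfg$n_mirnas, cfg$archetype_mix)
  archetype <- rep(names(n_arch), n_arch)
  is_cis <- archetype %in% CIS_ARCHETYPES
  # cis features: line membership proportional to segment size
  cis_line <- sample(line_ids, sum(is_cis), replace = TRUE,
                     prob = sizes / sum(sizes))
  # trans features respond to a uniformly chosen line; null features to none
  trans_line <- sample(line_ids, sum(!is_cis), replace = TRUE)
  trans_line[archetype[!is_cis] == "null"] <- NA_character_

  feature_id <- sprintf("Cluster_%05d", seq_len(cfg$n_mirnas))
  chrom <- character(cfg$n_mirnas)
  pos <- integer(cfg$n_mirnas)
  line <- character(cfg$n_mirnas)
  line[is_cis] <- cis_line
  line[!is_cis] <- trans_line
  for (i in which(is_cis)) {
    s <- segments[segments$line_id == line[i], ]
    chrom[i] <- s$chrom
    pos[i] <- sample.int(s$end - s$start - 200L, 1) + s$start
  }
  n_trans <- sum(!is_cis)
  chrom[!is_cis] <- "chr0"
  pos[!is_cis] <- sort(sample.int(3e8, n_trans))
  loci <- data.frame(
    feature_id = feature_id,
    chrom = chrom,
    start = pos,
    end = pos + 120L,
    feature_class = "mirna_cluster",
    archetype = archetype,
    line_id = ifelse(is.na(line) | line == "", NA_character_, line),
    stringsAsFactors = FALSE
  )
  # B-responsive decoys among null trans features
  nulls <- which(loci$archetype == "null")
  if (cfg$n_b_responsive > 0 && length(nulls) >= cfg$n_b_responsive) {
    loci$archetype[nulls[seq_len(cfg$n_b_responsive)]] <- "b_responsive"
  }

  info <- data.frame(
    genotype_id = c("2D", "h1D", "1X", "2X", "3X", "4X", "0B", "1B",
                    unlist(lapply(line_ids, function(l) {
                      paste0(l, "_", c("1D", "3D", "4D", "h2D"))
                    }))),
    stringsAsFactors = FALSE
  )
  info$background_ploidy <- 2L
  info$background_ploidy[info$genotype_id %in% c("h1D", "1X")] <- 1L
  info$background_ploidy[info$genotype_id == "3X"] <- 3L
  info$background_ploidy[info$genotype_id == "4X"] <- 4L
  info$background_ploidy[grepl("_h2D$", info$genotype_id)] <- 1L
  info$b_count <- ifelse(info$genotype_id == "1B", 1L, 0L)
  dosages <- do.call(rbind, lapply(line_ids, function(l) {
    data.frame(
      genotype_id = paste0(l, "_", c("1D", "3D", "4D", "h2D")),
      line_id = l,
      segment_dosage = c(1L, 3L, 4L, 2L),
      stringsAsFactors = FALSE
    )
  }))
  design <- genotype_design(info, dosages)

  samples <- do.call(rbind, lapply(info$genotype_id, function(g) {
    data.frame(
      sample_id = paste0(g, "_r", seq_len(cfg$replicates)),
      genotype_id = g,
      replicate = seq_len(cfg$replicates),
      include_flag = TRUE,
      stringsAsFactors = FALSE
    )
  }))
  list(segments = segments, loci = loci, design = design, samples = samples)
}

#' Expected RPM of one feature in one genotype
#'
#' Closed-form mean model. `d` is the genotype's dosage of the feature's
#' responding line segment and `ref` its background ploidy (the euploid
#' dosage). Direct dosage scales as d/ref, negative dosage as ref/d,
#' compensation is flat, increased/decreased shift by exp(+/-delta) whenever
#' the segment is off-euploid; trans archetypes respond identically but to a
#' segment they do not sit on; the mixed archetype is direct on the diploid
#' background and inverse on the haploid background. Whole-ploidy genotypes
#' leave RPM unchanged for every archetype: a jointly scaled transcriptome
#' cancels in reads-per-million units.
#'
#' @param archetype Archetype label.
#' @param mu Baseline RPM of the feature (euploid diploid).
#' @param d Segment dosage of the responding line in this genotype.
#' @param ref Background ploidy of the genotype.
#' @param delta Increased/decreased log-magnitude.
#' @param b_count B-chromosome count of the genotype.
#' @param b_effect Fold change per B chromosome for `b_responsive` features.
#' @return Expected RPM (numeric scalar).
#' @export
archetype_mean <- function(archetype, mu, d, ref, delta = log(1.5),
                           b_count = 0, b_effect = 3) {
  if (archetype == "b_responsive") return(mu * b_effect^b_count)
  if (is.na(d) || d == ref) return(mu)
  switch(archetype,
    direct_dosage = ,
    trans_positive = mu * d / ref,
    negative_dosage = ,
    trans_inverse = mu * ref / d,
    compensation = mu,
    increased = ,
    trans_increased = mu * exp(delta),
    decreased = ,
    trans_decreased = mu * exp(-delta),
    mixed = if (ref == 2) mu * d / ref else mu * ref / d,
    null = mu,
    stop("unknown archetype: ", archetype)
  )
}

# Expected-RPM matrix (features x genotypes) for a genotype design.
expected_rpm_matrix <- function(cfg, gd, loci, baselines) {
  info <- gd$info
  genos <- info$genotype_id
  out <- matrix(NA_real_, nrow(loci), length(genos),
                dimnames = list(loci$feature_id, genos))
  for (j in seq_along(genos)) {
    g <- genos[j]
    ref <- info$background_ploidy[j]
    bc <- info$b_count[j]
    d <- vapply(loci$line_id, function(l) {
      if (is.na(l)) NA_real_
      else as.numeric(segment_dosage(gd, g, l))
    }, numeric(1))
    out[, j] <- vapply(seq_len(nrow(loci)), function(i) {
      archetype_mean(loci$archetype[i], baselines[i], d[i], ref,
                     delta = cfg$effect_delta, b_count = bc,
                     b_effect = cfg$b_effect)
    }, numeric(1))
  }
  out
}

# Draw an NB (or Poisson at dispersion 0) count matrix given expected RPM
# per genotype and per-sample library sizes.
draw_counts <- function(expected_rpm, samples, lib_sizes, dispersion) {
  n_f <- nrow(expected_rpm)
  counts <- matrix(0L, n_f, nrow(samples),
                   dimnames = list(rownames(expected_rpm), samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu <- expected_rpm[, samples$genotype_id[j]] * lib_sizes[j] / 1e6
    counts[, j] <- if (dispersion == 0) {
      stats::rpois(n_f, mu)
    } else {
      stats::rnbinom(n_f, size = 1 / dispersion, mu = mu)
    }
  }
  counts
}

rlnorm_libs <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  round(stats::rlnorm(n, meanlog, sdlog))
}

#' Simulate miRNA counts for a design
#'
#' Draws per-feature baselines (log-normal RPM), computes the closed-form
#' expected mean of every feature in every genotype from its archetype, and
#' samples NB counts against log-normal library sizes.
#'
#' @param cfg A `sim_config`.
#' @param design Output of [simulate_design()].
#' @return list with `cm` (a `count_matrix`), `truth` (data.frame
#'   feature_id, archetype, line_id, baseline_rpm), `expected_rpm`
#'   (features x genotypes matrix), `lib_sizes`.
#' @export
simulate_counts <- function(cfg, design) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  loci <- design$loci
  baselines <- stats::rlnorm(nrow(loci), cfg$baseline_meanlog,
                             cfg$baseline_sdlog)
  expected <- expected_rpm_matrix(cfg, design$design, loci, baselines)
  libs <- rlnorm_libs(nrow(design$samples), cfg$lib_size_mean, cfg$lib_size_cv)
  names(libs) <- design$samples$sample_id
  counts <- draw_counts(expected, design$samples, libs, cfg$dispersion)
  truth <- data.frame(
    feature_id = loci$feature_id,
    archetype = loci$archetype,
    line_id = loci$line_id,
    baseline_rpm = baselines,
    stringsAsFactors = FALSE
  )
  list(cm = count_matrix(counts, design$samples), truth = truth,
       expected_rpm = expected, lib_sizes = libs)
}

#' Simulate target-gene counts and an interaction table
#'
#' Couples a subset of genes to dosage-responsive miRNAs through the
#' cleavage model: target mean per genotype = baseline *
#' (miRNA genotype mean / miRNA baseline)^(sign * gamma), with negative
#' sign for the configured fraction of couplings. The remaining genes are
#' uncoupled decoys paired with random miRNAs. The interaction table is
#' emitted with sources assigned at random to prediction, degradome, or
#' both, plus a small set of translational-inhibition rows that the loader
#' must drop.
#'
#' @param cfg A `sim_config`.
#' @param design Output of [simulate_design()].
#' @param sim Output of [simulate_counts()].
#' @return list with `gene_cm` (a `count_matrix`), `interactions`
#'   (data.frame ready to write as the interaction TSV), `truth`
#'   (per-interaction coupling sign and strength; sign 0 for decoys),
#'   `expected_rpm`, `lib_sizes` (true simulated totals of mapped reads).
#' @export
simulate_targets <- function(cfg, design, sim) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  n_genes <- cfg$n_genes
  n_coupled <- floor(n_genes / 2)
  responsive <- sim$truth$feature_id[
    !sim$truth$archetype %in% c("compensation", "null", "b_responsive")]
  if (!length(responsive)) stop("no dosage-responsive miRNAs to couple to")
  gene_id <- sprintf("Gene_%05d", seq_len(n_genes))
  partner <- sample(responsive, n_genes, replace = TRUE)
  sign_vec <- integer(n_genes)
  sign_vec[seq_len(n_coupled)] <- ifelse(
    stats::runif(n_coupled) < cfg$coupling_fraction_negative, -1L, 1L)

  gene_base <- stats::rlnorm(n_genes, cfg$baseline_meanlog + 1,
                             cfg$baseline_sdlog / 2)
  mir_base <- stats::setNames(sim$truth$baseline_rpm, sim$truth$feature_id)
  genos <- colnames(sim$expected_rpm)
  expected <- matrix(NA_real_, n_genes, length(genos),
                     dimnames = list(gene_id, genos))
  for (i in seq_len(n_genes)) {
    if (sign_vec[i] == 0) {
      expected[i, ] <- gene_base[i]
    } else {
      ratio <- sim$expected_rpm[partner[i], ] / mir_base[partner[i]]
      expected[i, ] <- gene_base[i] *
        ratio^(sign_vec[i] * cfg$coupling_exponent)
    }
  }
  libs <- rlnorm_libs(nrow(design$samples), cfg$lib_size_mean,
                      cfg$lib_size_cv)
  names(libs) <- design$samples$sample_id
  counts <- draw_counts(expected, design$samples, libs, cfg$dispersion)

  src_kind <- sample(c("prediction", "degradome", "both"), n_genes,
                     replace = TRUE, prob = c(0.35, 0.35, 0.3))
  rows <- lapply(seq_len(n_genes), function(i) {
    srcs <- if (src_kind[i] == "both") c("prediction", "degradome")
            else src_kind[i]
    data.frame(
      mirna_id = partner[i], target_id = gene_id[i], source = srcs,
      mode = "cleavage",
      expectation_score = ifelse(srcs == "prediction",
                                 round(stats::runif(length(srcs), 0, 3), 2),
                                 NA_real_),
      stringsAsFactors = FALSE
    )
  })
  interactions <- do.call(rbind, rows)
  # translational-inhibition decoy rows the loader must drop
  n_inh <- max(1L, round(n_genes * 0.05))
  inh <- data.frame(
    mirna_id = sample(sim$truth$feature_id, n_inh, replace = TRUE),
    target_id = sample(gene_id, n_inh, replace = TRUE),
    source = "prediction", mode = "inhibition",
    expectation_score = round(stats::runif(n_inh, 0, 3), 2),
    stringsAsFactors = FALSE
  )
  interactions <- rbind(interactions, inh)
  rownames(interactions) <- NULL
  truth <- data.frame(
    mirna_id = partner, target_id = gene_id, coupling_sign = sign_vec,
    coupling_exponent = ifelse(sign_vec == 0, 0, cfg$coupling_exponent),
    stringsAsFactors = FALSE
  )
  list(gene_cm = count_matrix(counts, design$samples),
       interactions = interactions, truth = truth, expected_rpm = expected,
       lib_sizes = libs)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the same dialects the readers accept: counts and sample sheet as
#' TSV, loci as BED (0-based half-open, converted from the internal 1-based
#' convention), segments and genotype design as TSV, interactions as TSV.
#'
#' @param design Output of [simulate_design()].
#' @param sim Output of [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @param targets Optional output of [simulate_targets()].
#' @return Invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(design, sim, dir, targets = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "mirna_counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    loci = file.path(dir, "mirna_loci.bed"),
    segments = file.path(dir, "segments.tsv"),
    genotypes = file.path(dir, "genotypes.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  counts <- data.frame(feature_id = rownames(sim$cm$counts),
                       sim$cm$counts, check.names = FALSE)
  utils::write.table(counts, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(design$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bed <- data.frame(design$loci$chrom, design$loci$start - 1L,
                    design$loci$end, design$loci$feature_id)
  utils::write.table(bed, paths["loci"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(design$segments, paths["segments"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  info <- design$design$info
  dos <- design$design$dosages
  long <- merge(info, dos, by = "genotype_id", all.x = TRUE)
  utils::write.table(long, paths["genotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(targets)) {
    paths <- c(paths,
               gene_counts = file.path(dir, "gene_counts.tsv"),
               interactions = file.path(dir, "interactions.tsv"))
    gc <- data.frame(feature_id = rownames(targets$gene_cm$counts),
                     targets$gene_cm$counts, check.names = FALSE)
    utils::write.table(gc, paths["gene_counts"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(targets$interactions, paths["interactions"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Classification recovery against simulation ground truth
#'
#' Compares pipeline response calls with the generator's truth labels,
#' per archetype, over the analysis-eligible sets: cis archetypes are scored
#' over truth features differentially expressed in at least one comparison
#' of their own line (the set the typology is assigned to), compensation
#' over truth features never differentially expressed, and trans archetypes
#' over features passing the trans eligibility rule (classified with a
#' definite label).
#'
#' @param truth Truth data.frame from [simulate_counts()].
#' @param cis_calls,trans_calls Call tables from [run_pipeline()].
#' @return data.frame with `archetype`, `n_eligible`, `n_correct`,
#'   `recovery`.
#' @export
recovery_rates <- function(truth, cis_calls, trans_calls) {
  rows <- list()
  if (!is.null(cis_calls)) {
    m <- merge(truth, cis_calls, by = "feature_id",
               suffixes = c(".truth", ".call"))
    m <- m[m$line_id.truth == m$line_id.call, , drop = FALSE]
    for (a in c("direct_dosage", "negative_dosage", "increased",
                "decreased", "mixed")) {
      sub <- m[m$archetype == a & m$n_significant >= 1, , drop = FALSE]
      rows[[a]] <- data.frame(archetype = a, n_eligible = nrow(sub),
                              n_correct = sum(sub$label == a))
    }
    sub <- m[m$archetype == "compensation" & m$n_significant == 0, ,
             drop = FALSE]
    rows[["compensation"]] <- data.frame(archetype = "compensation",
                                         n_eligible = nrow(sub),
                                         n_correct = sum(sub$label ==
                                                           "compensation"))
  }
  if (!is.null(trans_calls)) {
    label_of <- c(trans_positive = "positive_trans",
                  trans_inverse = "inverse_trans",
                  trans_increased = "increased",
                  trans_decreased = "decreased")
    m <- merge(truth, trans_calls, by = "feature_id",
               suffixes = c(".truth", ".call"))
    m <- m[!is.na(m$line_id.truth) & m$line_id.truth == m$line_id.call, ,
           drop = FALSE]
    for (a in names(label_of)) {
      sub <- m[m$archetype == a & m$label != "unclassified", , drop = FALSE]
      rows[[a]] <- data.frame(archetype = a, n_eligible = nrow(sub),
                              n_correct = sum(sub$label == label_of[[a]]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$recovery <- ifelse(out$n_eligible > 0, out$n_correct / out$n_eligible,
                         NA_real_)
  out
}
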