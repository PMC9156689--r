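#' Read feature loci from a BED or GFF3 file
#'
#' Reads genomic locations of features (miRNA clusters or protein-coding
#' genes) and normalizes coordinates to the internal 1-based inclusive
#' convention (GFF-style). BED input (0-based half-open) is converted on
#' read; GFF3 coordinates are taken as-is.
#'
#' @param path Path to a BED (>= 4 columns, name in column 4) or GFF3 file.
#' @param dialect One of `"auto"`, `"bed"`, `"gff3"`. With `"auto"` the
#'   dialect is inferred from the file extension.
#' @param feature_class Default feature class used for BED input and for GFF3
#'   records whose `type` is not informative. One of `"mirna_cluster"`,
#'   `"gene"`.
#' @return A data.frame with columns `feature_id`, `chrom`, `start`, `end`
#'   (1-based inclusive) and `feature_class`.
#' @export
read_loci <- function(path, dialect = c("auto", "bed", "gff3"),
                      feature_class = c("mirna_cluster", "gene")) {
  dialect <- match.arg(dialect)
  feature_class <- match.arg(feature_class)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext,
      bed = "bed",
      gff = "gff3", gff3 = "gff3",
      stop("cannot infer locus file dialect from extension '.", ext,
           "'; pass dialect = \"bed\" or \"gff3\"")
    )
  }
  gr <- rtracklayer::import(path, format = if (dialect == "bed") "BED" else "GFF3")
  if (dialect == "bed") {
    ids <- as.character(gr$name)
    cls <- rep(feature_class, length(gr))
  } else {
    meta <- S4Vectors::mcols(gr)
    ids <- if ("ID" %in% names(meta) && !all(is.na(meta$ID))) {
      as.character(meta$ID)
    } else if ("Name" %in% names(meta)) {
      as.character(meta$Name)
    } else {
      stop("GFF3 records carry neither ID nor Name attributes")
    }
    type <- as.character(meta$type)
    cls <- ifelse(grepl("rna|cluster", type, ignore.case = TRUE),
                  "mirna_cluster",
                  ifelse(type == "gene", "gene", feature_class))
  }
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("locus file contains records without a feature identifier")
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate feature_id in locus file: ", paste(dup, collapse = ", "))
  }
  data.frame(
    feature_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    feature_class = cls,
    stringsAsFactors = FALSE
  )
}

#' Read varied-segment definitions for B-A translocation lines
#'
#' Each line of a B-A translocation series varies the dosage of one
#' chromosomal segment; distal segments run from a breakpoint to the
#' telomere, interstitial ones (e.g. a proximal duplication spanning a
#' centromere) are internal intervals.
#'
#' @param path TSV with columns `line_id`, `chrom`, `start`, `end`, `kind`
#'   (`distal` or `interstitial`), coordinates 1-based inclusive.
#' @return Validated data.frame of segment definitions.
#' @export
read_segments <- function(path) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("line_id", "chrom", "start", "end", "kind")
  if (!all(need %in% names(seg))) {
    stop("segment file must have columns: ", paste(need, collapse = ", "))
  }
  seg <- seg[need]
  if (anyDuplicated(seg$line_id)) {
    stop("duplicate line_id in segment file: ",
         paste(unique(seg$line_id[duplicated(seg$line_id)]), collapse = ", "))
  }
  if (any(seg$start >= seg$end)) {
    bad <- seg$line_id[seg$start >= seg$end]
    stop("segment start must be < end for line(s): ", paste(bad, collapse = ", "))
  }
  if (!all(seg$kind %in% c("distal", "interstitial"))) {
    stop("segment kind must be 'distal' or 'interstitial'")
  }
  seg
}

#' Read a genotype design table
#'
#' Long-format TSV describing each genotype's background ploidy, B-chromosome
#' count, and per-line segment dosages. Euploid genotypes appear with an
#' empty `line_id`. A genotype's dosage for a line that is not listed
#' defaults to its background ploidy.
#'
#' @param path TSV with columns `genotype_id`, `background_ploidy`,
#'   `b_count`, `line_id`, `segment_dosage` (the last two may be empty/NA).
#' @return A `genotype_design` object.
#' @export
read_genotype_design <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("genotype_id", "background_ploidy", "b_count")
  if (!all(need %in% names(tab))) {
    stop("genotype design file must have columns: ", paste(need, collapse = ", "))
  }
  info <- unique(tab[need])
  if (anyDuplicated(info$genotype_id)) {
    stop("conflicting background_ploidy/b_count rows for a genotype_id")
  }
  dos <- tab[!is.na(tab$line_id), c("genotype_id", "line_id", "segment_dosage")]
  genotype_design(info, dos)
}

#' Construct a genotype design
#'
#' @param info data.frame with `genotype_id`, `background_ploidy` (1-4),
#'   `b_count` (>= 0).
#' @param dosages data.frame with `genotype_id`, `line_id`, `segment_dosage`
#'   (>= 0); genotypes absent here are euploid.
#' @return An object of class `genotype_design`.
#' @export
genotype_design <- function(info, dosages = NULL) {
  stopifnot(all(c("genotype_id", "background_ploidy", "b_count") %in% names(info)))
  if (!all(info$background_ploidy %in% 1:4)) {
    stop("background_ploidy must be in 1..4")
  }
  if (any(info$b_count < 0)) stop("b_count must be >= 0")
  if (is.null(dosages)) {
    dosages <- data.frame(genotype_id = character(), line_id = character(),
                          segment_dosage = integer(), stringsAsFactors = FALSE)
  }
  if (nrow(dosages)) {
    if (!all(dosages$genotype_id %in% info$genotype_id)) {
      stop("dosage rows refer to unknown genotype_id")
    }
    if (any(dosages$segment_dosage < 0)) stop("segment_dosage must be >= 0")
  }
  structure(list(info = info, dosages = dosages), class = "genotype_design")
}

#' Segment dosage of a genotype for one translocation line
#'
#' Defaults to the genotype's background ploidy when the line is not listed
#' in the design (the segment is unvaried in that genotype).
#'
#' @param design A `genotype_design`.
#' @param genotype_id Genotype identifier.
#' @param line_id Translocation line identifier.
#' @return Integer dosage.
#' @export
segment_dosage <- function(design, genotype_id, line_id) {
  stopifnot(inherits(design, "genotype_design"))
  i <- match(genotype_id, design$info$genotype_id)
  if (is.na(i)) stop("unknown genotype_id: ", genotype_id)
  hit <- design$dosages$genotype_id == genotype_id &
    design$dosages$line_id == line_id
  if (any(hit)) design$dosages$segment_dosage[which(hit)[1]]
  else design$info$background_ploidy[i]
}

#' @export
print.genotype_design <- function(x, ...) {
  cat("genotype_design:", nrow(x$info), "genotypes,",
      length(unique(x$dosages$line_id)), "varied line(s)\n")
  invisible(x)
}

#' Partition features into cis and trans for one translocation line
#'
#' A feature is `cis` iff its locus overlaps the line's varied segment by at
#' least 1 bp on the same chromosome (so breakpoint-straddling loci count as
#' cis); every other feature is `trans`. The partition is exhaustive and
#' exclusive.
#'
#' @param loci data.frame as returned by [read_loci()].
#' @param segment One-row data.frame (one segment definition).
#' @return data.frame with `feature_id`, `line_id`, `label` (`cis`/`trans`).
#' @export
partition_cis_trans <- function(loci, segment) {
  if (!nrow(loci)) stop("loci must be non-empty")
  if (nrow(segment) != 1L) stop("partition_cis_trans takes exactly one segment")
  gr_loci <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(loci$start, loci$end))
  gr_seg <- GenomicRanges::GRanges(
    segment$chrom, IRanges::IRanges(segment$start, segment$end))
  cis <- IRanges::overlapsAny(gr_loci, gr_seg)
  data.frame(
    feature_id = loci$feature_id,
    line_id = segment$line_id,
    label = ifelse(cis, "cis", "trans"),
    stringsAsFactors = FALSE
  )
}

#' Partition features for every line of a segment table
#'
#' @param loci data.frame of feature loci.
#' @param segments data.frame of segment definitions (one row per line).
#' @return data.frame stacking [partition_cis_trans()] over all lines.
#' @export
partition_all_lines <- function(loci, segments) {
  do.call(rbind, lapply(seq_len(nrow(segments)), function(i) {
    partition_cis_trans(loci, segments[i, , drop = FALSE])
  }))
}

# Pearson correlation between a per-line count and segment size, shared by
# the cis-count and trans-DEM size correlations.
size_correlation <- function(counts, sizes) {
  n <- length(counts)
  if (n != length(sizes)) stop("counts and sizes must be parallel vectors")
  if (n < 3) stop("correlation undefined for fewer than 3 lines")
  ct <- stats::cor.test(counts, sizes, method = "pearson",
                        alternative = "two.sided")
  list(R = unname(ct$estimate), P = ct$p.value, n = n)
}

#' Correlate per-line cis feature counts with segment sizes
#'
#' Tests whether larger varied segments carry more cis features
#' (Pearson, two-sided). Segment length is `end - start + 1` bp.
#'
#' @param labels data.frame of cis/trans labels over all lines, as from
#'   [partition_all_lines()].
#' @param segments Segment definition data.frame.
#' @return list with `R`, `P`, `n`.
#' @export
cis_count_size_correlation <- function(labels, segments) {
  counts <- vapply(segments$line_id, function(l) {
    sum(labels$line_id == l & labels$label == "cis")
  }, numeric(1))
  sizes <- segments$end - segments$start + 1
  size_correlation(counts, sizes)
}

#' Correlate per-line DEM counts with segment sizes
#'
#' @param dem_counts Named numeric vector: number of differentially expressed
#'   features per line.
#' @param segments Segment definition data.frame; rows are matched to
#'   `dem_counts` by `line_id`.
#' @return list with `R`, `P`, `n`.
#' @export
dem_size_correlation <- function(dem_counts, segments) {
  i <- match(names(dem_counts), segments$line_id)
  if (anyNA(i)) stop("dem_counts names must match segment line_ids")
  sizes <- segments$end[i] - segments$start[i] + 1
  size_correlation(as.numeric(dem_counts), sizes)
}
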