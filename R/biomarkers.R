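#' Configuration of the genomic biomarker rules
#'
#' Houses the decision thresholds of every per-sample biomarker: TMB
#' very-high cutoff (10 mut/Mb, inclusive), hypermutation (at least 100
#' non-silent SNVs + coding indels), HRD class boundaries (low <= 10,
#' intermediate 11-20, high > 20), MSI score cutoff (strictly above 3.5),
#' the germline alt-read support fraction (1/30), the LOH-HRD and LST
#' segment-length rules, mutational-catalog normalization constants
#' (2800 Mb for WGS, 30 Mb for WES, minimum 50 SNVs) and the viral
#' detection thresholds of the three callers with their two-method
#' consensus rule.
#'
#' @param tmb_very_high_cutoff Mutations/Mb at or above which TMB is
#'   flagged very high.
#' @param hypermutation_cutoff Total mutation count defining
#'   hypermutation.
#' @param hrd_low_max,hrd_intermediate_max Upper bounds of the low and
#'   intermediate HRD classes.
#' @param msi_cutoff MSI score strictly above which a sample is MSI.
#' @param germline_fraction Minimum control alt-allele fraction calling a
#'   variant germline.
#' @param loh_min_mb Minimum merged LOH run length (Mb, strict).
#' @param lst_min_segment_mb Minimum flanking segment length at an LST
#'   breakpoint (Mb).
#' @param lst_filter_below_mb Segments shorter than this (Mb) are removed
#'   before LST counting.
#' @param catalog_norm_wgs_mb,catalog_norm_wes_mb,catalog_min_snvs
#'   Mutational-catalog normalization lengths and exclusion floor.
#' @param viral List of viral-caller thresholds; see defaults.
#' @return A list of class `cup_biomarker_config`.
#' @export
biomarker_config <- function(tmb_very_high_cutoff = 10,
                             hypermutation_cutoff = 100,
                             hrd_low_max = 10,
                             hrd_intermediate_max = 20,
                             msi_cutoff = 3.5,
                             germline_fraction = 1 / 30,
                             loh_min_mb = 15,
                             lst_min_segment_mb = 10,
                             lst_filter_below_mb = 3,
                             catalog_norm_wgs_mb = 2800,
                             catalog_norm_wes_mb = 30,
                             catalog_min_snvs = 50,
                             viral = list(kraken_reads_per_40m = 1,
                                          kraken_genome_frac = 0.10,
                                          pdip_reads_per_1m = 1,
                                          arriba_genome_frac = 0.05,
                                          arriba_min_bp = 100,
                                          consensus_min_methods = 2)) {
  for (nm in c("tmb_very_high_cutoff", "hypermutation_cutoff", "hrd_low_max",
               "hrd_intermediate_max", "msi_cutoff", "germline_fraction",
               "loh_min_mb", "lst_min_segment_mb", "lst_filter_below_mb",
               "catalog_norm_wgs_mb", "catalog_norm_wes_mb",
               "catalog_min_snvs")) {
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  if (hrd_low_max >= hrd_intermediate_max) {
    stop_config("`hrd_low_max` must be below `hrd_intermediate_max`")
  }
  structure(list(
    tmb_very_high_cutoff = tmb_very_high_cutoff,
    hypermutation_cutoff = hypermutation_cutoff,
    hrd_low_max = hrd_low_max, hrd_intermediate_max = hrd_intermediate_max,
    msi_cutoff = msi_cutoff, germline_fraction = germline_fraction,
    loh_min_mb = loh_min_mb, lst_min_segment_mb = lst_min_segment_mb,
    lst_filter_below_mb = lst_filter_below_mb,
    catalog_norm_wgs_mb = catalog_norm_wgs_mb,
    catalog_norm_wes_mb = catalog_norm_wes_mb,
    catalog_min_snvs = catalog_min_snvs, viral = viral),
    class = "cup_biomarker_config")
}

intervals_to_gr <- function(x) {
  GenomicRanges::GRanges(x$chromosome,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' Total coding length in megabases
#'
#' Merges (unions) the CDS intervals, optionally intersects the union
#' with the union of the capture target intervals (the exome TMB
#' denominator), and returns the total covered bases divided by 1e6.
#' All intervals use the package's 0-based half-open convention.
#'
#' @param cds_intervals Tibble with `chromosome`, `start`, `end`.
#' @param capture_intervals Optional tibble in the same shape.
#' @return Length in Mb (0 for an empty CDS set).
#' @export
coding_length_mb <- function(cds_intervals, capture_intervals = NULL) {
  if (is.null(cds_intervals) || nrow(cds_intervals) == 0L) return(0)
  gr <- GenomicRanges::reduce(intervals_to_gr(cds_intervals))
  if (!is.null(capture_intervals) && nrow(capture_intervals) > 0L) {
    cap <- GenomicRanges::reduce(intervals_to_gr(capture_intervals))
    gr <- GenomicRanges::intersect(gr, cap)
  }
  sum(as.numeric(GenomicRanges::width(gr))) / 1e6
}

#' Tumor mutational burden
#'
#' TMB is the number of non-silent SNVs plus coding indels divided by the
#' coding-sequence length in Mb (from [coding_length_mb()]; the
#' denominator depends on the sequencing platform and capture kit). A
#' burden at or above the very-high cutoff (default 10 mut/Mb) is
#' flagged.
#'
#' @param n_nonsilent_snv,n_coding_indel Nonnegative mutation counts.
#' @param length_mb Coding length in Mb (> 0).
#' @param config A [biomarker_config()].
#' @return Tibble with `tmb` and `very_high_tmb`.
#' @export
compute_tmb <- function(n_nonsilent_snv, n_coding_indel, length_mb,
                        config = biomarker_config()) {
  check_number(n_nonsilent_snv, "n_nonsilent_snv", lower = 0)
  check_number(n_coding_indel, "n_coding_indel", lower = 0)
  if (!is.numeric(length_mb) || length_mb <= 0) {
    stop_input("`length_mb` must be positive")
  }
  tmb <- (n_nonsilent_snv + n_coding_indel) / length_mb
  tibble(tmb = tmb, very_high_tmb = tmb >= config$tmb_very_high_cutoff)
}

#' Hypermutation flag
#'
#' A sample is hypermutated when it carries at least 100 (by default)
#' non-silent SNVs plus coding indels in total, independent of the
#' sequencing footprint.
#'
#' @inheritParams compute_tmb
#' @return Logical.
#' @export
flag_hypermutation <- function(n_nonsilent_snv, n_coding_indel,
                               config = biomarker_config()) {
  check_number(n_nonsilent_snv, "n_nonsilent_snv", lower = 0)
  check_number(n_coding_indel, "n_coding_indel", lower = 0)
  (n_nonsilent_snv + n_coding_indel) >= config$hypermutation_cutoff
}

check_segments_cn <- function(segments) {
  if (!all(c("cn_major", "cn_minor") %in% names(segments)) ||
      anyNA(segments$cn_major) || anyNA(segments$cn_minor)) {
    stop_input("segments must carry complete allele-specific copy numbers")
  }
  segments
}

#' LOH-HRD score
#'
#' Counts maximal runs of loss of heterozygosity (minor copy number 0
#' with at least one retained major copy) whose merged length exceeds
#' 15 Mb, excluding runs that span their entire chromosome. Consecutive
#' LOH segments on a chromosome are merged into one run.
#'
#' @param segments Tibble with `chromosome`, `start`, `end`, `cn_major`,
#'   `cn_minor`.
#' @param chromosome_lengths Named numeric vector of chromosome lengths
#'   (bases), used for the whole-chromosome exclusion; a run is taken to
#'   span the chromosome when it covers the full stated length (or, if
#'   the chromosome is absent from the vector, the full extent of its
#'   segments).
#' @param config A [biomarker_config()].
#' @return Integer score.
#' @export
loh_hrd_score <- function(segments, chromosome_lengths = NULL,
                          config = biomarker_config()) {
  check_segments_cn(segments)
  if (nrow(segments) == 0L) return(0L)
  score <- 0L
  for (chr in unique(segments$chromosome)) {
    s <- segments[segments$chromosome == chr, ]
    s <- s[order(s$start), ]
    chr_len <- if (!is.null(chromosome_lengths) && chr %in% names(chromosome_lengths)) {
      chromosome_lengths[[chr]]
    } else {
      max(s$end) - min(s$start)
    }
    is_loh <- s$cn_minor == 0 & s$cn_major >= 1
    runs <- rle(is_loh)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (j in which(runs$values)) {
      run_len <- sum(s$end[starts[j]:ends[j]] - s$start[starts[j]:ends[j]])
      spans_chr <- (s$end[ends[j]] - s$start[starts[j]]) >= chr_len
      if (run_len > config$loh_min_mb * 1e6 && !spans_chr) {
        score <- score + 1L
      }
    }
  }
  score
}

#' Large-scale state transition (LST) score
#'
#' Per chromosome: segments shorter than 3 Mb are removed (smoothing),
#' neighbouring segments with equal total copy number are merged, and
#' every remaining breakpoint whose two flanking segments are each at
#' least 10 Mb long counts as one LST.
#'
#' @param segments Tibble with `chromosome`, `start`, `end` and either
#'   `cn_major`/`cn_minor` or a `cn_total` column.
#' @param chromosome_lengths Unused placeholder for API symmetry.
#' @param config A [biomarker_config()].
#' @return Integer score.
#' @export
lst_score <- function(segments, chromosome_lengths = NULL,
                      config = biomarker_config()) {
  if (nrow(segments) == 0L) return(0L)
  total <- if ("cn_total" %in% names(segments)) {
    segments$cn_total
  } else {
    check_segments_cn(segments)
    segments$cn_major + segments$cn_minor
  }
  segments$.total <- total
  score <- 0L
  for (chr in unique(segments$chromosome)) {
    s <- segments[segments$chromosome == chr, ]
    s <- s[order(s$start), ]
    s <- s[(s$end - s$start) >= config$lst_filter_below_mb * 1e6, ]
    if (nrow(s) < 2L) next
    # merge equal-CN neighbours, accumulating their lengths
    len <- s$end - s$start
    keep_len <- numeric(0)
    keep_cn <- numeric(0)
    for (i in seq_len(nrow(s))) {
      if (length(keep_cn) && keep_cn[length(keep_cn)] == s$.total[i]) {
        keep_len[length(keep_len)] <- keep_len[length(keep_len)] + len[i]
      } else {
        keep_len <- c(keep_len, len[i])
        keep_cn <- c(keep_cn, s$.total[i])
      }
    }
    if (length(keep_len) < 2L) next
    min_bp <- config$lst_min_segment_mb * 1e6
    for (i in seq_len(length(keep_len) - 1L)) {
      if (keep_len[i] >= min_bp && keep_len[i + 1L] >= min_bp) {
        score <- score + 1L
      }
    }
  }
  score
}

#' HRD composite score and class
#'
#' The unweighted sum of LOH-HRD and LST classifies a sample as low
#' (<= 10), intermediate (11-20) or high (> 20) homologous recombination
#' deficiency.
#'
#' @param loh_hrd,lst Nonnegative integer component scores.
#' @param config A [biomarker_config()].
#' @return Tibble with `loh_hrd`, `lst`, `hrd_sum`, `hrd_class`.
#' @export
classify_hrd <- function(loh_hrd, lst, config = biomarker_config()) {
  check_number(loh_hrd, "loh_hrd", lower = 0)
  check_number(lst, "lst", lower = 0)
  s <- loh_hrd + lst
  cls <- if (s <= config$hrd_low_max) "low"
         else if (s <= config$hrd_intermediate_max) "intermediate"
         else "high"
  tibble(loh_hrd = loh_hrd, lst = lst, hrd_sum = s, hrd_class = cls)
}

#' Microsatellite instability call
#'
#' A sample is MSI when its instability score (fraction of unstable
#' microsatellite loci, as emitted by an MSIsensor-style caller) is
#' strictly greater than 3.5; otherwise MSS.
#'
#' @param msi_score Nonnegative score.
#' @param config A [biomarker_config()].
#' @return `"MSI"` or `"MSS"`.
#' @export
classify_msi <- function(msi_score, config = biomarker_config()) {
  if (!is.numeric(msi_score) || is.na(msi_score) || msi_score < 0) {
    stop_input("`msi_score` must be a nonnegative number")
  }
  if (msi_score > config$msi_cutoff) "MSI" else "MSS"
}

#' Germline-support flag for a tumor variant
#'
#' A variant found in the tumor is annotated as germline when the control
#' sample supports the alternative allele with at least 1/30 of its
#' reads.
#'
#' @param control_alt_reads,control_depth Read counts in the control.
#' @param config A [biomarker_config()].
#' @return Logical.
#' @export
flag_germline <- function(control_alt_reads, control_depth,
                          config = biomarker_config()) {
  check_number(control_alt_reads, "control_alt_reads", lower = 0)
  check_number(control_depth, "control_depth", lower = 0)
  if (control_alt_reads > control_depth) {
    stop_input("`control_alt_reads` cannot exceed `control_depth`")
  }
  control_depth > 0 &&
    control_alt_reads / control_depth >= config$germline_fraction
}

#' Normalize a 96-channel mutational catalog
#'
#' Divides each trinucleotide channel by the average coding-sequence
#' length in Mb of the sequencing platform (2800 for WGS, 30 for WES) so
#' catalogs from both platforms can be merged for signature
#' decomposition. Samples with fewer than 50 SNVs in total are excluded
#' rather than normalized.
#'
#' @param mutation_counts Numeric vector of 96 nonnegative channel
#'   counts.
#' @param platform `"WGS"`, `"WES_v5"` or `"WES_v5_UTR"`.
#' @param config A [biomarker_config()].
#' @return List with `excluded` (logical), `n_snvs`, and `catalog` (the
#'   normalized vector, or `NULL` when excluded).
#' @export
normalize_catalog <- function(mutation_counts,
                              platform = c("WGS", "WES_v5", "WES_v5_UTR"),
                              config = biomarker_config()) {
  platform <- match.arg(platform)
  if (length(mutation_counts) != 96L) {
    stop_input(sprintf("catalog must have 96 channels, got %d",
                       length(mutation_counts)))
  }
  if (any(mutation_counts < 0)) stop_input("negative channel count")
  n <- sum(mutation_counts)
  if (n < config$catalog_min_snvs) {
    return(list(excluded = TRUE, n_snvs = n, catalog = NULL))
  }
  denom <- if (platform == "WGS") config$catalog_norm_wgs_mb
           else config$catalog_norm_wes_mb
  list(excluded = FALSE, n_snvs = n, catalog = mutation_counts / denom)
}

#' Multi-method viral detection consensus
#'
#' Combines per-method viral detection summaries. The k-mer caller
#' (kraken) passes when it sees at least one viral read per 40 million
#' mapped reads and at least 10% of the viral genome covered; the
#' assembly caller (pdip) when it sees at least one viral read per
#' million mapped reads; the alignment caller (arriba) when at least 5%
#' of the viral genome and 100 bp - whichever is bigger - are covered. A
#' virus is reported when at least two methods pass.
#'
#' @param detections Tibble with columns `virus`, `method` (one of
#'   `"kraken"`, `"pdip"`, `"arriba"`), `viral_reads`,
#'   `total_mapped_reads`, `genome_frac_covered`, `bp_covered`,
#'   `genome_length`.
#' @param config A [biomarker_config()].
#' @return List with `reported` (character vector of virus names) and
#'   `detail` (tibble with per-method `passes` flags and per-virus
#'   `n_methods_passed`).
#' @export
viral_consensus <- function(detections, config = biomarker_config()) {
  d <- as_tibble(detections)
  need <- c("virus", "method", "viral_reads", "total_mapped_reads",
            "genome_frac_covered", "bp_covered", "genome_length")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_input(sprintf("detections missing columns: %s",
                       paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(d$method), c("kraken", "pdip", "arriba"))
  if (length(bad)) stop_input(sprintf("unknown method '%s'", bad[1L]))
  if (any(d$total_mapped_reads <= 0)) {
    stop_input("total_mapped_reads must be positive")
  }
  v <- config$viral
  rate <- d$viral_reads / d$total_mapped_reads
  d$passes <- dplyr::case_when(
    d$method == "kraken" ~ rate >= v$kraken_reads_per_40m / 4e7 &
      d$genome_frac_covered >= v$kraken_genome_frac,
    d$method == "pdip" ~ rate >= v$pdip_reads_per_1m / 1e6,
    d$method == "arriba" ~ d$bp_covered >=
      pmax(v$arriba_genome_frac * d$genome_length, v$arriba_min_bp)
  )
  per_virus <- d |>
    dplyr::group_by(.data$virus) |>
    dplyr::summarise(n_methods_passed = sum(.data$passes), .groups = "drop")
  reported <- sort(per_virus$virus[per_virus$n_methods_passed >=
                                     v$consensus_min_methods])
  list(reported = reported,
       detail = dplyr::left_join(d, per_virus, by = "virus"))
}

#' Assemble a per-sample biomarker report
#'
#' Bundles TMB, hypermutation, HRD, MSI and viral consensus for one
#' sample into a single one-row tibble.
#'
#' @param sample_id Sample identifier.
#' @param n_nonsilent_snv,n_coding_indel Mutation counts.
#' @param length_mb Coding length denominator (Mb).
#' @param segments Allele-specific copy-number segments (or `NULL` to
#'   skip HRD).
#' @param msi_score MSI score (or `NA` to skip).
#' @param viral_detections Per-method viral detections (or `NULL`).
#' @param chromosome_lengths Passed to [loh_hrd_score()].
#' @param config A [biomarker_config()].
#' @return One-row tibble of class `cup_biomarker_report`.
#' @export
biomarker_report <- function(sample_id, n_nonsilent_snv, n_coding_indel,
                             length_mb, segments = NULL, msi_score = NA,
                             viral_detections = NULL,
                             chromosome_lengths = NULL,
                             config = biomarker_config()) {
  tmb_res <- compute_tmb(n_nonsilent_snv, n_coding_indel, length_mb, config)
  hrd <- if (!is.null(segments)) {
    classify_hrd(loh_hrd_score(segments, chromosome_lengths, config),
                 lst_score(segments, chromosome_lengths, config), config)
  } else {
    tibble(loh_hrd = NA_integer_, lst = NA_integer_,
           hrd_sum = NA_integer_, hrd_class = NA_character_)
  }
  viruses <- if (!is.null(viral_detections)) {
    paste(viral_consensus(viral_detections, config)$reported, collapse = ",")
  } else NA_character_
  out <- tibble(
    sample_id = sample_id,
    tmb = tmb_res$tmb, very_high_tmb = tmb_res$very_high_tmb,
    hypermutated = flag_hypermutation(n_nonsilent_snv, n_coding_indel, config),
    loh_hrd = hrd$loh_hrd, lst = hrd$lst, hrd_sum = hrd$hrd_sum,
    hrd_class = hrd$hrd_class,
    msi_class = if (is.na(msi_score)) NA_character_
                else classify_msi(msi_score, config),
    viruses_reported = viruses)
  class(out) <- c("cup_biomarker_report", class(out))
  out
}
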