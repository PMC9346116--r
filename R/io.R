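#' Read and write feature-by-sample matrices
#'
#' Strict TSV readers/writers for expression (FPKM, genes x samples) and
#' methylation (beta values, probes x samples) matrices. Readers validate
#' instead of coercing: negative FPKM, beta values outside \[0, 1\],
#' duplicated gene/probe or sample identifiers and ragged rows are
#' rejected with the offending line number. Missing beta cells may be
#' empty or `NA`; FPKM has no missing state.
#'
#' @param path File path of a tab-separated matrix with a header row of
#'   sample identifiers and the feature identifier in the first column.
#' @return A numeric matrix with feature rownames and sample colnames.
#' @name io_matrix
NULL

read_feature_matrix <- function(path, what = c("fpkm", "beta")) {
  what <- match.arg(what)
  lines <- readLines(path)
  if (length(lines) < 1L) stop_format(sprintf("%s: empty file", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- length(fields[[1L]])
  samples <- fields[[1L]][-1L]
  if (anyDuplicated(samples)) {
    stop_format(sprintf("%s: duplicated sample ids in header", path))
  }
  body <- fields[-1L]
  n <- length(body)
  ids <- character(n)
  vals <- matrix(NA_real_, n, length(samples))
  for (i in seq_len(n)) {
    row <- body[[i]]
    if (length(row) != ncol) {
      stop_format(sprintf("%s: line %d has %d fields, expected %d",
                          path, i + 1L, length(row), ncol))
    }
    ids[i] <- row[1L]
    cells <- row[-1L]
    missing <- cells == "" | cells == "NA"
    x <- suppressWarnings(as.numeric(cells))
    if (any(is.na(x) & !missing)) {
      stop_format(sprintf("%s: line %d: non-numeric value", path, i + 1L))
    }
    if (what == "fpkm") {
      if (any(missing)) {
        stop_format(sprintf("%s: line %d: missing FPKM not allowed", path, i + 1L))
      }
      if (any(x < 0)) {
        stop_format(sprintf("%s: line %d: negative FPKM", path, i + 1L))
      }
    } else {
      bad <- !is.na(x) & (x < 0 | x > 1)
      if (any(bad)) {
        stop_format(sprintf("%s: line %d: beta value outside [0, 1]", path, i + 1L))
      }
    }
    vals[i, ] <- x
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop_format(sprintf("%s: duplicated feature id '%s'", path, dup))
  }
  dimnames(vals) <- list(ids, samples)
  vals
}

#' @rdname io_matrix
#' @export
read_expression_matrix <- function(path) read_feature_matrix(path, "fpkm")

#' @rdname io_matrix
#' @export
read_beta_matrix <- function(path) read_feature_matrix(path, "beta")

write_feature_matrix <- function(x, path, id_col) {
  check_matrix(x, "x")
  cells <- format(x, trim = TRUE, digits = 15)
  cells[is.na(x)] <- "NA"
  lines <- c(paste(c(id_col, colnames(x)), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i) {
               paste(c(rownames(x)[i], cells[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname io_matrix
#' @param x Numeric matrix to write.
#' @export
write_expression_matrix <- function(x, path) {
  if (any(is.na(x)) || any(x < 0)) stop_input("FPKM must be nonnegative and complete")
  write_feature_matrix(x, path, "gene_id")
}

#' @rdname io_matrix
#' @export
write_beta_matrix <- function(x, path) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) stop_input("beta values must be in [0, 1]")
  write_feature_matrix(x, path, "probe_id")
}

#' Read and write copy-number segment tables
#'
#' SEG-like tab-separated tables with 0-based half-open coordinates and
#' columns `chromosome`, `start`, `end`, `coverage_ratio`, `baf`,
#' `n_het_snps` and optional `cn_major`/`cn_minor`.
#'
#' @param path File path.
#' @return A tibble of segments.
#' @export
read_segments <- function(path) {
  seg <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chromosome", "start", "end", "coverage_ratio", "baf", "n_het_snps")
  miss <- setdiff(need, names(seg))
  if (length(miss)) {
    stop_format(sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")))
  }
  bad <- which(seg$end <= seg$start)
  if (length(bad)) {
    stop_format(sprintf("%s: line %d: end <= start", path, bad[1L] + 1L))
  }
  if (any(seg$baf < 0 | seg$baf > 0.5, na.rm = TRUE)) {
    stop_format(sprintf("%s: BAF outside [0, 0.5]", path))
  }
  if (any(seg$coverage_ratio <= 0, na.rm = TRUE)) {
    stop_format(sprintf("%s: nonpositive coverage ratio", path))
  }
  as_tibble(seg)
}

#' @rdname read_segments
#' @param segments Tibble of segments to write.
#' @export
write_segments <- function(segments, path) {
  readr::write_tsv(segments, path, progress = FALSE)
  invisible(path)
}

#' Read genomic intervals from BED or GTF
#'
#' Internal coordinates are 0-based half-open throughout the package. BED
#' input is already in that convention; GTF (GENCODE dialect, 1-based
#' inclusive) is converted at the boundary, so a GTF feature `1..100`
#' becomes the interval `(0, 100)` of length 100. Parsing goes through
#' \pkg{rtracklayer}.
#'
#' @param path Path to a `.bed`, `.gtf` or `.gff` file.
#' @param feature_filter Optional GTF feature type to keep (e.g. `"CDS"`);
#'   ignored for BED input.
#' @return Tibble with `chromosome`, `start`, `end` (0-based half-open).
#'   A GTF with no matching features yields an empty tibble, not an error.
#' @export
read_intervals <- function(path, feature_filter = NULL) {
  is_gtf <- grepl("\\.(gtf|gff[3]?)$", path, ignore.case = TRUE)
  gr <- if (is_gtf) {
    rtracklayer::import(path, format = "gtf")
  } else {
    rtracklayer::import(path, format = "bed")
  }
  if (is_gtf && !is.null(feature_filter)) {
    gr <- gr[as.character(gr$type) %in% feature_filter]
  }
  if (length(gr) == 0L) {
    return(tibble(chromosome = character(), start = integer(), end = integer()))
  }
  out <- tibble(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    # GRanges are 1-based inclusive internally for both formats
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr))
  bad <- which(out$end <= out$start)
  if (length(bad)) {
    stop_format(sprintf("%s: interval %d has end <= start", path, bad[1L]))
  }
  out
}

clinical_roles <- c("pre_mtb_last", "recommended_first",
                    "recommended_later", "post_mtb_other")

#' Read and write clinical therapy-line tables
#'
#' CSV with columns `patient_id`, `line_role` (one of `pre_mtb_last`,
#' `recommended_first`, `recommended_later`, `post_mtb_other`),
#' `start_date`, `event_date` (ISO-8601; may be empty for censored
#' lines) and `event_type` (`progression`, `death` or `censored`).
#'
#' @param path File path.
#' @return Tibble of therapy lines with `Date` columns.
#' @export
read_clinical <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  need <- c("patient_id", "line_role", "start_date", "event_date", "event_type")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop_format(sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")))
  }
  bad_role <- setdiff(unique(x$line_role), clinical_roles)
  if (length(bad_role)) {
    stop_format(sprintf("%s: unknown line_role '%s'", path, bad_role[1L]))
  }
  bad_ev <- setdiff(unique(x$event_type), c("progression", "death", "censored"))
  if (length(bad_ev)) {
    stop_format(sprintf("%s: unknown event_type '%s'", path, bad_ev[1L]))
  }
  parse_date <- function(s, col) {
    s[!is.na(s) & s == ""] <- NA_character_
    d <- as.Date(s, format = "%Y-%m-%d")
    if (any(is.na(d) & !is.na(s))) {
      stop_format(sprintf("%s: unparseable %s '%s'", path, col,
                          s[which(is.na(d) & !is.na(s))[1L]]))
    }
    d
  }
  out <- tibble(
    patient_id = x$patient_id,
    line_role = x$line_role,
    start_date = parse_date(x$start_date, "start_date"),
    event_date = parse_date(x$event_date, "event_date"),
    event_type = x$event_type)
  if (any(is.na(out$start_date))) {
    stop_format(sprintf("%s: missing start_date", path))
  }
  bad <- which(!is.na(out$event_date) & out$event_date < out$start_date)
  if (length(bad)) {
    stop_format(sprintf("%s: line %d: event_date before start_date", path, bad[1L] + 1L))
  }
  out
}

#' @rdname read_clinical
#' @param lines Tibble of therapy lines to write.
#' @export
write_clinical <- function(lines, path) {
  readr::write_csv(lines, path, progress = FALSE)
  invisible(path)
}
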