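iv <- function(chrom, start, end) {
  tibble::tibble(chromosome = chrom, start = start, end = end)
}

test_that("coding length merges unions and intersects capture targets", {
  # overlapping intervals merge to one 2-Mb stretch
  expect_equal(coding_length_mb(iv("chr1", c(0, 5e5), c(1e6, 2e6))), 2.0)
  # CDS (50, 150) restricted to capture (0, 100) leaves 50 bp
  expect_equal(coding_length_mb(iv("chr1", 50, 150), iv("chr1", 0, 100)),
               0.00005)
  expect_equal(coding_length_mb(iv(character(), integer(), integer())), 0)
  expect_equal(coding_length_mb(NULL), 0)
})

test_that("coding length is idempotent, order-invariant and subadditive", {
  set.seed(4)
  a <- iv("chr1", s <- sort(sample(0:1e6, 20)), s + sample(1e3:1e5, 20, TRUE))
  b <- iv("chr1", s2 <- sort(sample(0:1e6, 15)), s2 + sample(1e3:1e5, 15, TRUE))
  la <- coding_length_mb(a)
  expect_equal(coding_length_mb(a[sample(nrow(a)), ]), la)
  expect_equal(coding_length_mb(dplyr::bind_rows(a, a)), la)
  expect_lte(coding_length_mb(dplyr::bind_rows(a, b)),
             la + coding_length_mb(b))
})

test_that("TMB divides mutation counts by the platform coding length", {
  expect_equal(compute_tmb(0, 0, 35.334619)$tmb, 0)
  expect_false(compute_tmb(0, 0, 35.334619)$very_high_tmb)

  # 354 mutations over the genome-wide coding footprint crosses 10/Mb
  t1 <- compute_tmb(354, 0, 35.334619)
  expect_equal(t1$tmb, 354 / 35.334619, tolerance = 1e-12)
  expect_gt(t1$tmb, 10)
  expect_true(t1$very_high_tmb)

  # 353 stays just below
  t2 <- compute_tmb(300, 53, 35.334619)
  expect_equal(t2$tmb, 353 / 35.334619, tolerance = 1e-12)
  expect_lt(t2$tmb, 10)
  expect_false(t2$very_high_tmb)

  expect_error(compute_tmb(1, 1, 0), class = "cupcompass_input_error")
})

test_that("hypermutation is at least 100 total mutations", {
  expect_true(flag_hypermutation(100, 0))
  expect_true(flag_hypermutation(60, 40))
  expect_false(flag_hypermutation(99, 0))
  expect_false(flag_hypermutation(0, 0))
})

test_that("LOH-HRD counts long sub-chromosomal LOH runs", {
  lens <- c(chr1 = 1e8)
  seg <- function(start, end, maj, min, chrom = "chr1") {
    tibble::tibble(chromosome = chrom, start = start, end = end,
                   cn_major = maj, cn_minor = min)
  }
  # no LOH at all
  expect_equal(loh_hrd_score(seg(0, 1e8, 2, 1), lens), 0)
  # one 20-Mb LOH region inside a 100-Mb chromosome
  s <- dplyr::bind_rows(seg(0, 4e7, 2, 1), seg(4e7, 6e7, 1, 0),
                        seg(6e7, 1e8, 2, 1))
  expect_equal(loh_hrd_score(s, lens), 1)
  # LOH covering the whole chromosome contributes nothing
  expect_equal(loh_hrd_score(seg(0, 1e8, 1, 0), lens), 0)
  # short LOH (10 Mb) below the 15-Mb bar
  s2 <- dplyr::bind_rows(seg(0, 4e7, 2, 1), seg(4e7, 5e7, 1, 0),
                         seg(5e7, 1e8, 2, 1))
  expect_equal(loh_hrd_score(s2, lens), 0)
  # adjacent LOH segments merge into one run, counted once
  s3 <- dplyr::bind_rows(seg(0, 4e7, 2, 1), seg(4e7, 5e7, 1, 0),
                         seg(5e7, 6e7, 2, 0), seg(6e7, 1e8, 2, 1))
  expect_equal(loh_hrd_score(s3, lens), 1)
  expect_error(loh_hrd_score(seg(0, 1e8, NA, NA), lens),
               class = "cupcompass_input_error")
})

test_that("LST counts breakpoints between long segments after 3-Mb smoothing", {
  seg <- function(start, end, total, chrom = "chr1") {
    tibble::tibble(chromosome = chrom, start = start, end = end,
                   cn_total = total)
  }
  # one segment per chromosome: no breakpoints
  expect_equal(lst_score(dplyr::bind_rows(seg(0, 5e7, 2),
                                          seg(0, 5e7, 3, "chr2"))), 0)
  # two adjacent 12-Mb segments with different copy number
  two <- dplyr::bind_rows(seg(0, 1.2e7, 2), seg(1.2e7, 2.4e7, 3))
  expect_equal(lst_score(two), 1)
  # a 2-Mb interloper is filtered out, the transition still counts
  three <- dplyr::bind_rows(seg(0, 1.2e7, 2), seg(1.2e7, 1.4e7, 5),
                            seg(1.4e7, 2.6e7, 3))
  expect_equal(lst_score(three), 1)
  # equal-CN neighbours merge: no transition left
  merged <- dplyr::bind_rows(seg(0, 1.2e7, 2), seg(1.2e7, 2.4e7, 2))
  expect_equal(lst_score(merged), 0)
  # a short flanking segment (5 Mb) blocks the count
  short <- dplyr::bind_rows(seg(0, 5e6, 2), seg(5e6, 1.7e7, 3))
  expect_equal(lst_score(short), 0)
})

test_that("HRD classes partition the score range at the printed boundaries", {
  for (s in 0:40) {
    cls <- classify_hrd(s, 0)$hrd_class
    expected <- if (s <= 10) "low" else if (s <= 20) "intermediate" else "high"
    expect_equal(cls, expected)
  }
  expect_equal(classify_hrd(5, 5)$hrd_class, "low")         # sum 10
  expect_equal(classify_hrd(10, 10)$hrd_class, "intermediate")  # sum 20
  expect_equal(classify_hrd(15, 6)$hrd_class, "high")       # sum 21
  expect_equal(classify_hrd(7, 9)$hrd_sum, 16)
})

test_that("MSI is called strictly above 3.5", {
  expect_equal(classify_msi(3.5), "MSS")
  expect_equal(classify_msi(3.6), "MSI")
  expect_equal(classify_msi(0), "MSS")
  expect_error(classify_msi(-1), class = "cupcompass_input_error")
})

test_that("germline support requires an alt fraction of at least 1/30", {
  expect_true(flag_germline(1, 30))
  expect_false(flag_germline(0, 100))
  expect_false(flag_germline(1, 60))
  expect_true(flag_germline(4, 100))
  expect_false(flag_germline(0, 0))
  expect_error(flag_germline(5, 3), class = "cupcompass_input_error")
})

test_that("catalog normalization divides by platform length or excludes", {
  uniform <- rep(1, 96)
  wes <- normalize_catalog(uniform, "WES_v5")
  expect_false(wes$excluded)
  expect_equal(wes$catalog, rep(1 / 30, 96))
  wgs <- normalize_catalog(uniform * 2, "WGS")
  expect_equal(wgs$catalog, rep(2 / 2800, 96))

  low <- c(rep(1, 49), rep(0, 47))
  expect_true(normalize_catalog(low, "WGS")$excluded)
  expect_true(normalize_catalog(rep(0, 96), "WES_v5")$excluded)
  expect_error(normalize_catalog(rep(1, 95), "WGS"),
               class = "cupcompass_input_error")
})

test_that("viral consensus needs two passing methods and is monotone", {
  det <- function(kraken_reads, pdip_reads, arriba_bp,
                  frac = 0.12, mapped = 4e7, glen = 8000) {
    tibble::tibble(
      virus = "HPV16",
      method = c("kraken", "pdip", "arriba"),
      viral_reads = c(kraken_reads, pdip_reads, 0),
      total_mapped_reads = mapped,
      genome_frac_covered = frac,
      bp_covered = c(0, 0, arriba_bp),
      genome_length = glen)
  }
  # kraken passes (2 reads / 40M, 12% covered), arriba passes (420 bp >
  # max(400, 100)), pdip fails (2 reads < 40 per 40M mapped)
  hit <- viral_consensus(det(2, 2, 420))
  expect_equal(hit$reported, "HPV16")
  expect_equal(sum(hit$detail$passes), 2)

  # only one method passing is not reported
  expect_length(viral_consensus(det(2, 2, 50))$reported, 0)
  # nothing detected
  expect_length(viral_consensus(det(0, 0, 0, frac = 0))$reported, 0)

  # monotonicity: more reads/coverage never removes a reported virus
  base <- det(2, 2, 420)
  more <- base
  more$viral_reads <- more$viral_reads * 10
  more$bp_covered <- more$bp_covered + 1000
  expect_true(all(viral_consensus(base)$reported %in%
                    viral_consensus(more)$reported))

  # the 100-bp floor dominates for tiny genomes: 5% of 1000 = 50 < 100
  tiny <- det(0, 2, 99, glen = 1000)
  expect_false(viral_consensus(tiny)$detail$passes[3])
  tiny$bp_covered[3] <- 100
  expect_true(viral_consensus(tiny)$detail$passes[3])

  bad <- det(1, 1, 1)
  bad$method[1] <- "blast"
  expect_error(viral_consensus(bad), class = "cupcompass_input_error")
})

test_that("biomarker reports bundle all calls for a sample", {
  seg <- sim_cna_segments(tiny_config())
  rep <- biomarker_report("S1", 120, 5, 35.334619, segments = seg,
                          msi_score = 4.0)
  expect_s3_class(rep, "cup_biomarker_report")
  expect_true(rep$hypermutated)
  expect_equal(rep$msi_class, "MSI")
  expect_equal(rep$hrd_sum, rep$loh_hrd + rep$lst)
  expect_true(rep$hrd_class %in% c("low", "intermediate", "high"))
})
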