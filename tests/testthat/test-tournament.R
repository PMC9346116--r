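make_profile <- function(values, genes = sprintf("g%d", seq_along(values))) {
  setNames(values, genes)
}

test_that("the gene universe is the shared gene set, liver-masked only for liver biopsies", {
  q <- make_profile(c(1, 2, 3, 4))
  ref <- cbind(r1 = c(1, 2, 3, 4))
  rownames(ref) <- names(q)
  colnames(ref) <- "r1"
  expect_equal(build_gene_universe(q, ref), c("g1", "g2", "g3", "g4"))
  # non-liver biopsy: liver set kept
  expect_equal(build_gene_universe(q, ref, liver_genes = "g4",
                                   biopsy_site = "lung"),
               c("g1", "g2", "g3", "g4"))
  # liver biopsy: masked
  expect_equal(build_gene_universe(q, ref, liver_genes = "g4",
                                   biopsy_site = "liver"),
               c("g1", "g2", "g3"))
  # masking disabled overrides the biopsy site
  cfg <- tournament_config(liver_mask_enabled = FALSE)
  expect_equal(build_gene_universe(q, ref, liver_genes = "g4",
                                   biopsy_site = "liver", config = cfg),
               c("g1", "g2", "g3", "g4"))
  rownames(ref) <- paste0("x", 1:4)
  expect_error(build_gene_universe(q, ref), class = "cupcompass_input_error")
})

test_that("pair similarity matches brute-force gene enumeration", {
  genes <- c("g1", "g2", "g3", "g4")
  q <- make_profile(c(20, 20, 1, 1))
  a <- make_profile(c(20, 20, 1, 1))
  b <- make_profile(c(1, 1, 20, 20))
  s <- pair_similarity(q, a, b, genes)
  expect_equal(unname(s), c(0.5, 0))
  # symmetric under swapping
  expect_equal(unname(pair_similarity(q, b, a, genes)), c(0, 0.5))
  # identical pair: no gene can be up in one and down in the other
  expect_equal(unname(pair_similarity(q, a, a, genes)), c(0, 0))
  # query below t_up everywhere
  q0 <- make_profile(c(5, 5, 5, 5))
  expect_equal(unname(pair_similarity(q0, a, b, genes)), c(0, 0))
  # neutral zone [t_down, t_up] contributes nothing
  mid <- make_profile(c(10, 10, 10, 10))
  expect_equal(unname(pair_similarity(q, a, mid, genes)), c(0, 0))
})

test_that("tournament wins are conserved and match the naive oracle exactly", {
  for (seed in 1:8) {
    ch <- random_fpkm_cohort(n_genes = 50, n_ref = sample(2:10, 1), seed)
    res <- tournament_rank(ch$query, ch$reference, ch$labels)
    expect_equal(sum(res$ranking$wins), choose(ncol(ch$reference), 2))
    oracle <- naive_tournament(ch$query, ch$reference, ch$labels)
    got <- res$ranking[order(res$ranking$sample_id), ]
    expect_equal(got$wins, unname(oracle$wins[got$sample_id]))
    expect_equal(got$similarity_sum, unname(oracle$similarity_sum[got$sample_id]),
                 tolerance = 1e-12)
    expect_equal(res$ranking$sample_id, oracle$ranking)
  }
})

test_that("a reference copy of the query wins the tournament", {
  genes <- sprintf("g%d", 1:6)
  q <- make_profile(c(20, 20, 20, 1, 1, 1), genes)
  ref <- cbind(copy = q,
               other1 = make_profile(c(1, 1, 1, 20, 20, 1), genes),
               other2 = make_profile(c(1, 1, 1, 1, 20, 20), genes))
  labels <- tibble::tibble(sample_id = colnames(ref),
                           entity = c("PAAD", "CHOL", "CHOL"),
                           is_cup = FALSE)
  res <- tournament_rank(q, ref, labels)
  expect_equal(res$ranking$sample_id[1], "copy")
  expect_equal(res$ranking$wins[res$ranking$sample_id == "copy"], 2)
  expect_equal(res$predicted_entity, "PAAD")
  expect_false(res$cup_skipped)
})

test_that("reference column order does not change wins, ranks or prediction", {
  ch <- random_fpkm_cohort(50, 8, seed = 42)
  res1 <- tournament_rank(ch$query, ch$reference, ch$labels)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  res2 <- tournament_rank(ch$query, ch$reference[, perm], ch$labels)
  expect_equal(res1$ranking, res2$ranking)
  expect_equal(res1$predicted_entity, res2$predicted_entity)
})

test_that("a CUP-labelled winner is skipped in favour of the first non-CUP sample", {
  genes <- sprintf("g%d", 1:6)
  q <- make_profile(c(20, 20, 20, 1, 1, 1), genes)
  ref <- cbind(cupref = q,
               chol = make_profile(c(20, 20, 1, 1, 1, 1), genes),
               other = make_profile(c(1, 1, 1, 20, 20, 20), genes))
  labels <- tibble::tibble(sample_id = colnames(ref),
                           entity = c("CUP", "CHOL", "BRCA"),
                           is_cup = c(TRUE, FALSE, FALSE))
  res <- tournament_rank(q, ref, labels)
  expect_equal(res$ranking$sample_id[1], "cupref")
  expect_equal(res$predicted_entity, "CHOL")
  expect_true(res$cup_skipped)

  labels$is_cup <- TRUE
  expect_error(tournament_rank(q, ref, labels),
               class = "cupcompass_input_error")
})

test_that("single-reference tournaments rank that sample first with zero wins", {
  ch <- random_fpkm_cohort(20, 1, seed = 1)
  res <- tournament_rank(ch$query, ch$reference, ch$labels)
  expect_equal(res$ranking$wins, 0)
  expect_equal(res$ranking$rank, 1L)
  expect_equal(res$predicted_entity, ch$labels$entity[1])
})

test_that("tidy, glance and autoplot expose the ranking", {
  ch <- random_fpkm_cohort(30, 5, seed = 3)
  res <- tournament_rank(ch$query, ch$reference, ch$labels)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5)
  expect_setequal(td$rank, 1:5)
  gl <- glance(res)
  expect_equal(gl$n_pairs, choose(5, 2))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("threshold tuning honours the grid contract and tie-breaks", {
  cfg <- tiny_config(n_entities = 3L, samples_per_entity = 4L,
                     n_genes = 120L, noise_cv = 0.1)
  ex <- sim_expression_cohort(cfg)
  ref <- ex$reference
  labels <- ex$reference_labels

  single <- tune_thresholds(ref, labels, tibble::tibble(t_up = 13, t_down = 3),
                            n_folds = 4, seed = 1)
  expect_equal(single$best$t_up, 13)
  expect_equal(single$best$t_down, 3)

  # markers at 50 vs background 1: all sensible grid points are perfect,
  # and the tie-break lands on the default (13, 3)
  grid <- tibble::tibble(t_up = c(20, 13, 5), t_down = c(4, 3, 2))
  tuned <- tune_thresholds(ref, labels, grid, n_folds = 4, seed = 1)
  expect_true(all(tuned$results$accuracy == 1))
  expect_equal(tuned$best$t_up, 13)
  expect_equal(tuned$best$t_down, 3)

  expect_error(tune_thresholds(ref, labels,
                               tibble::tibble(t_up = 3, t_down = 13)),
               class = "cupcompass_config_error")
  expect_error(tune_thresholds(ref[, 1:3], labels[1:3, ], grid, n_folds = 10),
               class = "cupcompass_input_error")
})
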