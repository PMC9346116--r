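# Shared fixture builders. Everything is generated in code at test time.

tiny_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_entities = 4L, samples_per_entity = 5L,
               n_genes = 300L, markers_per_entity = 10L,
               marker_fpkm_mean = 50, background_fpkm_mean = 1,
               noise_cv = 0, n_probes = 400L, cpgs_per_entity = 20L,
               missing_rate = 0, n_segments = 30L, n_patients = 12L)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_config, args)
}

# independent naive implementation of the tournament: explicit loops over
# unordered reference pairs, scoring through pair_similarity()
naive_tournament <- function(query, reference, labels,
                             config = tournament_config()) {
  genes <- build_gene_universe(query, reference, config = config)
  n <- ncol(reference)
  wins <- setNames(rep(0, n), colnames(reference))
  sims <- setNames(rep(0, n), colnames(reference))       # integer gene counts
  if (n > 1) {
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        s <- pair_similarity(query, reference[, a], reference[, b], genes,
                             config)
        sims[a] <- sims[a] + round(s[["score_a"]] * length(genes))
        sims[b] <- sims[b] + round(s[["score_b"]] * length(genes))
        if (s[["score_a"]] > s[["score_b"]]) {
          wins[a] <- wins[a] + 1
        } else if (s[["score_b"]] > s[["score_a"]]) {
          wins[b] <- wins[b] + 1
        } else {
          wins[a] <- wins[a] + config$tie_award
          wins[b] <- wins[b] + config$tie_award
        }
      }
    }
  }
  ord <- order(-wins, -sims, colnames(reference))
  list(wins = wins, similarity_sum = sims / length(genes),
       ranking = colnames(reference)[ord])
}

random_fpkm_cohort <- function(n_genes, n_ref, seed) {
  set.seed(seed)
  ref <- matrix(rexp(n_genes * n_ref, rate = 1 / 8), n_genes, n_ref,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("r%02d", seq_len(n_ref))))
  query <- setNames(rexp(n_genes, 1 / 8), rownames(ref))
  labels <- tibble::tibble(sample_id = colnames(ref),
                           entity = sample(c("A", "B", "C"), n_ref, TRUE),
                           is_cup = FALSE)
  list(query = query, reference = ref, labels = labels)
}

# rank-then-Pearson Spearman oracle (average ranks for ties)
spearman_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  cor(rank(x[ok]), rank(y[ok]))
}
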