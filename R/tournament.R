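#' Configuration of the pairwise-tournament expression classifier
#'
#' @param t_up FPKM above which a gene counts as upregulated (default 13).
#' @param t_down FPKM below which a gene counts as downregulated
#'   (default 3). Both comparisons are strict, so values in
#'   `[t_down, t_up]` are neutral.
#' @param liver_mask_enabled Drop liver-upregulated genes from the gene
#'   universe when the query was obtained by liver biopsy.
#' @param tie_award Win fraction credited to each reference of a pair
#'   whose similarity scores tie exactly (default 0.5, conserving the
#'   one-win-per-pair total).
#' @return A list of class `cup_tournament_config`.
#' @export
tournament_config <- function(t_up = 13, t_down = 3,
                              liver_mask_enabled = TRUE, tie_award = 0.5) {
  check_number(t_up, "t_up", lower = 0, strict_lower = TRUE)
  check_number(t_down, "t_down", lower = 0, strict_lower = TRUE)
  if (t_down >= t_up) stop_config("`t_down` must be strictly below `t_up`")
  check_number(tie_award, "tie_award", lower = 0, upper = 1)
  structure(list(t_up = t_up, t_down = t_down,
                 liver_mask_enabled = isTRUE(liver_mask_enabled),
                 tie_award = tie_award),
            class = "cup_tournament_config")
}

#' Gene universe shared by a query and a reference cohort
#'
#' The duels are fought over the intersection of the query's and the
#' reference cohort's gene sets. When the query biopsy was taken from the
#' liver and masking is enabled, genes upregulated in normal liver tissue
#' are removed first, so that contamination by surrounding normal liver
#' cannot dominate the similarity scores. The returned order is
#' deterministic (sorted).
#'
#' @param query Named FPKM vector of the query sample.
#' @param reference Genes x samples FPKM matrix of the reference cohort.
#' @param liver_genes Character vector of liver-upregulated gene ids.
#' @param biopsy_site Biopsy site label of the query; masking applies
#'   only when this is `"liver"`.
#' @param config A [tournament_config()].
#' @return Sorted character vector of gene ids.
#' @export
build_gene_universe <- function(query, reference, liver_genes = character(),
                                biopsy_site = NULL,
                                config = tournament_config()) {
  genes <- intersect(names(query), rownames(reference))
  if (length(genes) == 0L) {
    stop_input("query and reference share no genes")
  }
  if (config$liver_mask_enabled && identical(biopsy_site, "liver")) {
    genes <- setdiff(genes, liver_genes)
    if (length(genes) == 0L) {
      stop_input("gene universe empty after liver masking")
    }
  }
  sort(genes)
}

#' Similarity duel between two reference samples
#'
#' For a pair of reference samples (a, b), sample a's score is the
#' fraction of universe genes that are upregulated in both the query and
#' a (FPKM above `t_up`) while downregulated in b (FPKM below `t_down`);
#' b's score is symmetric. The comparison of the two scores is what
#' drives the tournament, and is invariant to the denominator choice
#' (the universe size is used here).
#'
#' @param query,ref_a,ref_b Named FPKM vectors.
#' @param genes Gene universe from [build_gene_universe()].
#' @param config A [tournament_config()].
#' @return Named numeric vector `c(score_a =, score_b =)`, both in
#'   \[0, 1\].
#' @export
pair_similarity <- function(query, ref_a, ref_b, genes,
                            config = tournament_config()) {
  if (length(genes) == 0L) stop_input("empty gene universe")
  q_up <- query[genes] > config$t_up
  a_up <- ref_a[genes] > config$t_up
  b_up <- ref_b[genes] > config$t_up
  a_dn <- ref_a[genes] < config$t_down
  b_dn <- ref_b[genes] < config$t_down
  c(score_a = sum(q_up & a_up & b_dn) / length(genes),
    score_b = sum(q_up & b_up & a_dn) / length(genes))
}

#' Rank reference samples by pairwise-tournament wins against a query
#'
#' Every unordered pair of reference samples duels over the query: the
#' member with the higher [pair_similarity()] score takes the pair's win
#' (an exact tie splits it, `tie_award` each). References are then ranked
#' by total wins, ties broken by the sum of their similarity scores over
#' all their pairs, then by sample id. The entity of the top-ranked
#' reference is the prediction; if that reference is itself a CUP, the
#' ranking is descended to the first non-CUP sample (see
#' [predict_entity_expression()]).
#'
#' The per-pair gene counts are obtained from precomputed up/down
#' indicator vectors via one matrix product; the contract is defined by
#' the naive per-pair formula, against which the implementation is
#' tested.
#'
#' @param query Named FPKM vector.
#' @param reference Genes x samples FPKM matrix.
#' @param labels Tibble with `sample_id`, `entity` and optionally
#'   `is_cup` for each reference sample.
#' @param liver_genes,biopsy_site,config Passed to
#'   [build_gene_universe()].
#' @return Object of class `cup_tournament`: list with `ranking` (tibble:
#'   `sample_id`, `entity`, `is_cup`, `wins`, `similarity_sum`, `rank`),
#'   `predicted_entity`, `winner_id`, `cup_skipped`,
#'   `gene_universe_size`, `n_pairs`.
#' @export
tournament_rank <- function(query, reference, labels,
                            liver_genes = character(), biopsy_site = NULL,
                            config = tournament_config()) {
  check_matrix(reference, "reference")
  stopifnot(all(c("sample_id", "entity") %in% names(labels)))
  if (!setequal(labels$sample_id, colnames(reference))) {
    stop_input("`labels` must cover exactly the reference samples")
  }
  genes <- build_gene_universe(query, reference, liver_genes, biopsy_site,
                               config)
  n <- ncol(reference)
  ref <- reference[genes, , drop = FALSE]
  q_up <- query[genes] > config$t_up

  # M[a, b] = #{g : q up, a up, b down}; scores are M / |genes|
  up <- (ref > config$t_up) * 1
  dn <- (ref < config$t_down) * 1
  M <- t(up * q_up) %*% dn
  diag(M) <- 0

  wins <- rep(0, n)
  sim_count <- unname(rowSums(M))  # integer-valued, exact for tie-breaks
  if (n > 1L) {
    gt <- M > t(M)
    eq <- M == t(M)
    diag(eq) <- FALSE
    wins <- unname(rowSums(gt) + config$tie_award * rowSums(eq))
  }

  lab <- labels[match(colnames(ref), labels$sample_id), ]
  is_cup <- if ("is_cup" %in% names(lab)) as.logical(lab$is_cup) else rep(FALSE, n)
  ranking <- tibble(
    sample_id = colnames(ref), entity = lab$entity, is_cup = is_cup,
    wins = wins, similarity_sum = sim_count / length(genes))
  ord <- order(-ranking$wins, -sim_count, ranking$sample_id)
  ranking <- ranking[ord, ]
  ranking$rank <- seq_len(n)

  res <- structure(list(
    ranking = ranking, gene_universe_size = length(genes),
    n_pairs = choose(n, 2), config = config), class = "cup_tournament")
  pred <- predict_entity_expression(res)
  res$predicted_entity <- pred$entity
  res$winner_id <- pred$winner_id
  res$cup_skipped <- pred$cup_skipped
  res
}

#' Read the predicted entity off a tournament ranking
#'
#' The prediction is the entity of the rank-1 reference sample. If that
#' sample is itself labelled CUP, the ranking is descended to the first
#' non-CUP sample and `cup_skipped` is set.
#'
#' @param result A `cup_tournament` from [tournament_rank()].
#' @return List with `entity`, `winner_id` and `cup_skipped`.
#' @export
predict_entity_expression <- function(result) {
  stopifnot(inherits(result, "cup_tournament"))
  rk <- result$ranking
  hit <- which(!rk$is_cup)
  if (length(hit) == 0L) {
    stop_input("all reference samples are CUP; no predictable entity")
  }
  list(entity = rk$entity[hit[1L]],
       winner_id = rk$sample_id[hit[1L]],
       cup_skipped = hit[1L] != 1L)
}

#' Classify a matrix of query samples
#'
#' Convenience wrapper running [tournament_rank()] per query column.
#'
#' @param queries Genes x samples FPKM matrix of query samples.
#' @param reference,labels,liver_genes,config As [tournament_rank()].
#' @param biopsy_sites Optional character vector of biopsy sites, one per
#'   query column (recycled if length 1).
#' @return Tibble with one row per query: `sample_id`,
#'   `predicted_entity`, `winner_id`, `cup_skipped`.
#' @export
classify_expression <- function(queries, reference, labels,
                                liver_genes = character(),
                                biopsy_sites = NULL,
                                config = tournament_config()) {
  check_matrix(queries, "queries")
  sites <- biopsy_sites %||% rep(NA_character_, ncol(queries))
  if (length(sites) == 1L) sites <- rep(sites, ncol(queries))
  purrr::map_dfr(seq_len(ncol(queries)), function(i) {
    site <- if (is.na(sites[i])) NULL else sites[i]
    r <- tournament_rank(queries[, i], reference, labels, liver_genes,
                         site, config)
    tibble(sample_id = colnames(queries)[i],
           predicted_entity = r$predicted_entity,
           winner_id = r$winner_id, cup_skipped = r$cup_skipped)
  })
}

#' Tune the up/down FPKM thresholds by stratified cross-validation
#'
#' Evaluates each `(t_up, t_down)` grid point by k-fold cross-validation
#' on a labelled reference cohort: folds are stratified by entity under a
#' fixed seed, each held-out sample is classified against the remaining
#' folds, and the grid point with the highest mean accuracy wins. Ties
#' are broken toward the default (13, 3) when present, then toward the
#' smallest `t_up`, then the smallest `t_down`.
#'
#' @param reference Genes x samples FPKM matrix.
#' @param labels Tibble with `sample_id`, `entity`.
#' @param grid Tibble/data frame with columns `t_up`, `t_down`; every row
#'   must satisfy `t_down < t_up`.
#' @param n_folds Number of cross-validation folds (default 10).
#' @param seed Seed fixing the fold assignment.
#' @return List with `best` (one-row tibble `t_up`, `t_down`,
#'   `accuracy`) and `results` (per-grid-point mean accuracy).
#' @export
tune_thresholds <- function(reference, labels, grid, n_folds = 10L,
                            seed = 1L) {
  check_matrix(reference, "reference")
  grid <- as_tibble(grid)
  stopifnot(all(c("t_up", "t_down") %in% names(grid)))
  if (any(grid$t_down >= grid$t_up)) {
    stop_config("every grid point must satisfy t_down < t_up")
  }
  n <- ncol(reference)
  if (n < n_folds) {
    stop_input(sprintf("%d samples are fewer than %d folds", n, n_folds))
  }
  lab <- labels[match(colnames(reference), labels$sample_id), ]

  fold <- integer(n)
  withr_seed(seed, "cv", {
    for (e in unique(lab$entity)) {
      idx <- sample(which(lab$entity == e))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })

  acc <- vapply(seq_len(nrow(grid)), function(g) {
    cfg <- tournament_config(t_up = grid$t_up[g], t_down = grid$t_down[g])
    correct <- vapply(seq_len(n), function(i) {
      train <- which(fold != fold[i])
      r <- tournament_rank(reference[, i], reference[, train, drop = FALSE],
                           lab[train, ], config = cfg)
      r$predicted_entity == lab$entity[i]
    }, logical(1))
    mean(correct)
  }, numeric(1))

  results <- dplyr::mutate(grid, accuracy = acc)
  is_default <- results$t_up == 13 & results$t_down == 3
  ord <- order(-results$accuracy, !is_default, results$t_up, results$t_down)
  list(best = results[ord[1L], ], results = results)
}

#' @export
print.cup_tournament <- function(x, ...) {
  cat("Pairwise-tournament entity prediction\n")
  cat(sprintf("  predicted entity: %s (winner %s%s)\n", x$predicted_entity,
              x$winner_id, if (x$cup_skipped) ", CUP skipped" else ""))
  cat(sprintf("  %d reference samples, %d pairs, %d genes in universe\n",
              nrow(x$ranking), x$n_pairs, x$gene_universe_size))
  print(head(x$ranking, 5))
  invisible(x)
}

#' Tidy a tournament result into its per-reference ranking
#'
#' @param x A `cup_tournament`.
#' @param ... Unused.
#' @return The ranking tibble (`sample_id`, `entity`, `is_cup`, `wins`,
#'   `similarity_sum`, `rank`).
#' @method tidy cup_tournament
#' @export
tidy.cup_tournament <- function(x, ...) x$ranking

#' One-row summary of a tournament result
#'
#' @param x A `cup_tournament`.
#' @param ... Unused.
#' @return Tibble with `predicted_entity`, `winner_id`, `cup_skipped`,
#'   `n_reference`, `n_pairs`, `gene_universe_size`.
#' @method glance cup_tournament
#' @export
glance.cup_tournament <- function(x, ...) {
  tibble(predicted_entity = x$predicted_entity, winner_id = x$winner_id,
         cup_skipped = x$cup_skipped, n_reference = nrow(x$ranking),
         n_pairs = x$n_pairs, gene_universe_size = x$gene_universe_size)
}

#' Plot the win distribution of a tournament
#'
#' Bar chart of tournament wins for the top-ranked reference samples,
#' coloured by entity.
#'
#' @param object A `cup_tournament`.
#' @param top_n Number of top-ranked references to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cup_tournament
#' @export
autoplot.cup_tournament <- function(object, top_n = 20, ...) {
  d <- head(object$ranking, top_n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$sample_id, .data$wins),
    y = .data$wins, fill = .data$entity)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "tournament wins",
                  title = sprintf("Predicted entity: %s",
                                  object$predicted_entity)) +
    ggplot2::theme_minimal()
}
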