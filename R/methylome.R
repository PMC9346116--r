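#' Select the most variant CpG probes after SNP and platform filtering
#'
#' Feature selection for the methylome classifier: (i) probes overlapping
#' known SNPs are removed, (ii) only probes present on every requested
#' platform manifest are kept (emulating the 850k/450k/27k array
#' intersection), and (iii) the K probes with the highest variance across
#' the reference cohort are retained. Variance is computed over
#' non-missing values with the sample (n-1) denominator; ties are broken
#' deterministically by probe id.
#'
#' @param reference Probes x samples beta matrix.
#' @param snp_probes Character vector of SNP-overlapping probe ids to
#'   exclude.
#' @param platform_manifests Optional list of character vectors; only
#'   probes present in every manifest survive.
#' @param k Number of probes to select (default 5000).
#' @return Object of class `cup_cpg_selection`: tibble with `probe_id`
#'   and `variance`, sorted by variance descending, plus attributes
#'   `n_excluded_snp` and `n_platform_common`.
#' @export
select_informative_probes <- function(reference, snp_probes = character(),
                                      platform_manifests = NULL, k = 5000L) {
  check_matrix(reference, "reference")
  k <- check_count(k, "k")
  probes <- rownames(reference)
  after_snp <- setdiff(probes, snp_probes)
  n_excluded_snp <- length(probes) - length(after_snp)
  common <- after_snp
  if (!is.null(platform_manifests)) {
    for (m in platform_manifests) common <- intersect(common, m)
  }
  if (length(common) < k) {
    stop_input(sprintf(
      paste0("only %d probes survive filtering (need K = %d): ",
             "%d input, %d after SNP removal, %d on all platforms"),
      length(common), k, length(probes), length(after_snp), length(common)))
  }
  v <- apply(reference[common, , drop = FALSE], 1, var, na.rm = TRUE)
  ord <- order(-v, common)
  sel <- tibble(probe_id = common[ord[seq_len(k)]],
                variance = unname(v[ord[seq_len(k)]]))
  structure(sel, class = c("cup_cpg_selection", class(sel)),
            n_excluded_snp = n_excluded_snp,
            n_platform_common = length(common))
}

#' Impute missing beta values by probe k-nearest neighbours
#'
#' Each missing cell is replaced by the mean beta of the k nearest probes
#' in that sample, where probe-probe distance is Euclidean over their
#' shared non-missing samples (rescaled to the full sample count, as in
#' [stats::dist()]'s NA handling). Only neighbours observed in the target
#' sample contribute. Imputed values are clipped to \[0, 1\]; complete
#' matrices are returned unchanged.
#'
#' @param beta Probes x samples beta matrix.
#' @param k_neighbours Number of nearest probes to average (default 10).
#' @return A complete beta matrix of the same shape.
#' @export
impute_missing <- function(beta, k_neighbours = 10L) {
  check_matrix(beta, "beta")
  k_neighbours <- check_count(k_neighbours, "k_neighbours")
  if (!anyNA(beta)) return(beta)
  fully_missing <- rowSums(!is.na(beta)) == 0L
  if (any(fully_missing)) {
    stop_input(sprintf("probe '%s' has no observed values",
                       rownames(beta)[which(fully_missing)[1L]]))
  }
  d <- as.matrix(stats::dist(beta))  # Euclidean, NA pairs dropped + rescaled
  out <- beta
  for (p in which(rowSums(is.na(beta)) > 0L)) {
    miss <- which(is.na(beta[p, ]))
    ord <- order(d[p, ], rownames(beta))   # deterministic neighbour order
    ord <- setdiff(ord, p)
    for (s in miss) {
      donors <- ord[!is.na(beta[ord, s])]
      if (length(donors) == 0L) {
        stop_input(sprintf("no observed neighbour for probe '%s' sample '%s'",
                           rownames(beta)[p], colnames(beta)[s]))
      }
      val <- mean(beta[donors[seq_len(min(k_neighbours, length(donors)))], s])
      out[p, s] <- min(max(val, 0), 1)
    }
  }
  out
}

# merged entity basket: colorectal and rectal adenocarcinomas are
# indistinguishable at the methylome level and reported as one label
merge_entity_baskets <- function(entity) {
  ifelse(entity %in% c("COAD", "READ"), "COAD/READ", entity)
}

#' Predict tumor entity by nearest Spearman neighbour in methylation
#'
#' Correlates the query's beta values over the selected CpGs with every
#' reference sample (Spearman, pairwise-complete probes) and predicts the
#' entity of the most correlated reference. Colorectal (COAD) and rectal
#' (READ) adenocarcinomas are reported as the merged basket
#' `"COAD/READ"`. Exact correlation ties are broken by sample id.
#'
#' @param query Named beta vector of the query sample.
#' @param reference Probes x samples beta matrix with labelled samples.
#' @param labels Tibble with `sample_id` and `entity`.
#' @param selection A [select_informative_probes()] result (or a
#'   character vector of probe ids).
#' @param min_coverage Minimum fraction of selected probes the query must
#'   observe (default 0.8).
#' @return Object of class `cup_meth_prediction`: list with
#'   `predicted_entity`, `winner_id`, and `correlations` (tibble:
#'   `sample_id`, `entity`, `rho`, sorted by `rho` descending).
#' @export
predict_entity_methylome <- function(query, reference, labels, selection,
                                     min_coverage = 0.8) {
  check_matrix(reference, "reference")
  probes <- if (is.character(selection)) selection else selection$probe_id
  probes <- intersect(probes, intersect(names(query), rownames(reference)))
  covered <- mean(!is.na(query[probes]))
  if (length(probes) == 0L || covered < min_coverage) {
    stop_input(sprintf(
      "query observes %.0f%% of the %d selected probes (minimum %.0f%%)",
      100 * covered, length(probes), 100 * min_coverage))
  }
  q <- query[probes]
  rho <- suppressWarnings(
    cor(q, reference[probes, , drop = FALSE], method = "spearman",
        use = "pairwise.complete.obs"))[1, ]
  lab <- labels[match(colnames(reference), labels$sample_id), ]
  cors <- tibble(sample_id = colnames(reference),
                 entity = merge_entity_baskets(lab$entity),
                 rho = unname(rho))
  cors <- cors[order(-cors$rho, cors$sample_id), ]
  structure(list(predicted_entity = cors$entity[1L],
                 winner_id = cors$sample_id[1L],
                 correlations = cors),
            class = "cup_meth_prediction")
}

#' Classify a matrix of methylome queries
#'
#' @param queries Probes x samples beta matrix.
#' @param reference,labels,selection,min_coverage As
#'   [predict_entity_methylome()].
#' @return Tibble with `sample_id`, `predicted_entity`, `winner_id`,
#'   `top_rho` per query.
#' @export
classify_methylome <- function(queries, reference, labels, selection,
                               min_coverage = 0.8) {
  check_matrix(queries, "queries")
  purrr::map_dfr(seq_len(ncol(queries)), function(i) {
    p <- predict_entity_methylome(queries[, i], reference, labels,
                                  selection, min_coverage)
    tibble(sample_id = colnames(queries)[i],
           predicted_entity = p$predicted_entity,
           winner_id = p$winner_id,
           top_rho = p$correlations$rho[1L])
  })
}

#' t-SNE embedding of methylation profiles
#'
#' Joint two-dimensional t-SNE embedding of reference and query samples
#' restricted to the selected CpGs, for visualization only. Missing
#' values are imputed with [impute_missing()] first. The perplexity
#' defaults to 100 and is automatically reduced with a warning when the
#' sample count does not support it (Rtsne requires
#' `n - 1 >= 3 * perplexity`).
#'
#' @param beta Probes x samples beta matrix (reference and queries
#'   column-bound by the caller).
#' @param selection Optional probe selection to restrict to.
#' @param perplexity t-SNE perplexity (default 100).
#' @param seed Seed making the embedding reproducible.
#' @param ... Passed on to [Rtsne::Rtsne()].
#' @return Tibble with `sample_id`, `tsne1`, `tsne2`.
#' @export
embed_tsne <- function(beta, selection = NULL, perplexity = 100, seed = 1L,
                       ...) {
  check_matrix(beta, "beta")
  if (!is.null(selection)) {
    probes <- if (is.character(selection)) selection else selection$probe_id
    beta <- beta[intersect(probes, rownames(beta)), , drop = FALSE]
  }
  if (anyNA(beta)) beta <- impute_missing(beta)
  n <- ncol(beta)
  max_perp <- floor((n - 1) / 3)
  if (perplexity > max_perp) {
    rlang::warn(sprintf(
      "perplexity %s too large for %d samples; reduced to %d",
      format(perplexity), n, max_perp))
    perplexity <- max_perp
  }
  coords <- withr_seed(seed, "tsne", {
    Rtsne::Rtsne(t(beta), perplexity = perplexity, theta = 0,
                 check_duplicates = FALSE, pca = FALSE, ...)$Y
  })
  tibble(sample_id = colnames(beta), tsne1 = coords[, 1], tsne2 = coords[, 2])
}

#' @export
print.cup_meth_prediction <- function(x, ...) {
  cat("Methylome nearest-neighbour entity prediction\n")
  cat(sprintf("  predicted entity: %s (winner %s, rho = %.3f)\n",
              x$predicted_entity, x$winner_id, x$correlations$rho[1L]))
  invisible(x)
}

#' Tidy a methylome prediction into per-reference correlations
#'
#' @param x A `cup_meth_prediction`.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `entity`, `rho`.
#' @method tidy cup_meth_prediction
#' @export
tidy.cup_meth_prediction <- function(x, ...) x$correlations

#' One-row summary of a methylome prediction
#'
#' @param x A `cup_meth_prediction`.
#' @param ... Unused.
#' @return Tibble with `predicted_entity`, `winner_id`, `top_rho`.
#' @method glance cup_meth_prediction
#' @export
glance.cup_meth_prediction <- function(x, ...) {
  tibble(predicted_entity = x$predicted_entity, winner_id = x$winner_id,
         top_rho = x$correlations$rho[1L])
}
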