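#' Run the CUP analysis pipeline from a configuration
#'
#' Orchestrates synthetic-cohort generation, expression- and
#' methylome-based entity prediction, biomarker scoring, purity/ploidy
#' fitting and the clinical benefit summary from one declarative
#' configuration. The configuration is a named list (or path to a YAML
#' file with the same structure):
#'
#' * `seed` - global seed propagated to every stochastic stage,
#' * `out_dir` - output directory (created if absent),
#' * `stages` - character vector choosing among `"synthetic"`,
#'   `"expression"`, `"methylome"`, `"biomarkers"`, `"cna"`,
#'   `"clinical"`,
#' * `synthetic` - overrides for [synthetic_config()],
#' * `tournament` - overrides for [tournament_config()],
#' * `mpfsr` - overrides for [mpfsr_rule()],
#' * `inputs` - optional named file paths (`expression_reference`,
#'   `expression_queries`, `segments`, `clinical`, ...) read instead of
#'   simulated; every referenced file must exist before any stage runs.
#'
#' Each stage writes its result as CSV under `out_dir`; the manifest
#' records file digests, so identical configuration and seed give
#' identical digests for the deterministic stages.
#'
#' @param config A named list or path to a YAML file.
#' @return Invisibly, a manifest tibble (`stage`, `output`, `md5`,
#'   `elapsed_s`) with the parsed configuration and seed attached as
#'   attributes.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_input(sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% stop_config("`out_dir` is required")
  all_stages <- c("synthetic", "expression", "methylome", "biomarkers",
                  "cna", "clinical")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop_config(sprintf("unknown stage '%s'", bad[1L]))

  # validation-first: every referenced input must exist before any stage runs
  inputs <- config$inputs %||% list()
  paths <- as.character(unlist(inputs))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop_input(sprintf("input file(s) not found: %s",
                       paste(missing, collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  syn_cfg <- do.call(synthetic_config,
                     c(list(seed = seed), config$synthetic %||% list()))
  tour_cfg <- do.call(tournament_config, config$tournament %||% list())
  rule <- do.call(mpfsr_rule, config$mpfsr %||% list())

  manifest <- list()
  emit <- function(stage, name, data) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(data, path, progress = FALSE)
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage, output = path, md5 = unname(tools::md5sum(path)))
    path
  }
  run_stage <- function(stage, code) {
    t0 <- proc.time()[["elapsed"]]
    n_before <- length(manifest)
    tryCatch(code, error = function(e) {
      rlang::abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                   class = "cupcompass_stage_error", parent = e)
    })
    for (i in seq(n_before + 1L, length.out = length(manifest) - n_before)) {
      manifest[[i]]$elapsed_s <<- proc.time()[["elapsed"]] - t0
    }
  }

  expr <- meth <- NULL
  if (any(c("synthetic", "expression", "methylome") %in% stages) &&
      is.null(inputs$expression_reference)) {
    expr <- sim_expression_cohort(syn_cfg)
  }

  if ("synthetic" %in% stages) {
    run_stage("synthetic", {
      if (!is.null(expr)) {
        emit("synthetic", "reference_labels", expr$reference_labels)
        emit("synthetic", "query_truth", expr$query_truth)
      }
      seg <- sim_cna_segments(syn_cfg)
      emit("synthetic", "segments", seg)
      clin <- sim_clinical_cohort(syn_cfg)
      emit("synthetic", "therapy_lines", clin$therapy_lines)
    })
  }

  if ("expression" %in% stages) {
    run_stage("expression", {
      if (!is.null(inputs$expression_reference)) {
        ref <- read_expression_matrix(inputs$expression_reference)
        qry <- read_expression_matrix(inputs$expression_queries)
        labels <- readr::read_csv(inputs$expression_labels,
                                  show_col_types = FALSE, progress = FALSE)
        liver <- if (!is.null(inputs$liver_genes)) readLines(inputs$liver_genes)
                 else character()
      } else {
        ref <- expr$reference; qry <- expr$queries
        labels <- expr$reference_labels; liver <- expr$liver_genes
      }
      pred <- classify_expression(qry, ref, labels, liver, config = tour_cfg)
      emit("expression", "expression_predictions", pred)
    })
  }

  if ("methylome" %in% stages) {
    run_stage("methylome", {
      meth <- sim_methylome_cohort(syn_cfg)
      k <- min(config$methylome$k %||% 5000L,
               syn_cfg$n_probes - length(meth$snp_probes))
      sel <- select_informative_probes(meth$reference, meth$snp_probes,
                                       meth$platform_manifests, k = k)
      pred <- classify_methylome(meth$queries, meth$reference,
                                 meth$reference_labels, sel)
      emit("methylome", "methylome_predictions", pred)
    })
  }

  if ("biomarkers" %in% stages) {
    run_stage("biomarkers", {
      seg <- if (!is.null(inputs$segments)) read_segments(inputs$segments)
             else sim_cna_segments(syn_cfg)
      rep <- biomarker_report(
        sample_id = "S1",
        n_nonsilent_snv = config$biomarkers$n_nonsilent_snv %||% 42,
        n_coding_indel = config$biomarkers$n_coding_indel %||% 3,
        length_mb = config$biomarkers$length_mb %||% 35.334619,
        segments = seg,
        msi_score = config$biomarkers$msi_score %||% 0.2)
      emit("biomarkers", "biomarker_report", as_tibble(rep))
    })
  }

  if ("cna" %in% stages) {
    run_stage("cna", {
      seg <- if (!is.null(inputs$segments)) read_segments(inputs$segments)
             else sim_cna_segments(syn_cfg)
      fit <- fit_ploidy_purity(seg)
      emit("cna", "ploidy_purity_fits", tidy(fit))
    })
  }

  if ("clinical" %in% stages) {
    run_stage("clinical", {
      lines <- if (!is.null(inputs$clinical)) read_clinical(inputs$clinical)
               else sim_clinical_cohort(syn_cfg)$therapy_lines
      pfs <- compute_pfs(lines, cutoff_date = config$cutoff_date)
      ratios <- modified_pfs_ratio(pfs_ratio(pfs), rule)
      emit("clinical", "pfs_ratios", ratios)
      emit("clinical", "cohort_summary", cohort_summary(ratios))
    })
  }

  out <- dplyr::bind_rows(manifest)
  attr(out, "seed") <- seed
  attr(out, "config") <- config
  invisible(out)
}
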