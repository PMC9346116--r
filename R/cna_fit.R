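#' Allele-specific copy numbers implied by a purity/ploidy hypothesis
#'
#' Inverts the tumor-normal mixture model for a segment with observed
#' coverage ratio `r` and B-allele frequency `b` under a candidate tumor
#' cell content (TCC) and ploidy:
#' `total = (r (tcc ploidy + 2 (1 - tcc)) - 2 (1 - tcc)) / tcc` and
#' `minor = (b (tcc total + 2 (1 - tcc)) - (1 - tcc)) / tcc`.
#' This is the exact inverse of [cna_forward_model()]: a diploid segment
#' in a pure sample (`tcc = 1`, `r = 1`, `ploidy = 2`) implies a total
#' copy number of 2, and a balanced BAF of 0.5 implies `minor =
#' total / 2`.
#'
#' @param coverage_ratio,baf Observed segment summaries (vectors).
#' @param tcc Tumor cell content in (0, 1].
#' @param ploidy Candidate tumor ploidy.
#' @return Tibble with `total_cn` and `minor_cn` (real-valued; integer
#'   at the true solution of noiseless data).
#' @export
implied_copy_numbers <- function(coverage_ratio, baf, tcc, ploidy) {
  if (!is.numeric(tcc) || length(tcc) != 1L || tcc <= 0 || tcc > 1) {
    stop_input("`tcc` must be in (0, 1]")
  }
  check_number(ploidy, "ploidy", lower = 0, strict_lower = TRUE)
  denom_sample <- tcc * ploidy + 2 * (1 - tcc)
  total <- (coverage_ratio * denom_sample - 2 * (1 - tcc)) / tcc
  minor <- (baf * (tcc * total + 2 * (1 - tcc)) - (1 - tcc)) / tcc
  tibble(total_cn = total, minor_cn = minor)
}

#' Estimate tumor purity and ploidy by exhaustive grid search
#'
#' Segments carrying at least `min_het_snps` heterozygous SNPs are kept;
#' every combination of TCC (0.15 to 1.0, step `tcc_step`) and ploidy
#' (1.0 to 6.5, step `ploidy_step`) is scored by the length-weighted mean
#' of squared distances of the implied total and minor copy numbers to
#' their nearest nonnegative integers. Grid points strictly smaller than
#' all of their 8-neighbourhood are local minima; all are returned ranked
#' by objective (ties broken toward ploidy nearest 2, then larger TCC).
#' Solutions at TCC = 1.0 are retained but flagged unreliable, since an
#' apparent 100% purity usually signals a sample whose true tumor
#' content was too low to resolve.
#'
#' @param segments Tibble with `coverage_ratio`, `baf`, `n_het_snps`,
#'   `start`, `end`.
#' @param tcc_step,ploidy_step Grid resolutions (defaults 0.01 and
#'   0.05).
#' @param tcc_range,ploidy_range Search ranges.
#' @param min_het_snps Minimum heterozygous SNPs per processed segment
#'   (default 20).
#' @return Object of class `cup_ploidy_fit`: tibble of local minima with
#'   `tcc`, `ploidy`, `objective`, `is_local_minimum`, `reliable`,
#'   `rank`, plus attributes `n_segments_used` and `grid` (the full
#'   objective surface).
#' @export
fit_ploidy_purity <- function(segments, tcc_step = 0.01, ploidy_step = 0.05,
                              tcc_range = c(0.15, 1.0),
                              ploidy_range = c(1.0, 6.5),
                              min_het_snps = 20L) {
  seg <- as_tibble(segments)
  need <- c("coverage_ratio", "baf", "n_het_snps", "start", "end")
  miss <- setdiff(need, names(seg))
  if (length(miss)) {
    stop_input(sprintf("segments missing columns: %s",
                       paste(miss, collapse = ", ")))
  }
  seg <- seg[seg$n_het_snps >= min_het_snps, ]
  if (nrow(seg) == 0L) {
    stop_input(sprintf("no segment has at least %d heterozygous SNPs",
                       min_het_snps))
  }
  w <- (seg$end - seg$start) / sum(seg$end - seg$start)
  tccs <- seq(tcc_range[1], tcc_range[2], by = tcc_step)
  ploidies <- seq(ploidy_range[1], ploidy_range[2], by = ploidy_step)

  obj <- matrix(NA_real_, length(tccs), length(ploidies),
                dimnames = list(format(tccs), format(ploidies)))
  for (i in seq_along(tccs)) {
    tcc <- tccs[i]
    # vectorized over segments and ploidies: total is affine in ploidy
    denom <- tcc * ploidies + 2 * (1 - tcc)             # length P
    total <- (seg$coverage_ratio %o% denom - 2 * (1 - tcc)) / tcc  # S x P
    minor <- (seg$baf * (tcc * total + 2 * (1 - tcc)) - (1 - tcc)) / tcc
    d2 <- (total - pmax(round(total), 0))^2 + (minor - pmax(round(minor), 0))^2
    obj[i, ] <- colSums(d2 * w)
  }

  # strict local minima over the 8-neighbourhood (edges use available
  # neighbours); padding with +Inf keeps the comparison uniform
  pad <- matrix(Inf, nrow(obj) + 2L, ncol(obj) + 2L)
  pad[2:(nrow(obj) + 1L), 2:(ncol(obj) + 1L)] <- obj
  is_min <- matrix(TRUE, nrow(obj), ncol(obj))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nb <- pad[2:(nrow(obj) + 1L) + di, 2:(ncol(obj) + 1L) + dj, drop = FALSE]
    is_min <- is_min & (obj < nb)
  }
  idx <- which(is_min, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    # fully flat surface: fall back to the global minimum
    idx <- which(obj == min(obj), arr.ind = TRUE)
  }
  fits <- tibble(
    tcc = tccs[idx[, 1]], ploidy = ploidies[idx[, 2]],
    objective = obj[idx],
    is_local_minimum = is_min[idx])
  # The integer-lattice objective admits exact whole-genome-doubling
  # aliases (e.g. tcc 0.6/ploidy 2 maps onto tcc 0.75/ploidy 6 with every
  # copy number doubled and shifted). Among solutions whose objectives are
  # numerically tied we therefore prefer the parsimonious one: lowest
  # ploidy, then highest tumor cell content. Genuinely better objectives
  # always win.
  best <- min(fits$objective)
  tied <- fits$objective <= best * 1.05 + 1e-12
  ord <- order(!tied, ifelse(tied, 0, fits$objective),
               fits$ploidy, -fits$tcc)
  fits <- fits[ord, ]
  fits$reliable <- fits$tcc < 1.0
  fits$rank <- seq_len(nrow(fits))
  structure(fits, class = c("cup_ploidy_fit", class(fits)),
            n_segments_used = nrow(seg), grid = obj)
}

#' Tidy a purity/ploidy fit
#'
#' @param x A `cup_ploidy_fit`.
#' @param ... Unused.
#' @return Plain tibble of ranked candidate solutions.
#' @method tidy cup_ploidy_fit
#' @export
tidy.cup_ploidy_fit <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cup_ploidy_fit")
  attr(out, "grid") <- NULL
  attr(out, "n_segments_used") <- NULL
  out
}

#' One-row summary of a purity/ploidy fit
#'
#' @param x A `cup_ploidy_fit`.
#' @param ... Unused.
#' @return Tibble with the top solution and bookkeeping counts.
#' @method glance cup_ploidy_fit
#' @export
glance.cup_ploidy_fit <- function(x, ...) {
  tibble(tcc = x$tcc[1L], ploidy = x$ploidy[1L], objective = x$objective[1L],
         reliable = x$reliable[1L], n_solutions = nrow(x),
         n_segments_used = attr(x, "n_segments_used"))
}

#' Plot the purity/ploidy objective surface
#'
#' Heatmap of the grid-search objective with candidate solutions
#' overlaid; the optimum is marked.
#'
#' @param object A `cup_ploidy_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cup_ploidy_fit
#' @export
autoplot.cup_ploidy_fit <- function(object, ...) {
  g <- attr(object, "grid")
  d <- expand.grid(tcc = as.numeric(rownames(g)),
                   ploidy = as.numeric(colnames(g)))
  d$objective <- as.vector(g)
  ggplot2::ggplot(d, ggplot2::aes(.data$ploidy, .data$tcc)) +
    ggplot2::geom_raster(ggplot2::aes(fill = log10(.data$objective + 1e-6))) +
    ggplot2::geom_point(data = as.data.frame(object[, c("ploidy", "tcc")]),
                        colour = "red", shape = 4, size = 2) +
    ggplot2::scale_fill_viridis_c(name = "log10 objective") +
    ggplot2::labs(x = "ploidy", y = "tumor cell content") +
    ggplot2::theme_minimal()
}
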