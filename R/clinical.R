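DAYS_PER_MONTH <- 30.4375  # mean Gregorian month

#' Progression-free survival of therapy lines
#'
#' PFS runs from therapy start to progression or death (events) or to
#' the last follow-up/cutoff (censored). Durations are reported in
#' months of 30.4375 days.
#'
#' @param lines Tibble of therapy lines (`patient_id`, `line_role`,
#'   `start_date`, `event_date`, `event_type` in `progression`/`death`/
#'   `censored`), as produced by [read_clinical()] or
#'   [sim_clinical_cohort()].
#' @param cutoff_date Administrative cutoff ([Date] or string); censored
#'   lines without an `event_date` are censored here.
#' @return Tibble with `patient_id`, `line_role`, `pfs_months`, `event`.
#' @export
compute_pfs <- function(lines, cutoff_date = NULL) {
  lines <- as_tibble(lines)
  cutoff <- if (!is.null(cutoff_date)) as.Date(cutoff_date) else NULL
  end <- lines$event_date
  ev <- lines$event_type
  cens <- ev == "censored"
  if (any(cens & is.na(end)) && is.null(cutoff)) {
    stop_input("censored lines without event_date require `cutoff_date`")
  }
  if (!is.null(cutoff)) {
    end[cens] <- pmin(end[cens], cutoff, na.rm = TRUE)
  }
  if (any(is.na(end))) stop_input("event lines must carry an event_date")
  days <- as.numeric(end - lines$start_date)
  if (any(days < 0)) stop_input("negative therapy-line duration")
  if (any(days == 0)) stop_input("zero-length therapy line; PFS must be positive")
  tibble(patient_id = lines$patient_id,
         line_role = lines$line_role,
         pfs_months = days / DAYS_PER_MONTH,
         event = ev)
}

#' Progression-free survival ratio per patient
#'
#' For each patient, pairs the last pre-board systemic therapy line
#' (`pre_mtb_last`, giving PFS1) with the first applied recommended
#' therapy (`recommended_first`, giving PFS2) and computes
#' `pfsr = PFS2 / PFS1`. The ratio is only defined when the prior line
#' ended in progression or death; patients whose prior line was censored
#' keep their PFS2 but get `undefined_reason = "no_progression_on_prior"`
#' (patients with no prior line at all get `"missing_prior"`). A ratio
#' strictly greater than 1.3 is flagged as clinical benefit.
#'
#' @param pfs Tibble from [compute_pfs()].
#' @param benefit_threshold Ratio above which benefit is called
#'   (default 1.3, strict).
#' @return Tibble with `patient_id`, `pfs1`, `pfs2`, `pfsr`, `benefit`,
#'   `undefined_reason`.
#' @export
pfs_ratio <- function(pfs, benefit_threshold = 1.3) {
  pfs <- as_tibble(pfs)
  pre <- pfs[pfs$line_role == "pre_mtb_last", ]
  rec <- pfs[pfs$line_role == "recommended_first", ]
  purrr::map_dfr(unique(rec$patient_id), function(pid) {
    p2 <- rec[rec$patient_id == pid, ][1, ]
    p1 <- pre[pre$patient_id == pid, ]
    if (nrow(p1) == 0L) {
      return(tibble(patient_id = pid, pfs1 = NA_real_,
                    pfs2 = p2$pfs_months, pfsr = NA_real_,
                    benefit = NA, undefined_reason = "missing_prior"))
    }
    p1 <- p1[1, ]
    if (!p1$event %in% c("progression", "death")) {
      return(tibble(patient_id = pid, pfs1 = p1$pfs_months,
                    pfs2 = p2$pfs_months, pfsr = NA_real_,
                    benefit = NA,
                    undefined_reason = "no_progression_on_prior"))
    }
    if (p1$pfs_months == 0) stop_input("PFS1 of zero months")
    r <- p2$pfs_months / p1$pfs_months
    tibble(patient_id = pid, pfs1 = p1$pfs_months, pfs2 = p2$pfs_months,
           pfsr = r, benefit = r > benefit_threshold,
           undefined_reason = NA_character_)
  })
}

#' Rule for modified PFS ratios
#'
#' The modified ratio (mPFSr) tempers extreme ratios driven by very
#' short prior lines: PFS1 is floored at `pfs1_floor_months` before
#' dividing, and the resulting ratio is capped at `ratio_cap`. With an
#' empty rule (both `NULL`, the default) the modified ratio equals the
#' plain ratio.
#'
#' @param pfs1_floor_months Optional positive floor on PFS1 (months).
#' @param ratio_cap Optional positive cap on the ratio.
#' @return A list of class `cup_mpfsr_rule`.
#' @export
mpfsr_rule <- function(pfs1_floor_months = NULL, ratio_cap = NULL) {
  if (!is.null(pfs1_floor_months)) {
    check_number(pfs1_floor_months, "pfs1_floor_months", lower = 0,
                 strict_lower = TRUE)
  }
  if (!is.null(ratio_cap)) {
    check_number(ratio_cap, "ratio_cap", lower = 0, strict_lower = TRUE)
  }
  structure(list(pfs1_floor_months = pfs1_floor_months,
                 ratio_cap = ratio_cap), class = "cup_mpfsr_rule")
}

#' Modified PFS ratio
#'
#' Applies an [mpfsr_rule()] to the ratios from [pfs_ratio()]: mPFSr is
#' `pfs2 / max(pfs1, floor)`, capped at `ratio_cap`. Undefined ratios
#' stay undefined.
#'
#' @param ratios Tibble from [pfs_ratio()].
#' @param rule An [mpfsr_rule()].
#' @return The input tibble with an `mpfsr` column added.
#' @export
modified_pfs_ratio <- function(ratios, rule = mpfsr_rule()) {
  stopifnot(inherits(rule, "cup_mpfsr_rule"))
  ratios <- as_tibble(ratios)
  p1 <- ratios$pfs1
  if (!is.null(rule$pfs1_floor_months)) {
    p1 <- pmax(p1, rule$pfs1_floor_months)
  }
  m <- ratios$pfs2 / p1
  if (!is.null(rule$ratio_cap)) m <- pmin(m, rule$ratio_cap)
  m[is.na(ratios$pfsr)] <- NA_real_
  dplyr::mutate(ratios, mpfsr = m)
}

#' Kaplan-Meier estimate of a survival function
#'
#' Product-limit estimator via [survival::survfit()]. The median is the
#' smallest event time at which the estimated survival drops to 0.5 or
#' below, and is undefined (`NA`) when the curve never reaches 0.5.
#'
#' @param time Positive event/censoring times (months).
#' @param event Logical (or 0/1): `TRUE` for an event, `FALSE` for
#'   censoring.
#' @return Object of class `cup_km`: list with `steps` (tibble: `time`,
#'   `n_risk`, `n_event`, `surv`), `median` and `n`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop_input("need at least one record")
  if (any(time <= 0)) stop_input("survival times must be positive")
  event <- as.logical(event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  steps <- tibble(time = fit$time, n_risk = fit$n.risk,
                  n_event = fit$n.event, surv = fit$surv)
  ev <- steps[steps$n_event > 0 & steps$surv <= 0.5, ]
  med <- if (nrow(ev)) min(ev$time) else NA_real_
  structure(list(steps = steps, median = med, n = length(time)),
            class = "cup_km")
}

#' Log-rank comparison of two survival groups
#'
#' Standard one-degree-of-freedom log-rank chi-square via
#' [survival::survdiff()], with a two-sided p-value. When neither group
#' has any event the statistic is 0 and p is 1.
#'
#' @param time Positive times for all subjects.
#' @param event Logical event indicators.
#' @param group Two-level grouping vector.
#' @return Tibble with `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop_input("`group` must have exactly two levels")
  if (any(table(group) == 0L)) stop_input("both groups must be nonempty")
  if (any(time <= 0)) stop_input("survival times must be positive")
  event <- as.logical(event)
  if (!any(event)) {
    return(tibble(statistic = 0, p_value = 1,
                  n_a = sum(group == levels(group)[1]),
                  n_b = sum(group == levels(group)[2])))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  tibble(statistic = sd$chisq, p_value = pchisq(sd$chisq, 1, lower.tail = FALSE),
         n_a = sum(group == levels(group)[1]),
         n_b = sum(group == levels(group)[2]))
}

#' Cohort-level clinical benefit summary
#'
#' Aggregates per-patient PFS and ratio results the way a clinical
#' outcome table reports them: median, mean and range of PFS1, PFS2,
#' PFSr and mPFSr, plus benefit counts. Patients with an undefined ratio
#' are excluded from the PFS1/PFSr/mPFSr aggregates but retained in the
#' PFS2 aggregates, so the `n` differs between rows.
#'
#' @param ratios Tibble from [pfs_ratio()] (optionally through
#'   [modified_pfs_ratio()]).
#' @return Tibble with one row per measure: `measure`, `n`, `median`,
#'   `mean`, `min`, `max`, plus a `benefit` row where `n` counts
#'   evaluable patients and `mean` the benefit fraction.
#' @export
cohort_summary <- function(ratios) {
  ratios <- as_tibble(ratios)
  if (nrow(ratios) == 0L) {
    return(tibble(measure = character(), n = integer(), median = numeric(),
                  mean = numeric(), min = numeric(), max = numeric()))
  }
  defined <- !is.na(ratios$pfsr)
  row <- function(measure, x) {
    x <- x[!is.na(x)]
    tibble(measure = measure, n = length(x),
           median = if (length(x)) median(x) else NA_real_,
           mean = if (length(x)) mean(x) else NA_real_,
           min = if (length(x)) min(x) else NA_real_,
           max = if (length(x)) max(x) else NA_real_)
  }
  out <- dplyr::bind_rows(
    row("pfs1", ratios$pfs1[defined]),
    row("pfs2", ratios$pfs2),
    row("pfsr", ratios$pfsr[defined]),
    if ("mpfsr" %in% names(ratios)) row("mpfsr", ratios$mpfsr[defined]))
  ben <- ratios$benefit[defined]
  dplyr::bind_rows(out, tibble(
    measure = "benefit", n = length(ben),
    median = NA_real_, mean = if (length(ben)) mean(ben) else NA_real_,
    min = NA_real_, max = if (length(ben)) sum(ben) else NA_real_))
}

#' @export
print.cup_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, median = %s months\n", x$n,
              if (is.na(x$median)) "not reached" else format(x$median, digits = 4)))
  invisible(x)
}

#' Tidy a Kaplan-Meier estimate into its step function
#'
#' @param x A `cup_km`.
#' @param ... Unused.
#' @return Tibble with `time`, `n_risk`, `n_event`, `surv`.
#' @method tidy cup_km
#' @export
tidy.cup_km <- function(x, ...) x$steps

#' One-row summary of a Kaplan-Meier estimate
#'
#' @param x A `cup_km`.
#' @param ... Unused.
#' @return Tibble with `n`, `n_events`, `median`.
#' @method glance cup_km
#' @export
glance.cup_km <- function(x, ...) {
  tibble(n = x$n, n_events = sum(x$steps$n_event), median = x$median)
}

#' Plot a Kaplan-Meier curve
#'
#' @param object A `cup_km`.
#' @param ... Unused.
#' @return A ggplot object (step curve with the median marked when
#'   reached).
#' @method autoplot cup_km
#' @export
autoplot.cup_km <- function(object, ...) {
  d <- dplyr::bind_rows(tibble(time = 0, surv = 1),
                        object$steps[, c("time", "surv")])
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "S(t)") +
    ggplot2::theme_minimal()
  if (!is.na(object$median)) {
    p <- p + ggplot2::geom_vline(xintercept = object$median,
                                 linetype = "dashed", colour = "grey50")
  }
  p
}
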