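# Replication testing, replication power by subsampling, and
# fixed-horizon incident-event risk.

#' Flag replication of discovered loci in a held-out cohort
#'
#' A locus replicates when its replication-cohort p-value is strictly
#' below `0.05 / n_discovered` (Bonferroni over the discovered loci), i.e.
#' `neglog10_p > -log10(0.05 / n_discovered)`; a p-value exactly at the
#' threshold does not replicate.  Loci without a replication result are
#' reported untested.
#'
#' @param results `assoc_result`-like `data.frame` with one row per
#'   discovered locus (`variant_id`, `neglog10_p`, optional `beta`), the
#'   association refit in the replication cohort; `NA` rows mark untested
#'   loci.
#' @param n_discovered Number of discovered loci defining the Bonferroni
#'   denominator (>= 1).
#' @param discovery_beta Optional named vector of discovery-stage effect
#'   sizes for direction-concordance bookkeeping.
#' @return `data.frame` of class `"replication_result"`: `variant_id`,
#'   `neglog10_p`, `threshold_neglog10`, `replicated`, `tested`,
#'   `direction_concordant` (`NA` without betas).
#' @export
replication_test <- function(results, n_discovered, discovery_beta = NULL) {
  stopifnot_scalar_number(n_discovered, "n_discovered", lower = 1)
  thr <- -log10(0.05 / n_discovered)
  tested <- !is.na(results$neglog10_p)
  conc <- rep(NA, nrow(results))
  if (!is.null(discovery_beta) && "beta" %in% names(results)) {
    db <- discovery_beta[results$variant_id]
    conc <- sign(results$beta) == sign(db)
  }
  out <- data.frame(
    variant_id = results$variant_id,
    neglog10_p = results$neglog10_p,
    threshold_neglog10 = thr,
    tested = tested,
    replicated = tested & results$neglog10_p > thr,
    direction_concordant = conc,
    stringsAsFactors = FALSE
  )
  class(out) <- c("replication_result", "data.frame")
  out
}

#' Estimate replication power by repeated subsampling of the discovery set
#'
#' For each locus, draws `n_reps` subsamples of `n_sub` records without
#' replacement from the discovery cohort (a fresh deterministic seed
#' stream per replicate), refits the lead association on each subsample,
#' and reports the fraction of replicates reaching the significance
#' threshold.
#'
#' @param phenotypes samples x loci matrix: column `j` is the lead
#'   phenotype (INT scale) of locus `j`.
#' @param dosages samples x loci matrix of the matching lead-variant
#'   dosages (a single vector is recycled across loci).
#' @param covariates Optional covariate table.
#' @param n_sub Subsample size (the held-out cohort's size in the emulated
#'   design); must not exceed the cohort size.
#' @param n_reps Number of subsamples (default 100).
#' @param threshold_neglog10 Significance level on the negative-log10
#'   scale.
#' @param seed Master seed for the replicate streams.
#' @return `data.frame`: `locus`, `power`, `n_subsamples`; attribute
#'   `"hits"` holds the per-replicate significance matrix.
#' @export
replication_power <- function(phenotypes, dosages, covariates = NULL,
                              n_sub, n_reps = 100, threshold_neglog10,
                              seed = 1L) {
  phenotypes <- as.matrix(phenotypes)
  n <- nrow(phenotypes)
  if (is.null(dim(dosages))) {
    dosages <- matrix(dosages, n, ncol(phenotypes))
  }
  stopifnot_scalar_number(n_reps, "n_reps", lower = 1)
  if (n_sub > n) stop("n_sub exceeds the cohort size", call. = FALSE)
  C <- covar_matrix(covariates)
  hits <- matrix(FALSE, n_reps, ncol(phenotypes),
                 dimnames = list(NULL, colnames(phenotypes)))
  for (r in seq_len(n_reps)) {
    idx <- with_seed(derive_seed(seed, r), sample.int(n, n_sub))
    for (j in seq_len(ncol(phenotypes))) {
      fit <- fit_one_safe(phenotypes[idx, j], dosages[idx, j],
                          if (!is.null(C)) C[idx, , drop = FALSE],
                          NA_character_, NA_character_, NEGLOG10_CAP)
      hits[r, j] <- isTRUE(fit$neglog10_p > threshold_neglog10)
    }
  }
  out <- data.frame(
    locus = colnames(phenotypes) %||% paste0("L", seq_len(ncol(phenotypes))),
    power = colMeans(hits),
    n_subsamples = n_reps,
    stringsAsFactors = FALSE
  )
  attr(out, "hits") <- hits
  out
}

#' Classify an event as incident, prevalent, or absent
#'
#' An event strictly after the assessment date is incident; an event on or
#' before the assessment date is prevalent; no event date means none.
#' Vectorized; dates may be `Date` or ISO-8601 strings.
#'
#' @param event_date Event dates (`NA` = no event).
#' @param assessment_date Assessment dates (must be present).
#' @return Factor with levels `incident`, `prevalent`, `none`.
#' @export
incident_event_flag <- function(event_date, assessment_date) {
  parse_date <- function(x, what) {
    if (inherits(x, "Date")) return(x)
    raw_missing <- is.na(x)
    d <- as.Date(as.character(x), format = "%Y-%m-%d")
    bad <- which(is.na(d) & !raw_missing)
    if (length(bad)) {
      stop(sprintf("unparseable %s date at sample index %d: '%s'",
                   what, bad[1], as.character(x)[bad[1]]), call. = FALSE)
    }
    d
  }
  ev <- parse_date(event_date, "event")
  as_ <- parse_date(assessment_date, "assessment")
  if (anyNA(as_)) stop("assessment_date must be present for every sample",
                       call. = FALSE)
  out <- ifelse(is.na(ev), "none", ifelse(ev > as_, "incident", "prevalent"))
  factor(out, levels = c("incident", "prevalent", "none"))
}

#' Median-split groups crossed with medication use
#'
#' Computes the trait median over the included samples (after excluding,
#' e.g., prevalent cases) and assigns each included sample to one of four
#' groups: \{high, low\} x \{medication, none\}.  Values equal to the
#' median go to "low" (strictly-above rule).
#'
#' @param values Trait vector (e.g. HDL-P % on any monotone scale).
#' @param medication Binary 0/1 medication flags.
#' @param exclusions Logical mask of samples to exclude (e.g. prevalent
#'   events); excluded samples get `NA` group.
#' @return Factor with levels `low_none`, `low_med`, `high_none`,
#'   `high_med`; attributes `"median"` and `"counts"`.
#' @export
median_split_groups <- function(values, medication, exclusions = NULL) {
  inc <- !is.na(values) & !is.na(medication)
  if (!is.null(exclusions)) inc <- inc & !exclusions
  if (!sum(inc)) stop("no samples left after exclusions", call. = FALSE)
  v <- values[inc]
  if (max(v) == min(v)) stop("constant trait: median split degenerate",
                             call. = FALSE)
  med <- median(v)
  g <- rep(NA_character_, length(values))
  g[inc] <- paste0(ifelse(values[inc] > med, "high", "low"),
                   ifelse(medication[inc] == 1, "_med", "_none"))
  g <- factor(g, levels = c("low_none", "low_med", "high_none", "high_med"))
  attr(g, "median") <- med
  attr(g, "counts") <- table(g)
  g
}

#' Kaplan-Meier risk at a fixed horizon
#'
#' Product-limit survival per group, evaluated at the horizon; risk is
#' `1 - S(horizon)` with a symmetric 95% normal CI from the Greenwood
#' variance of `S`, clipped to `[0, 1]`.  Follow-up beyond the horizon is
#' administratively censored at the horizon, so with no earlier censoring
#' the risk reduces exactly to the empirical event fraction.
#'
#' @param times Follow-up times in years (>= 0).
#' @param events Logical/0-1 event indicators.
#' @param groups Optional group labels (one estimate per level); `NULL`
#'   for a single overall estimate.
#' @param horizon Horizon in years (default 10).
#' @return `data.frame` of class `"survival_estimate"`: `group`, `n`,
#'   `events`, `risk`, `ci_low`, `ci_high`.
#' @export
km_risk <- function(times, events, groups = NULL, horizon = 10) {
  stopifnot_scalar_number(horizon, "horizon", lower = 0, strict_lower = TRUE)
  if (any(times < 0, na.rm = TRUE)) stop("negative follow-up time", call. = FALSE)
  events <- as.logical(events)
  if (is.null(groups)) groups <- rep("all", length(times))
  keep <- !is.na(times) & !is.na(events) & !is.na(groups)
  t2 <- pmin(times[keep], horizon)
  e2 <- events[keep] & times[keep] <= horizon
  gr <- droplevels(factor(groups[keep]))
  rows <- lapply(levels(gr), function(g) {
    i <- gr == g
    if (!sum(i)) return(NULL)
    fit <- survival::survfit(survival::Surv(t2[i], e2[i]) ~ 1)
    sm <- summary(fit, times = horizon, extend = TRUE)
    s <- sm$surv
    se_s <- sm$std.err # Greenwood SE of S
    risk <- 1 - s
    data.frame(group = g, n = sum(i), events = sum(e2[i]),
               risk = risk,
               ci_low = max(0, risk - 1.96 * se_s),
               ci_high = min(1, risk + 1.96 * se_s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("survival_estimate", "data.frame")
  out
}
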