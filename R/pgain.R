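# The p-gain statistic and the multiple-testing framework around it.

#' Bonferroni-style significance thresholds for trait and ratio families
#'
#' All thresholds derive from a genome-wide alpha and family sizes; nothing
#' is hand-set.  On the negative-log10 scale:
#' \itemize{
#'   \item `p_ref = -log10(alpha_gw / m_lipids)` for the classical lipid
#'     panel,
#'   \item `p_nmr = -log10(alpha_gw / m_traits)` for the full trait panel,
#'   \item `p_nightratios = -log10(alpha_gw / m_night)` for a curated ratio
#'     subset,
#'   \item `p_allratios = -log10(alpha_gw / m_all)` with
#'     `m_all = m_traits (m_traits + 1) / 2` for all ratios and traits,
#'   \item `pgain_allratios_log10 = log10(pgain_single * genomewide_tests *
#'     m_all)` for the p-gain.
#' }
#' A p-gain of `pgain_single = 10` corresponds to nominal 0.05 significance
#' of a single ratio test; the genome-wide multiplier reflects ~1e6
#' independent variants.
#'
#' @param alpha_gw Genome-wide alpha (default `5e-8`).
#' @param m_lipids Number of classical lipid traits (default 5).
#' @param m_traits Number of panel traits (default 168).
#' @param m_night Size of the curated ratio subset; `NULL` to skip.
#' @param pgain_single Single-test p-gain significance level (default 10).
#' @param genomewide_tests Genome-wide test multiplier (default 1e6).
#' @return A list of class `"threshold_set"`; all `p_*` entries are
#'   negative-log10 thresholds at full precision (the print method rounds
#'   to one decimal for display).
#' @examples
#' compute_thresholds() # p_nmr 9.5, p_allratios 11.5, p-gain 11.2
#' @export
compute_thresholds <- function(alpha_gw = 5e-8, m_lipids = 5, m_traits = 168,
                               m_night = 249, pgain_single = 10,
                               genomewide_tests = 1e6) {
  stopifnot_scalar_number(alpha_gw, "alpha_gw", lower = 0, upper = 1,
                          strict_lower = TRUE)
  for (m in c(m_lipids, m_traits, m_night %||% 1)) {
    stopifnot_scalar_number(m, "m", lower = 1)
  }
  m_all <- m_traits * (m_traits + 1) / 2
  out <- structure(list(
    alpha_gw = alpha_gw, m_lipids = m_lipids, m_traits = m_traits,
    m_night = m_night, m_all = m_all,
    pgain_single = pgain_single, genomewide_tests = genomewide_tests,
    p_ref = -log10(alpha_gw / m_lipids),
    p_nmr = -log10(alpha_gw / m_traits),
    p_nightratios = if (!is.null(m_night)) -log10(alpha_gw / m_night),
    p_allratios = -log10(alpha_gw / m_all),
    pgain_allratios_log10 = log10(pgain_single * genomewide_tests * m_all)
  ), class = "threshold_set")
  if (m_lipids <= m_traits) { # threshold ordering only holds for nested panels
    stopifnot(out$p_ref <= out$p_nmr + 1e-12,
              out$p_nmr <= out$p_allratios + 1e-12)
  }
  out
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set>\n")
  cat(sprintf("  alpha_gw = %g; families: %d lipids, %d traits, %d ratios+traits\n",
              x$alpha_gw, x$m_lipids, x$m_traits, x$m_all))
  cat(sprintf("  p_ref         = %.1f\n", x$p_ref))
  cat(sprintf("  p_nmr         = %.1f\n", x$p_nmr))
  if (!is.null(x$p_nightratios)) {
    cat(sprintf("  p_nightratios = %.1f\n", x$p_nightratios))
  }
  cat(sprintf("  p_allratios   = %.1f\n", x$p_allratios))
  cat(sprintf("  log10 p-gain  = %.1f\n", x$pgain_allratios_log10))
  invisible(x)
}

#' Compute the p-gain of a ratio association
#'
#' The p-gain is the smaller of the two single-trait p-values divided by
#' the ratio p-value; on the log10 scale this is exact arithmetic on
#' negative-log10 p-values,
#' `log10_pgain = neglog10_p_ratio - max(neglog10_p_a, neglog10_p_b)`,
#' and never re-exponentiates (so p-gains thousands of orders of magnitude
#' large stay exact).  Negative values (ratio weaker than the best single
#' trait) are permitted.
#'
#' @param res_a,res_b Single-trait [fit_linear_assoc()] results for the
#'   numerator and denominator traits.
#' @param res_ratio The ratio-test result; all three must share a variant.
#' @param thresholds A [compute_thresholds()] set used to flag
#'   significance: `significant_ratio` compares the ratio p-value to
#'   `p_allratios`, `significant_pgain` compares the log10 p-gain to
#'   `pgain_allratios_log10`.
#' @return One-row `data.frame` of class `"pgain_record"`.
#' @export
compute_pgain <- function(res_a, res_b, res_ratio, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  v <- unique(c(res_a$variant_id, res_b$variant_id, res_ratio$variant_id))
  if (length(v) != 1L) {
    stop("the three results must share one variant id", call. = FALSE)
  }
  pgain_records(
    variant_id = v, test_id = res_ratio$test_id,
    trait_a = res_a$test_id, trait_b = res_b$test_id,
    neglog10_p_a = res_a$neglog10_p, neglog10_p_b = res_b$neglog10_p,
    neglog10_p_ratio = res_ratio$neglog10_p, thresholds = thresholds
  )
}

# Vectorized record builder shared by compute_pgain() and pgain_table().
pgain_records <- function(variant_id, test_id, trait_a, trait_b,
                          neglog10_p_a, neglog10_p_b, neglog10_p_ratio,
                          thresholds) {
  log10_pgain <- neglog10_p_ratio - pmax(neglog10_p_a, neglog10_p_b)
  out <- data.frame(
    variant_id = variant_id, test_id = test_id,
    trait_a = trait_a, trait_b = trait_b,
    neglog10_p_a = neglog10_p_a, neglog10_p_b = neglog10_p_b,
    neglog10_p_ratio = neglog10_p_ratio,
    log10_pgain = log10_pgain,
    significant_ratio = neglog10_p_ratio > thresholds$p_allratios,
    significant_pgain = log10_pgain > thresholds$pgain_allratios_log10,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pgain_record", "data.frame")
  out
}

#' Build the p-gain table for a whole association scan
#'
#' Joins every ratio-test result with its two component single-trait
#' results (same variant) and computes all p-gain records.
#'
#' @param results An `assoc_result` `data.frame` from
#'   [scan_associations()] covering singles and ratios.
#' @param tests The test table from [enumerate_tests()].
#' @param thresholds A [compute_thresholds()] set.
#' @return A `"pgain_record"` `data.frame`, one row per
#'   (variant, ratio) with both component traits available.
#' @export
pgain_table <- function(results, tests, thresholds) {
  ratios <- tests[tests$kind == "ratio", , drop = FALSE]
  singles <- results[results$test_id %in% tests$test_id[tests$kind == "single"], ]
  key <- function(v, t) paste(v, t, sep = "\r")
  nlp <- setNames(singles$neglog10_p, key(singles$variant_id, singles$test_id))
  rr <- results[results$test_id %in% ratios$test_id, , drop = FALSE]
  ta <- ratios$trait_a[match(rr$test_id, ratios$test_id)]
  tb <- ratios$trait_b[match(rr$test_id, ratios$test_id)]
  pa <- nlp[key(rr$variant_id, ta)]
  pb <- nlp[key(rr$variant_id, tb)]
  ok <- !is.na(pa) & !is.na(pb) & !is.na(rr$neglog10_p)
  pgain_records(rr$variant_id[ok], rr$test_id[ok], ta[ok], tb[ok],
                unname(pa[ok]), unname(pb[ok]), rr$neglog10_p[ok], thresholds)
}

#' Composite linkage disequilibrium r-squared between two variants
#'
#' Squared Pearson correlation of additive dosages over complete pairs;
#' invariant to allele flips (`g -> 2 - g`).
#'
#' @param dosage_a,dosage_b Dosage vectors of equal length.
#' @return A value in `[0, 1]`.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  cc <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(cc) < 2) stop("fewer than 2 complete pairs", call. = FALSE)
  a <- dosage_a[cc]; b <- dosage_b[cc]
  if (max(a) == min(a) || max(b) == min(b)) {
    stop("constant dosage vector", call. = FALSE)
  }
  cor(a, b)^2
}

#' Curate lead variants: MAF filter, significance filter, LD pruning
#'
#' Applies the lead-variant curation rules of a targeted fine-mapping
#' design: keep variants with MAF strictly above `maf_min` and a best
#' association at `neglog10_p >= p_min_neglog10`; collapse duplicate lead
#' variants (several conditional models on one variant) to the strongest
#' model; then greedily prune by LD, walking variants in decreasing
#' association strength (ties broken by variant id) and dropping any
#' variant with `r^2 >= r2_max` to an already-kept variant.
#'
#' @param variants `data.frame` with columns `variant_id`, `neglog10_p`
#'   (strength of the variant's best association), optional `model_id`.
#' @param geno Genotype matrix holding a dosage column per listed variant.
#' @param r2_max LD pruning threshold (default 0.7).
#' @param maf_min MAF exclusion bound, exclusive (default 0.01).
#' @param p_min_neglog10 Minimum association strength (default 8).
#' @return The curated subset of `variants`, strongest first, with a
#'   `kept` reason trail in attribute `"dropped"`.
#' @export
curate_variants <- function(variants, geno, r2_max = 0.7, maf_min = 0.01,
                            p_min_neglog10 = 8) {
  need <- c("variant_id", "neglog10_p")
  if (!all(need %in% names(variants))) {
    stop("`variants` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  missing_g <- setdiff(variants$variant_id, colnames(geno))
  if (length(missing_g)) {
    stop("no dosage column for variant(s): ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  }
  freq <- colMeans(geno[, variants$variant_id, drop = FALSE], na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  dropped <- list()
  keep <- maf[variants$variant_id] > maf_min
  dropped$maf <- variants$variant_id[!keep]
  v <- variants[keep, , drop = FALSE]
  keep <- v$neglog10_p >= p_min_neglog10
  dropped$weak <- v$variant_id[!keep]
  v <- v[keep, , drop = FALSE]
  # duplicate collapse: strongest model per variant id
  v <- v[order(-v$neglog10_p, v$variant_id), , drop = FALSE]
  dup <- duplicated(v$variant_id)
  dropped$duplicate_model <- v$variant_id[dup]
  v <- v[!dup, , drop = FALSE]
  # greedy LD prune in descending strength order
  kept <- character(0)
  pruned <- character(0)
  for (i in seq_len(nrow(v))) {
    vid <- v$variant_id[i]
    hit <- any(vapply(kept, function(k) {
      ld_r2(geno[, vid], geno[, k]) >= r2_max
    }, logical(1)))
    if (hit) pruned <- c(pruned, vid) else kept <- c(kept, vid)
  }
  dropped$ld <- pruned
  out <- v[v$variant_id %in% kept, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Select the lead association at a locus
#'
#' The lead is the record with the largest `neglog10_p` (for ratio
#' families, `neglog10_p_ratio`); for p-gain records the lead ratio by
#' p-gain -- the largest `log10_pgain` among p-gain-significant records --
#' is returned alongside.  The locus is flagged significant if the lead
#' passes the family threshold.
#'
#' @param records `assoc_result` or `pgain_record` rows for one locus.
#' @param thresholds A [compute_thresholds()] set.
#' @param family One of `"five_lipids"`, `"nmr"`, `"all_ratios"` selecting
#'   the threshold (`p_ref`, `p_nmr`, `p_allratios`).
#' @return List: `lead` (one row or `NULL` if `records` is empty),
#'   `significant` (logical), and for p-gain input `lead_pgain` (the lead
#'   ratio by p-gain among significant p-gains, or `NULL`).
#' @export
select_lead <- function(records, thresholds,
                        family = c("five_lipids", "nmr", "all_ratios")) {
  family <- match.arg(family)
  thr <- switch(family, five_lipids = thresholds$p_ref,
                nmr = thresholds$p_nmr, all_ratios = thresholds$p_allratios)
  if (NROW(records) == 0) {
    return(list(lead = NULL, significant = FALSE, lead_pgain = NULL))
  }
  nlp <- if ("neglog10_p_ratio" %in% names(records)) {
    records$neglog10_p_ratio
  } else {
    records$neglog10_p
  }
  ord <- order(-nlp, records$test_id)
  lead <- records[ord[1], , drop = FALSE]
  out <- list(lead = lead, significant = nlp[ord[1]] > thr, lead_pgain = NULL)
  if ("log10_pgain" %in% names(records)) {
    sig <- which(records$significant_pgain)
    if (length(sig)) {
      o2 <- sig[order(-records$log10_pgain[sig], records$test_id[sig])]
      out$lead_pgain <- records[o2[1], , drop = FALSE]
    }
  }
  out
}

#' Summarize discovery counts and percentages across test families
#'
#' Given per-locus significance flags under one threshold set, emits the
#' discovery bookkeeping: how many loci replicated with the reference
#' lipid panel, how many became significant with the full trait panel and
#' with all ratios, how many ratio discoveries were new or lost relative
#' to the trait panel, and how many trait-significant loci carried a
#' significant p-gain -- together with the derived percentages (one
#' decimal).
#'
#' @param flags `data.frame` with one row per locus and logical columns
#'   `sig_ref`, `sig_nmr`, `sig_ratio`, `sig_pgain`.
#' @param replication Optional list/`data.frame` with counts
#'   `n_high_power` and `n_replicated` from a replication study, adding
#'   the replicated-given-power percentage.
#' @return A list of class `"discovery_summary"` with components `counts`
#'   and `percent` (named numeric vectors; percentages rounded to one
#'   decimal).
#' @export
count_discoveries <- function(flags, replication = NULL) {
  need <- c("sig_ref", "sig_nmr", "sig_ratio", "sig_pgain")
  if (!all(need %in% names(flags))) {
    stop("`flags` needs logical columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(flags[need])) {
    stop("inconsistent locus sets: NA flags present", call. = FALSE)
  }
  counts <- c(
    n_loci = nrow(flags),
    n_ref = sum(flags$sig_ref),
    n_nmr = sum(flags$sig_nmr),
    n_ratio = sum(flags$sig_ratio),
    n_pgain = sum(flags$sig_nmr & flags$sig_pgain),
    n_new_ratio = sum(flags$sig_ratio & !flags$sig_nmr),
    n_lost_ratio = sum(flags$sig_nmr & !flags$sig_ratio)
  )
  pct <- c(
    pct_replicated = 100 * counts[["n_ref"]] / counts[["n_loci"]],
    pct_additional_nmr =
      100 * (counts[["n_nmr"]] - counts[["n_ref"]]) / counts[["n_ref"]],
    pct_new_via_ratios = 100 * counts[["n_new_ratio"]] / counts[["n_nmr"]],
    pct_pgain_linking = 100 * counts[["n_pgain"]] / counts[["n_nmr"]]
  )
  if (!is.null(replication)) {
    counts <- c(counts,
                n_high_power = replication$n_high_power,
                n_replicated = replication$n_replicated)
    pct <- c(pct, pct_replicated_high_power =
               100 * replication$n_replicated / replication$n_high_power)
  }
  structure(list(counts = counts, percent = round(pct, 1)),
            class = "discovery_summary")
}

#' @export
print.discovery_summary <- function(x, ...) {
  cat("<discovery_summary>\n  counts:\n")
  for (nm in names(x$counts)) cat(sprintf("    %-22s %d\n", nm, x$counts[[nm]]))
  cat("  percent:\n")
  for (nm in names(x$percent)) cat(sprintf("    %-26s %.1f\n", nm, x$percent[[nm]]))
  invisible(x)
}
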