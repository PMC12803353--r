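# P-gain arithmetic, threshold formulas, variant curation, discovery
# bookkeeping.

test_that("compute_thresholds reproduces the published formula set", {
  thr <- compute_thresholds(5e-8, 5, 168, 249)
  expect_equal(round(thr$p_ref, 1), 8.0)
  expect_equal(round(thr$p_nmr, 1), 9.5)
  expect_equal(round(thr$p_nightratios, 1), 9.7)
  expect_equal(round(thr$p_allratios, 1), 11.5)
  expect_equal(round(thr$pgain_allratios_log10, 1), 11.2)
  expect_equal(thr$m_all, 14196)
})

test_that("compute_thresholds covers degenerate and derived panels", {
  unit <- compute_thresholds(5e-8, 5, 1, NULL)
  expect_equal(unit$m_all, 1)
  expect_equal(unit$pgain_allratios_log10, 7.0)
  t20 <- compute_thresholds(5e-8, 5, 20, NULL)
  expect_equal(t20$m_all, 210)
  expect_equal(t20$p_allratios, -log10(5e-8 / 210), tolerance = 1e-12)
  expect_error(compute_thresholds(alpha_gw = 0), "alpha_gw")
})

test_that("compute_pgain is exact arithmetic on neglog10 values", {
  thr <- compute_thresholds()
  mk <- function(v, t, nlp) data.frame(variant_id = v, test_id = t,
                                       neglog10_p = nlp)
  # published worked example: LA / PUFA at the FADS2 lead variant
  rec <- compute_pgain(mk("rs174564", "LA", 169.6),
                       mk("rs174564", "PUFA", 282.5),
                       mk("rs174564", "LA/PUFA", 5101.7), thr)
  expect_equal(rec$log10_pgain, 4819.2)
  expect_true(rec$significant_pgain)
  rec2 <- compute_pgain(mk("rs12928099", "LA", 3.1),
                        mk("rs12928099", "PUFA", 20.1),
                        mk("rs12928099", "LA/PUFA", 170.4), thr)
  expect_equal(rec2$log10_pgain, 150.3)
  # no-gain boundary
  rec3 <- compute_pgain(mk("v", "A", 5), mk("v", "B", 9),
                        mk("v", "A/B", 9), thr)
  expect_equal(rec3$log10_pgain, 0)
  expect_error(compute_pgain(mk("v1", "A", 5), mk("v2", "B", 9),
                             mk("v1", "A/B", 9), thr),
               "share one variant")
})

test_that("pgain_table joins ratio results with their components", {
  co <- make_small_cohort(n = 300)
  thr <- compute_thresholds(m_traits = 6)
  res <- scan_associations(co$geno[, 1:3], co$phenotypes, co$covariates)
  pg <- pgain_table(res, co$tests, thr)
  expect_equal(nrow(pg), 3 * choose(6, 2))
  # invariant: log10_pgain = nlp_ratio - max(component nlps), exactly
  expect_identical(pg$log10_pgain,
                   pg$neglog10_p_ratio - pmax(pg$neglog10_p_a,
                                              pg$neglog10_p_b))
  i <- which(pg$variant_id == "v001" & pg$test_id == "T1/T2")
  a <- res[res$variant_id == "v001" & res$test_id == "T1", "neglog10_p"]
  expect_equal(pg$neglog10_p_a[i], a)
})

test_that("ld_r2 is the squared dosage correlation", {
  a <- c(0, 1, 2, 0)
  b <- c(0, 1, 1, 1)
  expect_equal(ld_r2(a, a), 1.0)
  expect_equal(ld_r2(a, 2 - a), 1.0)      # allele-flip invariance
  expect_equal(ld_r2(a, b), cor(a, b)^2)  # hand correlation oracle
  expect_error(ld_r2(a, rep(1, 4)), "constant")
  expect_error(ld_r2(c(1, NA, NA, NA), c(1, NA, NA, NA)), "complete pairs")
})

test_that("curate_variants filters, collapses and prunes deterministically", {
  set.seed(31)
  n <- 400
  v1 <- rbinom(n, 2, 0.3)
  v2 <- v1                               # r^2 = 1 with v1
  v3 <- rbinom(n, 2, 0.4)                # independent
  v4 <- rbinom(n, 2, 0.005)              # MAF below 1%
  geno <- cbind(v1 = v1, v2 = v2, v3 = v3, v4 = v4)
  variants <- data.frame(
    variant_id = c("v1", "v1", "v2", "v3", "v4"),
    model_id = c("m1", "m2", "m1", "m1", "m1"),
    neglog10_p = c(300, 200, 40, 30, 500)
  )
  out <- curate_variants(variants, geno)
  # duplicate collapse keeps the strongest model of v1
  expect_equal(out$neglog10_p[out$variant_id == "v1"], 300)
  # greedy LD pruning drops v2 (r^2 >= 0.7 with the stronger v1), keeps v3
  expect_setequal(out$variant_id, c("v1", "v3"))
  # MAF 0.5% excluded regardless of strength
  expect_true("v4" %in% attr(out, "dropped")$maf)
  # weak associations excluded
  weak <- curate_variants(
    data.frame(variant_id = "v3", neglog10_p = 5), geno)
  expect_equal(nrow(weak), 0)
  expect_error(curate_variants(data.frame(variant_id = "zz", neglog10_p = 9),
                               geno), "no dosage")
})

test_that("curate_variants greedy pruning matches the brute-force oracle", {
  # three variants, r2(v1,v2) ~ 0.9, low r2 to v3, strengths 50 > 40 > 30
  set.seed(32)
  n <- 2000
  v1 <- rbinom(n, 2, 0.5)
  v2 <- v1; flip <- sample(n, 60); v2[flip] <- rbinom(60, 2, 0.5)
  v3 <- rbinom(n, 2, 0.5)
  geno <- cbind(v1 = v1, v2 = v2, v3 = v3)
  expect_gte(ld_r2(v1, v2), 0.7)
  expect_lt(ld_r2(v1, v3), 0.7)
  out <- curate_variants(
    data.frame(variant_id = c("v1", "v2", "v3"),
               neglog10_p = c(50, 40, 30)),
    geno)
  expect_identical(out$variant_id, c("v1", "v3"))
})

test_that("select_lead equals an exhaustive max scan", {
  thr <- compute_thresholds(m_traits = 6)
  set.seed(41)
  recs <- data.frame(
    variant_id = "v", test_id = paste0("t", 1:100),
    neglog10_p = runif(100, 0, 20)
  )
  sl <- select_lead(recs, thr, "nmr")
  expect_equal(sl$lead$neglog10_p, max(recs$neglog10_p))
  expect_identical(sl$significant, max(recs$neglog10_p) > thr$p_nmr)
  # below-threshold list still returns its lead, flagged FALSE
  low <- recs; low$neglog10_p <- low$neglog10_p / 100
  expect_false(select_lead(low, thr, "nmr")$significant)
  expect_null(select_lead(recs[0, ], thr, "nmr")$lead)
})

test_that("count_discoveries reproduces printed-count percentages", {
  # flag table realizing the published counts: 1054 loci, 274 replicated,
  # 446 trait-significant, 554 ratio-significant (446 - 6 + 114), 327
  # with significant p-gain
  flags <- data.frame(
    sig_ref = rep(c(TRUE, FALSE), c(274, 780)),
    sig_nmr = rep(c(TRUE, FALSE), c(446, 608)),
    sig_ratio = rep(c(TRUE, FALSE, TRUE, FALSE),
                    c(440, 6, 114, 494)),
    sig_pgain = rep(c(TRUE, FALSE), c(327, 727))
  )
  s <- count_discoveries(flags, replication = list(n_high_power = 163,
                                                   n_replicated = 140))
  expect_equal(unname(s$counts["n_ref"]), 274)
  expect_equal(unname(s$counts["n_ratio"]), 554)
  expect_equal(unname(s$counts["n_new_ratio"]), 114)
  expect_equal(unname(s$counts["n_lost_ratio"]), 6)
  expect_equal(unname(s$percent["pct_replicated"]), 26.0)
  expect_equal(unname(s$percent["pct_additional_nmr"]), 62.8)
  expect_equal(unname(s$percent["pct_new_via_ratios"]), 25.6)
  expect_equal(unname(s$percent["pct_pgain_linking"]), 73.3)
  expect_equal(unname(s$percent["pct_replicated_high_power"]), 85.9)
  # degenerate: nothing significant
  z <- count_discoveries(data.frame(sig_ref = rep(FALSE, 10),
                                    sig_nmr = FALSE, sig_ratio = FALSE,
                                    sig_pgain = FALSE))
  expect_equal(unname(z$percent["pct_replicated"]), 0.0)
  expect_error(count_discoveries(data.frame(sig_ref = NA, sig_nmr = TRUE,
                                            sig_ratio = TRUE,
                                            sig_pgain = TRUE)), "NA")
})
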