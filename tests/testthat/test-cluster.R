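# P-gain matrix construction, per-locus normalization, clustering, and
# effect-profile comparisons.

make_records <- function(df, thr) {
  pg <- df$neglog10_p_ratio - pmax(df$neglog10_p_a, df$neglog10_p_b)
  out <- cbind(df, log10_pgain = pg,
               significant_ratio = df$neglog10_p_ratio > thr$p_allratios,
               significant_pgain = pg > thr$pgain_allratios_log10)
  class(out) <- c("pgain_record", "data.frame")
  out
}

test_that("build_pgain_matrix dedupes lead ratios and drops empty sets", {
  thr <- compute_thresholds(m_traits = 6)
  # three loci all lead on the same ratio -> one row, three columns
  df <- data.frame(
    variant_id = c("L1", "L2", "L3"), test_id = "T1/T2",
    trait_a = "T1", trait_b = "T2",
    neglog10_p_a = 1, neglog10_p_b = 2,
    neglog10_p_ratio = c(15, 14, 16)
  )
  m <- build_pgain_matrix(make_records(df, thr), thr)
  expect_equal(dim(m), c(1L, 3L))
  expect_equal(m["T1/T2", "L2"], 12)  # 14 - 2
  # nothing significant -> empty matrix with warning
  df$neglog10_p_ratio <- 3
  expect_warning(m0 <- build_pgain_matrix(make_records(df, thr), thr),
                 "empty")
  expect_equal(ncol(m0), 0)
})

test_that("build_pgain_matrix rows equal a brute-force lead recomputation", {
  co <- make_small_cohort(n = 2000)
  thr <- compute_thresholds(m_traits = 6)
  res <- scan_associations(co$geno, co$phenotypes, co$covariates)
  pg <- pgain_table(res, co$tests, thr)
  m <- build_pgain_matrix(pg, thr)
  # brute force: per significant locus, the max-log10_pgain significant row
  sig <- unique(pg$variant_id[pg$significant_pgain])
  leads <- vapply(sig, function(v) {
    sub <- pg[pg$variant_id == v & pg$significant_pgain, ]
    sub$test_id[which.max(sub$log10_pgain)]
  }, character(1))
  expect_setequal(colnames(m), sig)
  expect_setequal(rownames(m), unique(leads))
  # every lead ratio contains the trait its locus genuinely affects (for
  # confounded loci all ratios with that trait cancel the confounder
  # equally well, so the partner trait is noise-determined)
  for (v in sig) {
    lead <- leads[[v]]
    num <- co$specs$trait_num[co$specs$id == v]
    expect_true(num %in% strsplit(lead, "/")[[1]], info = v)
  }
})

test_that("normalize_per_locus scales every column max to 1 and is idempotent", {
  m <- cbind(L1 = c(2, 4, 8), L2 = c(1, 1, 1), L3 = c(0, 3, 6))
  rownames(m) <- paste0("r", 1:3)
  attr(m, "stage") <- "raw"
  nm <- normalize_per_locus(m)
  expect_equal(unname(nm[, "L1"]), c(0.25, 0.5, 1.0))
  expect_equal(unname(nm[, "L2"]), c(1, 1, 1))
  expect_equal(normalize_per_locus(nm), nm, ignore_attr = TRUE)
  set.seed(9)
  r <- matrix(abs(rnorm(60)) + 0.1, 6, 10,
              dimnames = list(paste0("r", 1:6), paste0("L", 1:10)))
  attr(r, "stage") <- "raw"
  expect_lt(max(abs(apply(normalize_per_locus(r), 2, max) - 1)), 1e-12)
  bad <- cbind(L1 = c(1, 2), L2 = c(0, 0))
  expect_warning(nb <- normalize_per_locus(bad), "non-positive")
  expect_equal(colnames(nb), "L1")
})

test_that("hierarchical_cluster merges identical columns first and recovers blocks", {
  set.seed(10)
  m <- matrix(runif(40), 8, 5,
              dimnames = list(paste0("r", 1:8), paste0("L", 1:5)))
  m <- cbind(m, L6 = m[, "L3"])  # exact duplicate column
  cl <- hierarchical_cluster(m)
  merged_first <- cl$col_tree$merge[1, ]
  labs <- cl$col_tree$labels[-merged_first]
  expect_setequal(labs, c("L3", "L6"))
  expect_equal(cl$col_tree$height[1], 0)
  adj <- abs(diff(match(c("L3", "L6"), cl$col_order)))
  expect_equal(adj, 1)

  # planted 2-block structure separates exactly at a 2-cut
  blocks <- rbind(matrix(1, 4, 6), matrix(0, 4, 6)) +
    matrix(rnorm(48, sd = 0.05), 8, 6)
  dimnames(blocks) <- list(paste0("r", 1:8), paste0("L", 1:6))
  clb <- hierarchical_cluster(blocks)
  cut <- cutree(clb$row_tree, k = 2)
  truth <- rep(1:2, each = 4)
  expect_equal(adjusted_rand_index(cut, truth), 1.0)

  # permutation invariance: same topology and heights
  perm <- sample(ncol(blocks))
  clp <- hierarchical_cluster(blocks[, perm])
  expect_equal(sort(clp$col_tree$height), sort(clb$col_tree$height),
               tolerance = 1e-12)
  expect_equal(
    adjusted_rand_index(cutree(clp$col_tree, 2)[colnames(blocks)],
                        cutree(clb$col_tree, 2)[colnames(blocks)]),
    1.0)
  expect_warning(hierarchical_cluster(blocks[1, , drop = FALSE]),
                 "fewer than 2")
})

test_that("compare_effect_profiles matches the direct Pearson formula", {
  tr <- paste0("T", 1:5)
  a <- effect_profile("v1", tr, c(0.1, -0.2, 0.3, 0.05, -0.4))
  expect_equal(compare_effect_profiles(a, a)$pearson_r, 1)
  neg <- effect_profile("v2", tr, -a$beta)
  expect_equal(compare_effect_profiles(a, neg)$pearson_r, -1)
  b <- effect_profile("v3", tr, c(0.2, -0.1, 0.25, 0.0, -0.3))
  # direct formula oracle
  x <- a$beta; y <- b$beta
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  cmp <- compare_effect_profiles(a, b)
  expect_equal(cmp$pearson_r, r_hand, tolerance = 1e-12)
  expect_equal(cmp$r_squared, r_hand^2, tolerance = 1e-12)
  # symmetry
  expect_equal(compare_effect_profiles(b, a)$pearson_r, cmp$pearson_r)
  expect_error(compare_effect_profiles(a, effect_profile("z", tr, rep(1, 5))),
               "constant")
})

test_that("directionality_panel re-signs relative to the reference class", {
  res <- data.frame(
    variant_id = rep(c("v1", "v2", "v3"), each = 3),
    size_class = rep(c("LDL", "HDL", "VLDL"), 3),
    beta = c(0.5, -0.2, 0.1,   # v1: positive at reference
             -0.3, 0.4, -0.1,  # v2: negative at reference -> flipped
             0.0, 0.2, -0.2)   # v3: zero at reference -> flagged
  )
  m <- directionality_panel(res, reference = "LDL")
  expect_true(all(m[, "LDL"] >= 0))
  expect_equal(m["v2", "HDL"], -0.4)
  expect_equal(attr(m, "flagged"), "v3")
  expect_equal(m["v3", "HDL"], 0.2)  # raw sign fallback
  expect_error(directionality_panel(res, "IDL"), "absent")
})

test_that("synthetic opposed classes match generative truth signs", {
  # two size classes with opposite planted directions
  set.seed(20)
  res <- data.frame(
    variant_id = rep(paste0("v", 1:4), each = 2),
    size_class = rep(c("LDL", "HDL"), 4),
    beta = as.vector(rbind(runif(4, 0.1, 1) * c(1, -1, 1, -1),
                           runif(4, 0.1, 1) * c(-1, 1, -1, 1)))
  )
  m <- directionality_panel(res, "LDL")
  expect_true(all(m[, "LDL"] > 0))
  expect_true(all(m[, "HDL"] < 0))
})
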