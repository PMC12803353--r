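# Shared fixtures and independent oracles for the test suite.

# Small standard cohort used across module tests: 6 traits, 10 variants
# (opposed on T1/T2, confounded on T3/T4, rest null).
make_small_cohort <- function(n = 500, seed = 11, na_rate = 0.002,
                              zero_rate = 0.001) {
  specs <- make_variant_specs(10, paste0("T", 1:6), seed = seed)
  geno <- simulate_genotypes(n, specs, seed = seed + 1)
  cfg <- cohort_config(6, seed = seed + 2)
  sim <- simulate_cohort(geno, specs, cfg)
  traits <- inject_missingness(sim$traits, na_rate, zero_rate, seed = seed + 3)
  lg <- log_transform(zeros_to_missing(traits))
  tests <- enumerate_tests(colnames(lg))
  list(specs = specs, geno = geno, config = cfg, traits = traits,
       log_traits = lg, tests = tests,
       phenotypes = build_phenotypes(lg, tests),
       covariates = sim$covariates[c("age", "age2", "sex",
                                     "lipid_lowering_medication")],
       truth = sim$truth)
}

# Adjusted Rand index between two partitions (independent of any
# clustering code in the package).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Arbitrary-precision oracle for -log10 two-sided t/normal tail
# probabilities, computed once with mpmath (50 significant digits) and
# frozen: columns df, |z|, -log10(p).
tail_oracle <- rbind(
  c(30, 1, 0.48770443477398051),
  c(30, 2, 1.2626081925447727),
  c(30, 5, 4.6327058637716164),
  c(30, 10, 10.33958503663427),
  c(30, 20, 18.170755188045072),
  c(30, 30, 23.203995505250547),
  c(30, 36.9, 25.831749450396091),
  c(30, 37.1, 25.900712658561275),
  c(30, 50, 29.727800476587402),
  c(30, 100, 38.70232443148391),
  c(30, 200, 47.719051426856247),
  c(30, 300, 52.999161102052074),
  c(1000, 1, 0.49818457586513166),
  c(1000, 2, 1.3394157998397397),
  c(1000, 5, 6.1695873707836628),
  c(1000, 10, 21.778046086758421),
  c(1000, 20, 74.391229236691326),
  c(1000, 30, 140.81319370434649),
  c(1000, 36.9, 188.08299809042477),
  c(1000, 37.1, 189.44058168179968),
  c(1000, 50, 273.55929986819291),
  c(1000, 100, 522.2738580806306),
  c(1000, 200, 807.9847457743058),
  c(1000, 300, 981.11647004695271),
  c(Inf, 1, 0.4985155458279893),
  c(Inf, 2, 1.3419860844769559),
  c(Inf, 5, 6.2416156767266733),
  c(Inf, 10, 22.817023409822095),
  c(Inf, 20, 88.259065347411611),
  c(Inf, 30, 197.00817926599697),
  c(Inf, 36.9, 297.33525942989378),
  c(Inf, 37.1, 300.55138272227706),
  c(Inf, 50, 544.66530586633267),
  c(Inf, 100, 2173.5705128733704),
  c(Inf, 200, 8688.2887388558992),
  c(Inf, 300, 19545.826871664927)
)
colnames(tail_oracle) <- c("df", "z", "neglog10_p")
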