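# Synthetic cohort generator with known ground truth.
#
# The generative model is deliberately minimal while still exhibiting the
# two mechanisms by which a ratio phenotype can out-perform its component
# traits: (1) an "opposed" variant pushes numerator and denominator in
# opposite directions, so the log-ratio effect is the sum of the two; and
# (2) a "confounded" variant affects only the numerator while both traits
# load on a shared non-genetic confounder, which the log-ratio cancels,
# shrinking the residual variance of the test.

#' Describe a simulated variant
#'
#' A `VariantSpec` carries the allele frequency and the planted genetic
#' architecture of one biallelic variant.
#'
#' @param id Variant identifier (string).
#' @param maf Minor allele frequency, in `(0, 0.5]`.
#' @param scenario One of `"null"` (no genetic effect), `"opposed"`
#'   (effects of opposite sign on the two traits of `target_pair`), or
#'   `"confounded"` (effect on the numerator trait only; the ratio gains
#'   power through the shared confounder loading of the pair).
#' @param theta_num,theta_den Per-allele effects on the natural-log scale
#'   of the numerator / denominator trait.  `theta_den` is the magnitude
#'   subtracted from the denominator in the `"opposed"` scenario.
#' @param target_pair Character vector of length 2 naming the
#'   (numerator, denominator) traits the variant acts on; ignored for
#'   `"null"` variants.
#'
#' @return A one-row `data.frame` with class `"variant_spec"`; rows from
#'   several calls can be `rbind`-ed into a spec table.
#' @examples
#' rbind(
#'   variant_spec("v1", 0.30, "opposed", 0.1, 0.1, c("T1", "T2")),
#'   variant_spec("v2", 0.10, "null")
#' )
#' @export
variant_spec <- function(id, maf, scenario = c("null", "opposed", "confounded"),
                         theta_num = 0, theta_den = 0, target_pair = NULL) {
  scenario <- match.arg(scenario)
  stopifnot_scalar_number(maf, "maf", lower = 0, upper = 0.5, strict_lower = TRUE)
  if (scenario == "null" && (theta_num != 0 || theta_den != 0)) {
    stop("scenario 'null' requires theta_num = theta_den = 0", call. = FALSE)
  }
  if (scenario == "confounded" && theta_den != 0) {
    stop("scenario 'confounded' requires theta_den = 0", call. = FALSE)
  }
  if (scenario != "null") {
    if (is.null(target_pair) || length(target_pair) != 2L) {
      stop("non-null scenarios need a (numerator, denominator) target_pair",
           call. = FALSE)
    }
  } else {
    target_pair <- c(NA_character_, NA_character_)
  }
  out <- data.frame(
    id = as.character(id), maf = maf, scenario = scenario,
    theta_num = theta_num, theta_den = theta_den,
    trait_num = target_pair[1], trait_den = target_pair[2],
    stringsAsFactors = FALSE
  )
  class(out) <- c("variant_spec", "data.frame")
  out
}

#' Cohort-level generator configuration
#'
#' Defaults state the simulated world once: trait residual spread and the
#' confounder scale are typical for log-scale NMR concentrations, the
#' missing/zero rates are the aggregate rates reported for the emulated
#' platform (20,856 NA and 5,940 zero values out of 46,092,312 cells), and
#' the covariate model uses a mid-life age range with weak linear effects.
#'
#' @param n_traits Number of traits in the panel.
#' @param trait_ids Trait names; default `T1..Tm`.
#' @param mu Baseline log-concentration per trait (recycled).
#' @param lambda Confounder loading per trait (recycled).  A common
#'   loading across a trait pair is what powers the "confounded" p-gain
#'   mechanism.
#' @param sigma_trait Residual SD per trait on the log scale (recycled).
#' @param sigma_confounder SD of the shared log-scale confounder.
#' @param na_rate,zero_rate Fractions of cells set missing / set to zero by
#'   [inject_missingness()]; must sum to < 1.
#' @param age_range Uniform age range in years.
#' @param beta_age,beta_sex,beta_med Linear covariate effects on log traits
#'   (age is centered at the range midpoint; sex is 0/1; medication 0/1).
#' @param med_rate Bernoulli rate of the lipid-lowering-medication flag.
#' @param seed Integer seed for all cohort-level randomness.
#'
#' @return A list with class `"cohort_config"`.
#' @export
cohort_config <- function(n_traits,
                          trait_ids = paste0("T", seq_len(n_traits)),
                          mu = 0,
                          lambda = 0.5,
                          sigma_trait = 0.2,
                          sigma_confounder = 1,
                          na_rate = 20856 / 46092312,
                          zero_rate = 5940 / 46092312,
                          age_range = c(40, 70),
                          beta_age = 0.002,
                          beta_sex = 0.05,
                          beta_med = -0.05,
                          med_rate = 0.15,
                          seed = 1L) {
  stopifnot_scalar_number(n_traits, "n_traits", lower = 1)
  if (length(trait_ids) != n_traits || anyDuplicated(trait_ids)) {
    stop("`trait_ids` must be ", n_traits, " unique names", call. = FALSE)
  }
  stopifnot_scalar_number(na_rate, "na_rate", lower = 0, upper = 1, strict_upper = TRUE)
  stopifnot_scalar_number(zero_rate, "zero_rate", lower = 0, upper = 1, strict_upper = TRUE)
  if (na_rate + zero_rate >= 1) {
    stop("na_rate + zero_rate must be < 1", call. = FALSE)
  }
  stopifnot_scalar_number(sigma_confounder, "sigma_confounder", lower = 0, strict_lower = TRUE)
  if (any(rep_len(sigma_trait, n_traits) <= 0)) {
    stop("all `sigma_trait` values must be > 0", call. = FALSE)
  }
  structure(list(
    n_traits = as.integer(n_traits),
    trait_ids = as.character(trait_ids),
    mu = rep_len(mu, n_traits),
    lambda = rep_len(lambda, n_traits),
    sigma_trait = rep_len(sigma_trait, n_traits),
    sigma_confounder = sigma_confounder,
    na_rate = na_rate, zero_rate = zero_rate,
    age_range = age_range, beta_age = beta_age, beta_sex = beta_sex,
    beta_med = beta_med, med_rate = med_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Draws additive dosages in `{0, 1, 2}` independently per sample and
#' variant as `Binomial(2, maf)`, i.e. under Hardy-Weinberg equilibrium.
#'
#' @param n_samples Number of samples (>= 2).
#' @param specs Variant spec table (see [variant_spec()]), or any
#'   `data.frame` with columns `id` and `maf`.
#' @param seed Integer seed; the draw is bit-reproducible given it.
#'
#' @return A numeric `n_samples x n_variants` matrix with sample ids as row
#'   names and variant ids as column names; attribute `"emp_freq"` records
#'   the realized allele frequency per variant.
#' @examples
#' g <- simulate_genotypes(100, variant_spec("v1", 0.3), seed = 1)
#' attr(g, "emp_freq")
#' @export
simulate_genotypes <- function(n_samples, specs, seed) {
  stopifnot_scalar_number(n_samples, "n_samples", lower = 2)
  if (!all(c("id", "maf") %in% names(specs))) {
    stop("`specs` needs columns `id` and `maf`", call. = FALSE)
  }
  if (any(specs$maf <= 0 | specs$maf > 0.5)) {
    stop("all `maf` must be in (0, 0.5]", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  g <- with_seed(seed, {
    vapply(specs$maf, function(p) rbinom(n_samples, 2L, p), numeric(n_samples))
  })
  g <- matrix(g, nrow = n_samples,
              dimnames = list(paste0("S", seq_len(n_samples)), specs$id))
  attr(g, "emp_freq") <- colMeans(g) / 2
  g
}

#' Simulate a trait panel, covariates and ground truth for a cohort
#'
#' Given genotypes and variant specs, draws for each sample a latent
#' log-scale confounder `c_i ~ N(0, sigma_confounder^2)` and builds each
#' log trait as
#' `log x_it = mu_t + lambda_t c_i + sum_v effect(v, t) g_iv +`
#' `beta_age (age_i - mid) + beta_sex sex_i + beta_med med_i + N(0, sigma_t^2)`.
#' Traits are returned as strictly positive raw concentrations
#' (`exp` of the log values); missingness is injected separately by
#' [inject_missingness()].
#'
#' @param geno Genotype matrix from [simulate_genotypes()].
#' @param specs Variant spec table; `target_pair` trait ids must exist in
#'   `config$trait_ids`.
#' @param config A [cohort_config()].
#'
#' @return A list with components `traits` (a raw-stage [trait_matrix()]),
#'   `covariates` (a `data.frame` with `sample_id`, `age`, `age2`, `sex`,
#'   `lipid_lowering_medication` and the latent `confounder`, the latter
#'   for truth-recovery checks only), and `truth` (a `"truth_table"` list
#'   recording every nonzero generative coefficient, the confounder
#'   loadings, and per-variant metadata).
#' @export
simulate_cohort <- function(geno, specs, config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(geno)
  m <- config$n_traits
  traits <- config$trait_ids
  tp <- specs[specs$scenario != "null", , drop = FALSE]
  bad <- setdiff(c(tp$trait_num, tp$trait_den), traits)
  if (length(bad)) {
    stop("target_pair names unknown traits: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  # variant x trait generative effect matrix
  E <- matrix(0, nrow = ncol(geno), ncol = m,
              dimnames = list(colnames(geno), traits))
  for (k in seq_len(nrow(tp))) {
    v <- tp$id[k]
    E[v, tp$trait_num[k]] <- E[v, tp$trait_num[k]] + tp$theta_num[k]
    if (tp$scenario[k] == "opposed") {
      E[v, tp$trait_den[k]] <- E[v, tp$trait_den[k]] - tp$theta_den[k]
    }
  }
  mid_age <- mean(config$age_range)
  sim <- with_seed(config$seed, {
    conf <- rnorm(n, 0, config$sigma_confounder)
    age <- runif(n, config$age_range[1], config$age_range[2])
    sex <- rbinom(n, 1L, 0.5)
    med <- rbinom(n, 1L, config$med_rate)
    noise <- matrix(rnorm(n * m), n, m) %*% diag(config$sigma_trait, m)
    list(conf = conf, age = age, sex = sex, med = med, noise = noise)
  })
  covar_fx <- config$beta_age * (sim$age - mid_age) +
    config$beta_sex * sim$sex + config$beta_med * sim$med
  logx <- matrix(config$mu, n, m, byrow = TRUE) +
    outer(sim$conf, config$lambda) +
    geno %*% E +
    covar_fx + # same small covariate shift on every trait
    sim$noise
  dimnames(logx) <- list(rownames(geno), traits)
  nz <- which(E != 0, arr.ind = TRUE)
  truth <- structure(list(
    effects = data.frame(
      variant_id = rownames(E)[nz[, 1]],
      trait_id = colnames(E)[nz[, 2]],
      effect = E[nz],
      stringsAsFactors = FALSE
    ),
    effect_matrix = E,
    loadings = setNames(config$lambda, traits),
    variants = data.frame(id = specs$id, maf = specs$maf,
                          scenario = specs$scenario, stringsAsFactors = FALSE),
    confounder = setNames(sim$conf, rownames(geno)),
    covariate_effects = c(age = config$beta_age, sex = config$beta_sex,
                          medication = config$beta_med)
  ), class = "truth_table")
  covariates <- data.frame(
    sample_id = rownames(geno),
    age = sim$age, age2 = sim$age^2, sex = sim$sex,
    lipid_lowering_medication = sim$med,
    confounder = sim$conf,
    stringsAsFactors = FALSE
  )
  list(
    traits = trait_matrix(exp(logx), stage = "raw"),
    covariates = covariates,
    truth = truth
  )
}

#' Inject missing and zero values completely at random
#'
#' Emulates platform missingness: cells are set `NA` at `na_rate` and to
#' exact zero at `zero_rate`, disjointly and uniformly at random.
#'
#' @param traits A raw-stage [trait_matrix()].
#' @param na_rate,zero_rate Fractions in `[0, 1)` with sum < 1.
#' @param seed Integer seed; the mask is reproducible given it.
#'
#' @return The trait matrix with cells blanked; attribute `"injected"`
#'   holds the index vectors of the NA and zero cells actually hit.
#' @export
inject_missingness <- function(traits, na_rate, zero_rate, seed) {
  stopifnot(trait_stage(traits) == "raw")
  stopifnot_scalar_number(na_rate, "na_rate", lower = 0, upper = 1, strict_upper = TRUE)
  stopifnot_scalar_number(zero_rate, "zero_rate", lower = 0, upper = 1, strict_upper = TRUE)
  if (na_rate + zero_rate >= 1) stop("rates must sum to < 1", call. = FALSE)
  u <- with_seed(seed, runif(length(traits)))
  na_idx <- which(u < na_rate)
  zero_idx <- which(u >= na_rate & u < na_rate + zero_rate)
  out <- traits
  out[na_idx] <- NA_real_
  out[zero_idx] <- 0
  attr(out, "injected") <- list(na = na_idx, zero = zero_idx)
  out
}

#' Simulate fixed-horizon event outcomes
#'
#' Event times are exponential with per-sample rate
#' `baseline_rate * exp(effect * risk_covariate)`; events beyond
#' `horizon_years` are censored at the horizon.  A `prevalent_fraction` of
#' samples instead receive an event date before their assessment date
#' (a prevalent event, to be excluded from incident analyses).
#'
#' @param n_samples Number of samples.
#' @param risk_covariate Numeric vector of length `n_samples` (e.g. a trait
#'   or ratio phenotype on the INT scale).
#' @param effect Log-hazard slope per covariate unit.
#' @param baseline_rate Baseline event rate per year (> 0).
#' @param horizon_years Administrative censoring horizon (> 0).
#' @param prevalent_fraction Fraction of samples given a prevalent event.
#' @param seed Integer seed.
#' @param assessment_date Assessment date (scalar `Date` or ISO string).
#' @param med_rate Bernoulli rate of the medication flag.
#'
#' @return A `data.frame`: `sample_id`, `assessment_date`, `event_date`
#'   (`NA` if censored), `medication_flag`, plus the generative
#'   `time_years` and `event` columns for convenience.
#' @export
simulate_outcomes <- function(n_samples, risk_covariate, effect, baseline_rate,
                              horizon_years, prevalent_fraction = 0, seed = 1L,
                              assessment_date = as.Date("2010-01-01"),
                              med_rate = 0.15) {
  stopifnot_scalar_number(baseline_rate, "baseline_rate", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(horizon_years, "horizon_years", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(prevalent_fraction, "prevalent_fraction",
                          lower = 0, upper = 1, strict_upper = TRUE)
  if (length(risk_covariate) != n_samples) {
    stop("`risk_covariate` must have length n_samples", call. = FALSE)
  }
  assessment_date <- as.Date(assessment_date)
  sim <- with_seed(seed, {
    rate <- baseline_rate * exp(effect * risk_covariate)
    t_raw <- rexp(n_samples, rate)
    n_prev <- floor(prevalent_fraction * n_samples)
    prev <- if (n_prev > 0) sample.int(n_samples, n_prev) else integer(0)
    prev_lag <- runif(length(prev), 1, 3650) # days before assessment
    med <- rbinom(n_samples, 1L, med_rate)
    list(t_raw = t_raw, prev = prev, prev_lag = prev_lag, med = med)
  })
  event <- sim$t_raw <= horizon_years
  time_years <- pmin(sim$t_raw, horizon_years)
  event_date <- rep(as.Date(NA), n_samples)
  event_date[event] <- assessment_date + round(sim$t_raw[event] * 365.25)
  # ensure incident dates are strictly after assessment
  event_date[event] <- pmax(event_date[event], assessment_date + 1)
  if (length(sim$prev)) {
    event_date[sim$prev] <- assessment_date - ceiling(sim$prev_lag)
    event[sim$prev] <- FALSE
    time_years[sim$prev] <- 0
  }
  data.frame(
    sample_id = paste0("S", seq_len(n_samples)),
    assessment_date = assessment_date,
    event_date = event_date,
    medication_flag = sim$med,
    time_years = time_years,
    event = event,
    stringsAsFactors = FALSE
  )
}
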