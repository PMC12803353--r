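# End-to-end orchestration: simulate -> preprocess -> assoc -> pgain ->
# cluster -> replicate -> survive, with one master seed, per-stage derived
# seeds, TSV products, and a JSON run manifest (written even on failure).

PIPELINE_STAGES <- c("simulate", "preprocess", "assoc", "pgain", "cluster",
                     "replicate", "survive")

#' Build a pipeline run configuration
#'
#' One list drives the whole pipeline.  Per-stage seeds derive
#' deterministically from the single `seed` (stage index into
#' a fixed affine counter scheme), so a config plus one integer reproduces
#' every output bit-for-bit.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Master seed.
#' @param n_samples,n_traits,n_variants Synthetic cohort dimensions.
#' @param frac_opposed,frac_confounded Fractions of variants planted with
#'   the opposed / confounded mechanism (the rest are null).
#' @param theta Per-allele log-scale effect magnitude for planted variants.
#' @param maf_range Uniform range of simulated minor allele frequencies.
#' @param replication_fraction Fraction of samples held out as the
#'   replication cohort.
#' @param n_reps Number of power subsamples.
#' @param n_sub Power subsample size; defaults to the replication-cohort
#'   size.
#' @param stages Character vector of stages to run (default: all).
#' @param cohort Overrides passed to [cohort_config()].
#' @param thresholds Overrides passed to [compute_thresholds()]
#'   (`m_traits` is set from `n_traits` automatically).
#' @param cluster_metric,cluster_linkage Clustering options.
#' @param survival Survival-stage parameters: `effect`, `baseline_rate`,
#'   `horizon_years`, `prevalent_fraction`.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(outdir,
                       seed = 1L,
                       n_samples = 2000,
                       n_traits = 20,
                       n_variants = 50,
                       frac_opposed = 0.2,
                       frac_confounded = 0.2,
                       theta = 0.05,
                       maf_range = c(0.05, 0.5),
                       replication_fraction = 0.15,
                       n_reps = 100,
                       n_sub = NULL,
                       stages = PIPELINE_STAGES,
                       cohort = list(),
                       thresholds = list(),
                       cluster_metric = "euclidean",
                       cluster_linkage = "average",
                       survival = list(effect = 0.3, baseline_rate = 0.005,
                                       horizon_years = 10,
                                       prevalent_fraction = 0.02)) {
  structure(list(
    outdir = outdir, seed = as.integer(seed),
    n_samples = n_samples, n_traits = n_traits, n_variants = n_variants,
    frac_opposed = frac_opposed, frac_confounded = frac_confounded,
    theta = theta, maf_range = maf_range,
    replication_fraction = replication_fraction,
    n_reps = n_reps, n_sub = n_sub,
    stages = stages, cohort = cohort, thresholds = thresholds,
    cluster_metric = cluster_metric, cluster_linkage = cluster_linkage,
    survival = survival
  ), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Collects every violation (ranges, cross-field constraints, unknown
#' stages) instead of stopping at the first.
#'
#' @param config A [run_config()].
#' @return Character vector of issues; empty when valid.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  chk <- function(cond, msg) if (!cond) issues <<- c(issues, msg)
  chk(is.character(config$outdir) && nzchar(config$outdir),
      "outdir must be a non-empty path")
  chk(config$n_samples >= 2, "n_samples must be >= 2")
  chk(config$n_traits >= 2, "n_traits must be >= 2")
  chk(config$n_variants >= 1, "n_variants must be >= 1")
  chk(config$frac_opposed >= 0 && config$frac_confounded >= 0 &&
        config$frac_opposed + config$frac_confounded <= 1,
      "scenario fractions must be non-negative and sum to <= 1")
  chk(all(config$maf_range > 0) && all(config$maf_range <= 0.5) &&
        config$maf_range[1] <= config$maf_range[2],
      "maf_range must be within (0, 0.5]")
  chk(config$replication_fraction >= 0 && config$replication_fraction < 1,
      "replication_fraction must be in [0, 1)")
  n_repl <- floor(config$n_samples * config$replication_fraction)
  n_disc <- config$n_samples - n_repl
  n_sub <- config$n_sub %||% n_repl
  chk(n_sub <= n_disc,
      sprintf("n_sub (%d) exceeds the discovery cohort size (%d)",
              n_sub, n_disc))
  chk(all(config$stages %in% PIPELINE_STAGES),
      paste("unknown stage(s):",
            paste(setdiff(config$stages, PIPELINE_STAGES), collapse = ", ")))
  if (!is.null(config$survival)) {
    chk(config$survival$baseline_rate > 0, "survival baseline_rate must be > 0")
    chk(config$survival$horizon_years > 0, "survival horizon_years must be > 0")
  }
  issues
}

#' Generate a default variant spec table for a pipeline run
#'
#' Opposed and confounded variants are planted on a small pool of trait
#' pairs forming two "pathway" groups -- (T1, T2)-like and (T3, T4)-like
#' pairs -- so that downstream clustering has recoverable block structure;
#' remaining variants are null.
#'
#' @param n_variants Number of variants.
#' @param trait_ids Panel trait ids (>= 4 for the two pathway groups).
#' @inheritParams run_config
#' @param seed Seed for MAF draws and pair assignment.
#' @return A variant spec `data.frame` (see [variant_spec()]).
#' @export
make_variant_specs <- function(n_variants, trait_ids, frac_opposed = 0.2,
                               frac_confounded = 0.2, theta = 0.05,
                               maf_range = c(0.05, 0.5), seed = 1L) {
  n_opp <- round(n_variants * frac_opposed)
  n_con <- round(n_variants * frac_confounded)
  pairs <- list(trait_ids[1:2], trait_ids[3:4])
  with_seed(seed, {
    mafs <- runif(n_variants, maf_range[1], maf_range[2])
    scen <- c(rep("opposed", n_opp), rep("confounded", n_con),
              rep("null", n_variants - n_opp - n_con))
    do.call(rbind, lapply(seq_len(n_variants), function(i) {
      tp <- if (scen[i] == "null") NULL else pairs[[1 + (i %% 2)]]
      variant_spec(
        id = sprintf("v%03d", i), maf = mafs[i], scenario = scen[i],
        theta_num = if (scen[i] == "null") 0 else theta,
        theta_den = if (scen[i] == "opposed") theta else 0,
        target_pair = tp
      )
    }))
  })
}

stage_path <- function(config, name) file.path(config$outdir, name)

# Loaders used when a stage runs standalone and its inputs are on disk.
pipeline_loaders <- list(
  geno = function(cfg) read_matrix_tsv(stage_path(cfg, "genotypes.tsv")),
  traits_raw = function(cfg) read_trait_matrix(stage_path(cfg, "traits_raw.tsv")),
  covariates = function(cfg) read_tsv(stage_path(cfg, "covariates.tsv")),
  tests = function(cfg) read_tsv(stage_path(cfg, "tests.tsv")),
  assoc = function(cfg) read_tsv(stage_path(cfg, "assoc.tsv")),
  pgain = function(cfg) read_tsv(stage_path(cfg, "pgain.tsv")),
  outcomes = function(cfg) read_tsv(stage_path(cfg, "outcomes.tsv"))
)

state_get <- function(state, key, config) {
  if (!is.null(state[[key]])) return(state[[key]])
  loader <- pipeline_loaders[[key]]
  if (is.null(loader)) {
    stop("stage input '", key, "' not available; run its producing stage",
         call. = FALSE)
  }
  value <- loader(config)
  state[[key]] <- value
  value
}

#' Run the pipeline
#'
#' Executes the requested stages in dependency order.  Stage inputs not
#' produced in this run are loaded from `config$outdir` (so single stages
#' can be re-run against existing products).  A JSON run manifest --
#' config echo, per-stage seeds and wall times, output checksums,
#' warnings, and the failure point if any -- is written even on partial
#' failure; on stage failure downstream stages are skipped.
#'
#' @param config A validated [run_config()].
#' @return The manifest list, invisibly.  Products land in
#'   `config$outdir` as TSV/JSON files.
#' @export
run_pipeline <- function(config) {
  issues <- validate_config(config)
  if (length(issues)) {
    stop("invalid config:\n  - ", paste(issues, collapse = "\n  - "),
         call. = FALSE)
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  manifest <- list(
    config = config[setdiff(names(config), "stages")],
    stages_requested = config$stages,
    stage_seeds = setNames(
      lapply(seq_along(PIPELINE_STAGES), function(i) derive_seed(config$seed, i)),
      PIPELINE_STAGES
    ),
    stage_status = list(), stage_seconds = list(), warnings = list(),
    checksums = list()
  )
  failed <- FALSE
  for (stage in PIPELINE_STAGES) {
    if (!(stage %in% config$stages)) next
    if (failed) {
      manifest$stage_status[[stage]] <- "skipped"
      next
    }
    seed <- derive_seed(config$seed, match(stage, PIPELINE_STAGES))
    t0 <- proc.time()[["elapsed"]]
    ws <- character(0)
    res <- withCallingHandlers(
      tryCatch({
        do.call(paste0("stage_", stage),
                list(state = state, config = config, seed = seed))
        "ok"
      }, error = function(e) paste("error:", conditionMessage(e))),
      warning = function(w) {
        ws <<- c(ws, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    manifest$stage_status[[stage]] <- res
    manifest$stage_seconds[[stage]] <- round(proc.time()[["elapsed"]] - t0, 3)
    if (length(ws)) manifest$warnings[[stage]] <- ws
    if (res != "ok") failed <- TRUE
  }
  files <- list.files(config$outdir, pattern = "\\.(tsv|json|vcf|nwk)$",
                      full.names = TRUE)
  files <- setdiff(files, stage_path(config, "manifest.json"))
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  manifest$versions <- list(
    R = paste(R.version$major, R.version$minor, sep = "."),
    ratiogain = as.character(utils::packageVersion("ratiogain"))
  )
  jsonlite::write_json(manifest, stage_path(config, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

stage_simulate <- function(state, config, seed) {
  cc_args <- modifyList(
    list(n_traits = config$n_traits, seed = derive_seed(seed, 1)),
    config$cohort
  )
  cohort_cfg <- do.call(cohort_config, cc_args)
  specs <- make_variant_specs(config$n_variants, cohort_cfg$trait_ids,
                              config$frac_opposed, config$frac_confounded,
                              config$theta, config$maf_range,
                              seed = derive_seed(seed, 2))
  geno <- simulate_genotypes(config$n_samples, specs,
                             seed = derive_seed(seed, 3))
  sim <- simulate_cohort(geno, specs, cohort_cfg)
  traits <- inject_missingness(sim$traits, cohort_cfg$na_rate,
                               cohort_cfg$zero_rate,
                               seed = derive_seed(seed, 4))
  # discovery / replication split
  n_repl <- floor(config$n_samples * config$replication_fraction)
  repl_idx <- with_seed(derive_seed(seed, 5),
                        sample.int(config$n_samples, n_repl))
  sim$covariates$cohort <- "discovery"
  sim$covariates$cohort[repl_idx] <- "replication"
  state$specs <- specs; state$geno <- geno
  state$traits_raw <- traits
  state$covariates <- sim$covariates
  state$truth <- sim$truth
  write_matrix_tsv(geno, stage_path(config, "genotypes.tsv"))
  write_genotypes_vcf(geno, stage_path(config, "genotypes.vcf"))
  write_trait_matrix(traits, stage_path(config, "traits_raw.tsv"))
  write_tsv(sim$covariates, stage_path(config, "covariates.tsv"))
  write_tsv(sim$truth$effects, stage_path(config, "truth_effects.tsv"))
  write_tsv(specs, stage_path(config, "variant_specs.tsv"))
  invisible(state)
}

stage_preprocess <- function(state, config, seed) {
  traits <- state_get(state, "traits_raw", config)
  lg <- log_transform(zeros_to_missing(traits))
  tests <- enumerate_tests(colnames(lg))
  phen <- build_phenotypes(lg, tests)
  state$traits_log <- lg
  state$tests <- tests
  state$phenotypes <- phen
  write_trait_matrix(lg, stage_path(config, "traits_log.tsv"))
  write_tsv(tests, stage_path(config, "tests.tsv"))
  invisible(state)
}

# phenotypes can always be rebuilt from raw traits + tests
ensure_phenotypes <- function(state, config) {
  if (is.null(state$phenotypes)) {
    lg <- log_transform(zeros_to_missing(state_get(state, "traits_raw", config)))
    state$traits_log <- lg
    state$phenotypes <- build_phenotypes(lg, state_get(state, "tests", config))
  }
  state$phenotypes
}

discovery_rows <- function(state, config) {
  cov <- state_get(state, "covariates", config)
  if ("cohort" %in% names(cov)) cov$cohort == "discovery" else
    rep(TRUE, nrow(cov))
}

model_covariates <- function(covariates) {
  covariates[, intersect(c("age", "age2", "sex", "lipid_lowering_medication"),
                         names(covariates)), drop = FALSE]
}

stage_assoc <- function(state, config, seed) {
  geno <- state_get(state, "geno", config)
  phen <- ensure_phenotypes(state, config)
  cov <- state_get(state, "covariates", config)
  disc <- discovery_rows(state, config)
  res <- scan_associations(geno[disc, , drop = FALSE],
                           phen[disc, , drop = FALSE],
                           model_covariates(cov)[disc, , drop = FALSE])
  state$assoc <- res
  write_tsv(res, stage_path(config, "assoc.tsv"))
  invisible(state)
}

stage_pgain <- function(state, config, seed) {
  res <- state_get(state, "assoc", config)
  tests <- state_get(state, "tests", config)
  thr_args <- modifyList(list(m_traits = config$n_traits), config$thresholds)
  thr <- do.call(compute_thresholds, thr_args)
  pg <- pgain_table(res, tests, thr)
  # per-locus flags: reference family = first five single traits
  ref_ids <- head(tests$test_id[tests$kind == "single"], thr$m_lipids)
  singles <- res[res$test_id %in% tests$test_id[tests$kind == "single"], ]
  loci <- unique(res$variant_id)
  flags <- do.call(rbind, lapply(loci, function(v) {
    sv <- singles[singles$variant_id == v, ]
    rv <- pg[pg$variant_id == v, ]
    data.frame(
      locus = v,
      sig_ref = isTRUE(select_lead(sv[sv$test_id %in% ref_ids, ], thr,
                                   "five_lipids")$significant),
      sig_nmr = isTRUE(select_lead(sv, thr, "nmr")$significant),
      sig_ratio = isTRUE(select_lead(rv, thr, "all_ratios")$significant) ||
        any(sv$neglog10_p > thr$p_allratios, na.rm = TRUE),
      sig_pgain = any(rv$significant_pgain),
      stringsAsFactors = FALSE
    )
  }))
  summ <- count_discoveries(flags)
  state$thresholds <- thr
  state$pgain <- pg
  state$flags <- flags
  state$summary <- summ
  write_tsv(pg, stage_path(config, "pgain.tsv"))
  write_tsv(flags, stage_path(config, "locus_flags.tsv"))
  jsonlite::write_json(
    list(thresholds = unclass(thr), counts = as.list(summ$counts),
         percent = as.list(summ$percent)),
    stage_path(config, "discovery_summary.json"),
    auto_unbox = TRUE, pretty = TRUE, force = TRUE
  )
  invisible(state)
}

ensure_thresholds <- function(state, config) {
  if (is.null(state$thresholds)) {
    thr_args <- modifyList(list(m_traits = config$n_traits), config$thresholds)
    state$thresholds <- do.call(compute_thresholds, thr_args)
  }
  state$thresholds
}

stage_cluster <- function(state, config, seed) {
  pg <- state_get(state, "pgain", config)
  thr <- ensure_thresholds(state, config)
  m <- build_pgain_matrix(pg, thr)
  nm <- normalize_per_locus(m)
  state$pgain_matrix <- nm
  write_matrix_tsv(nm, stage_path(config, "pgain_matrix.tsv"))
  if (nrow(nm) >= 2 && ncol(nm) >= 2) {
    cl <- hierarchical_cluster(nm, config$cluster_metric,
                               config$cluster_linkage)
    state$clustering <- cl
    jsonlite::write_json(list(row_order = cl$row_order,
                              col_order = cl$col_order),
                         stage_path(config, "cluster_orders.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (requireNamespace("ape", quietly = TRUE)) {
      cluster_tree_newick(cl$col_tree, stage_path(config, "loci_tree.nwk"))
      cluster_tree_newick(cl$row_tree, stage_path(config, "ratios_tree.nwk"))
    }
  } else {
    warning("p-gain matrix too small to cluster")
  }
  invisible(state)
}

stage_replicate <- function(state, config, seed) {
  geno <- state_get(state, "geno", config)
  phen <- ensure_phenotypes(state, config)
  cov <- state_get(state, "covariates", config)
  res <- state_get(state, "assoc", config)
  thr <- ensure_thresholds(state, config)
  disc <- discovery_rows(state, config)
  repl <- !disc
  if (!sum(repl)) stop("no replication cohort (replication_fraction = 0)",
                       call. = FALSE)
  C <- model_covariates(cov)
  # discovered loci: significant with any test at the all-ratios level
  leads <- do.call(rbind, lapply(unique(res$variant_id), function(v) {
    sl <- select_lead(res[res$variant_id == v, ], thr, "all_ratios")
    if (!sl$significant) return(NULL)
    data.frame(variant_id = v, test_id = sl$lead$test_id,
               discovery_neglog10_p = sl$lead$neglog10_p,
               discovery_beta = sl$lead$beta, stringsAsFactors = FALSE)
  }))
  if (is.null(leads) || !nrow(leads)) {
    warning("no discovered loci to replicate")
    state$replication <- NULL
    return(invisible(state))
  }
  refit <- do.call(rbind, lapply(seq_len(nrow(leads)), function(i) {
    fit_one_safe(phen[repl, leads$test_id[i]], geno[repl, leads$variant_id[i]],
                 C[repl, , drop = FALSE], leads$variant_id[i],
                 leads$test_id[i], NEGLOG10_CAP)
  }))
  rep_res <- replication_test(
    refit, n_discovered = nrow(leads),
    discovery_beta = setNames(leads$discovery_beta, leads$variant_id)
  )
  n_sub <- config$n_sub %||% sum(repl)
  pw <- replication_power(
    phenotypes = phen[disc, leads$test_id, drop = FALSE],
    dosages = geno[disc, leads$variant_id, drop = FALSE],
    covariates = C[disc, , drop = FALSE],
    n_sub = n_sub, n_reps = config$n_reps,
    threshold_neglog10 = unique(rep_res$threshold_neglog10),
    seed = seed
  )
  out <- cbind(leads, rep_res[, c("neglog10_p", "threshold_neglog10",
                                  "tested", "replicated",
                                  "direction_concordant")],
               power = pw$power, n_subsamples = pw$n_subsamples)
  state$replication <- out
  write_tsv(out, stage_path(config, "replication.tsv"))
  invisible(state)
}

stage_survive <- function(state, config, seed) {
  phen <- ensure_phenotypes(state, config)
  cov <- state_get(state, "covariates", config)
  sv <- config$survival
  # risk marker: lead ratio phenotype if known, else the first ratio column
  marker <- if (!is.null(state$replication) && nrow(state$replication)) {
    state$replication$test_id[1]
  } else {
    grep("/", colnames(phen), value = TRUE)[1]
  }
  y <- phen[, marker]
  y[is.na(y)] <- 0 # mean-impute the few missing marker values
  outcomes <- simulate_outcomes(
    n_samples = nrow(phen), risk_covariate = y, effect = sv$effect,
    baseline_rate = sv$baseline_rate, horizon_years = sv$horizon_years,
    prevalent_fraction = sv$prevalent_fraction, seed = seed,
    med_rate = mean(cov$lipid_lowering_medication)
  )
  flag <- incident_event_flag(outcomes$event_date, outcomes$assessment_date)
  groups <- median_split_groups(y, cov$lipid_lowering_medication,
                                exclusions = flag == "prevalent")
  est <- km_risk(outcomes$time_years, flag == "incident", groups,
                 horizon = sv$horizon_years)
  est$marker <- marker
  state$outcomes <- outcomes
  state$survival <- est
  write_tsv(outcomes, stage_path(config, "outcomes.tsv"))
  write_tsv(est, stage_path(config, "survival.tsv"))
  invisible(state)
}

#' Command-line entry point
#'
#' Subcommands: `run`, `validate`, plus every single stage name
#' (`simulate`, `preprocess`, `assoc`, `pgain`, `cluster`, `replicate`,
#' `survive`), each taking `--config <path.json>` (a JSON-serialized
#' [run_config()]); single-stage calls read their inputs from the config's
#' `outdir`.  Exit codes: 0 ok, 1 validation failure, 2 runtime failure.
#'
#' @param args Command-line arguments (default `commandArgs(TRUE)`).
#' @return Exit code, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: ratiogain <run|validate|simulate|preprocess|assoc|pgain|cluster|replicate|survive> --config config.json"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  cfg_idx <- which(args == "--config")
  if (!length(cfg_idx) || cfg_idx + 1 > length(args)) {
    message("missing --config\n", usage); return(invisible(1L))
  }
  cfg_raw <- jsonlite::read_json(args[cfg_idx + 1], simplifyVector = TRUE)
  config <- do.call(run_config, cfg_raw)
  if (cmd == "validate") {
    issues <- validate_config(config)
    if (length(issues)) {
      message(paste(issues, collapse = "\n")); return(invisible(1L))
    }
    message("config ok"); return(invisible(0L))
  }
  if (cmd %in% PIPELINE_STAGES) config$stages <- cmd
  if (!cmd %in% c("run", PIPELINE_STAGES)) {
    message("unknown subcommand '", cmd, "'\n", usage); return(invisible(1L))
  }
  code <- tryCatch({
    manifest <- run_pipeline(config)
    if (any(grepl("^error", unlist(manifest$stage_status)))) 2L else 0L
  }, error = function(e) {
    message(conditionMessage(e))
    if (grepl("invalid config", conditionMessage(e))) 1L else 2L
  })
  invisible(code)
}
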