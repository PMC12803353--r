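# Linear association engine.
#
# All p-values are carried as negative log10 values computed in log space,
# so association strengths thousands of orders of magnitude below the
# double-precision underflow limit (p ~ 1e-308) remain finite and exact
# arithmetic on them (p-gain) never re-exponentiates.

NEGLOG10_CAP <- 9999 # reported for perfect (zero-residual) fits

#' Negative log10 two-sided p-value of a t statistic
#'
#' Computed entirely in log space.  For finite degrees of freedom (up to
#' `1e5`) the t survival function is evaluated on the log scale via the
#' regularized incomplete beta function.  For larger/infinite df the
#' statistic is in the normal regime: below `|z| = 37` (where the tail
#' probability is still representable, p > ~5e-300) the standard normal
#' survival function is used directly; above it the Mills-ratio asymptotic
#' expansion
#' \deqn{\ln p = \ln 2 + \ln\varphi(z) - \ln z + \ln(1 - z^{-2} + 3 z^{-4}
#'   - 15 z^{-6} + 105 z^{-8})}
#' takes over.  The two branches agree to well under 1e-6 relative at the
#' seam.
#'
#' @param t_stat t (or z) statistic; vectorized.
#' @param df Residual degrees of freedom (>= 1); `Inf` for the normal case.
#' @return Non-negative, finite `-log10(p)` values.
#' @examples
#' neglog10_p_from_t(1.96, Inf) # ~1.30 (p ~ 0.05)
#' neglog10_p_from_t(40, Inf)   # ~349.1: far below underflow, still exact
#' @export
neglog10_p_from_t <- function(t_stat, df) {
  if (any(!is.finite(t_stat))) stop("non-finite t statistic", call. = FALSE)
  if (any(is.na(df)) || any(df < 1)) stop("df must be >= 1", call. = FALSE)
  n <- max(length(t_stat), length(df))
  z <- abs(rep_len(t_stat, n))
  df <- rep_len(df, n)
  out <- numeric(n)
  normal <- is.infinite(df) | df > 1e5
  tt <- !normal
  if (any(tt)) {
    # log-space t survival function: R's pt() routes through the
    # log-regularized incomplete beta and stays accurate at extreme t
    out[tt] <- -(log(2) + pt(z[tt], df[tt], lower.tail = FALSE,
                             log.p = TRUE)) / log(10)
  }
  safe <- normal & z <= 37
  if (any(safe)) {
    out[safe] <- -log10(2 * pnorm(z[safe], lower.tail = FALSE))
  }
  deep <- normal & z > 37
  if (any(deep)) {
    zz <- z[deep]
    series <- 1 - 1 / zz^2 + 3 / zz^4 - 15 / zz^6 + 105 / zz^8
    lnp <- log(2) - zz^2 / 2 - log(zz) - 0.5 * log(2 * pi) + log(series)
    out[deep] <- -lnp / log(10)
  }
  pmax(out, 0)
}

#' Covariate table validator
#'
#' Checks the conventions the association models assume: no missing values
#' left in used columns is checked per fit; here we check that an `age2`
#' column, when present alongside `age`, is its square.
#'
#' @param covariates A `data.frame` of numeric covariate columns (a
#'   `sample_id` column is ignored by the models).
#' @return The validated `data.frame`, invisibly.
#' @export
validate_covariates <- function(covariates) {
  if (all(c("age", "age2") %in% names(covariates))) {
    if (max(abs(covariates$age2 - covariates$age^2), na.rm = TRUE) > 1e-9) {
      stop("`age2` must equal age^2", call. = FALSE)
    }
  }
  invisible(covariates)
}

# Internal: covariate data.frame -> numeric model matrix (no intercept),
# dropping identifier columns.
covar_matrix <- function(covariates, exclude = c("sample_id", "confounder")) {
  if (is.null(covariates)) return(NULL)
  if (is.data.frame(covariates)) {
    covariates <- covariates[setdiff(names(covariates), exclude)]
    covariates <- as.matrix(covariates)
  }
  storage.mode(covariates) <- "double"
  covariates
}

# Internal OLS via QR with rank-deficiency reporting.
ols_qr <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  list(qr = qx, beta = beta, resid = res)
}

#' Fit one covariate-adjusted association model
#'
#' Ordinary least squares of `y` on `[intercept, dosage, covariates]` with
#' listwise deletion over all model variables; reports the dosage term.
#' The two-sided p-value comes from the t distribution with residual
#' degrees of freedom via [neglog10_p_from_t()].
#'
#' @param y Phenotype vector (typically INT scale), missing allowed.
#' @param dosage Additive allele dosage vector (fractional values from
#'   imputation are used as-is).
#' @param covariates Optional covariate `data.frame`/matrix (a `sample_id`
#'   column is ignored).
#' @param variant_id,test_id Labels carried into the result.
#' @param cap Negative-log10 p reported for perfect (zero-residual) fits.
#' @return One-row `data.frame` of class `"assoc_result"`: `variant_id`,
#'   `test_id`, `beta`, `se`, `t_stat`, `neglog10_p`, `n`, `df`,
#'   `perfect_fit`.
#' @export
fit_linear_assoc <- function(y, dosage, covariates = NULL,
                             variant_id = NA_character_,
                             test_id = NA_character_,
                             cap = NEGLOG10_CAP) {
  C <- covar_matrix(covariates)
  cc <- !is.na(y) & !is.na(dosage)
  if (!is.null(C)) cc <- cc & complete.cases(C)
  n <- sum(cc)
  if (n < 10) stop("fewer than 10 complete cases", call. = FALSE)
  g <- dosage[cc]
  if (max(g) == min(g)) {
    stop("degenerate variant: dosage constant on complete cases", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, dosage = g,
             if (!is.null(C)) C[cc, , drop = FALSE])
  fit <- ols_qr(X, y[cc])
  df <- n - ncol(X)
  if (df < 1) stop("non-positive residual degrees of freedom", call. = FALSE)
  rss <- sum(fit$resid^2)
  tss <- sum((y[cc] - mean(y[cc]))^2)
  perfect <- rss <= 1e-12 * max(tss, 1)
  R <- qr.R(fit$qr)
  XtX_inv_gg <- chol2inv(R)[2, 2]
  se <- sqrt(rss / df * XtX_inv_gg)
  beta <- unname(fit$beta["dosage"])
  if (perfect || se == 0) {
    res <- data.frame(
      variant_id = variant_id, test_id = test_id, beta = beta, se = se,
      t_stat = Inf * sign(beta), neglog10_p = cap, n = n, df = df,
      perfect_fit = TRUE, note = "perfect_fit", stringsAsFactors = FALSE
    )
    warning("perfect fit: neglog10_p capped at ", cap)
  } else {
    t_stat <- beta / se
    res <- data.frame(
      variant_id = variant_id, test_id = test_id, beta = beta, se = se,
      t_stat = t_stat, neglog10_p = neglog10_p_from_t(t_stat, df), n = n,
      df = df, perfect_fit = FALSE, note = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Residualize columns against covariates
#'
#' Replaces each column of `m` by its OLS residual against
#' `[intercept, covariates]` on the shared complete-case set (rows complete
#' in the covariates and in every column of `m`).  Residuals are orthogonal
#' to the covariates; rows outside the complete-case set are `NA`.
#'
#' @param m Numeric matrix (phenotypes or dosages as columns).
#' @param covariates Covariate `data.frame`/matrix.
#' @return Matrix of residuals, same shape as `m`.
#' @export
residualize <- function(m, covariates) {
  m <- as.matrix(m)
  C <- covar_matrix(covariates)
  cc <- complete.cases(m)
  if (!is.null(C)) cc <- cc & complete.cases(C)
  X <- cbind(1, if (!is.null(C)) C[cc, , drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- c("(Intercept)", colnames(C))[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient covariates; aliased: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  out[cc, ] <- qr.resid(qx, m[cc, , drop = FALSE])
  out
}

#' Scan one variant against a list of tests
#'
#' Fits the full model `phenotype ~ dosage + covariates (+ conditional
#' dosages)` for every test.  The default fast path groups phenotypes by
#' missingness pattern and, per group, residualizes the dosage and the
#' phenotype block once against the covariates (Frisch-Waugh-Lovell), then
#' computes each per-test slope from a simple regression of residuals with
#' `df = n - k - 1` matching the full model exactly.  `engine = "naive"`
#' fits every model separately; the two agree to numerical precision.
#'
#' @param dosage Lead-variant dosage vector.
#' @param phenotypes samples x tests matrix from [build_phenotypes()].
#' @param covariates Covariate `data.frame`/matrix.
#' @param conditional Optional matrix of conditional-variant dosages
#'   included as extra covariates; must not contain the lead variant.
#' @param variant_id Label carried into the results.
#' @param engine `"fast"` (residualization) or `"naive"` (per-test OLS).
#' @param cap Perfect-fit cap, see [fit_linear_assoc()].
#' @return `data.frame` of class `"assoc_result"`, one row per test.
#'   Degenerate tests are returned flagged (`NA` statistics, reason in
#'   `note`) rather than aborting the scan.
#' @export
scan_variant <- function(dosage, phenotypes, covariates = NULL,
                         conditional = NULL, variant_id = NA_character_,
                         engine = c("fast", "naive"), cap = NEGLOG10_CAP) {
  engine <- match.arg(engine)
  phenotypes <- as.matrix(phenotypes)
  if (!is.null(conditional)) {
    conditional <- as.matrix(conditional)
    same <- apply(conditional, 2, function(cv) {
      isTRUE(all.equal(cv, dosage, tolerance = 0, check.attributes = FALSE))
    })
    if (any(same)) {
      stop("lead variant listed among its own conditional covariates",
           call. = FALSE)
    }
  }
  C <- cbind(covar_matrix(covariates), conditional)
  res <- if (engine == "naive") {
    do.call(rbind, lapply(seq_len(ncol(phenotypes)), function(j) {
      fit_one_safe(phenotypes[, j], dosage, C, variant_id,
                   colnames(phenotypes)[j], cap)
    }))
  } else {
    scan_fast(dosage, phenotypes, C, variant_id, cap)
  }
  rownames(res) <- NULL
  class(res) <- c("assoc_result", "data.frame")
  res
}

# Internal: naive fit returning a flagged row instead of an error.
fit_one_safe <- function(y, dosage, C, variant_id, test_id, cap) {
  tryCatch(
    fit_linear_assoc(y, dosage, C, variant_id, test_id, cap),
    error = function(e) {
      data.frame(variant_id = variant_id, test_id = test_id,
                 beta = NA_real_, se = NA_real_, t_stat = NA_real_,
                 neglog10_p = NA_real_, n = NA_integer_, df = NA_integer_,
                 perfect_fit = FALSE, note = conditionMessage(e),
                 stringsAsFactors = FALSE)
    }
  )
}

# Internal fast path: FWL residualization grouped by missingness pattern.
scan_fast <- function(dosage, phenotypes, C, variant_id, cap) {
  base <- !is.na(dosage)
  if (!is.null(C)) base <- base & complete.cases(C)
  miss <- is.na(phenotypes[base, , drop = FALSE])
  pat <- apply(miss, 2, function(v) paste(which(v), collapse = ","))
  k_cov <- if (is.null(C)) 0L else ncol(C)
  out <- vector("list", ncol(phenotypes))
  suppressWarnings(
    for (p in unique(pat)) {
      cols <- which(pat == p)
      rows <- which(base)
      if (nzchar(p)) rows <- rows[-as.integer(strsplit(p, ",")[[1]])]
      n <- length(rows)
      if (n < 10) {
        for (j in cols) {
          out[[j]] <- fit_one_safe(phenotypes[, j], dosage, C, variant_id,
                                   colnames(phenotypes)[j], cap)
        }
        next
      }
      X <- cbind(1, if (!is.null(C)) C[rows, , drop = FALSE])
      qx <- qr(X)
      if (qx$rank < ncol(X)) {
        stop("rank-deficient covariates in fast path", call. = FALSE)
      }
      gr <- qr.resid(qx, dosage[rows])
      gg <- sum(gr^2)
      if (gg <= 0 || max(dosage[rows]) == min(dosage[rows])) {
        for (j in cols) {
          out[[j]] <- fit_one_safe(phenotypes[, j], dosage, C, variant_id,
                                   colnames(phenotypes)[j], cap)
        }
        next
      }
      Pr <- qr.resid(qx, phenotypes[rows, cols, drop = FALSE])
      beta <- as.vector(crossprod(Pr, gr)) / gg
      rss <- pmax(colSums(Pr^2) - beta^2 * gg, 0)
      df <- n - k_cov - 2L # intercept + dosage + covariates
      tss <- colSums(Pr^2)
      perfect <- rss <= 1e-12 * pmax(tss, 1)
      se <- sqrt(rss / df / gg)
      t_stat <- ifelse(perfect, Inf * sign(beta), beta / se)
      nlp <- ifelse(perfect, cap, neglog10_p_from_t(ifelse(perfect, 0, t_stat), df))
      for (i in seq_along(cols)) {
        j <- cols[i]
        out[[j]] <- data.frame(
          variant_id = variant_id, test_id = colnames(phenotypes)[j],
          beta = beta[i], se = se[i], t_stat = t_stat[i],
          neglog10_p = nlp[i], n = n, df = df, perfect_fit = perfect[i],
          note = if (perfect[i]) "perfect_fit" else NA_character_,
          stringsAsFactors = FALSE
        )
      }
    }
  )
  do.call(rbind, out)
}

#' Scan every variant of a genotype matrix against every test
#'
#' Convenience loop over [scan_variant()]; conditional variants may be
#' supplied per lead variant.
#'
#' @param geno Genotype dosage matrix (samples x variants).
#' @param phenotypes samples x tests INT phenotype matrix.
#' @param covariates Covariate table.
#' @param conditional Named list: for variant id `v`, a character vector of
#'   other variant ids whose dosages enter the model as covariates.
#' @inheritParams scan_variant
#' @return `data.frame` of class `"assoc_result"` over all
#'   (variant, test) pairs.
#' @export
scan_associations <- function(geno, phenotypes, covariates = NULL,
                              conditional = list(),
                              engine = c("fast", "naive"),
                              cap = NEGLOG10_CAP) {
  engine <- match.arg(engine)
  res <- lapply(colnames(geno), function(v) {
    cond_ids <- conditional[[v]]
    cond <- if (length(cond_ids)) geno[, cond_ids, drop = FALSE] else NULL
    scan_variant(geno[, v], phenotypes, covariates, cond,
                 variant_id = v, engine = engine, cap = cap)
  })
  out <- do.call(rbind, res)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Regress an outcome on a log-ratio or on its two components
#'
#' Examines the identity `log(A/B) = log A - log B` from the modelling
#' side: `mode = "ratio"` fits `outcome ~ I(log_num - log_den) +
#' covariates`; `mode = "two_coef"` fits `outcome ~ log_num + log_den +
#' covariates`.  When the two free coefficients are equal and opposite the
#' two models coincide and so do their R-squared values.
#'
#' @param outcome Numeric response (e.g. a protein level).
#' @param log_num,log_den Log-scale component traits.
#' @param covariates Optional covariates.
#' @param mode `"ratio"` or `"two_coef"`.
#' @return List: `coefficients` (`data.frame` term/estimate/se/t),
#'   `r_squared`, `n`, `mode`.
#' @export
trait_on_ratio <- function(outcome, log_num, log_den, covariates = NULL,
                           mode = c("ratio", "two_coef")) {
  mode <- match.arg(mode)
  C <- covar_matrix(covariates)
  P <- if (mode == "ratio") {
    cbind(ratio = log_num - log_den)
  } else {
    cbind(log_num = log_num, log_den = log_den)
  }
  cc <- complete.cases(P) & !is.na(outcome)
  if (!is.null(C)) cc <- cc & complete.cases(C)
  n <- sum(cc)
  if (n < 10) stop("fewer than 10 complete cases", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, P[cc, , drop = FALSE],
             if (!is.null(C)) C[cc, , drop = FALSE])
  fit <- ols_qr(X, outcome[cc])
  rss <- sum(fit$resid^2)
  tss <- sum((outcome[cc] - mean(outcome[cc]))^2)
  df <- n - ncol(X)
  sigma2 <- rss / df
  covb <- sigma2 * chol2inv(qr.R(fit$qr))
  se <- sqrt(diag(covb))
  list(
    coefficients = data.frame(
      term = colnames(X), estimate = unname(fit$beta), se = se,
      t_stat = unname(fit$beta) / se, stringsAsFactors = FALSE
    ),
    r_squared = 1 - rss / tss,
    n = n, mode = mode
  )
}

#' Per-trait association with a binary exposure
#'
#' Fits `trait ~ exposure + covariates` for every trait column after
#' applying a sample exclusion mask, returning the exposure effect profile
#' (the beta vector compared across exposures/variants in effect-profile
#' scatter plots).
#'
#' @param traits samples x traits numeric matrix (INT scale recommended).
#' @param exposure Binary 0/1 vector.
#' @param covariates Optional covariates.
#' @param exclusions Logical mask of samples to drop before fitting.
#' @param label Exposure label carried into the `variant_id` column.
#' @return `assoc_result` data.frame, one row per trait, `variant_id` set
#'   to the exposure label.
#' @export
exposure_assoc <- function(traits, exposure, covariates = NULL,
                           exclusions = NULL, label = "exposure") {
  if (!all(exposure %in% c(0, 1, NA))) {
    stop("`exposure` must be binary 0/1", call. = FALSE)
  }
  keep <- if (is.null(exclusions)) rep(TRUE, length(exposure)) else !exclusions
  ex <- exposure[keep]
  if (length(unique(ex[!is.na(ex)])) < 2) {
    stop("exposure constant after exclusions", call. = FALSE)
  }
  C <- covar_matrix(covariates)
  scan_variant(
    dosage = ex,
    phenotypes = as.matrix(traits)[keep, , drop = FALSE],
    covariates = if (!is.null(C)) C[keep, , drop = FALSE],
    variant_id = label
  )
}
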