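# Trait-panel preprocessing: zeros -> missing, log scale, rank-based
# inverse-normal transform, ratio construction, and test enumeration.

#' Trait matrix container
#'
#' A numeric samples x traits matrix tagged with its processing stage:
#' `"raw"` (positive concentrations, zeros allowed before
#' [zeros_to_missing()]), `"log"` (natural-log scale), or `"int"`
#' (inverse-normal transformed).
#'
#' @param x Numeric matrix with sample row names and trait column names.
#' @param stage One of `"raw"`, `"log"`, `"int"`.
#' @return `x` with class `"trait_matrix"` and a `stage` attribute.
#' @export
trait_matrix <- function(x, stage = c("raw", "log", "int")) {
  stage <- match.arg(stage)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix", call. = FALSE)
  }
  if (stage == "raw" && any(x < 0, na.rm = TRUE)) {
    stop("raw-stage traits must be non-negative", call. = FALSE)
  }
  structure(x, stage = stage, class = c("trait_matrix", class(x)))
}

#' @rdname trait_matrix
#' @param traits A `trait_matrix`.
#' @export
trait_stage <- function(traits) {
  attr(traits, "stage") %||% stop("not a staged trait matrix", call. = FALSE)
}

set_stage <- function(traits, stage) {
  attr(traits, "stage") <- stage
  traits
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("<trait_matrix> %d samples x %d traits, stage = %s, %d missing\n",
              nrow(x), ncol(x), trait_stage(x), sum(is.na(x))))
  invisible(x)
}

#' Convert exact zeros to missing values
#'
#' Platform values of exactly zero are below-detection artifacts and are
#' treated as missing before log-scaling.
#'
#' @param traits A raw-stage [trait_matrix()].
#' @return The matrix with zero cells set `NA`; attribute
#'   `"n_zero_converted"` records how many cells were converted.
#' @export
zeros_to_missing <- function(traits) {
  if (trait_stage(traits) != "raw") {
    stop("zeros_to_missing() expects a raw-stage trait matrix", call. = FALSE)
  }
  idx <- which(!is.na(traits) & traits == 0)
  traits[idx] <- NA_real_
  attr(traits, "n_zero_converted") <- length(idx)
  traits
}

#' Natural-log transform a raw trait matrix
#'
#' @param traits A raw-stage [trait_matrix()] with all non-missing values
#'   strictly positive (run [zeros_to_missing()] first).
#' @return A log-stage trait matrix; missing cells stay missing.
#' @export
log_transform <- function(traits) {
  if (trait_stage(traits) != "raw") {
    stop("log_transform() expects a raw-stage trait matrix", call. = FALSE)
  }
  bad <- which(!is.na(traits) & traits <= 0)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(traits))
    stop(sprintf(
      "non-positive value at sample '%s', trait '%s' (%d offending cells); run zeros_to_missing() first",
      rownames(traits)[rc[1]] %||% rc[1], colnames(traits)[rc[2]] %||% rc[2],
      length(bad)
    ), call. = FALSE)
  }
  out <- log(unclass(traits))
  trait_matrix(out, stage = "log")
}

#' Rank-based inverse-normal transform of one column
#'
#' Maps the non-missing values of `x` to normal quantiles
#' `qnorm((r - offset) / (n - 2 * offset + 1))` with ties given average
#' ranks.  The default `offset = 3/8` is the Blom variant; the transform
#' makes downstream linear-model statistics robust to outliers (which for
#' ratio phenotypes can arise from division by small denominators).
#'
#' @param x Numeric vector, missing allowed.
#' @param offset Rank offset; `3/8` (Blom) by default.
#' @return Vector of normal scores, missing preserved.  Strictly monotone
#'   on distinct inputs.
#' @examples
#' inverse_normal(c(3, 1, 2)) # middle value maps to 0
#' @export
inverse_normal <- function(x, offset = 3 / 8) {
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 3) stop("inverse_normal() needs >= 3 non-missing values", call. = FALSE)
  v <- x[obs]
  if (max(v) == min(v)) {
    stop("constant column: inverse-normal transform is degenerate",
         call. = FALSE)
  }
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[obs] <- qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Inverse-normal transform every column of a trait matrix
#'
#' Columns that are constant (or have fewer than 3 observations) cannot be
#' transformed; they are dropped with a warning and listed in the
#' `"dropped"` attribute.
#'
#' @param traits A log-stage [trait_matrix()].
#' @inheritParams inverse_normal
#' @return An int-stage trait matrix.
#' @export
int_transform <- function(traits, offset = 3 / 8) {
  if (trait_stage(traits) != "log") {
    stop("int_transform() expects a log-stage trait matrix", call. = FALSE)
  }
  cols <- lapply(seq_len(ncol(traits)), function(j) {
    tryCatch(inverse_normal(traits[, j], offset = offset),
             error = function(e) NULL)
  })
  keep <- !vapply(cols, is.null, logical(1))
  if (!all(keep)) {
    warning("dropping degenerate trait column(s): ",
            paste(colnames(traits)[!keep], collapse = ", "))
  }
  out <- do.call(cbind, cols[keep])
  dimnames(out) <- list(rownames(traits), colnames(traits)[keep])
  out <- trait_matrix(out, stage = "int")
  attr(out, "dropped") <- colnames(traits)[!keep]
  out
}

#' Enumerate single-trait and ratio tests for a panel
#'
#' Returns all `m` single-trait tests plus all `m(m-1)/2` unordered trait
#' pairs in canonical orientation (numerator precedes denominator in panel
#' order), `m(m+1)/2` tests in total -- the multiple-testing family used
#' by the "all ratios & traits" threshold.
#'
#' @param traits Either the number of traits or a character vector of
#'   trait ids fixing the panel order.
#' @return A `data.frame` with columns `test_id`, `kind`
#'   (`"single"`/`"ratio"`), `trait_a`, `trait_b` (`NA` for singles).
#' @examples
#' nrow(enumerate_tests(168)) # 14196
#' @export
enumerate_tests <- function(traits) {
  ids <- if (is.numeric(traits)) {
    stopifnot_scalar_number(traits, "traits", lower = 1)
    paste0("T", seq_len(traits))
  } else {
    as.character(traits)
  }
  m <- length(ids)
  if (m < 1) stop("need at least one trait", call. = FALSE)
  singles <- data.frame(
    test_id = ids, kind = "single", trait_a = ids, trait_b = NA_character_,
    stringsAsFactors = FALSE
  )
  if (m == 1) return(singles)
  pr <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  pr <- pr[order(pr[, "row"], pr[, "col"]), , drop = FALSE]
  ratios <- data.frame(
    test_id = paste0(ids[pr[, "row"]], "/", ids[pr[, "col"]]),
    kind = "ratio",
    trait_a = ids[pr[, "row"]],
    trait_b = ids[pr[, "col"]],
    stringsAsFactors = FALSE
  )
  rbind(singles, ratios)
}

#' Construct a log-ratio phenotype
#'
#' The log-ratio is the elementwise difference `log A - log B`, which makes
#' every downstream association statistic invariant to inverting the ratio
#' (the effect size flips sign; the p-value is unchanged).
#'
#' @param log_traits A log-stage [trait_matrix()].
#' @param trait_a,trait_b Numerator and denominator trait ids.
#' @return Numeric vector `log A - log B`; missing wherever either
#'   component is missing.  Feed through [inverse_normal()] to obtain the
#'   analysis phenotype.
#' @export
make_ratio <- function(log_traits, trait_a, trait_b) {
  if (trait_stage(log_traits) != "log") {
    stop("make_ratio() expects a log-stage trait matrix", call. = FALSE)
  }
  if (identical(trait_a, trait_b)) {
    stop("ratio of a trait with itself is identically zero", call. = FALSE)
  }
  miss <- setdiff(c(trait_a, trait_b), colnames(log_traits))
  if (length(miss)) stop("unknown trait id: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  log_traits[, trait_a] - log_traits[, trait_b]
}

#' Build the full inverse-normal phenotype block for a test list
#'
#' Singles become `INT(log x)`; ratios become `INT(log A - log B)`, so the
#' combined family is one uniform phenotype set.  Degenerate phenotypes
#' (constant after missingness) are dropped with a warning.
#'
#' @param log_traits A log-stage [trait_matrix()].
#' @param tests A test table from [enumerate_tests()] (or any subset).
#' @inheritParams inverse_normal
#' @return samples x tests numeric matrix of INT phenotypes with test ids
#'   as column names; attribute `"dropped"` lists degenerate tests.
#' @export
build_phenotypes <- function(log_traits, tests, offset = 3 / 8) {
  if (trait_stage(log_traits) != "log") {
    stop("build_phenotypes() expects a log-stage trait matrix", call. = FALSE)
  }
  cols <- lapply(seq_len(nrow(tests)), function(k) {
    y <- if (tests$kind[k] == "single") {
      log_traits[, tests$trait_a[k]]
    } else {
      make_ratio(log_traits, tests$trait_a[k], tests$trait_b[k])
    }
    tryCatch(inverse_normal(y, offset = offset), error = function(e) NULL)
  })
  keep <- !vapply(cols, is.null, logical(1))
  if (!all(keep)) {
    warning("dropping degenerate test phenotype(s): ",
            paste(tests$test_id[!keep], collapse = ", "))
  }
  out <- do.call(cbind, cols[keep])
  dimnames(out) <- list(rownames(log_traits), tests$test_id[keep])
  attr(out, "dropped") <- tests$test_id[!keep]
  out
}
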