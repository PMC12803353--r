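# Locus-by-ratio p-gain matrices, per-locus normalization, hierarchical
# clustering, and effect-profile comparisons.

#' Build the lead-ratio by locus log10 p-gain matrix
#'
#' Columns are the loci with at least one p-gain-significant ratio; rows
#' are the union of those loci's lead ratios (the ratio with the largest
#' log10 p-gain among significant ones at each locus).  Cells hold the
#' log10 p-gain of the (ratio, locus) pair, with 0 -- "no evidence" --
#' where the pair was not computed or not present.
#'
#' @param records A `"pgain_record"` `data.frame` (all flagged under one
#'   threshold set).
#' @param thresholds The [compute_thresholds()] set used for the flags.
#' @return A ratios x loci numeric matrix with attribute `stage = "raw"`;
#'   empty (0 columns) with a warning if no locus has a significant
#'   p-gain.
#' @export
build_pgain_matrix <- function(records, thresholds) {
  sig_loci <- unique(records$variant_id[records$significant_pgain])
  if (!length(sig_loci)) {
    warning("no locus with a significant p-gain: empty matrix")
    m <- matrix(numeric(0), nrow = 0, ncol = 0)
    attr(m, "stage") <- "raw"
    return(m)
  }
  lead_ratios <- vapply(sig_loci, function(l) {
    rec <- records[records$variant_id == l, , drop = FALSE]
    select_lead(rec, thresholds, family = "all_ratios")$lead_pgain$test_id
  }, character(1))
  rows <- sort(unique(lead_ratios))
  m <- matrix(0, nrow = length(rows), ncol = length(sig_loci),
              dimnames = list(rows, sig_loci))
  hit <- records[records$test_id %in% rows & records$variant_id %in% sig_loci, ]
  m[cbind(match(hit$test_id, rows), match(hit$variant_id, sig_loci))] <-
    hit$log10_pgain
  attr(m, "stage") <- "raw"
  m
}

#' Normalize a p-gain matrix per locus
#'
#' Divides every locus column by its own maximum so that the strongest
#' ratio at each locus scores 1, making loci with very different absolute
#' p-gains comparable before clustering.  Columns without a positive
#' maximum carry no evidence and are dropped with a warning.
#'
#' @param m A raw-stage matrix from [build_pgain_matrix()].
#' @return The column-normalized matrix, `stage = "normalized"`;
#'   idempotent.
#' @export
normalize_per_locus <- function(m) {
  if (!ncol(m)) {
    attr(m, "stage") <- "normalized"
    return(m)
  }
  mx <- apply(m, 2, max)
  bad <- mx <= 0
  if (any(bad)) {
    warning("dropping column(s) with non-positive maximum: ",
            paste(colnames(m)[bad], collapse = ", "))
  }
  out <- sweep(m[, !bad, drop = FALSE], 2, mx[!bad], `/`)
  attr(out, "stage") <- "normalized"
  out
}

#' Hierarchically cluster rows and columns of a normalized p-gain matrix
#'
#' Rows (ratios) and columns (loci) are clustered independently by
#' agglomerative clustering; defaults (Euclidean distance, average
#' linkage) are the common heatmap defaults and both are configurable.
#' Deterministic given the inputs.
#'
#' @param m A normalized matrix from [normalize_per_locus()].
#' @param metric Distance metric passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A list of class `"pgain_clustering"`: `row_order`, `col_order`
#'   (leaf orders as names), `row_tree`, `col_tree` (`hclust` objects or
#'   `NULL` when a dimension has fewer than 2 elements, in which case the
#'   identity order is returned with a warning).
#' @export
hierarchical_cluster <- function(m, metric = "euclidean", linkage = "average") {
  cluster_dim <- function(x, what) {
    if (nrow(x) < 2) {
      warning("fewer than 2 ", what, ": identity ordering")
      return(list(order = rownames(x), tree = NULL))
    }
    hc <- hclust(dist(x, method = metric), method = linkage)
    list(order = rownames(x)[hc$order], tree = hc)
  }
  rowc <- cluster_dim(m, "rows")
  colc <- cluster_dim(t(m), "columns")
  structure(list(row_order = rowc$order, col_order = colc$order,
                 row_tree = rowc$tree, col_tree = colc$tree,
                 metric = metric, linkage = linkage),
            class = "pgain_clustering")
}

#' Export a cluster tree in Newick format
#'
#' @param tree An `hclust` object (e.g. `row_tree` from
#'   [hierarchical_cluster()]).
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to `file`.
#' @export
cluster_tree_newick <- function(tree, file = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for Newick export", call. = FALSE)
  }
  phy <- ape::as.phylo(tree)
  if (is.null(file)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = file)
    invisible(ape::write.tree(phy))
  }
}

#' Effect profile of a variant or exposure over an ordered trait list
#'
#' @param id Entity label.
#' @param traits Ordered trait ids.
#' @param beta,se Effect and standard-error vectors in `traits` order.
#' @return A list of class `"effect_profile"`.
#' @export
effect_profile <- function(id, traits, beta, se = rep(NA_real_, length(beta))) {
  if (length(traits) != length(beta) || length(beta) != length(se)) {
    stop("`traits`, `beta`, `se` must share length", call. = FALSE)
  }
  structure(list(id = id, traits = as.character(traits),
                 beta = as.numeric(beta), se = as.numeric(se)),
            class = "effect_profile")
}

#' Compare two effect profiles
#'
#' Pearson correlation of the two beta vectors over the shared trait
#' order, its square, and the paired table for scatter export.  Symmetric
#' in its arguments.
#'
#' @param a,b `effect_profile` objects with identical trait order
#'   (length >= 3).
#' @return List: `pearson_r`, `r_squared`, `table` (`data.frame` trait /
#'   beta_a / beta_b).
#' @export
compare_effect_profiles <- function(a, b) {
  if (!identical(a$traits, b$traits)) {
    stop("profiles must share the same trait order", call. = FALSE)
  }
  if (length(a$beta) < 3) stop("need >= 3 traits", call. = FALSE)
  if (sd(a$beta) == 0 || sd(b$beta) == 0) {
    stop("constant effect vector: correlation undefined", call. = FALSE)
  }
  r <- cor(a$beta, b$beta)
  list(pearson_r = r, r_squared = r^2,
       table = data.frame(trait = a$traits, beta_a = a$beta, beta_b = b$beta,
                          stringsAsFactors = FALSE))
}

#' Re-sign per-size-class effects relative to a reference class
#'
#' For one ratio family measured across lipoprotein size classes, flips
#' each variant's effects so that its effect in the reference class is
#' positive -- the heatmap convention "directionality relative to the
#' reference class".  Variants with a zero reference effect fall back to
#' their raw signs and are flagged.
#'
#' @param results `data.frame` with columns `variant_id`, `size_class`,
#'   `beta` (one row per variant x class).
#' @param reference The reference size-class label.
#' @return A variants x classes matrix of re-signed betas with attribute
#'   `"flagged"` naming zero-reference variants.
#' @export
directionality_panel <- function(results, reference) {
  if (!reference %in% results$size_class) {
    stop("reference class '", reference, "' absent from results", call. = FALSE)
  }
  variants <- unique(results$variant_id)
  classes <- unique(results$size_class)
  m <- matrix(NA_real_, length(variants), length(classes),
              dimnames = list(variants, classes))
  m[cbind(match(results$variant_id, variants),
          match(results$size_class, classes))] <- results$beta
  ref <- m[, reference]
  s <- sign(ref)
  flagged <- variants[!is.na(s) & s == 0]
  s[is.na(s) | s == 0] <- 1
  out <- m * s
  attr(out, "flagged") <- flagged
  attr(out, "reference") <- reference
  out
}
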