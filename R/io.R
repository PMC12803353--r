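# Plain-TSV readers/writers for every pipeline product.  All tables are
# tab-separated with a header row; matrices gain a `sample_id` first
# column; trait matrices carry their processing stage in a JSON sidecar.

#' Write / read a data frame as TSV
#'
#' @param df A `data.frame`.
#' @param path Output path (`.tsv`).
#' @return `path`, invisibly (writer); the `data.frame` (reader).
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a samples x columns matrix as TSV with a sample_id column
#'
#' @param m Numeric matrix with sample row names.
#' @inheritParams write_tsv
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "double"
  m
}

#' Write / read a staged trait matrix (TSV + JSON stage sidecar)
#'
#' @param traits A [trait_matrix()].
#' @inheritParams write_tsv
#' @export
write_trait_matrix <- function(traits, path) {
  write_matrix_tsv(traits, path)
  meta <- list(stage = trait_stage(traits),
               n_samples = nrow(traits), n_traits = ncol(traits))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trait_matrix
#' @export
read_trait_matrix <- function(path) {
  m <- read_matrix_tsv(path)
  meta_path <- paste0(path, ".meta.json")
  stage <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path)$stage
  } else {
    "raw"
  }
  trait_matrix(m, stage = stage)
}

#' Write genotype dosages as VCF with a DS (dosage) FORMAT field
#'
#' Minimal VCF 4.2 output for interoperability; positions are synthetic
#' (sequential on chromosome 1) unless a `pos` vector is given.
#'
#' @param geno samples x variants dosage matrix.
#' @param path Output `.vcf` path.
#' @param pos Optional integer positions per variant.
#' @export
write_genotypes_vcf <- function(geno, path, pos = NULL) {
  ids <- colnames(geno)
  pos <- pos %||% seq_len(ncol(geno)) * 1000L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t")
  ), con)
  for (j in seq_len(ncol(geno))) {
    writeLines(paste(c("1", pos[j], ids[j], "A", "G", ".", "PASS", ".",
                       "DS", formatC(geno[, j], format = "g")),
                     collapse = "\t"), con)
  }
  invisible(path)
}
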