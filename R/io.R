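# Plain-text readers/writers for the pipeline's external interfaces:
# manifest TSV, beta matrices as TSV (samples as rows, probes as columns,
# NA for missing), sample sheet CSV.

#' Write / read a probe manifest as TSV
#' @param manifest a `probe_manifest`.
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  class(m) <- c("probe_manifest", "data.frame")
  m
}

#' Write / read a beta matrix as TSV (samples x probes)
#' @param betas numeric matrix with sample row names and probe column names.
#' @param path file path.
#' @export
write_beta_matrix <- function(betas, path) {
  df <- data.frame(sample_id = rownames(betas), betas, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$sample_id
  m
}

#' Write / read a sample sheet as CSV
#' @param sheet a `sample_sheet`.
#' @param path file path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("smoking", "depression", "medication"))
    if (col %in% names(s)) s[[col]] <- as.logical(s[[col]])
  class(s) <- c("sample_sheet", "data.frame")
  s
}
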