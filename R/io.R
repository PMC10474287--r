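# TSV/JSON readers and writers for the pipeline artifacts. All tables are
# tab-separated with a mandatory header; '.' encodes missing values.

na_str <- "."

#' Read and write a beta-value matrix as TSV
#'
#' Rows are CpG IDs (first column `site_id`), columns are sample IDs.
#'
#' @param path File path.
#' @return `read_beta_matrix()`: numeric sites x samples matrix.
#' @export
read_beta_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = na_str)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  assert_matrix_like(m, "beta matrix")
}

#' @rdname read_beta_matrix
#' @param m Matrix to write.
#' @export
write_beta_matrix <- function(m, path) {
  df <- data.frame(site_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = na_str)
  invisible(path)
}

#' Read and write a sample sheet TSV
#'
#' Columns: `sample_id`, `status` (control / case_initial / candidate),
#' covariates (`sex`, `age`, cell-fraction columns), `age_at_onset`,
#' `onset_observed`.
#'
#' @param path File path.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = na_str,
                   stringsAsFactors = FALSE)
  req <- c("sample_id", "status")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_episig("sample sheet lacks column(s): %s", paste(miss, collapse = ", "))
  df
}

#' @rdname read_sample_sheet
#' @param df data.frame to write.
#' @export
write_sample_sheet <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = na_str)
  invisible(path)
}

#' Read a variant-observation TSV
#'
#' Columns: `sample_id`, `gene`, `depth`, and either `variant_reads` or
#' `vaf`.
#'
#' @param path File path.
#' @export
read_variant_observations <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = na_str,
                   stringsAsFactors = FALSE)
  if (!all(c("sample_id", "depth") %in% names(df)) ||
      !any(c("variant_reads", "vaf") %in% names(df)))
    stop_episig("variant table needs sample_id, depth and variant_reads or vaf")
  if (!"vaf" %in% names(df)) df$vaf <- df$variant_reads / df$depth
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = na_str)
  invisible(path)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

# Run manifest: input checksums + config + seed + package version, enough
# to re-run a stage exactly.
write_manifest <- function(out_dir, inputs, config, seed) {
  files <- inputs[file.exists(inputs)]
  write_json(list(
    inputs = as.list(setNames(unname(tools::md5sum(files)), files)),
    config = config, seed = seed,
    package = as.character(utils::packageVersion("episig")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(out_dir, "manifest.json"))
}
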