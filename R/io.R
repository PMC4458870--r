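# Readers and writers. TSV is the canonical dialect; comma-separated
# files are auto-detected on import. Every output file embeds a config
# echo and MD5 checksums of its inputs as '# ' comment lines.

WELL_TABLE_COLUMNS <- c("plate_id", "well", "role", "shrna_id", "gene",
                        "pax7_count", "dapi_count")

normalize_headers <- function(dt, required, optional = character()) {
  names(dt) <- tolower(trimws(names(dt)))
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    schema_error(paste0("missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 columns = missing_cols)
  dt[, c(required, intersect(optional, names(dt))), with = FALSE]
}

check_numeric_column <- function(values, column, offset = 1L) {
  suppressWarnings(num <- as.numeric(values))
  bad <- which(!is.na(values) & values != "" & is.na(num))
  if (length(bad))
    schema_error(sprintf(
      "malformed numeric in column '%s' at line %d (value '%s')",
      column, bad[1] + offset, values[bad[1]]))
  num
}

#' Read a long-format per-well screen table
#'
#' Expects columns `plate_id`, `well`, `role`, `shrna_id`, `gene`,
#' `pax7_count`, `dapi_count` (case-insensitive, any order; TSV or CSV).
#' Row-level problems — malformed counts, a Pax7 count exceeding the DAPI
#' count, unknown roles — are reported with their line number.
#'
#' @param path input file.
#' @return data.frame of wells (use [as_plate_list()] to validate plates).
#' @export
read_well_table <- function(path) {
  if (!file.exists(path)) schema_error(paste0("file not found: ", path))
  dt <- data.table::fread(path, colClasses = "character", sep = "auto",
                          header = TRUE)
  dt <- normalize_headers(dt, WELL_TABLE_COLUMNS)
  df <- as.data.frame(dt, stringsAsFactors = FALSE)
  header_line <- 1L + sum(startsWith(readLines(path, n = 50L), "#"))
  df$pax7_count <- as.integer(check_numeric_column(df$pax7_count,
                                                  "pax7_count", header_line))
  df$dapi_count <- as.integer(check_numeric_column(df$dapi_count,
                                                  "dapi_count", header_line))
  bad_role <- which(!df$role %in% WELL_ROLES)
  if (length(bad_role))
    schema_error(sprintf(
      "unknown well role '%s' at line %d; allowed roles: %s",
      df$role[bad_role[1]], bad_role[1] + header_line,
      paste(WELL_ROLES, collapse = ", ")))
  over <- which(df$pax7_count > df$dapi_count)
  if (length(over))
    data_error(sprintf("pax7_count exceeds dapi_count at line %d",
                       over[1] + header_line))
  df$shrna_id[df$shrna_id %in% c("", "NA")] <- NA_character_
  df$gene[df$gene %in% c("", "NA")] <- NA_character_
  df
}

#' Read a per-fraction protein table
#'
#' Expects the canonical protein-group columns (`protein_id`,
#' `gene_symbol`, `peptide_count`, `unique_peptide_count`,
#' `min_peptide_length`, `intensity`, `fdr_pass`), case-insensitive and
#' order-free, TSV or CSV.
#'
#' @param path input file.
#' @param fraction_label the population the table belongs to.
#' @return A validated `fraction_proteome`.
#' @export
read_fraction_table <- function(path, fraction_label) {
  if (!file.exists(path)) schema_error(paste0("file not found: ", path))
  dt <- data.table::fread(path, colClasses = "character", sep = "auto",
                          header = TRUE)
  dt <- normalize_headers(dt, PROTEOME_COLUMNS)
  df <- as.data.frame(dt, stringsAsFactors = FALSE)
  header_line <- 1L + sum(startsWith(readLines(path, n = 50L), "#"))
  for (col in c("peptide_count", "unique_peptide_count",
                "min_peptide_length", "intensity"))
    df[[col]] <- check_numeric_column(df[[col]], col, header_line)
  df$fdr_pass <- df$fdr_pass %in% c("TRUE", "true", "T", "1", "yes")
  fraction_proteome(df, fraction_label)
}

#' Import a sheet of a supplementary-style spreadsheet
#'
#' Thin wrapper over `readxl` for workbook tabs (e.g. pre-normalized score
#' lists); empty rows are dropped. Requires the `readxl` package.
#'
#' @param path `.xlsx`/`.xls` workbook.
#' @param tab sheet name or index.
#' @return data.frame of the non-empty rows.
#' @export
read_supplementary_workbook <- function(path, tab = 1L) {
  if (!requireNamespace("readxl", quietly = TRUE))
    schema_error("reading spreadsheets requires the 'readxl' package")
  if (!file.exists(path)) schema_error(paste0("file not found: ", path))
  df <- as.data.frame(readxl::read_excel(path, sheet = tab),
                      stringsAsFactors = FALSE)
  df[rowSums(!is.na(df)) > 0, , drop = FALSE]
}

config_echo_lines <- function(config = NULL, inputs = character()) {
  lines <- sprintf("# muscscreen %s | written %s",
                   as.character(utils::packageVersion("muscscreen")),
                   format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(config))
    lines <- c(lines, paste0("# config: ", jsonlite::toJSON(
      unclass(config), auto_unbox = TRUE, null = "null")))
  inputs <- inputs[file.exists(inputs)]
  if (length(inputs)) {
    sums <- tools::md5sum(inputs)
    lines <- c(lines, sprintf("# input: %s md5=%s", names(sums), sums))
  }
  lines
}

write_table_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a per-well table
#'
#' @param wells well data.frame or a list of `screen_plate` objects.
#' @param path output TSV.
#' @param config optional [run_config()] echoed into the header.
#' @param inputs paths whose MD5 checksums are recorded in the header.
#' @return `path`, invisibly.
#' @export
write_well_table <- function(wells, path, config = NULL,
                             inputs = character()) {
  if (is.list(wells) && !is.data.frame(wells))
    wells <- do.call(rbind, lapply(wells, as.data.frame))
  write_table_with_header(wells[WELL_TABLE_COLUMNS], path,
                          config_echo_lines(config, inputs))
}

#' Write a fraction table
#'
#' @param fraction a `fraction_proteome`.
#' @inheritParams write_well_table
#' @return `path`, invisibly.
#' @export
write_fraction_table <- function(fraction, path, config = NULL,
                                 inputs = character()) {
  hdr <- c(config_echo_lines(config, inputs),
           paste0("# fraction_label: ", fraction_label(fraction)))
  write_table_with_header(as.data.frame(fraction), path, hdr)
}

#' Write an enrichment result with gate provenance
#'
#' One row per input GFP+ protein with the per-gate pass flags; the
#' ranking mode is recorded in a header comment line.
#'
#' @param result an `enrichment_result` from [musc_specific_proteome()].
#' @inheritParams write_well_table
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(result, path, config = NULL,
                                   inputs = character()) {
  prov <- result$provenance
  prov$rank <- match(prov$protein_id, result$retained)
  prov <- prov[order(prov$rank, prov$protein_id), ]
  hdr <- c(config_echo_lines(config, inputs),
           paste0("# ranking_mode: ", result$ranking_mode),
           paste0("# retained: ", length(result$retained)))
  write_table_with_header(prov, path, hdr)
}

#' Write the screen hit report
#'
#' Emits four files next to `prefix`: `<prefix>_qc.tsv` (per-plate QC),
#' `<prefix>_scores.tsv` (normalized scores with direction calls),
#' `<prefix>_genes.tsv` (per-gene consensus with supporting shRNAs) and
#' `<prefix>_hits.tsv` (final UP/DOWN lists). A JSON run summary with the
#' config echo goes to `<prefix>_run.json`.
#'
#' @param result a `screen_result` from [screen_hits()].
#' @param prefix output path prefix.
#' @param inputs paths checksummed into the headers.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_screen_report <- function(result, prefix, inputs = character()) {
  config <- result$report$config
  hdr <- config_echo_lines(config, inputs)
  paths <- c(qc = paste0(prefix, "_qc.tsv"),
             scores = paste0(prefix, "_scores.tsv"),
             genes = paste0(prefix, "_genes.tsv"),
             hits = paste0(prefix, "_hits.tsv"),
             run = paste0(prefix, "_run.json"))
  write_table_with_header(result$report$qc, paths["qc"], hdr)
  if (!is.null(result$scores))
    write_table_with_header(result$scores, paths["scores"], hdr)
  if (!is.null(result$gene_calls))
    write_table_with_header(result$gene_calls, paths["genes"], hdr)
  hits <- rbind(
    if (length(result$up_genes))
      data.frame(gene = result$up_genes, direction = "UP"),
    if (length(result$down_genes))
      data.frame(gene = result$down_genes, direction = "DOWN"))
  if (is.null(hits)) hits <- data.frame(gene = character(),
                                        direction = character())
  write_table_with_header(hits, paths["hits"], hdr)
  run <- result$report
  run$qc <- NULL
  jsonlite::write_json(run, paths["run"], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(paths)
}
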