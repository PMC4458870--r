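# Run configuration: every tunable of the pipeline with its default.

#' Pipeline run configuration
#'
#' Collects every tunable stage parameter. Defaults equal the screen's
#' documented processing constants where one exists: 25% percentile cuts,
#' two independent supporting shRNAs, Z' gate at 0.5, peptides of at least
#' six amino acids with at least one unique peptide.
#'
#' @param q percentile tail fraction for hit cuts (default 0.25).
#' @param min_support concordant shRNAs required per gene call (default 2).
#' @param z_prime_gate plate QC pass threshold on Z' (default 0.5).
#' @param min_len,min_unique proteome identification thresholds (6, 1).
#' @param dapi_floor minimum DAPI+ nuclei per measurable well (default 10;
#'   with 450 cells seeded per well, emptier wells are failures).
#' @param convention normalization orientation, see [normalize_plate()].
#' @param positive_role QC positive-control role (default `"sh_pax7"`).
#' @param artifact_exclusion character vector of genes to exclude as
#'   manually flagged imaging artifacts.
#' @param seed integer seed driving all randomness, or `NULL`.
#' @return Named list of class `run_config` with a schema id field.
#' @export
run_config <- function(q = 0.25, min_support = 2L, z_prime_gate = 0.5,
                       min_len = 6L, min_unique = 1L, dapi_floor = 10L,
                       convention = c("fold", "fold_minus_one", "neg_fold"),
                       positive_role = c("sh_pax7", "sh_nf1"),
                       artifact_exclusion = character(),
                       seed = NULL) {
  convention <- match.arg(convention)
  positive_role <- match.arg(positive_role)
  if (!is.numeric(q) || q <= 0 || q >= 0.5)
    param_error("`q` must be in (0, 0.5)")
  if (!is_count(min_support, 1)) param_error("`min_support` must be >= 1")
  structure(list(schema = "muscscreen/config/v1",
                 q = q, min_support = as.integer(min_support),
                 z_prime_gate = z_prime_gate,
                 min_len = as.integer(min_len),
                 min_unique = as.integer(min_unique),
                 dapi_floor = as.integer(dapi_floor),
                 convention = convention, positive_role = positive_role,
                 quantile_convention = "type7_linear_interpolation",
                 artifact_exclusion = as.character(artifact_exclusion),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = c("run_config", "list"))
}

#' Read a run configuration from JSON or YAML
#'
#' JSON is the canonical on-disk dialect; YAML is accepted when the `yaml`
#' package is installed. Unknown keys are rejected so typos do not silently
#' fall back to defaults. A seed is mandatory in files driving generators.
#'
#' @param path configuration file.
#' @param require_seed error when the file carries no seed (default FALSE).
#' @return A [run_config()] list.
#' @export
read_run_config <- function(path, require_seed = FALSE) {
  if (!file.exists(path)) schema_error(paste0("config file not found: ", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      schema_error("YAML config supplied but the 'yaml' package is not installed")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  raw$schema <- NULL
  raw$quantile_convention <- NULL
  allowed <- setdiff(names(formals(run_config)), "...")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    schema_error(paste0("unknown config key(s): ",
                        paste(unknown, collapse = ", ")))
  if (require_seed && is.null(raw$seed))
    schema_error("config file must set an integer `seed`")
  do.call(run_config, raw)
}
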