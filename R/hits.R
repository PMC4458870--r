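# Gene-level hit calling: screen-wide percentile thresholds on normalized
# shRNA scores, multi-shRNA consensus, opposing-phenotype subtraction and
# an externally supplied artifact exclusion list.

#' Percentile thresholds of the pooled score distribution
#'
#' Hit cuts are the `q` and `1 - q` quantiles of all normalized sample-well
#' scores pooled screen-wide (scores are already plate-normalized, so one
#' pooled distribution is used). Quantiles use the linear-interpolation
#' convention between order statistics (R type 7).
#'
#' @param scores numeric vector of normalized scores, length >= 4.
#' @param q tail fraction in (0, 0.5); default 0.25.
#' @return Named numeric vector `c(low = ..., high = ...)`.
#' @export
percentile_thresholds <- function(scores, q = 0.25) {
  if (length(scores) < 4L)
    param_error("need at least 4 scores to set percentile thresholds")
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 0.5)
    param_error("`q` must be a single number in (0, 0.5)")
  cuts <- stats::quantile(scores, probs = c(q, 1 - q), names = FALSE,
                          type = 7)
  c(low = cuts[1], high = cuts[2])
}

#' Direction call per shRNA
#'
#' An shRNA is called `UP` if its score is strictly above the high cut,
#' `DOWN` if strictly below the low cut, and `none` otherwise. Boundary
#' scores are non-hits (conservative strict inequalities).
#'
#' @param scores data.frame with columns `shrna_id`, `gene`, `score`
#'   (e.g. rows of [normalize_plate()] output), or a named numeric vector.
#' @param low_cut,high_cut thresholds from [percentile_thresholds()].
#' @return data.frame `shrna_id`, `gene`, `score`, `direction` (factor-free
#'   character: `"UP"`, `"DOWN"`, `"none"`).
#' @export
call_shrnas <- function(scores, low_cut, high_cut) {
  if (is.numeric(scores)) {
    scores <- data.frame(shrna_id = names(scores) %||%
                           as.character(seq_along(scores)),
                         gene = NA_character_, score = as.numeric(scores),
                         stringsAsFactors = FALSE)
  }
  direction <- rep("none", nrow(scores))
  direction[scores$score > high_cut] <- "UP"
  direction[scores$score < low_cut] <- "DOWN"
  out <- scores[, intersect(c("shrna_id", "gene", "score", "plate_id"),
                            names(scores)), drop = FALSE]
  out$direction <- direction
  out
}

#' Gene-level consensus over independent shRNA constructs
#'
#' A gene is called in a direction when at least `min_support` distinct
#' shRNA constructs against it are called in that direction ("two
#' independent shRNAs" in the default configuration). A gene may
#' provisionally satisfy both directions; [subtract_opposing()] resolves
#' that. Genes represented by fewer than `min_support` scored shRNAs can
#' never be hits and are reported separately as insufficient evidence.
#'
#' @param shrna_calls output of [call_shrnas()].
#' @param min_support minimum number of concordant shRNAs (default 2).
#' @return list with `calls` (per-gene data.frame: `gene`, `n_shrnas`,
#'   `n_up`, `n_down`, `up`, `down`, supporting ids), `provisional_up`,
#'   `provisional_down` (character vectors) and `insufficient` (genes with
#'   fewer than `min_support` scored shRNAs).
#' @export
gene_consensus <- function(shrna_calls, min_support = 2L) {
  if (!is_count(min_support, min = 1))
    param_error("`min_support` must be a single integer >= 1")
  sc <- shrna_calls[!is.na(shrna_calls$gene), , drop = FALSE]
  split_gene <- split(sc, sc$gene)
  calls <- do.call(rbind, lapply(split_gene, function(g) {
    up_ids <- g$shrna_id[g$direction == "UP"]
    down_ids <- g$shrna_id[g$direction == "DOWN"]
    data.frame(gene = g$gene[1], n_shrnas = nrow(g),
               n_up = length(up_ids), n_down = length(down_ids),
               up = length(up_ids) >= min_support,
               down = length(down_ids) >= min_support,
               up_shrnas = paste(up_ids, collapse = ";"),
               down_shrnas = paste(down_ids, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  calls <- calls[order(calls$gene), , drop = FALSE]
  list(calls = calls,
       provisional_up = calls$gene[calls$up],
       provisional_down = calls$gene[calls$down],
       insufficient = calls$gene[calls$n_shrnas < min_support],
       min_support = as.integer(min_support))
}

#' Remove genes with opposing phenotypes
#'
#' Genes qualifying for both the UP and DOWN provisional lists are removed
#' from both, leaving disjoint final lists.
#'
#' @param up_genes,down_genes character vectors of provisional gene calls.
#' @return list `up`, `down` (disjoint) and `opposing` (the removed genes).
#' @export
subtract_opposing <- function(up_genes, down_genes) {
  opposing <- intersect(up_genes, down_genes)
  list(up = setdiff(up_genes, opposing),
       down = setdiff(down_genes, opposing),
       opposing = opposing)
}

#' Apply an external artifact exclusion list
#'
#' Genes flagged as imaging artifacts after manual re-evaluation (supplied
#' externally; the manual step is not reproducible) are removed from both
#' hit lists; removals are recorded.
#'
#' @param up_genes,down_genes final hit lists.
#' @param exclusion character vector of gene symbols to drop.
#' @return list `up`, `down`, `removed` (excluded genes that were hits)
#'   and `noop` (excluded genes that were not hits).
#' @export
apply_artifact_exclusion <- function(up_genes, down_genes,
                                     exclusion = character()) {
  removed <- intersect(exclusion, union(up_genes, down_genes))
  list(up = setdiff(up_genes, exclusion),
       down = setdiff(down_genes, exclusion),
       removed = removed,
       noop = setdiff(exclusion, removed))
}

#' Full screen hit-calling pipeline
#'
#' Composition of the whole analysis on raw plates: Z'-factor QC gate,
#' per-plate empty-vector normalization of passing plates, screen-wide
#' percentile thresholds, per-shRNA direction calls, gene-level consensus,
#' opposing-phenotype subtraction and artifact exclusion. Every gate
#' decision is recorded in the report.
#'
#' @param plates list of `screen_plate` objects (see [as_plate_list()]).
#' @param config a [run_config()] list; individual fields can be
#'   overridden via `...`.
#' @param ... overrides merged into `config`.
#' @return An object of class `screen_result`: list with `up_genes`,
#'   `down_genes`, `scores` (pooled normalized score table with direction
#'   calls), `gene_calls`, `insufficient`, and `report` (plate QC table,
#'   cuts, per-stage counts, config echo).
#' @export
screen_hits <- function(plates, config = run_config(), ...) {
  config <- modifyList(config, list(...))
  if (inherits(plates, "screen_plate")) plates <- list(plates)
  qc <- lapply(plates, function(p)
    tryCatch(plate_qc(p, positive_role = config$positive_role,
                      gate = config$z_prime_gate,
                      dapi_floor = config$dapi_floor),
             msc_qc_error = function(e)
               structure(list(plate_id = p$plate_id[1],
                              positive_role = config$positive_role,
                              mu_pos = NA_real_, mu_neg = NA_real_,
                              sigma_pos = NA_real_, sigma_neg = NA_real_,
                              z_prime = NA_real_, passed = FALSE,
                              reason = conditionMessage(e)),
                         class = "plate_qc")))
  qc_table <- do.call(rbind, lapply(qc, function(x)
    data.frame(plate_id = x$plate_id, mu_pos = x$mu_pos, mu_neg = x$mu_neg,
               sigma_pos = x$sigma_pos, sigma_neg = x$sigma_neg,
               z_prime = x$z_prime, passed = x$passed,
               reason = x$reason %||% NA_character_,
               stringsAsFactors = FALSE)))
  passing <- plates[vapply(qc, `[[`, logical(1), "passed")]

  empty_result <- function(reason) {
    structure(list(up_genes = character(), down_genes = character(),
                   scores = NULL, gene_calls = NULL,
                   insufficient = character(),
                   report = list(qc = qc_table, reason = reason,
                                 config = config)),
              class = "screen_result")
  }
  if (!length(passing)) return(empty_result("all plates failed QC"))

  scores <- do.call(rbind, lapply(passing, normalize_plate,
                                  dapi_floor = config$dapi_floor,
                                  convention = config$convention))
  rownames(scores) <- NULL
  if (is.null(scores) || nrow(scores) < 4L)
    return(empty_result("fewer than 4 scored sample wells"))

  cuts <- percentile_thresholds(scores$score, q = config$q)
  scores <- call_shrnas(scores, cuts[["low"]], cuts[["high"]])
  consensus <- gene_consensus(scores, min_support = config$min_support)
  resolved <- subtract_opposing(consensus$provisional_up,
                                consensus$provisional_down)
  final <- apply_artifact_exclusion(resolved$up, resolved$down,
                                    config$artifact_exclusion)

  report <- list(
    qc = qc_table,
    n_plates = length(plates), n_plates_passed = length(passing),
    n_scored_shrnas = nrow(scores),
    cuts = cuts, quantile_convention = "linear interpolation (R type 7)",
    n_provisional_up = length(consensus$provisional_up),
    n_provisional_down = length(consensus$provisional_down),
    opposing_removed = resolved$opposing,
    artifacts_removed = final$removed,
    artifact_noop = final$noop,
    config = config
  )
  structure(list(up_genes = sort(final$up), down_genes = sort(final$down),
                 scores = scores, gene_calls = consensus$calls,
                 insufficient = consensus$insufficient, report = report),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(paste0("<screen_result: %d/%d plate(s) passed QC, ",
                     "%d shRNA scores, %d UP / %d DOWN gene(s)>\n"),
              x$report$n_plates_passed %||% 0L, x$report$n_plates %||% 0L,
              if (is.null(x$scores)) 0L else nrow(x$scores),
              length(x$up_genes), length(x$down_genes)))
  if (!is.null(x$report$cuts))
    cat(sprintf("cuts: DOWN < %.4f, UP > %.4f (q = %g)\n",
                x$report$cuts[["low"]], x$report$cuts[["high"]],
                x$report$config$q))
  invisible(x)
}
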