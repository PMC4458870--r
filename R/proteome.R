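# Derivation of the muscle-stem-cell-specific proteome from label-free
# protein-group tables: identification filtering, fraction subtraction,
# intensity gating and ranking.

FRACTION_LABELS <- c("myotube", "gfp_neg", "percoll_sc", "gfp_pos")

PROTEOME_COLUMNS <- c("protein_id", "gene_symbol", "peptide_count",
                      "unique_peptide_count", "min_peptide_length",
                      "intensity", "fdr_pass")

#' Construct a per-fraction protein table
#'
#' A `fraction_proteome` is the protein-group table of one sorted cell
#' population: FACS-purified GFP+ muscle stem cells (`gfp_pos`), the GFP-
#' mononuclear remainder (`gfp_neg`), percoll-gradient cells before sorting
#' (`percoll_sc`) or differentiated myotubes (`myotube`). Each row is one
#' protein group with its summarized label-free intensity and peptide
#' evidence. A protein absent from a fraction is simply absent from the
#' table; its intensity in that fraction is treated as exactly 0.
#'
#' @param records data.frame with columns `protein_id`, `gene_symbol`,
#'   `peptide_count`, `unique_peptide_count`, `min_peptide_length`,
#'   `intensity`, `fdr_pass`.
#' @param fraction_label one of `"myotube"`, `"gfp_neg"`, `"percoll_sc"`,
#'   `"gfp_pos"`.
#' @return A data.frame of class `fraction_proteome` with the fraction label
#'   attached as an attribute.
#' @examples
#' fp <- fraction_proteome(data.frame(
#'   protein_id = "P1", gene_symbol = "Pax7", peptide_count = 10L,
#'   unique_peptide_count = 3L, min_peptide_length = 7L,
#'   intensity = 1e8, fdr_pass = TRUE), "gfp_pos")
#' @export
fraction_proteome <- function(records, fraction_label) {
  fraction_label <- match.arg(fraction_label, FRACTION_LABELS)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PROTEOME_COLUMNS, names(records))
  if (length(missing_cols))
    schema_error(paste0("fraction table is missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 columns = missing_cols)
  records <- records[PROTEOME_COLUMNS]
  records$protein_id <- as.character(records$protein_id)
  records$gene_symbol <- as.character(records$gene_symbol)
  records$fdr_pass <- as.logical(records$fdr_pass)
  if (anyDuplicated(records$protein_id))
    data_error(sprintf("duplicated protein_id within fraction '%s': %s",
                       fraction_label,
                       paste(unique(records$protein_id[
                         duplicated(records$protein_id)]), collapse = ", ")))
  bad <- which(records$unique_peptide_count > records$peptide_count)
  if (length(bad))
    data_error(sprintf(
      "unique_peptide_count exceeds peptide_count for %d record(s), first at row %d",
      length(bad), bad[1]))
  if (any(records$intensity < 0, na.rm = TRUE))
    data_error("negative intensities are not allowed")
  if (any(records$min_peptide_length < 1 & records$peptide_count > 0))
    data_error("min_peptide_length must be >= 1 for identified proteins")
  structure(records,
            fraction_label = fraction_label,
            class = c("fraction_proteome", "data.frame"))
}

#' @export
print.fraction_proteome <- function(x, ...) {
  cat(sprintf("<fraction_proteome '%s': %d protein group(s)>\n",
              attr(x, "fraction_label"), nrow(x)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more row(s)\n", nrow(x) - 6L))
  invisible(x)
}

fraction_label <- function(x) attr(x, "fraction_label")

#' Average replicate fraction tables into one summarized table
#'
#' Mass-spectrometry fractions are typically measured in replicate (n = 3
#' here); the enrichment logic operates on one summarized intensity per
#' fraction. Replicates are combined per protein: intensities with
#' `summarizer` (absence counted as intensity 0), peptide counts with the
#' maximum over replicates, and `fdr_pass` with "passes in at least one
#' replicate".
#'
#' @param replicates list of `fraction_proteome` objects with a common
#'   fraction label.
#' @param summarizer function reducing a numeric vector of per-replicate
#'   intensities to one value; the default is `mean`.
#' @return A single summarized `fraction_proteome`.
#' @export
summarize_replicates <- function(replicates, summarizer = mean) {
  if (!length(replicates)) param_error("no replicate tables supplied")
  labels <- unique(vapply(replicates, fraction_label, character(1)))
  if (length(labels) != 1L)
    param_error(paste0("replicates must share one fraction label, got: ",
                       paste(labels, collapse = ", ")))
  if (length(replicates) == 1L) return(replicates[[1]])
  ids <- unique(unlist(lapply(replicates, `[[`, "protein_id")))
  n_rep <- length(replicates)
  intensity <- matrix(0, nrow = length(ids), ncol = n_rep,
                      dimnames = list(ids, NULL))
  out <- data.frame(protein_id = ids, gene_symbol = NA_character_,
                    peptide_count = 0L, unique_peptide_count = 0L,
                    min_peptide_length = NA_integer_, intensity = 0,
                    fdr_pass = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- ids
  for (k in seq_len(n_rep)) {
    r <- replicates[[k]]
    i <- r$protein_id
    intensity[i, k] <- r$intensity
    out[i, "gene_symbol"] <- r$gene_symbol
    out[i, "peptide_count"] <- pmax(out[i, "peptide_count"], r$peptide_count)
    out[i, "unique_peptide_count"] <-
      pmax(out[i, "unique_peptide_count"], r$unique_peptide_count)
    out[i, "min_peptide_length"] <-
      pmin(out[i, "min_peptide_length"], r$min_peptide_length, na.rm = TRUE)
    out[i, "fdr_pass"] <- out[i, "fdr_pass"] | r$fdr_pass
  }
  out$intensity <- apply(intensity, 1L, summarizer)
  rownames(out) <- NULL
  fraction_proteome(out, labels)
}

#' Identification-confidence filter
#'
#' Keeps only protein groups that survive the search-engine identification
#' criteria: a passing 1% FDR flag, shortest contributing peptide of at
#' least `min_len` amino acids, and at least `min_unique` unique peptides.
#' Row order is preserved. The FDR is consumed as a boolean computed
#' upstream by the search engine; it is not re-estimated here.
#'
#' @param table a `fraction_proteome`.
#' @param min_len minimum peptide length in amino acids (default 6).
#' @param min_unique minimum number of unique peptides (default 1).
#' @return The filtered `fraction_proteome`.
#' @export
filter_identifications <- function(table, min_len = 6L, min_unique = 1L) {
  if (!inherits(table, "fraction_proteome"))
    param_error("`table` must be a fraction_proteome")
  if (!is_count(min_len, min = 1))
    param_error("`min_len` must be a single integer >= 1")
  if (!is_count(min_unique, min = 0))
    param_error("`min_unique` must be a single non-negative integer")
  keep <- table$fdr_pass &
    table$min_peptide_length >= min_len &
    table$unique_peptide_count >= min_unique
  keep[is.na(keep)] <- FALSE
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, fraction_label = fraction_label(table),
            class = c("fraction_proteome", "data.frame"))
}

#' Subtract one fraction's protein set from another
#'
#' Returns the protein groups identified in `target` but not in
#' `background`, matched on `protein_id` (not gene symbol: one gene may
#' yield several protein groups). An empty background returns the full
#' target set.
#'
#' @param target,background filtered `fraction_proteome` tables.
#' @return Character vector of protein ids, in target order.
#' @export
subtract_fraction <- function(target, background) {
  if (!inherits(target, "fraction_proteome") ||
      !inherits(background, "fraction_proteome"))
    param_error("`target` and `background` must be fraction_proteome objects")
  target$protein_id[!(target$protein_id %in% background$protein_id)]
}

#' Intensity gate against a reference fraction
#'
#' Keeps a candidate protein only if its label-free intensity in the target
#' fraction is strictly higher than in the reference fraction. A protein
#' absent from the reference has reference intensity 0, so it is kept iff
#' its target intensity is positive; ties drop the protein.
#'
#' @param candidates character vector of protein ids, a subset of the
#'   target's protein set.
#' @param target `fraction_proteome` the candidates come from.
#' @param reference `fraction_proteome` to gate against (e.g. myotubes).
#' @return Character vector of retained protein ids, in candidate order.
#' @export
intensity_gate <- function(candidates, target, reference) {
  if (!inherits(target, "fraction_proteome") ||
      !inherits(reference, "fraction_proteome"))
    param_error("`target` and `reference` must be fraction_proteome objects")
  candidates <- as.character(candidates)
  missing <- setdiff(candidates, target$protein_id)
  if (length(missing))
    data_error(paste0("candidate protein(s) missing from target fraction: ",
                      paste(utils::head(missing, 5L), collapse = ", ")),
               missing = missing)
  t_int <- setNames(target$intensity, target$protein_id)[candidates]
  r_int <- setNames(reference$intensity, reference$protein_id)[candidates]
  r_int[is.na(r_int)] <- 0
  candidates[t_int > r_int]
}

#' Derive the muscle-stem-cell-specific proteome
#'
#' Full enrichment composition: identification filtering of all three
#' fractions, subtraction of every protein identified in the GFP- fraction
#' from the GFP+ fraction, and an intensity gate keeping proteins whose
#' GFP+ intensity strictly exceeds their myotube intensity. The retained
#' list is ordered by `ranking_mode`: descending GFP+ intensity
#' (`"intensity"`), descending total peptide count (`"peptide_sum"`), or
#' original table order (`"presence"`).
#'
#' @param gfp_pos,gfp_neg,myotube `fraction_proteome` tables for the three
#'   populations entering the gates.
#' @param ranking_mode one of `"intensity"`, `"peptide_sum"`, `"presence"`.
#' @param min_len,min_unique identification thresholds, see
#'   [filter_identifications()].
#' @return An object of class `enrichment_result`: list with `retained`
#'   (ordered protein ids), `ranking_mode`, and `provenance`, a per-protein
#'   data.frame recording which gates each GFP+ protein passed.
#' @export
musc_specific_proteome <- function(gfp_pos, gfp_neg, myotube,
                                   ranking_mode = c("intensity",
                                                    "peptide_sum",
                                                    "presence"),
                                   min_len = 6L, min_unique = 1L) {
  ranking_mode <- match.arg(ranking_mode)
  pos_f <- filter_identifications(gfp_pos, min_len, min_unique)
  neg_f <- filter_identifications(gfp_neg, min_len, min_unique)
  myo_f <- filter_identifications(myotube, min_len, min_unique)

  after_sub <- subtract_fraction(pos_f, neg_f)
  retained <- intensity_gate(after_sub, pos_f, myo_f)

  prov <- data.frame(
    protein_id = gfp_pos$protein_id,
    gene_symbol = gfp_pos$gene_symbol,
    passed_identification = gfp_pos$protein_id %in% pos_f$protein_id,
    passed_subtraction = gfp_pos$protein_id %in% after_sub,
    passed_intensity_gate = gfp_pos$protein_id %in% retained,
    stringsAsFactors = FALSE
  )
  prov$retained <- prov$passed_intensity_gate

  ord <- switch(ranking_mode,
    intensity = {
      key <- setNames(pos_f$intensity, pos_f$protein_id)[retained]
      retained[order(-key, retained)]
    },
    peptide_sum = {
      key <- setNames(pos_f$peptide_count, pos_f$protein_id)[retained]
      retained[order(-key, retained)]
    },
    presence = retained   # original gfp_pos table order
  )

  structure(list(retained = ord, ranking_mode = ranking_mode,
                 provenance = prov),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result: %d retained protein(s), ranked by %s>\n",
              length(x$retained), x$ranking_mode))
  if (length(x$retained)) cat("top:", paste(utils::head(x$retained, 8L),
                                            collapse = ", "), "\n")
  invisible(x)
}
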