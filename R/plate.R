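# 384-well screen plate model: well roles, Pax7+/DAPI+ ratios, Z'-factor
# plate QC and empty-vector normalization.

WELL_ROLES <- c("sample", "empty_vector", "sh_pax7", "sh_nf1",
                "gfp_control", "blank")

PLATE_ROWS <- LETTERS[1:16]
PLATE_COLS <- 1:24

#' Default 384-well control layout
#'
#' Each plate carries 56 control wells: 12 GFP transduction controls
#' (monitor lentiviral transduction efficiency only; never enter ratio
#' statistics), 4 Pax7-knockdown and 4 Nf1-knockdown positive controls,
#' 4 empty-vector (plko.1) normalization wells, and 32 blank wells.
#'
#' @return Named integer vector of control-well counts per role.
#' @export
default_layout_spec <- function() {
  c(gfp_control = 12L, sh_pax7 = 4L, sh_nf1 = 4L, empty_vector = 4L,
    blank = 32L)
}

well_names <- function() {
  as.vector(t(outer(PLATE_ROWS, PLATE_COLS, paste0)))
}

#' Assemble and validate one 384-well screen plate
#'
#' @param wells data.frame with columns `plate_id`, `well` (e.g. `"A1"`..
#'   `"P24"`), `role` (one of `r paste(WELL_ROLES, collapse=", ")`),
#'   `shrna_id`, `gene` (NA outside sample/knockdown-control wells),
#'   `pax7_count`, `dapi_count`.
#' @param layout_spec named integer vector of expected control counts;
#'   `NULL` skips the layout check (partial plates).
#' @return The validated data.frame with class `screen_plate`.
#' @export
screen_plate <- function(wells, layout_spec = default_layout_spec()) {
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  req <- c("plate_id", "well", "role", "shrna_id", "gene",
           "pax7_count", "dapi_count")
  missing_cols <- setdiff(req, names(wells))
  if (length(missing_cols))
    schema_error(paste0("well table is missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 columns = missing_cols)
  wells <- wells[req]
  if (length(unique(wells$plate_id)) != 1L)
    data_error("a screen_plate holds exactly one plate_id")
  if (nrow(wells) != 384L)
    data_error(sprintf("plate '%s' has %d wells, expected 384",
                       wells$plate_id[1], nrow(wells)))
  if (anyDuplicated(wells$well))
    data_error(sprintf("plate '%s' has duplicated well coordinates",
                       wells$plate_id[1]))
  bad_coord <- setdiff(wells$well, well_names())
  if (length(bad_coord))
    data_error(paste0("invalid well coordinate(s): ",
                      paste(utils::head(bad_coord, 5L), collapse = ", ")))
  bad_role <- setdiff(unique(wells$role), WELL_ROLES)
  if (length(bad_role))
    schema_error(paste0("unknown well role(s): ",
                        paste(bad_role, collapse = ", "),
                        "; allowed: ", paste(WELL_ROLES, collapse = ", ")))
  over <- which(wells$pax7_count > wells$dapi_count)
  if (length(over))
    data_error(sprintf(
      "pax7_count exceeds dapi_count in %d well(s) of plate '%s', first at well %s",
      length(over), wells$plate_id[1], wells$well[over[1]]))
  if (any(wells$pax7_count < 0 | wells$dapi_count < 0, na.rm = TRUE))
    data_error("nucleus counts must be non-negative")
  no_id <- wells$role == "sample" &
    (is.na(wells$shrna_id) | is.na(wells$gene))
  if (any(no_id))
    data_error(sprintf("sample well(s) without shrna_id/gene on plate '%s'",
                       wells$plate_id[1]))
  if (!is.null(layout_spec)) {
    counts <- table(factor(wells$role, levels = WELL_ROLES))
    for (role in names(layout_spec)) {
      if (counts[[role]] != layout_spec[[role]])
        data_error(sprintf(
          "plate '%s': %d wells of role '%s', layout requires %d",
          wells$plate_id[1], counts[[role]], role, layout_spec[[role]]))
    }
  }
  rownames(wells) <- NULL
  structure(wells, layout_spec = layout_spec,
            class = c("screen_plate", "data.frame"))
}

#' @export
print.screen_plate <- function(x, ...) {
  cat(sprintf("<screen_plate '%s': %d sample wells, %d controls>\n",
              x$plate_id[1], sum(x$role == "sample"),
              sum(!x$role %in% c("sample", "blank"))))
  invisible(x)
}

#' Split a long-format well table into validated plates
#'
#' @param wells long-format well table covering one or more plates.
#' @inheritParams screen_plate
#' @return Named list of `screen_plate` objects, one per `plate_id`.
#' @export
as_plate_list <- function(wells, layout_spec = default_layout_spec()) {
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  lapply(split(wells, wells$plate_id), screen_plate,
         layout_spec = layout_spec)
}

#' Pax7+/DAPI+ well ratio
#'
#' The screen's phenotypic read-out: the fraction of all (DAPI-stained)
#' nuclei in a well that are Pax7-positive. Wells with no DAPI+ nuclei are
#' unmeasurable and yield `NA`; a Pax7 count exceeding the DAPI count is a
#' data error.
#'
#' @param pax7_count,dapi_count non-negative integer vectors.
#' @return Numeric vector of ratios in `[0, 1]`, `NA` where `dapi_count`
#'   is 0.
#' @export
well_ratio <- function(pax7_count, dapi_count) {
  if (any(pax7_count > dapi_count, na.rm = TRUE))
    data_error("pax7_count exceeds dapi_count")
  if (any(pax7_count < 0 | dapi_count < 0, na.rm = TRUE))
    data_error("nucleus counts must be non-negative")
  ifelse(dapi_count > 0, pax7_count / dapi_count, NA_real_)
}

#' Z'-factor of a control configuration
#'
#' Plate-level assay-quality statistic comparing positive- and
#' negative-control separation to their spreads:
#' `1 - (2*sd(pos) + 2*sd(neg)) / abs(mean(neg) - mean(pos))`.
#' The spread coefficient is 2 (not the conventional 3), matching the QC
#' rule this screen was processed with; sample standard deviations (n-1)
#' are used. The statistic is symmetric in its two arguments and never
#' exceeds 1, reaching 1 exactly when both groups have zero variance.
#'
#' @param pos_ratios,neg_ratios numeric vectors of control well ratios,
#'   at least 2 values each.
#' @return The Z' value, or `NA` when the group means coincide (zero
#'   separation, undefined).
#' @export
z_prime <- function(pos_ratios, neg_ratios) {
  if (length(pos_ratios) < 2L || length(neg_ratios) < 2L)
    param_error("z_prime needs at least 2 ratios per control group")
  sep <- abs(mean(neg_ratios) - mean(pos_ratios))
  if (sep == 0) return(NA_real_)
  1 - (2 * stats::sd(pos_ratios) + 2 * stats::sd(neg_ratios)) / sep
}

measurable_ratios <- function(plate, role, dapi_floor) {
  w <- plate[plate$role == role & plate$dapi_count >= max(1L, dapi_floor), ,
             drop = FALSE]
  well_ratio(w$pax7_count, w$dapi_count)
}

#' Z'-factor quality control for one plate
#'
#' Computes the Z' of the chosen positive-control knockdown wells against
#' the empty-vector negatives and gates the plate at `z_prime > gate`.
#' Pax7 knockdown is the default positive control because its directional
#' effect (loss of Pax7+ cells) is the documented one; the Nf1 control is
#' available via `positive_role`. Wells with fewer than `dapi_floor` DAPI+
#' nuclei are low-content failures and excluded from the control
#' statistics.
#'
#' @param plate a `screen_plate`.
#' @param positive_role `"sh_pax7"` (default) or `"sh_nf1"`.
#' @param gate pass threshold on Z' (default 0.5).
#' @param dapi_floor minimum DAPI+ nuclei for a well to count (default 10).
#' @return A `plate_qc` object: list with `plate_id`, `mu_pos`, `mu_neg`,
#'   `sigma_pos`, `sigma_neg`, `z_prime`, `passed`, `reason`.
#' @export
plate_qc <- function(plate, positive_role = c("sh_pax7", "sh_nf1"),
                     gate = 0.5, dapi_floor = 10L) {
  positive_role <- match.arg(positive_role)
  if (!inherits(plate, "screen_plate"))
    param_error("`plate` must be a screen_plate")
  pos <- measurable_ratios(plate, positive_role, dapi_floor)
  neg <- measurable_ratios(plate, "empty_vector", dapi_floor)
  if (length(pos) < 2L || length(neg) < 2L)
    qc_error(sprintf(
      "plate '%s': need >=2 measurable %s and empty_vector wells (have %d and %d)",
      plate$plate_id[1], positive_role, length(pos), length(neg)))
  z <- z_prime(pos, neg)
  reason <- if (is.na(z)) "zero separation"
            else if (z > gate) NA_character_
            else "z_prime below gate"
  structure(list(plate_id = plate$plate_id[1],
                 positive_role = positive_role,
                 mu_pos = mean(pos), mu_neg = mean(neg),
                 sigma_pos = stats::sd(pos), sigma_neg = stats::sd(neg),
                 z_prime = z,
                 passed = !is.na(z) && z > gate,
                 reason = reason),
            class = "plate_qc")
}

#' @export
print.plate_qc <- function(x, ...) {
  cat(sprintf("<plate_qc '%s': Z' = %s vs %s -> %s>\n", x$plate_id,
              format(x$z_prime, digits = 4), x$positive_role,
              if (x$passed) "PASS" else paste0("FAIL (", x$reason, ")")))
  invisible(x)
}

#' Normalize sample-well scores to the plate's empty-vector controls
#'
#' Each measurable sample well's Pax7+/DAPI+ ratio `x` is divided by the
#' mean empty-vector ratio `mu_ref` of the same plate (n = 4 wells in the
#' default layout), so 1.0 means control-like. The `convention` switch
#' exposes alternative orientations of the printed normalization rule:
#' `"fold"` (default) reports `x/mu`, `"fold_minus_one"` reports
#' `x/mu - 1` (0 = control-like) and `"neg_fold"` reports `-x/mu`.
#'
#' @param plate a `screen_plate` that passed QC.
#' @param dapi_floor minimum DAPI+ nuclei for a well to be scored.
#' @param convention score orientation, see Details.
#' @return data.frame with one row per measurable sample well: `shrna_id`,
#'   `gene`, `plate_id`, `well`, `x` (raw ratio), `mu_ref`, `score`.
#'   Unmeasurable sample wells are recorded in attribute `"excluded"`.
#' @export
normalize_plate <- function(plate, dapi_floor = 10L,
                            convention = c("fold", "fold_minus_one",
                                           "neg_fold")) {
  convention <- match.arg(convention)
  if (!inherits(plate, "screen_plate"))
    param_error("`plate` must be a screen_plate")
  neg <- measurable_ratios(plate, "empty_vector", dapi_floor)
  if (!length(neg))
    qc_error(sprintf("plate '%s': no measurable empty-vector well",
                     plate$plate_id[1]))
  mu_ref <- mean(neg)
  if (mu_ref == 0)
    qc_error(sprintf("plate '%s': empty-vector mean ratio is 0",
                     plate$plate_id[1]))
  samples <- plate[plate$role == "sample", , drop = FALSE]
  measurable <- samples$dapi_count >= max(1L, dapi_floor)
  scored <- samples[measurable, , drop = FALSE]
  x <- well_ratio(scored$pax7_count, scored$dapi_count)
  score <- switch(convention,
                  fold = x / mu_ref,
                  fold_minus_one = x / mu_ref - 1,
                  neg_fold = -x / mu_ref)
  out <- data.frame(shrna_id = scored$shrna_id, gene = scored$gene,
                    plate_id = scored$plate_id, well = scored$well,
                    x = x, mu_ref = mu_ref, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- samples$well[!measurable]
  attr(out, "convention") <- convention
  out
}
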