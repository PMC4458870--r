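# Seeded synthetic-data generators: arrayed knockdown screens and
# four-fraction proteome tables carrying planted ground truth, plus
# recovery metrics against that truth.

#' Configuration for a synthetic arrayed knockdown screen
#'
#' The generated world mirrors the screen it emulates: 384-well plates
#' with 56 control wells each (12 GFP transduction controls, 4 Pax7 and 4
#' Nf1 knockdown positive controls, 4 empty-vector normalization wells,
#' 32 blanks), one shRNA per well with on average five constructs per gene
#' across ~400 genes, and 450 seeded cells per well.
#'
#' The count model: the DAPI+ nucleus count of a well is Poisson around
#' `cells_per_well` (negative-binomial when `dispersion > 0`), and the
#' Pax7+ count is a binomial thinning of it with success probability
#' `baseline_pax7_fraction`, multiplied by the planted effect for UP/DOWN
#' genes and by the knockdown-control effects for sh_pax7/sh_nf1 wells.
#' `noise = "none"` replaces both draws by their rounded expectations,
#' giving a deterministic screen for exact-recovery tests.
#'
#' @param n_genes number of targeted genes (default 400).
#' @param shrnas_per_gene constructs per gene (default 5).
#' @param baseline_pax7_fraction Pax7+ fraction of a control-like well
#'   (default 0.5, a proliferating culture roughly half Pax7+).
#' @param effect_up,effect_down multiplicative shifts on the Pax7 fraction
#'   of planted effect genes (defaults 1.6 and 0.4).
#' @param n_up,n_down planted effect-gene counts (defaults 0, 0).
#' @param cells_per_well expected DAPI+ count (default 450).
#' @param dispersion negative-binomial excess dispersion; 0 gives Poisson.
#' @param noise `"poisson"` (count noise, default) or `"none"`
#'   (deterministic expectations).
#' @param sh_pax7_effect,sh_nf1_effect multiplicative Pax7-fraction effects
#'   of the knockdown control wells (defaults 0.1 and 1.5: Pax7 knockdown
#'   depletes Pax7+ cells, Nf1 knockdown increases them).
#' @param plate_effect_sd sd of an optional log-normal per-plate multiplier
#'   on the Pax7 fraction (default 0, no plate effects).
#' @param shuffle permute shRNAs across sample wells (default TRUE);
#'   `FALSE` fills plates gene-contiguously, making plate effects
#'   confoundable for QC testing.
#' @param seed mandatory integer seed.
#' @return Validated list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 400L, shrnas_per_gene = 5L,
                              baseline_pax7_fraction = 0.5,
                              effect_up = 1.6, effect_down = 0.4,
                              n_up = 0L, n_down = 0L,
                              cells_per_well = 450L, dispersion = 0,
                              noise = c("poisson", "none"),
                              sh_pax7_effect = 0.1, sh_nf1_effect = 1.5,
                              plate_effect_sd = 0, shuffle = TRUE,
                              seed) {
  noise <- match.arg(noise)
  if (missing(seed) || is.null(seed))
    param_error("`seed` is mandatory for the screen generator")
  stopifnot_scalar_prob(baseline_pax7_fraction, "baseline_pax7_fraction")
  if (!is_count(n_genes, 1) || !is_count(shrnas_per_gene, 1))
    param_error("`n_genes` and `shrnas_per_gene` must be positive integers")
  if (!is_count(n_up) || !is_count(n_down) || n_up + n_down > n_genes)
    param_error("`n_up` + `n_down` must not exceed `n_genes`")
  if (dispersion < 0) param_error("`dispersion` must be >= 0")
  p_values <- baseline_pax7_fraction *
    c(1, effect_up, effect_down, sh_pax7_effect, sh_nf1_effect)
  if (any(p_values <= 0 | p_values >= 1))
    param_error(paste0("infeasible Pax7 fraction: baseline times each ",
                       "effect must stay inside (0, 1)"))
  structure(list(n_genes = as.integer(n_genes),
                 shrnas_per_gene = as.integer(shrnas_per_gene),
                 baseline_pax7_fraction = baseline_pax7_fraction,
                 effect_up = effect_up, effect_down = effect_down,
                 n_up = as.integer(n_up), n_down = as.integer(n_down),
                 cells_per_well = as.integer(cells_per_well),
                 dispersion = dispersion, noise = noise,
                 sh_pax7_effect = sh_pax7_effect,
                 sh_nf1_effect = sh_nf1_effect,
                 plate_effect_sd = plate_effect_sd,
                 shuffle = isTRUE(shuffle), seed = as.integer(seed)),
            class = c("screen_sim_config", "list"))
}

# Fixed control geometry: column 1 carries GFP and empty-vector controls,
# column 24 the knockdown controls, columns 2/23 (and the rest of 24) are
# blanks; the remaining 328 wells are sample wells.
control_layout <- function() {
  rows <- PLATE_ROWS
  layout <- data.frame(well = well_names(), role = "sample",
                       stringsAsFactors = FALSE)
  set_role <- function(layout, wells, role) {
    layout$role[layout$well %in% wells] <- role
    layout
  }
  layout <- set_role(layout, paste0(rows[1:12], 1), "gfp_control")
  layout <- set_role(layout, paste0(rows[13:16], 1), "empty_vector")
  layout <- set_role(layout, paste0(rows[1:4], 24), "sh_pax7")
  layout <- set_role(layout, paste0(rows[5:8], 24), "sh_nf1")
  layout <- set_role(layout, c(paste0(rows[9:16], 24), paste0(rows, 2),
                               paste0(rows[1:8], 23)), "blank")
  layout
}

#' Simulate an arrayed knockdown screen with planted truth
#'
#' Generates complete 384-well plates following the fixed control layout,
#' assigns shRNAs to sample wells (gene-contiguous fill, then a seeded
#' shuffle across all plates unless `shuffle = FALSE`), draws nucleus
#' counts from the configured noise model and returns both the plates and
#' the planted truth. Fully reproducible from `config$seed`.
#'
#' @param config a [screen_sim_config()].
#' @return list with `plates` (list of `screen_plate`), `truth` (class
#'   `synthetic_truth`: `up_genes`, `down_genes`, `shrna_table`) and
#'   `config`.
#' @export
simulate_screen <- function(config) {
  if (!inherits(config, "screen_sim_config"))
    param_error("`config` must be a screen_sim_config")
  with_seed(config$seed, {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    planted <- sample(genes, config$n_up + config$n_down)
    up_genes <- sort(utils::head(planted, config$n_up))
    down_genes <- sort(utils::tail(planted, config$n_down))

    shrna <- data.frame(
      shrna_id = sprintf("%s_sh%02d",
                         rep(genes, each = config$shrnas_per_gene),
                         rep(seq_len(config$shrnas_per_gene),
                             config$n_genes)),
      gene = rep(genes, each = config$shrnas_per_gene),
      stringsAsFactors = FALSE)
    shrna$effect <- 1
    shrna$effect[shrna$gene %in% up_genes] <- config$effect_up
    shrna$effect[shrna$gene %in% down_genes] <- config$effect_down

    layout <- control_layout()
    n_sample_slots <- sum(layout$role == "sample")      # 328
    n_plates <- ceiling(nrow(shrna) / n_sample_slots)
    # the library occupies the first n_shrna sample slots in plate order
    # (only the last plate is partially filled); shuffling permutes which
    # shRNA lands in which occupied slot
    slot_of <- if (config$shuffle) sample(nrow(shrna))
               else seq_len(nrow(shrna))

    wells <- do.call(rbind, lapply(seq_len(n_plates), function(i) {
      w <- layout
      w$plate_id <- sprintf("P%03d", i)
      w
    }))
    wells <- wells[, c("plate_id", "well", "role")]
    wells$shrna_id <- NA_character_
    wells$gene <- NA_character_
    wells$effect <- 1
    sample_rows <- which(wells$role == "sample")
    assigned <- sample_rows[seq_len(nrow(shrna))][slot_of]
    wells$shrna_id[assigned] <- shrna$shrna_id
    wells$gene[assigned] <- shrna$gene
    wells$effect[assigned] <- shrna$effect
    # sample slots left over on the last plate become blanks
    unfilled <- setdiff(sample_rows, assigned)
    wells$role[unfilled] <- "blank"

    wells$effect[wells$role == "sh_pax7"] <- config$sh_pax7_effect
    wells$effect[wells$role == "sh_nf1"] <- config$sh_nf1_effect

    p <- config$baseline_pax7_fraction * wells$effect
    if (config$plate_effect_sd > 0) {
      mult <- exp(rnorm(n_plates, 0, config$plate_effect_sd))
      p <- pmin(p * mult[as.integer(factor(wells$plate_id))], 0.999)
    }
    n <- nrow(wells)
    lambda <- ifelse(wells$role == "blank", 0, config$cells_per_well)
    if (config$noise == "none") {
      dapi <- as.integer(round(lambda))
      pax7 <- as.integer(round(p * dapi))
    } else {
      dapi <- if (config$dispersion > 0)
        rnbinom(n, mu = lambda, size = 1 / config$dispersion)
      else rpois(n, lambda)
      pax7 <- integer(n)
      nz <- dapi > 0
      pax7[nz] <- rbinom(sum(nz), dapi[nz], p[nz])
    }
    pax7[wells$role == "blank"] <- 0L
    wells$pax7_count <- as.integer(pax7)
    wells$dapi_count <- as.integer(dapi)
    wells$effect <- NULL

    plates <- lapply(split(wells, wells$plate_id), function(w) {
      counts <- table(factor(w$role, levels = WELL_ROLES))
      spec <- default_layout_spec()
      spec["blank"] <- counts[["blank"]]
      screen_plate(w, layout_spec = spec)
    })
    truth <- structure(list(up_genes = up_genes, down_genes = down_genes,
                            genes = genes, shrna_table = shrna),
                       class = "synthetic_truth")
    list(plates = plates, truth = truth, config = config)
  })
}

#' Simulate four-fraction proteome tables with planted specific proteins
#'
#' Generates MaxQuant-style protein-group tables for the four populations
#' (myotubes, GFP- mononuclear cells, percoll-gradient cells, GFP+ stem
#' cells). `n_specific` planted proteins are present only in the GFP+
#' fraction (and sometimes percoll) and pass every identification gate;
#' the remaining proteins are constructed so that none of them can survive
#' the full enrichment composition: they are either shared with the GFP-
#' fraction, out-gated by a strictly higher myotube intensity, failed by an
#' identification gate, or absent from the GFP+ fraction altogether.
#' Intensities are log-normal.
#'
#' @param n_proteins universe size (default 400).
#' @param n_specific planted stem-cell-specific proteins (default 25).
#' @param intensity_meanlog,intensity_sdlog log-normal intensity model
#'   (defaults `log(1e8)` and 1, typical label-free intensity scales).
#' @param seed mandatory integer seed.
#' @return list with `fractions` (named list of four `fraction_proteome`
#'   tables) and `truth` (`musc_specific_proteins` id set).
#' @export
simulate_proteome <- function(n_proteins = 400L, n_specific = 25L,
                              intensity_meanlog = log(1e8),
                              intensity_sdlog = 1, seed) {
  if (missing(seed) || is.null(seed))
    param_error("`seed` is mandatory for the proteome generator")
  if (!is_count(n_proteins, 1) || !is_count(n_specific, 0) ||
      n_specific > n_proteins)
    param_error("need 0 <= n_specific <= n_proteins")
  with_seed(seed, {
    ids <- sprintf("PG%05d", seq_len(n_proteins))
    genes <- sprintf("Gene%05d", seq_len(n_proteins))
    n_rest <- n_proteins - n_specific
    classes <- c(rep("specific", n_specific),
                 if (n_rest > 0) sample(c("shared", "myotube_enriched",
                                          "low_confidence", "non_musc"),
                                        n_rest, replace = TRUE,
                                        prob = c(0.5, 0.2, 0.1, 0.2)))
    rint <- function(n) stats::rlnorm(n, intensity_meanlog, intensity_sdlog)

    passing_evidence <- function(n) {
      peptides <- 2L + rpois(n, 5)
      data.frame(peptide_count = peptides,
                 unique_peptide_count = pmin(peptides, 1L + rpois(n, 1)),
                 min_peptide_length = sample(6:15, n, replace = TRUE),
                 fdr_pass = TRUE)
    }
    failing_evidence <- function(n) {
      # violate exactly one identification gate per record
      mode <- sample(c("short", "no_unique", "fdr"), n, replace = TRUE)
      ev <- passing_evidence(n)
      ev$min_peptide_length[mode == "short"] <-
        sample(3:5, sum(mode == "short"), replace = TRUE)
      ev$unique_peptide_count[mode == "no_unique"] <- 0L
      ev$fdr_pass[mode == "fdr"] <- FALSE
      ev
    }

    base_int <- rint(n_proteins)
    rows <- vector("list", length(FRACTION_LABELS))
    names(rows) <- FRACTION_LABELS
    present <- matrix(FALSE, n_proteins, 4,
                      dimnames = list(ids, FRACTION_LABELS))
    present[classes == "specific", "gfp_pos"] <- TRUE
    present[classes == "specific", "percoll_sc"] <-
      stats::runif(n_specific) < 0.5
    sh <- classes == "shared"
    present[sh, "gfp_pos"] <- TRUE
    present[sh, "gfp_neg"] <- TRUE
    present[sh, "myotube"] <- stats::runif(sum(sh)) < 0.6
    present[sh, "percoll_sc"] <- stats::runif(sum(sh)) < 0.6
    me <- classes == "myotube_enriched"
    present[me, "gfp_pos"] <- TRUE
    present[me, "myotube"] <- TRUE
    lc <- classes == "low_confidence"
    present[lc, "gfp_pos"] <- TRUE
    nm <- classes == "non_musc"
    present[nm, "gfp_neg"] <- stats::runif(sum(nm)) < 0.7
    present[nm, "myotube"] <- stats::runif(sum(nm)) < 0.7
    present[nm, "percoll_sc"] <- stats::runif(sum(nm)) < 0.3
    none <- nm & rowSums(present) == 0
    present[none, "gfp_neg"] <- TRUE

    fractions <- lapply(FRACTION_LABELS, function(label) {
      idx <- which(present[, label])
      n <- length(idx)
      intensity <- base_int[idx] * stats::rlnorm(n, 0, 0.3)
      # out-gated class: myotube intensity strictly above the GFP+ one
      if (label == "myotube") {
        bump <- classes[idx] == "myotube_enriched"
        intensity[bump] <- base_int[idx][bump] * stats::runif(sum(bump), 1.5, 4)
      }
      # GFP+ intensity pinned at the base draw so the myotube bump above is
      # strictly higher and the gate decision is deterministic
      if (label == "gfp_pos") intensity <- base_int[idx]
      ev <- passing_evidence(n)
      if (label == "gfp_pos") {
        fail <- classes[idx] == "low_confidence"
        if (any(fail)) ev[fail, ] <- failing_evidence(sum(fail))
      }
      fraction_proteome(cbind(
        data.frame(protein_id = ids[idx], gene_symbol = genes[idx],
                   stringsAsFactors = FALSE),
        ev["peptide_count"], ev["unique_peptide_count"],
        ev["min_peptide_length"],
        data.frame(intensity = intensity), ev["fdr_pass"]), label)
    })
    names(fractions) <- FRACTION_LABELS
    list(fractions = fractions,
         truth = structure(list(
           musc_specific_proteins = ids[classes == "specific"],
           classes = setNames(classes, ids)),
           class = "synthetic_truth"))
  })
}

confusion_counts <- function(called, truth, universe) {
  tp <- length(intersect(called, truth))
  data.frame(n_true = length(truth), n_called = length(called),
             tp = tp, fp = length(called) - tp, fn = length(truth) - tp,
             sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
             false_discoveries = length(setdiff(called, truth)))
}

#' Recovery metrics against planted truth
#'
#' Standard confusion counts of a call set against the generator's planted
#' truth, overall and per direction. `called` and `truth` are lists with
#' elements `up` and `down` (either may be empty); for proteome recovery,
#' pass single-set lists like `list(up = retained_ids)` against
#' `list(up = truth_ids)`.
#'
#' @param called list with character vectors `up` and/or `down`.
#' @param truth list with the matching planted sets.
#' @param universe character vector of all genes/proteins in play; calls or
#'   truth outside it raise an error.
#' @return list with `per_direction` (data.frame of confusion counts) and
#'   `overall` (pooled sensitivity and false discoveries).
#' @export
recovery_metrics <- function(called, truth, universe) {
  dirs <- union(names(called), names(truth))
  if (!length(dirs)) param_error("`called`/`truth` carry no direction sets")
  all_members <- unique(c(unlist(called), unlist(truth)))
  outside <- setdiff(all_members, universe)
  if (length(outside))
    data_error(paste0("call/truth members outside the universe: ",
                      paste(utils::head(outside, 5L), collapse = ", ")))
  per_dir <- do.call(rbind, lapply(dirs, function(d) {
    cbind(data.frame(direction = d, stringsAsFactors = FALSE),
          confusion_counts(called[[d]] %||% character(),
                           truth[[d]] %||% character(), universe))
  }))
  pooled_called <- unlist(called) %||% character()
  pooled_truth <- unlist(truth) %||% character()
  overall <- confusion_counts(unique(pooled_called), unique(pooled_truth),
                              universe)
  list(per_direction = per_dir, overall = overall)
}
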