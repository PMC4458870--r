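# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Minimal protein record data.frame; defaults pass every identification gate.
protein_rows <- function(ids, intensity = 100, peptide_count = 8L,
                         unique_peptide_count = 2L, min_peptide_length = 9L,
                         fdr_pass = TRUE, gene_symbol = NULL) {
  n <- length(ids)
  data.frame(protein_id = ids,
             gene_symbol = gene_symbol %||%
               if (n) paste0("gene_", ids) else character(0),
             peptide_count = rep_len(peptide_count, n),
             unique_peptide_count = rep_len(unique_peptide_count, n),
             min_peptide_length = rep_len(min_peptide_length, n),
             intensity = rep_len(intensity, n),
             fdr_pass = rep_len(fdr_pass, n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_fraction <- function(ids, label, ...) {
  fraction_proteome(protein_rows(ids, ...), label)
}

# A fully valid 384-well plate with prescribed control ratios. Control and
# sample counts are exact (dapi fixed), so expected statistics are easy to
# compute by hand in tests.
make_plate <- function(plate_id = "P001", sample_p = 0.5, ev_p = 0.5,
                       pax7_p = 0.05, nf1_p = 0.75, dapi = 400L,
                       gene_of = NULL) {
  layout <- muscscreen:::control_layout()
  w <- data.frame(plate_id = plate_id, well = layout$well,
                  role = layout$role, stringsAsFactors = FALSE)
  w$shrna_id <- NA_character_
  w$gene <- NA_character_
  is_sample <- w$role == "sample"
  n_s <- sum(is_sample)
  w$shrna_id[is_sample] <- sprintf("sh%04d", seq_len(n_s))
  w$gene[is_sample] <- if (is.null(gene_of))
    sprintf("G%03d", rep(seq_len(ceiling(n_s / 4)), each = 4)[seq_len(n_s)])
  else gene_of
  p <- rep(0, nrow(w))
  p[is_sample] <- rep_len(sample_p, n_s)
  p[w$role == "empty_vector"] <- ev_p
  p[w$role == "sh_pax7"] <- pax7_p
  p[w$role == "sh_nf1"] <- nf1_p
  p[w$role == "gfp_control"] <- ev_p
  w$dapi_count <- ifelse(w$role == "blank", 0L, dapi)
  w$pax7_count <- as.integer(round(p * w$dapi_count))
  screen_plate(w)
}

# Independent quantile oracle: sort + linear interpolation between order
# statistics, written from the definition (not via stats::quantile).
quantile_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
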