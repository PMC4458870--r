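test_that("identification filter applies each gate and preserves order", {
  tab <- make_fraction(sprintf("p%02d", 1:10), "gfp_pos")
  tab$min_peptide_length[2] <- 5L   # too-short peptide
  tab$unique_peptide_count[5] <- 0L # no unique peptide
  tab$fdr_pass[9] <- FALSE          # fails 1% FDR
  out <- filter_identifications(tab)
  expect_equal(out$protein_id, sprintf("p%02d", setdiff(1:10, c(2, 5, 9))))

  # boundary: length exactly 6 passes, 5 drops; unique 0 drops
  edge <- make_fraction(c("a", "b", "c"), "gfp_pos")
  edge$min_peptide_length <- c(5L, 6L, 7L)
  expect_equal(filter_identifications(edge)$protein_id, c("b", "c"))
  edge$min_peptide_length <- 6L
  edge$unique_peptide_count <- c(0L, 1L, 2L)
  expect_equal(filter_identifications(edge)$protein_id, c("b", "c"))

  expect_error(filter_identifications(edge, min_len = -1),
               class = "msc_param_error")
  expect_error(filter_identifications(edge, min_unique = -1),
               class = "msc_param_error")
  # empty table is not an error
  expect_equal(nrow(filter_identifications(edge[0, ])), 0L)
})

test_that("filter matches brute-force per-record re-check on random tables", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    tab <- make_fraction(sprintf("p%03d", seq_len(n)), "gfp_pos")
    tab$min_peptide_length <- sample(4:9, n, replace = TRUE)
    tab$unique_peptide_count <- sample(0:3, n, replace = TRUE)
    tab$fdr_pass <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.8, .2))
    out <- filter_identifications(tab)$protein_id
    oracle <- character()
    for (i in seq_len(n)) {  # one gate at a time, re-derived from scratch
      ok <- tab$fdr_pass[i]
      ok <- ok && tab$min_peptide_length[i] >= 6
      ok <- ok && tab$unique_peptide_count[i] >= 1
      if (ok) oracle <- c(oracle, tab$protein_id[i])
    }
    expect_identical(out, oracle)
  }
})

test_that("filter is monotone in its thresholds", {
  set.seed(11)
  tab <- make_fraction(sprintf("p%03d", 1:80), "gfp_pos")
  tab$min_peptide_length <- sample(4:12, 80, replace = TRUE)
  tab$unique_peptide_count <- sample(0:4, 80, replace = TRUE)
  for (ml in 1:10) for (mu in 0:3) {
    a <- filter_identifications(tab, ml, mu)$protein_id
    expect_true(all(filter_identifications(tab, ml + 1, mu)$protein_id %in% a))
    expect_true(all(filter_identifications(tab, ml, mu + 1)$protein_id %in% a))
  }
})

test_that("fraction subtraction is an id-level set difference", {
  t1 <- make_fraction(c("A", "B", "C"), "gfp_pos")
  b1 <- make_fraction("B", "gfp_neg")
  expect_equal(subtract_fraction(t1, b1), c("A", "C"))
  expect_equal(subtract_fraction(make_fraction("A", "gfp_pos"),
                                 make_fraction("A", "gfp_neg")), character())
  expect_equal(subtract_fraction(t1, make_fraction(character(), "gfp_neg")),
               c("A", "B", "C"))

  set.seed(7)
  ids <- sprintf("pr%04d", 1:200)
  target <- make_fraction(ids, "gfp_pos")
  background <- make_fraction(sample(ids, 120), "gfp_neg")
  got <- subtract_fraction(target, background)
  oracle <- character()   # naive double loop
  for (p in target$protein_id) {
    found <- FALSE
    for (q in background$protein_id) if (identical(p, q)) found <- TRUE
    if (!found) oracle <- c(oracle, p)
  }
  expect_identical(got, oracle)
})

test_that("intensity gate is strict and treats absence as zero", {
  target <- make_fraction(c("hi", "lo", "tie", "only"), "gfp_pos",
                          intensity = c(100, 10, 50, 30))
  ref <- make_fraction(c("hi", "lo", "tie"), "myotube",
                       intensity = c(50, 20, 50))
  expect_equal(intensity_gate(c("hi", "lo", "tie", "only"), target, ref),
               c("hi", "only"))
  # zero target intensity on an absent-reference protein drops it
  z <- make_fraction("only", "gfp_pos", intensity = 0)
  expect_equal(intensity_gate("only", z, ref), character())
  expect_error(intensity_gate("ghost", target, ref),
               class = "msc_data_error")
})

test_that("full enrichment equals exhaustive per-protein gate evaluation", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(50:500, 1)
    ids <- sprintf("u%04d", seq_len(n))
    mk <- function(label) {
      keep <- runif(n) < 0.6
      tab <- protein_rows(ids[keep],
                          intensity = round(runif(sum(keep), 0, 1000)))
      tab$min_peptide_length <- sample(4:9, sum(keep), replace = TRUE)
      tab$unique_peptide_count <- sample(0:3, sum(keep), replace = TRUE)
      tab$fdr_pass <- runif(sum(keep)) < 0.9
      fraction_proteome(tab, label)
    }
    pos <- mk("gfp_pos"); neg <- mk("gfp_neg"); myo <- mk("myotube")
    got <- musc_specific_proteome(pos, neg, myo, "presence")$retained

    # oracle: evaluate every gate per protein, straight from the rules
    lookup <- function(tab, id, col) {
      i <- match(id, tab$protein_id)
      if (is.na(i)) NA else tab[[col]][i]
    }
    survives <- function(tab, id) {
      i <- match(id, tab$protein_id)
      !is.na(i) && tab$fdr_pass[i] && tab$min_peptide_length[i] >= 6 &&
        tab$unique_peptide_count[i] >= 1
    }
    oracle <- character()
    for (id in pos$protein_id) {
      if (!survives(pos, id)) next
      if (survives(neg, id)) next
      myo_int <- if (survives(myo, id)) lookup(myo, id, "intensity") else 0
      if (lookup(pos, id, "intensity") > myo_int) oracle <- c(oracle, id)
    }
    expect_identical(got, oracle)

    # structural invariants on every run
    expect_true(all(got %in% pos$protein_id))
    expect_length(intersect(got, filter_identifications(neg)$protein_id), 0)
  }
})

test_that("enrichment ranking modes order the retained list as declared", {
  pos <- make_fraction(c("a", "b", "c", "d"), "gfp_pos",
                       intensity = c(10, 40, 20, 30),
                       peptide_count = c(9L, 2L, 5L, 7L))
  neg <- make_fraction(character(), "gfp_neg")
  myo <- make_fraction(character(), "myotube")
  expect_equal(musc_specific_proteome(pos, neg, myo, "intensity")$retained,
               c("b", "d", "c", "a"))
  expect_equal(musc_specific_proteome(pos, neg, myo, "peptide_sum")$retained,
               c("a", "d", "c", "b"))
  expect_equal(musc_specific_proteome(pos, neg, myo, "presence")$retained,
               c("a", "b", "c", "d"))
  expect_error(musc_specific_proteome(pos, neg, myo, "zscore"))
})

test_that("enrichment is idempotent and empty on identical fractions", {
  sim <- simulate_proteome(n_proteins = 120, n_specific = 12, seed = 5)
  fr <- sim$fractions
  r1 <- musc_specific_proteome(fr$gfp_pos, fr$gfp_neg, fr$myotube)
  # re-run on the restricted universe: same retained set
  sub <- function(tab) {
    keep <- tab$protein_id %in% r1$retained
    fraction_proteome(as.data.frame(tab)[keep, ], fraction_label =
                        attr(tab, "fraction_label"))
  }
  r2 <- musc_specific_proteome(sub(fr$gfp_pos), sub(fr$gfp_neg),
                               sub(fr$myotube))
  expect_setequal(r2$retained, r1$retained)

  same <- musc_specific_proteome(fr$gfp_pos, fr$gfp_pos, fr$myotube)
  expect_length(same$retained, 0)
})

test_that("replicate summarizer averages intensities and unions evidence", {
  r1 <- make_fraction(c("a", "b"), "gfp_pos", intensity = c(100, 30))
  r2 <- make_fraction(c("a", "c"), "gfp_pos", intensity = c(50, 80))
  r3 <- make_fraction("a", "gfp_pos", intensity = 60)
  out <- summarize_replicates(list(r1, r2, r3))
  expect_equal(out$intensity[out$protein_id == "a"], (100 + 50 + 60) / 3)
  expect_equal(out$intensity[out$protein_id == "b"], 10)   # absence = 0
  med <- summarize_replicates(list(r1, r2, r3), summarizer = stats::median)
  expect_equal(med$intensity[med$protein_id == "a"], 60)
  expect_error(summarize_replicates(list(r1, make_fraction("x", "myotube"))),
               class = "msc_param_error")
})

test_that("fraction table validation catches inconsistent records", {
  bad <- protein_rows(c("a", "a"))
  expect_error(fraction_proteome(bad, "gfp_pos"), class = "msc_data_error")
  bad2 <- protein_rows("a")
  bad2$unique_peptide_count <- 99L
  expect_error(fraction_proteome(bad2, "gfp_pos"), class = "msc_data_error")
  bad3 <- protein_rows("a", intensity = -5)
  expect_error(fraction_proteome(bad3, "gfp_pos"), class = "msc_data_error")
  expect_error(fraction_proteome(protein_rows("a"), "mystery"))
})
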