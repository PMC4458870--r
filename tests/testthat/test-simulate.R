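test_that("screen generator is byte-identical under a fixed seed", {
  cfg <- screen_sim_config(n_genes = 40, n_up = 3, n_down = 5, seed = 123)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(lapply(a$plates, as.data.frame),
                   lapply(b$plates, as.data.frame))
  expect_identical(a$truth$up_genes, b$truth$up_genes)
  c_ <- simulate_screen(screen_sim_config(n_genes = 40, n_up = 3,
                                          n_down = 5, seed = 124))
  expect_false(identical(lapply(a$plates, as.data.frame),
                         lapply(c_$plates, as.data.frame)))
})

test_that("generated plates respect the documented control layout", {
  sim <- simulate_screen(screen_sim_config(n_genes = 100, seed = 2))
  plate <- as.data.frame(sim$plates[[1]])
  counts <- table(plate$role)
  expect_equal(unname(counts[["gfp_control"]]), 12)
  expect_equal(unname(counts[["sh_pax7"]]), 4)
  expect_equal(unname(counts[["sh_nf1"]]), 4)
  expect_equal(unname(counts[["empty_vector"]]), 4)
  # 56 control wells in total (including blanks), 328 samples on full plates
  expect_equal(unname(counts[["blank"]]), 32)
  expect_equal(unname(counts[["sample"]]), 328)
  # every shRNA appears exactly once across the screen
  all_wells <- do.call(rbind, lapply(sim$plates, as.data.frame))
  ids <- all_wells$shrna_id[!is.na(all_wells$shrna_id)]
  expect_equal(length(ids), 500)
  expect_false(anyDuplicated(ids) > 0)
})

test_that("null construction: no-effect sample wells look like empty vector", {
  sim <- simulate_screen(screen_sim_config(n_genes = 200, seed = 55))
  wells <- do.call(rbind, lapply(sim$plates, as.data.frame))
  s <- wells[wells$role == "sample", ]
  e <- wells[wells$role == "empty_vector", ]
  # pooled rank test over one seeded screen; under the null construction
  # the two groups share one distribution
  p <- stats::wilcox.test(s$pax7_count / s$dapi_count,
                          e$pax7_count / e$dapi_count)$p.value
  expect_gt(p, 1e-4)
  # deterministic expectations at zero noise
  det <- simulate_screen(screen_sim_config(n_genes = 20, noise = "none",
                                           seed = 1))
  w <- as.data.frame(det$plates[[1]])
  expect_true(all(w$dapi_count[w$role != "blank"] == 450))
  expect_true(all(w$pax7_count[w$role == "sample"] == 225))
})

test_that("planted DOWN shRNAs at strong effect all fall below the low cut", {
  sim <- simulate_screen(screen_sim_config(n_genes = 100, n_down = 5,
                                           effect_down = 0.2,
                                           noise = "none", seed = 9))
  res <- screen_hits(sim$plates, run_config())
  down_scores <- res$scores[res$scores$gene %in% sim$truth$down_genes, ]
  expect_true(all(down_scores$score < res$report$cuts[["low"]]))
  expect_true(all(down_scores$direction == "DOWN"))
})

test_that("infeasible effect sizes are a config error", {
  expect_error(screen_sim_config(baseline_pax7_fraction = 0.5,
                                 effect_up = 2.5, seed = 1),
               class = "msc_param_error")
  expect_error(screen_sim_config(effect_down = 0, seed = 1),
               class = "msc_param_error")
  expect_error(screen_sim_config(n_genes = 10, n_up = 6, n_down = 6,
                                 seed = 1), class = "msc_param_error")
  expect_error(simulate_screen(list()), class = "msc_param_error")
})

test_that("planted truth sets are disjoint and sensitivity grows with effect", {
  cfg <- function(eff, seed = 77) screen_sim_config(
    n_genes = 100, n_up = 0, n_down = 15, effect_down = eff, seed = seed)
  sens <- vapply(c(0.85, 0.55, 0.25), function(eff) {
    sim <- simulate_screen(cfg(eff))
    expect_length(intersect(sim$truth$up_genes, sim$truth$down_genes), 0)
    res <- screen_hits(sim$plates, run_config())
    m <- recovery_metrics(list(down = res$down_genes),
                          list(down = sim$truth$down_genes),
                          sim$truth$genes)
    m$per_direction$sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))   # stronger knockdown, better recovery
  expect_equal(sens[3], 1)
})

test_that("proteome generator plants exactly the specific set", {
  sim <- simulate_proteome(n_proteins = 400, n_specific = 25, seed = 4)
  expect_length(sim$truth$musc_specific_proteins, 25)
  r <- musc_specific_proteome(sim$fractions$gfp_pos, sim$fractions$gfp_neg,
                              sim$fractions$myotube)
  expect_setequal(r$retained, sim$truth$musc_specific_proteins)

  none <- simulate_proteome(n_proteins = 100, n_specific = 0, seed = 4)
  r0 <- musc_specific_proteome(none$fractions$gfp_pos,
                               none$fractions$gfp_neg,
                               none$fractions$myotube)
  expect_length(r0$retained, 0)

  again <- simulate_proteome(n_proteins = 400, n_specific = 25, seed = 4)
  expect_identical(lapply(sim$fractions, as.data.frame),
                   lapply(again$fractions, as.data.frame))
})

test_that("recovery metrics equal a brute-force confusion count", {
  universe <- sprintf("g%03d", 1:50)
  truth <- list(up = universe[1:10], down = universe[11:25])
  called <- list(up = universe[c(1:7, 30:34)], down = universe[c(11:25)])
  m <- recovery_metrics(called, truth, universe)
  up <- m$per_direction[m$per_direction$direction == "up", ]
  expect_equal(up$tp, 7); expect_equal(up$fp, 5); expect_equal(up$fn, 3)
  expect_equal(up$sensitivity, 0.7)
  down <- m$per_direction[m$per_direction$direction == "down", ]
  expect_equal(down$sensitivity, 1)
  expect_equal(down$false_discoveries, 0)

  perfect <- recovery_metrics(truth, truth, universe)
  expect_equal(perfect$overall$sensitivity, 1)
  expect_equal(perfect$overall$false_discoveries, 0)
  empty <- recovery_metrics(list(up = character()), truth, universe)
  expect_equal(empty$overall$sensitivity, 0)

  set.seed(66)
  for (i in 1:20) {  # randomized calls vs naive double-loop counting
    called <- list(up = sample(universe, sample(0:20, 1)))
    truth <- list(up = sample(universe, sample(1:20, 1)))
    m <- recovery_metrics(called, truth, universe)
    tp <- 0
    for (g in called$up) for (t in truth$up) if (g == t) tp <- tp + 1
    expect_equal(m$per_direction$tp, tp)
    expect_equal(m$per_direction$sensitivity, tp / length(truth$up))
  }

  expect_error(recovery_metrics(list(up = "alien"), truth, universe),
               class = "msc_data_error")
})
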