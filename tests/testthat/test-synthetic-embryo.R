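test_that("embryo model geometry is constructed as specified", {
  cfg <- simulation_config()
  model <- build_embryo_model(cfg)
  expect_equal(sum(model$u * model$axis_ml), 1, tolerance = 1e-9)
  expect_equal(sqrt(sum((model$lens_center - model$eye_center)^2)),
               cfg$eye_radius_um, tolerance = 1e-9)

  big <- simulation_config(eye_radius_um = 100)
  mb <- build_embryo_model(big)
  expect_equal(sqrt(sum((mb$lens_center - mb$eye_center)^2)), 100,
               tolerance = 1e-9)

  mm <- build_embryo_model(simulation_config(mirrored = TRUE))
  expect_equal(sum(mm$u * mm$axis_ml), -1, tolerance = 1e-9)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(simulation_config(n_entering_2nc = 50, n_2nc = 10),
               "n_entering_2nc")
  expect_error(simulation_config(cluster_window = c(22, 18)), "window")
  expect_error(simulation_config(mixing_fraction = 1.5), "fractions")
  expect_error(simulation_config(t_end_hpf = 10), "t_end_hpf")
})

test_that("zero founders yield an empty ground truth with a warning", {
  cfg <- simulation_config(n_1nc = 0, n_2nc = 0)
  model <- build_embryo_model(cfg)
  expect_warning(truth <- simulate_populations(model, cfg), "zero founders")
  expect_length(truth$cells, 0)
})

test_that("zero division rate gives single-cell lineages", {
  cfg <- small_config(division_rate_per_h = 0, mixing_fraction = 0)
  model <- build_embryo_model(cfg)
  truth <- simulate_populations(model, cfg)
  expect_length(truth$cells, cfg$n_1nc + cfg$n_2nc)
  expect_true(all(vapply(truth$cells, function(cl) is.na(cl$parent_id),
                         TRUE)))
})

test_that("divisions produce exactly two daughters born at the parent end", {
  cfg <- small_config(division_rate_per_h = 0.15)
  model <- build_embryo_model(cfg)
  truth <- simulate_populations(model, cfg)
  parents <- vapply(truth$cells, function(cl) cl$parent_id, 1L)
  tab <- table(parents[!is.na(parents)])
  expect_true(length(tab) > 0)
  expect_true(all(tab == 2L))
  for (cl in truth$cells) {
    if (is.na(cl$parent_id)) next
    par <- truth$cells[[cl$parent_id]]
    expect_identical(cl$birth_frame, par$end_frame + 1L)
  }
})

test_that("population schedules respect the anatomical windows", {
  # mixing disabled: the schedule invariants concern canonical programmes
  cfg <- coarse_config(mixing_fraction = 0)
  model <- build_embryo_model(cfg)
  truth <- simulate_populations(model, cfg)
  entry_start <- cfg$entry_window[1]
  for (cl in truth$cells) {
    fr <- (cl$birth_frame:cl$end_frame)
    t <- truth$t_hpf[fr + 1L]
    r <- sqrt(rowSums((cl$pos -
                         matrix(model$eye_center, nrow(cl$pos), 3,
                                byrow = TRUE))^2))
    proj <- proximodistal_coord(cl$pos, model)
    in_shell <- abs(r - model$eye_radius) <= cfg$shell_um
    if (cl$population == "2NC") {
      expect_false(any(in_shell[t < entry_start]),
                   label = sprintf("2NC cell %d in shell before entry",
                                   cl$cell_id))
    } else {
      expect_false(any(in_shell & proj > 0),
                   label = sprintf("1NC cell %d in distal hemisphere",
                                   cl$cell_id))
    }
  }
})

test_that("the distal eye holds 20-30 second-wave cells at entry end", {
  cfg <- coarse_config()
  model <- build_embryo_model(cfg)
  truth <- simulate_populations(model, cfg)
  forest <- as_lineage_forest(truth)
  at <- forest$positions[abs(forest$positions$t_hpf -
                               cfg$entry_window[2]) < 0.04]
  two <- forest$segments$cell_id[forest$segments$population_truth == "2NC"]
  at <- at[at$cell_id %in% two]
  inside <- region_and(region_eye_shell(model, cfg$shell_um),
                       region_halfspace(model, "distal"))
  n_in <- count_cells_in_region(at, inside)
  expect_gte(n_in, 20)
  expect_lte(n_in, 30)
})

test_that("identical config and seed reproduce bitwise-identical exports", {
  cfg <- small_config()
  model <- build_embryo_model(cfg)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  export_truth(simulate_populations(model, cfg), d1)
  export_truth(simulate_populations(model, cfg), d2)
  for (f in c("tracks.csv", "lineages.nwk"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("photoconversion recovery separates the two promoter schedules", {
  cfg <- small_config()
  model <- build_embryo_model(cfg)
  truth <- simulate_populations(model, cfg)
  # conversion at 16 hpf: the 1NC promoter is already off, no green recovery
  conv16 <- apply_photoconversion(truth, 16)
  es <- expression_states(conv16, 30)
  expect_true(all(es$pool_green[es$population == "1NC"] < 1e-9))
  # conversion at 17 hpf: 2NC cells (promoter on until 20 hpf) recover green
  conv17 <- apply_photoconversion(truth, 17)
  es17 <- expression_states(conv17, 24)
  expect_true(all(es17$pool_green[es17$population == "2NC"] > 0.1))
  expect_true(all(es17$pool_green[es17$population == "1NC"] < 1e-9))
  # no synthesis: nothing recovers
  cfg0 <- small_config(k_syn_per_h = 0)
  t0 <- simulate_populations(build_embryo_model(cfg0), cfg0)
  c0 <- apply_photoconversion(t0, 17)
  es0 <- expression_states(c0, 24)
  expect_true(all(es0$pool_green < 1e-12))
  expect_error(apply_photoconversion(truth, 40), "outside")
})

test_that("pools stay non-negative and G+R is conserved without decay", {
  cfg <- small_config(halflife_h = Inf)
  model <- build_embryo_model(cfg)
  truth <- simulate_populations(model, cfg)
  conv <- apply_photoconversion(truth, 17)
  fcv <- which.min(abs(truth$t_hpf - 17)) - 1L
  for (cl in conv$cells) {
    expect_true(all(cl$pool_green >= 0) && all(cl$pool_red >= 0))
    orig <- truth$cells[[cl$cell_id]]
    k <- fcv - cl$birth_frame + 1L
    if (k < 1 || k > length(cl$pool_green)) next
    # promoter-off cells: total fluorophore is unchanged by conversion
    if (!any(cl$promoter[k:length(cl$promoter)])) {
      tot_before <- orig$pool_green + orig$pool_red
      tot_after <- cl$pool_green + cl$pool_red
      expect_equal(tot_after[k:length(tot_after)],
                   tot_before[k:length(tot_before)], tolerance = 1e-9)
    }
  }
})

test_that("export round-trips through the readers", {
  cfg <- small_config()
  model <- build_embryo_model(cfg)
  truth <- simulate_populations(model, cfg)
  dir <- file.path(tempdir(), "sim_rt")
  paths <- export_truth(truth, dir)
  tab <- read_tracks(paths[["tracks"]])
  expect_identical(length(unique(tab$cell_id)), length(truth$cells))
  expect_true(all(stats::na.omit(unique(tab$parent_id)) %in% tab$cell_id))
  nwk <- read_lineage_newick(paths[["lineages"]])
  expect_identical(sort(as.integer(nwk$label)),
                   sort(vapply(truth$cells, `[[`, 1L, "cell_id")))
  # empty truth exports a header-only table
  cfg0 <- simulation_config(n_1nc = 0, n_2nc = 0)
  t0 <- suppressWarnings(simulate_populations(build_embryo_model(cfg0), cfg0))
  p0 <- export_truth(t0, file.path(tempdir(), "sim_empty"))
  expect_identical(nrow(data.table::fread(p0[["tracks"]])), 0L)
})

test_that("mutant genotypes reproduce the described migration defects", {
  cfg <- coarse_config(genotype = "pax6_double_null")
  model <- build_embryo_model(cfg)
  truth <- simulate_populations(model, cfg)
  forest <- as_lineage_forest(truth)
  labels <- classify_destination(forest, model, 30)
  segs <- forest$segments
  terms <- terminal_cells(forest)
  pop <- segs$population_truth[match(terms, segs$cell_id)]
  lab <- labels[as.character(terms)]
  # no 2NC cell enters the distal eye; 1NC cells cross the equator
  expect_identical(sum(pop == "2NC" & lab == "distal"), 0L)
  expect_gt(sum(pop == "1NC" & lab == "distal"), 0L)
  cfgb <- coarse_config(genotype = "pax6b_null")
  tb <- simulate_populations(build_embryo_model(cfgb), cfgb)
  fb <- as_lineage_forest(tb)
  lb <- classify_destination(fb, build_embryo_model(cfgb), 30)
  popb <- fb$segments$population_truth[match(terminal_cells(fb),
                                             fb$segments$cell_id)]
  labb <- lb[as.character(terminal_cells(fb))]
  expect_identical(sum(popb == "2NC" & labb == "distal"), 0L)
  expect_identical(sum(popb == "1NC" & labb == "distal"), 0L)
})
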