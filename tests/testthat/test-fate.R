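sim_forest <- function(cfg = small_config()) {
  model <- build_embryo_model(cfg)
  truth <- simulate_populations(model, cfg)
  list(model = model, truth = truth, forest = as_lineage_forest(truth))
}

test_that("cell selection honours regions and selection times", {
  s <- sim_forest()
  all_region <- region_box(c(-1e6, -1e6, -1e6), c(1e6, 1e6, 1e6))
  alive17 <- s$forest$positions[abs(s$forest$positions$t_hpf - 17) ==
                                  min(abs(s$forest$positions$t_hpf - 17))]
  sel <- select_cells(s$forest, all_region, 17)
  expect_setequal(sel, unique(alive17$cell_id))
  # disjoint region
  far <- region_sphere(c(1e5, 1e5, 1e5), 1)
  expect_length(select_cells(s$forest, far, 17), 0)
  # proximal half-space at 17 hpf contains only 1NC-truth cells
  prox <- region_and(region_eye_shell(s$model, 6),
                     region_halfspace(s$model, "proximal"))
  sel_p <- select_cells(s$forest, prox, 17)
  pops <- s$forest$segments$population_truth[
    match(sel_p, s$forest$segments$cell_id)]
  expect_true(length(sel_p) > 0)
  expect_true(all(pops == "1NC"))
})

test_that("selection propagates backward to ancestors and forward to all", {
  s <- sim_forest(small_config(division_rate_per_h = 0.2))
  segs <- s$forest$segments
  roots <- segs$cell_id[is.na(segs$parent_id)]
  full <- propagate_selection(s$forest, roots, min(s$truth$t_hpf),
                              max(s$truth$t_hpf), "forward")
  expect_setequal(full$segments$cell_id, segs$cell_id)
  # backward from a post-division segment includes its parent
  child <- segs$cell_id[!is.na(segs$parent_id)][1]
  par <- segs$parent_id[match(child, segs$cell_id)]
  t_child <- s$forest$positions[s$forest$positions$cell_id == child]$t_hpf[1]
  back <- propagate_selection(s$forest, child, t_child,
                              min(s$truth$t_hpf), "backward")
  expect_true(par %in% back$segments$cell_id)
  expect_error(propagate_selection(s$forest, 99999L, 17, 11, "backward"),
               "absent")
  # closure: forward(backward(S)) contains S
  sel <- segs$cell_id[seq_len(min(5, nrow(segs)))]
  b <- propagate_selection(s$forest, sel, max(s$truth$t_hpf),
                           min(s$truth$t_hpf), "backward")
  f <- propagate_selection(s$forest, b$segments$cell_id[
    is.na(b$segments$parent_id)], min(s$truth$t_hpf),
    max(s$truth$t_hpf), "forward")
  expect_true(all(sel %in% f$segments$cell_id))
})

test_that("destination classification follows the shell/half-space rules", {
  cfg <- simulation_config()
  model <- build_embryo_model(cfg)
  mk <- function(p) {
    segs <- data.frame(cell_id = 1L, parent_id = NA_integer_,
                       lineage_id = 1L, start_frame = 0L, end_frame = 1L)
    pos <- data.frame(cell_id = 1L, frame = 0:1, t_hpf = c(0, 1),
                      x_um = p[1], y_um = p[2], z_um = p[3])
    lineage_forest(segs, pos)
  }
  lab_at <- function(p) unname(classify_destination(mk(p), model, 1)["1"])
  expect_identical(lab_at(model$lens_center), "distal")
  expect_identical(lab_at(2 * model$eye_center - model$lens_center),
                   "proximal")
  # equatorial tie with zero margin resolves proximal by convention
  eq <- model$eye_center + model$eye_radius * model$axis_dv
  expect_identical(lab_at(eq), "proximal")
  # outside the shell
  expect_identical(lab_at(model$eye_center + c(0, 0, 500)), "periocular")
  # every terminal alive at t_eval receives exactly one label
  s <- sim_forest()
  labs <- classify_destination(s$forest, s$model, 30)
  expect_setequal(names(labs), as.character(terminal_cells(s$forest)))
  expect_true(all(labs %in% c("proximal", "distal", "periocular",
                              "unlabelled")))
})

test_that("terminals dead before evaluation stay unlabelled", {
  segs <- data.frame(cell_id = 1:2, parent_id = NA_integer_,
                     lineage_id = 1:2, start_frame = 0L,
                     end_frame = c(1L, 5L))
  pos <- do.call(rbind, lapply(1:2, function(i)
    data.frame(cell_id = i, frame = 0:(c(1, 5)[i]),
               t_hpf = 0:(c(1, 5)[i]), x_um = 0, y_um = 0, z_um = 0)))
  f <- lineage_forest(segs, pos)
  model <- build_embryo_model(simulation_config())
  labs <- classify_destination(f, model, 5)
  expect_identical(unname(labs["1"]), "unlabelled")
})

test_that("lineage homogeneity counts match direct tallies", {
  # 3 lineages, one mixed
  x <- make_label_forest(list("proximal", c("distal", "distal"),
                              c("proximal", "distal")))
  rep3 <- lineage_homogeneity(x$forest, x$labels)
  expect_identical(rep3$n_lineages, 3L)
  expect_identical(rep3$n_mixed, 1L)
  expect_equal(rep3$fraction_homogeneous, 2 / 3)
  # periocular terminals are ignored for the dichotomy
  y <- make_label_forest(list(c("proximal", "periocular"),
                              c("periocular", "periocular")))
  repy <- lineage_homogeneity(y$forest, y$labels)
  expect_identical(repy$n_lineages, 1L)
  expect_identical(repy$n_homogeneous, 1L)
  expect_identical(repy$n_excluded, 1L)
  # all singleton same-label lineages: fully homogeneous
  z <- make_label_forest(as.list(rep("distal", 7)))
  expect_equal(lineage_homogeneity(z$forest, z$labels)$fraction_homogeneous,
               1)
  expect_error(lineage_homogeneity(x$forest, x$labels[-1]), "cover")
})

test_that("penetrance rows format as 'x% (a/n)' with half-up rounding", {
  out <- penetrance_table(data.frame(
    genotype = c(rep("g1", 8), rep("g2", 4)),
    affected = c(rep(TRUE, 7), FALSE, rep(c(TRUE, FALSE), 2))))
  expect_identical(out$formatted[out$genotype == "g1"], "88% (7/8)")
  expect_identical(out$formatted[out$genotype == "g2"], "50% (2/4)")
})

test_that("defect calls separate wildtype from pax6 mutant behaviour", {
  cfgw <- coarse_config(mixing_fraction = 0)
  sw <- sim_forest(cfgw)
  labw <- classify_destination(sw$forest, sw$model, 30)
  expect_false(defect_call(sw$forest, labw, sw$model))
  cfgm <- coarse_config(genotype = "pax6_double_null")
  sm <- sim_forest(cfgm)
  labm <- classify_destination(sm$forest, sm$model, 30)
  expect_true(defect_call(sm$forest, labm, sm$model))
  # empty forest is affected by convention, with a flag
  empty <- lineage_forest(
    data.frame(cell_id = integer(), parent_id = integer(),
               lineage_id = integer(), start_frame = integer(),
               end_frame = integer()),
    data.frame(cell_id = integer(), frame = integer(), t_hpf = numeric(),
               x_um = numeric(), y_um = numeric(), z_um = numeric()))
  call <- defect_call(empty, c(), sw$model)
  expect_true(call)
  expect_identical(attr(call, "flag"), "empty_forest")
})

test_that("region specs compose and build from config descriptions", {
  model <- build_embryo_model(simulation_config())
  p <- matrix(c(model$lens_center, model$eye_center + c(0, 0, 500)),
              ncol = 3, byrow = TRUE)
  shell <- region_eye_shell(model, 6)
  distal <- region_halfspace(model, "distal")
  both <- region_and(shell, distal)
  expect_identical(both(p), c(TRUE, FALSE))
  expect_identical(region_not(both)(p), c(FALSE, TRUE))
  spec <- list(type = "and",
               regions = list(list(type = "eye_shell", shell_um = 6),
                              list(type = "halfspace", side = "distal")))
  expect_identical(region_from_config(spec, model)(p), c(TRUE, FALSE))
  expect_error(region_from_config(list(type = "nope"), model), "unknown")
})
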