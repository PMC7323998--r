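test_that("stationary points link into identity tracks without divisions", {
  pts <- expand.grid(x_um = c(0, 20, 40), y_um = c(0, 20), z_um = 0)
  det <- data.table::rbindlist(lapply(0:5, function(f)
    data.table::data.table(frame = f, x_um = pts$x_um + 0.01 * f,
                           y_um = pts$y_um, z_um = pts$z_um)))
  g <- link_frames(det, gate_um = 5)
  fo <- build_lineages(g)
  expect_identical(nrow(fo$segments), 6L)
  expect_true(all(is.na(fo$segments$parent_id)))
})

test_that("frame-pair assignment equals brute-force minimum cost", {
  # the worked two-point swap
  A <- rbind(c(0, 0, 0), c(3, 0, 0))
  B <- rbind(c(3, 0.1, 0), c(0, 0.1, 0))
  expect_equal(gated_assignment_cost(A, B, gate = 10),
               brute_force_gated_cost(A, B, gate = 10), tolerance = 1e-9)
  # randomised instances with up to 7 points per frame, incl. gating
  set.seed(31)
  for (i in 1:25) {
    n <- sample(0:7, 1); m <- sample(0:7, 1)
    A <- matrix(runif(3 * n, 0, 12), ncol = 3)
    B <- matrix(runif(3 * m, 0, 12), ncol = 3)
    gate <- runif(1, 2, 8)
    expect_equal(gated_assignment_cost(A, B, gate),
                 brute_force_gated_cost(A, B, gate), tolerance = 1e-9,
                 label = sprintf("instance %d", i))
  }
})

test_that("a constructed division attaches exactly two successors", {
  det <- data.table::rbindlist(list(
    data.table::data.table(frame = 0L, x_um = 0, y_um = 0, z_um = 0),
    data.table::data.table(frame = 1L, x_um = 0.2, y_um = 0, z_um = 0),
    data.table::data.table(frame = 2L, x_um = c(2, -2), y_um = 0, z_um = 0),
    data.table::data.table(frame = 3L, x_um = c(2.4, -2.4), y_um = 0,
                           z_um = 0)))
  g <- link_frames(det, gate_um = 5)
  succ <- table(g$edges$from)
  expect_identical(max(succ), 2L)
  fo <- build_lineages(g)
  expect_identical(nrow(fo$segments), 3L)
  expect_identical(sum(is.na(fo$segments$parent_id)), 1L)
  expect_identical(length(unique(fo$segments$lineage_id)), 1L)
})

test_that("graph invariants hold on randomised inputs", {
  set.seed(17)
  for (i in 1:5) {
    det <- data.table::rbindlist(lapply(0:8, function(f)
      data.table::data.table(frame = f, x_um = runif(12, 0, 60),
                             y_um = runif(12, 0, 60), z_um = 0)))
    g <- link_frames(det, gate_um = 8)
    expect_silent(validate_track_graph(g))
    ed <- g$edges
    if (nrow(ed) > 0) {
      expect_lte(max(table(ed$from)), 2L)
      expect_lte(max(table(ed$to)), 1L)
    }
  }
})

test_that("gap closing bridges dropouts into one segment", {
  det <- data.table::rbindlist(lapply(c(0:3, 6:9), function(f)
    data.table::data.table(frame = f, x_um = f * 1.0, y_um = 0, z_um = 0)))
  g <- link_frames(det, gate_um = 5, max_gap_frames = 2)
  expect_true(any(g$edges$gap))
  fo <- build_lineages(g)
  expect_identical(nrow(fo$segments), 1L)
  # beyond the allowed gap the track stays split
  g2 <- link_frames(det, gate_um = 5, max_gap_frames = 1)
  expect_identical(nrow(build_lineages(g2)$segments), 2L)
})

test_that("empty detections give an empty graph", {
  g <- link_frames(data.table::data.table(frame = integer(),
                                          x_um = numeric(),
                                          y_um = numeric(),
                                          z_um = numeric()))
  expect_identical(nrow(g$edges), 0L)
})

test_that("linking exported truth reproduces the true forest", {
  # hand-built truth without mid-movie delamination: recovery is exact
  cfg <- simulation_config(n_1nc = 0, n_2nc = 0)
  model <- build_embryo_model(cfg)
  mkcell <- function(id, parent, lineage, b, e, xoff, slope)
    list(cell_id = id, parent_id = parent, lineage_id = lineage,
         population = "1NC", destination_truth = "proximal",
         birth_frame = b, end_frame = e,
         pos = cbind(xoff + slope * (b:e), 0, 0),
         pool_green = rep(1, e - b + 1), pool_red = rep(0, e - b + 1),
         wnt_intensity = rep(0, e - b + 1),
         promoter = rep(TRUE, e - b + 1))
  truth <- structure(list(model = model, config = cfg,
                          t_hpf = frame_times(cfg),
                          cells = list(
                            mkcell(1L, NA_integer_, 1L, 0L, 9L, 0, 0.5),
                            mkcell(2L, 1L, 1L, 10L, 19L, 1, 0.5),
                            mkcell(3L, 1L, 1L, 10L, 19L, -2, 0.5),
                            mkcell(4L, NA_integer_, 4L, 0L, 19L, 40, 0))),
                     class = "ground_truth")
  tab <- track_table(truth)
  det <- tab[, c("frame", "t_hpf", "x_um", "y_um", "z_um")]
  g <- link_frames(det, gate_um = 3, max_gap_frames = 0)
  fo <- build_lineages(g)
  m <- evaluate_tracking(truth, fo, r_match_um = 0.5)
  expect_equal(m$edge_precision, 1)
  expect_equal(m$edge_recall, 1)
  expect_equal(m$division_recall, 1)
  expect_identical(nrow(fo$segments), 4L)
  # simulated embryo: near-exact up to delamination appearances
  cfg2 <- small_config()
  truth2 <- simulate_populations(build_embryo_model(cfg2), cfg2)
  tab2 <- track_table(truth2)
  g2 <- link_frames(tab2[, c("frame", "t_hpf", "x_um", "y_um", "z_um")],
                    gate_um = 12, max_gap_frames = 0)
  m2 <- evaluate_tracking(truth2, build_lineages(g2), r_match_um = 1)
  expect_gte(m2$edge_precision, 0.99)
  expect_gte(m2$edge_recall, 0.99)
  expect_equal(m2$division_recall, 1)
})

test_that("randomly relinked detections score near chance", {
  cfg <- small_config()
  model <- build_embryo_model(cfg)
  truth <- simulate_populations(model, cfg)
  tab <- track_table(truth)
  # scramble cell identity within frames: permute cell ids per frame
  set.seed(8)
  perm <- data.table::copy(tab)
  perm <- perm[, {
    idx <- sample(.N)
    list(cell_id = cell_id[idx], t_hpf = t_hpf[1],
         x_um = x_um, y_um = y_um, z_um = z_um)
  }, by = "frame"]
  data.table::setorderv(perm, c("cell_id", "frame"))
  segs <- data.table::copy(as_lineage_forest(truth)$segments)
  fo_bad <- lineage_forest(segs, perm)
  m <- evaluate_tracking(truth, fo_bad, r_match_um = 1)
  expect_lt(m$edge_precision, 0.35)
})

test_that("build_lineages orders and structures segments deterministically", {
  cfg <- small_config(division_rate_per_h = 0.2)
  model <- build_embryo_model(cfg)
  truth <- simulate_populations(model, cfg)
  tab <- track_table(truth)
  det <- tab[, c("frame", "t_hpf", "x_um", "y_um", "z_um")]
  g <- link_frames(det, gate_um = 12)
  f1 <- build_lineages(g)
  f2 <- build_lineages(g)
  expect_identical(f1$segments, f2$segments)
})
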