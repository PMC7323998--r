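#' Simulate the two ocular neural crest populations
#'
#' Generates ground-truth trajectories, divisions and reporter pools for the
#' two NC waves on the frame grid of `config`. 1NC founders delaminate in the
#' lateral zone at 12-14 hpf, migrate over the proximal eye hemisphere and
#' (wildtype) halt at the equatorial plane, afterwards drifting slowly in a
#' distal-ward direction. 2NC founders appear mediodorsally at 16-17 hpf,
#' collect into a dorsal periocular cluster (mean-reverting attraction plus
#' jitter), and during the entry window disperse and migrate over the dorsal
#' rim into the distal hemisphere. Under `pax6b_null` and `pax6_double_null`
#' the 2NC cluster persists periocularly; the double null additionally sends
#' 1NC cells across the equator into the distal half. Divisions are a
#' per-cell Poisson process within the division window; with probability
#' `mixing_fraction` a founder lineage is programmed mixed-destination, in
#' which case its first division assigns the second daughter's subtree the
#' opposite eye hemisphere (such lineages are guaranteed at least one
#' division, since a divergent-daughter programme can only be realised at a
#' division).
#'
#' @param model an [build_embryo_model()] result.
#' @param config a [simulation_config()].
#' @return an object of class `ground_truth`: a list with `model`, `config`,
#'   `t_hpf` (frame grid), and `cells`, a list of cell records. Each cell
#'   record spans the interval from its birth to its division or the end of
#'   the recording and carries `cell_id`, `parent_id`, `lineage_id`,
#'   `population`, `destination_truth`, `wnt_positive`, `birth_frame`,
#'   `end_frame` (0-based), `pos` (n x 3 matrix, micrometres), `promoter`
#'   (logical), `pool_green`, `pool_red`, `wnt_intensity`.
#' @export
simulate_populations <- function(model, config = simulation_config()) {
  validate_embryo_model(model)
  validate_sim_config(config)
  set.seed(config$seed)
  tg <- frame_times(config)
  nf <- length(tg)
  if (config$n_1nc + config$n_2nc == 0L) {
    .warnf("zero founders in both populations; returning empty ground truth")
    out <- list(model = model, config = config, t_hpf = tg, cells = list())
    class(out) <- "ground_truth"
    return(out)
  }

  founders <- .draw_founders(model, config)
  cells <- list()
  next_id <- 1L
  # stack of cells awaiting integration
  queue <- founders
  while (length(queue) > 0L) {
    cl <- queue[[1L]]; queue <- queue[-1L]
    cl$cell_id <- next_id; next_id <- next_id + 1L
    cl <- .integrate_cell(cl, model, config, tg)
    div <- .maybe_divide(cl, config, tg)
    if (!is.null(div)) {
      cl$end_frame <- div$frame
      cl <- .trim_cell(cl)
      daughters <- .make_daughters(cl, div, model, config, tg)
      queue <- c(daughters, queue)
    }
    cells[[cl$cell_id]] <- cl
  }
  truth <- list(model = model, config = config, t_hpf = tg, cells = cells)
  class(truth) <- "ground_truth"
  truth <- .compute_pools(truth)
  truth
}

# founder cell stubs -------------------------------------------------------

.draw_founders <- function(model, config) {
  tg <- frame_times(config)
  founders <- list()
  zone_draw <- function(zone) zone$center + stats::rnorm(3) * zone$sd
  mk <- function(pop, birth_hpf, pos0, lineage_id, program, mixed, wntpos) {
    list(cell_id = NA_integer_, parent_id = NA_integer_,
         lineage_id = lineage_id, population = pop,
         destination_truth = program, mixed_lineage = mixed,
         flip_pending = mixed,   # flip happens at the lineage's 1st division
         wnt_positive = wntpos,
         birth_frame = .hpf_to_frame(birth_hpf, tg) - 1L,
         end_frame = length(tg) - 1L,
         generation = 0L,
         state = NULL)
  }
  lin <- 0L
  dbl <- identical(config$genotype, "pax6_double_null")
  mut2 <- config$genotype %in% c("pax6b_null", "pax6_double_null")
  for (i in seq_len(config$n_1nc)) {
    lin <- lin + 1L
    b <- stats::runif(1, config$delamination_window_1nc[1],
                      config$delamination_window_1nc[2])
    program <- if (dbl && stats::runif(1) < 0.5) "distal" else "proximal"
    mixed <- stats::runif(1) < config$mixing_fraction && !mut2
    f <- mk("1NC", b, NULL, lin, program, mixed, FALSE)
    f$pos0 <- zone_draw(model$origin_zone_1nc)
    founders[[length(founders) + 1L]] <- f
  }
  enter <- rep(FALSE, config$n_2nc)
  if (config$n_2nc > 0L)
    enter[sample.int(config$n_2nc,
                     min(config$n_entering_2nc, config$n_2nc))] <- TRUE
  for (i in seq_len(config$n_2nc)) {
    lin <- lin + 1L
    b <- stats::runif(1, config$delamination_window_2nc[1],
                      config$delamination_window_2nc[2])
    program <- if (mut2) "periocular" else
      if (enter[i]) "distal" else "periocular"
    mixed <- stats::runif(1) < config$mixing_fraction && !mut2 &&
      program == "distal"
    wntpos <- stats::runif(1) < config$wnt_wave2_fraction
    f <- mk("2NC", b, NULL, lin, program, mixed, wntpos)
    f$pos0 <- zone_draw(model$origin_zone_2nc)
    founders[[length(founders) + 1L]] <- f
  }
  founders
}

# motion -------------------------------------------------------------------

# sample a unit vector whose component along `axis` lies in [lo, hi]
.sample_cap_dir <- function(axis, lo, hi) {
  z <- stats::runif(1, lo, hi)
  # orthonormal completion of `axis`
  a <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(a - sum(a * axis) * axis)
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  phi <- stats::runif(1, 0, 2 * pi)
  r <- sqrt(max(0, 1 - z^2))
  z * axis + r * (cos(phi) * e1 + sin(phi) * e2)
}

.cell_targets <- function(cell, model, config) {
  R <- model$eye_radius
  u <- model$u
  st <- cell$state %||% list()
  if (is.null(st$target)) {
    if (cell$destination_truth == "proximal") {
      st$target <- model$eye_center +
        (R + 1) * .sample_cap_dir(-u, 0.15, 0.95)
    } else if (cell$destination_truth == "distal") {
      st$target <- model$eye_center +
        (R + 1) * .sample_cap_dir(u, 0.5, 0.95)
    } else {
      st$target <- model$cluster_center
    }
    # entry route passes over the dorsal rim of the optic cup
    rim_dir <- .unit(0.25 * model$u + 0.97 * model$axis_dv +
                       0.12 * stats::rnorm(3))
    st$waypoint <- model$eye_center + (R + config$shell_um) * rim_dir
    st$depart_hpf <- stats::runif(1, config$entry_window[1],
                                  config$entry_window[1] +
                                    0.15 * diff(config$entry_window))
    # per-cell stall depth for the post-22-hpf distal-ward creep, so cells
    # spread over the hemisphere instead of crowding at the equator
    st$drift_stop <- stats::runif(1, -0.7 * R, -3)
    st$settled <- FALSE
    st$via_rim_done <- FALSE
  }
  st
}

# integrate one cell's trajectory over [birth_frame, end_frame]
.integrate_cell <- function(cell, model, config, tg) {
  i0 <- cell$birth_frame + 1L
  i1 <- cell$end_frame + 1L
  n <- i1 - i0 + 1L
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- cell$pos0
  st <- .cell_targets(cell, model, config)
  dt_min <- config$dt_s / 60
  dt_h <- config$dt_s / 3600
  sp <- unname(config$speed_um_per_min[[cell$population]]) * dt_min
  drift_sp <- config$drift_um_per_min * dt_min
  sig <- config$noise_sigma_um * sqrt(dt_min)
  csig <- config$cluster_sd_um * sqrt(2 * config$cluster_kappa_per_h * dt_h)
  kdt <- config$cluster_kappa_per_h * dt_h
  R <- model$eye_radius
  u <- model$u
  cc <- model$eye_center
  shell <- config$shell_um
  th <- config$drift_angle_deg * pi / 180
  drift_dir <- cos(th) * model$axis_ap + sin(th) * u
  pop <- cell$population
  prog <- cell$destination_truth
  uses_rim <- (pop == "2NC") || (pop == "1NC" && prog == "distal")
  # 2NC cells stay clear of the ocular shell until the entry phase
  outside_shell <- function(p) {
    d <- p - cc
    r <- .norm2(d)
    if (r < R + shell + 0.5) cc + d * ((R + shell + 0.5) / max(r, 1e-9))
    else p
  }
  if (n >= 2L) for (k in 2:n) {
    t_now <- tg[i0 + k - 2L]
    p <- pos[k - 1L, ]
    noise <- stats::rnorm(3) * sig
    if (pop == "2NC" && t_now < config$entry_window[1] &&
        t_now >= config$cluster_window[1] - 0.25) {
      # cluster phase: mean-reverting attraction + jitter
      p <- outside_shell(p + kdt * (model$cluster_center - p) +
                           stats::rnorm(3) * csig)
    } else if (pop == "2NC" && prog == "periocular") {
      if (t_now < config$cluster_window[1] - 0.25) {
        p <- outside_shell(.step_towards(p, model$cluster_center, sp) + noise)
      } else {
        p <- outside_shell(p + kdt * (model$cluster_center - p) +
                             stats::rnorm(3) * csig)
      }
    } else if (pop == "2NC" && t_now < st$depart_hpf && !st$settled) {
      # awaiting dispersal
      p <- outside_shell(p + kdt * (model$cluster_center - p) +
                           stats::rnorm(3) * csig)
    } else if (!st$settled) {
      if (uses_rim && st$via_rim_done) {
        # crawl over the eye surface toward the target (great-circle step)
        radial <- .unit(p - cc)
        dirv <- st$target - p
        tang <- dirv - sum(dirv * radial) * radial
        if (.norm2(tang) > 1e-6) p <- p + sp * .unit(tang)
        p <- .clamp_shell(p + noise, cc, R, shell)
      } else {
        goal <- if (uses_rim) st$waypoint else st$target
        p <- .step_towards(p, goal, sp) + noise
      }
      if (uses_rim && !st$via_rim_done &&
          .norm2(p - st$waypoint) < max(4, 1.5 * sp))
        st$via_rim_done <- TRUE
      if (.norm2(p - st$target) < max(3, 1.5 * sp)) st$settled <- TRUE
    } else {
      # settled on the ocular shell: quiescent epithelial jitter; 1NC cells
      # additionally creep distal-ward after 22 hpf until near the equator
      proj <- sum((p - cc) * u)
      if (pop == "1NC" && prog == "proximal" && t_now >= 22 &&
          proj < st$drift_stop)
        p <- p + drift_sp * drift_dir
      p <- p + 0.4 * noise
      p <- .clamp_shell(p, cc, R, shell)
    }
    if (!is.null(cell$sep_dir) && t_now < cell$sep_until_hpf)
      p <- p + cell$sep_rate_um_min * dt_min * cell$sep_dir
    if (prog == "proximal" && st$settled)
      p <- .clamp_hemisphere(p, cc, u, max_proj = -1)
    if (prog == "distal" && st$settled)
      p <- .clamp_hemisphere(p, cc, -u, max_proj = -1)
    pos[k, ] <- p
  }
  cell$pos <- pos
  cell$state <- st
  cell
}

.step_towards <- function(p, goal, step) {
  d <- goal - p
  nd <- .norm2(d)
  if (nd <= step) goal else p + d * (step / nd)
}

.clamp_shell <- function(p, center, R, shell) {
  d <- p - center
  r <- .norm2(d)
  if (r < 1e-9) return(center + c(R, 0, 0))
  rc <- min(max(r, R - shell / 2), R + shell / 2)
  center + d * (rc / r)
}

.clamp_hemisphere <- function(p, center, u, max_proj) {
  proj <- sum((p - center) * u)
  if (proj > max_proj) p - (proj - max_proj) * u else p
}

# divisions ----------------------------------------------------------------

.maybe_divide <- function(cell, config, tg) {
  if (config$division_rate_per_h <= 0 && !isTRUE(cell$flip_pending))
    return(NULL)
  t_birth <- tg[cell$birth_frame + 1L]
  t_end <- tg[cell$end_frame + 1L]
  w0 <- max(t_birth, config$division_window_hpf[1])
  w1 <- min(t_end, config$division_window_hpf[2])
  if (w0 >= w1) {
    if (isTRUE(cell$flip_pending) && t_birth < config$division_window_hpf[2]) {
      # guarantee the mixed programme a division even for late-born founders
      t_div <- min(t_end - 2 * config$dt_s / 3600,
                   config$division_window_hpf[2])
      if (t_div <= t_birth) return(NULL)
      return(list(t = t_div, frame = .hpf_to_frame(t_div, tg) - 1L))
    }
    return(NULL)
  }
  t_div <- if (config$division_rate_per_h > 0)
    w0 + stats::rexp(1, config$division_rate_per_h) else Inf
  if (t_div >= w1) {
    if (!isTRUE(cell$flip_pending)) return(NULL)
    t_div <- stats::runif(1, w0, w1)  # forced division of a mixed lineage
  }
  f <- .hpf_to_frame(t_div, tg) - 1L
  f <- max(f, cell$birth_frame + 1L)
  if (f >= cell$end_frame) return(NULL)
  list(t = tg[f + 1L], frame = f)
}

.trim_cell <- function(cell) {
  keep <- seq_len(cell$end_frame - cell$birth_frame + 1L)
  cell$pos <- cell$pos[keep, , drop = FALSE]
  cell
}

.flip_program <- function(program) {
  switch(program, proximal = "distal", distal = "proximal",
         periocular = "distal", program)
}

.make_daughters <- function(cell, div, model, config, tg) {
  p_end <- cell$pos[nrow(cell$pos), ]
  dir <- .sample_cap_dir(c(0, 0, 1), -1, 1)
  eps <- config$division_sep_um
  flip_here <- isTRUE(cell$flip_pending)
  mk <- function(sign_, flip_dest) {
    d <- cell
    d$cell_id <- NA_integer_
    d$parent_id <- cell$cell_id
    d$birth_frame <- div$frame + 1L
    d$end_frame <- length(tg) - 1L
    d$generation <- cell$generation + 1L
    # sisters start ~1.5 um apart and drift apart over ~25 min of
    # post-mitotic separation until they sit division_sep_um from the
    # division point each
    d$pos0 <- p_end + sign_ * 0.75 * dir
    d$sep_dir <- sign_ * dir
    d$sep_rate_um_min <- max(0, (eps - 0.75)) / 25
    d$sep_until_hpf <- tg[div$frame + 2L] + 25 / 60
    d$pos <- NULL
    d$flip_pending <- FALSE
    if (flip_dest) {
      d$destination_truth <- .flip_program(cell$destination_truth)
      d$state <- NULL       # flipped subtree draws its own route
    } else {
      d$state <- cell$state # inherit target/settled mode
    }
    d
  }
  if (div$frame + 1L > length(tg) - 1L) return(list())
  list(mk(+1, FALSE), mk(-1, flip_here))
}

# reporter pools -----------------------------------------------------------

# promoter activity: on from birth until the population silencing time
.promoter_series <- function(cell, config, tg) {
  t <- tg[(cell$birth_frame:cell$end_frame) + 1L]
  t < config$silencing_hpf[[cell$population]]
}

# exact update of dG/dt = k_syn*a(t) - k_deg*G over one frame
.integrate_pools <- function(G0, R0, promoter, config) {
  n <- length(promoter)
  kd <- log(2) / config$halflife_h
  dt_h <- config$dt_s / 3600
  decay <- exp(-kd * dt_h)
  gain <- if (kd > 0) config$k_syn_per_h * (1 - decay) / kd else
    config$k_syn_per_h * dt_h
  G <- numeric(n); R <- numeric(n)
  G[1] <- G0; R[1] <- R0
  if (n >= 2L) for (k in 2:n) {
    a <- as.numeric(promoter[k - 1L])
    G[k] <- G[k - 1L] * decay + gain * a
    R[k] <- R[k - 1L] * decay
  }
  list(G = G, R = R)
}

.wnt_series <- function(cell, config, tg) {
  t <- tg[(cell$birth_frame:cell$end_frame) + 1L]
  w <- config$wnt_amplitudes_au[1] *
    exp(-(t - config$wnt_peaks_hpf[1])^2 / (2 * config$wnt_sigmas_h[1]^2))
  if (cell$population == "2NC" && isTRUE(cell$wnt_positive))
    w <- w + config$wnt_amplitudes_au[2] *
      exp(-(t - config$wnt_peaks_hpf[2])^2 / (2 * config$wnt_sigmas_h[2]^2))
  w
}

# fill promoter, green/red pools and Wnt intensity for every cell,
# propagating pools across divisions (daughters inherit the parent's pools)
.compute_pools <- function(truth, from_frame = 0L,
                           convert = FALSE, t_convert_hpf = NULL) {
  cfg <- truth$config
  tg <- truth$t_hpf
  by_parent <- split(seq_along(truth$cells),
                     vapply(truth$cells, function(cl)
                       cl$parent_id %||% NA_integer_, 1L))
  roots <- which(vapply(truth$cells, function(cl) is.na(cl$parent_id), TRUE))
  conv_frame <- if (convert) .hpf_to_frame(t_convert_hpf, tg) - 1L else -1L
  walk <- function(id, G0, R0) {
    cl <- truth$cells[[id]]
    prom <- .promoter_series(cl, cfg, tg)
    pools <- .integrate_pools(G0, R0, prom, cfg)
    if (convert && conv_frame >= cl$birth_frame &&
        conv_frame <= cl$end_frame) {
      k <- conv_frame - cl$birth_frame + 1L
      # instantaneous green-to-red conversion, then re-integrate forward
      Gc <- 0
      Rc <- pools$R[k] + pools$G[k]
      tail_prom <- prom[k:length(prom)]
      tail <- .integrate_pools(Gc, Rc, tail_prom, cfg)
      pools$G[k:length(prom)] <- tail$G
      pools$R[k:length(prom)] <- tail$R
    }
    cl$promoter <- prom
    cl$pool_green <- pools$G
    cl$pool_red <- pools$R
    cl$wnt_intensity <- .wnt_series(cl, cfg, tg)
    truth$cells[[id]] <<- cl
    kids <- by_parent[[as.character(id)]]
    nlast <- length(prom)
    for (kid in kids %||% integer(0))
      walk(kid, pools$G[nlast], pools$R[nlast])
    invisible(NULL)
  }
  for (r in roots) walk(r, 0, 0)
  truth
}

#' Apply photoconversion to a simulated embryo
#'
#' Models the irreversible green-to-red switch of the EosFP reporter: at
#' `t_convert_hpf` every live cell's green pool is added to its red pool and
#' zeroed, after which synthesis continues only while the sox10 promoter is
#' active (1NC silenced from 16 hpf, 2NC from 20 hpf) and both pools decay
#' with the configured half-life. Converting at 17 hpf therefore leaves 1NC
#' cells red-only while 2NC cells recover green fluorescence.
#'
#' @param truth a `ground_truth`.
#' @param t_convert_hpf conversion time; must lie within the simulated
#'   window.
#' @return the `ground_truth` with pools recomputed; the conversion time is
#'   recorded in `attr(truth, "converted_at_hpf")`.
#' @export
apply_photoconversion <- function(truth, t_convert_hpf) {
  stopifnot(inherits(truth, "ground_truth"))
  tg <- truth$t_hpf
  if (t_convert_hpf < tg[1] || t_convert_hpf > tg[length(tg)])
    .stopf("t_convert_hpf = %s outside simulated window [%s, %s]",
           t_convert_hpf, tg[1], tg[length(tg)])
  out <- .compute_pools(truth, convert = TRUE, t_convert_hpf = t_convert_hpf)
  attr(out, "converted_at_hpf") <- t_convert_hpf
  out
}
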