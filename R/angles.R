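#' Circular distance between angles
#'
#' @param a,b angles in degrees.
#' @return elementwise `min(|a - b|, 360 - |a - b|)`.
#' @export
circular_distance <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Stride-sampled planar migration angles
#'
#' For every cell and every stride-th frame, the displacement over the next
#' stride is projected onto the horizontal (anteroposterior-mediolateral)
#' plane and converted to an angle measured from the anterior direction,
#' increasing toward the tracked eye's distal side, mapped to `[0, 360)`.
#' Steps shorter than `min_step_um` in the plane are discarded to suppress
#' angle noise from stationary cells.
#'
#' @param tracks a track table (or `lineage_forest` positions) with
#'   `cell_id`, `frame`, `x_um`, `y_um`, `z_um`.
#' @param stride_frames sampling stride in frames (default 10; at the
#'   default 20.4 s frame interval this is one step per 3 min 24 s).
#' @param min_step_um minimum planar step length retained.
#' @param model an `embryo_model` supplying the anterior (`axis_ap`) and
#'   distal-ward (`u`) directions.
#' @param group name recorded in the sample.
#' @return an `angle_sample`: list with `group`, `angles` (degrees in
#'   `[0, 360)`), `cell_ids`, `n`.
#' @export
sample_displacement_angles <- function(tracks, stride_frames = 10,
                                       min_step_um = 0.5,
                                       model = build_embryo_model(),
                                       group = "all") {
  if (inherits(tracks, "lineage_forest")) tracks <- tracks$positions
  stopifnot(stride_frames >= 1)
  d <- data.table::as.data.table(tracks)
  data.table::setorderv(d, c("cell_id", "frame"))
  angs <- numeric(0); ids <- c()
  for (cid in unique(d$cell_id)) {
    s <- d[d$cell_id == cid]
    n <- nrow(s)
    if (n <= stride_frames) next
    idx <- seq(1L, n - stride_frames, by = stride_frames)
    P0 <- as.matrix(s[idx, c("x_um", "y_um", "z_um")])
    P1 <- as.matrix(s[idx + stride_frames, c("x_um", "y_um", "z_um")])
    D <- P1 - P0
    comp_ap <- D %*% model$axis_ap
    comp_dist <- D %*% model$u   # distal-ward in the horizontal plane
    len <- sqrt(comp_ap^2 + comp_dist^2)
    ok <- len >= min_step_um
    if (!any(ok)) next
    th <- (atan2(comp_dist[ok], comp_ap[ok]) * 180 / pi) %% 360
    angs <- c(angs, th)
    ids <- c(ids, rep(cid, sum(ok)))
  }
  out <- list(group = group, angles = angs, cell_ids = ids,
              n = length(angs))
  class(out) <- "angle_sample"
  out
}

#' Circular median direction
#'
#' The data angle minimising the summed circular distance to the sample
#' (ties resolved by the smallest such angle). For circular L1 distance the
#' minimum over the continuum is always attained at a data angle, so this
#' equals exhaustive minimisation over a fine grid.
#'
#' @param angles numeric vector of degrees.
#' @return the median direction in degrees.
#' @export
circular_median <- function(angles) {
  if (inherits(angles, "angle_sample")) angles <- angles$angles
  if (length(angles) == 0L) .stopf("circular_median of an empty sample")
  a <- angles %% 360
  cand <- sort(unique(a))
  sums <- vapply(cand, function(m) sum(circular_distance(a, m)), 0)
  cand[which.min(sums)]  # which.min takes the first (= smallest angle) tie
}

#' Angle histogram with circular median
#'
#' Half-open binning `[k*w, (k+1)*w)` over `[0, 360)`.
#'
#' @param sample an `angle_sample` (or numeric vector of degrees).
#' @param bin_width_deg bin width; must divide 360.
#' @return an `angle_histogram`: list with `bin_width_deg`, `breaks`,
#'   `counts`, `n`, `median_direction` (NA with `median_defined = FALSE`
#'   for an empty sample).
#' @export
angle_histogram <- function(sample, bin_width_deg = 10) {
  angles <- if (inherits(sample, "angle_sample")) sample$angles else sample
  if (360 %% bin_width_deg != 0)
    .stopf("bin width %.3f does not divide 360", bin_width_deg)
  nb <- as.integer(360 / bin_width_deg)
  breaks <- seq(0, 360, by = bin_width_deg)
  a <- angles %% 360
  counts <- tabulate(pmin(floor(a / bin_width_deg) + 1L, nb), nbins = nb)
  out <- list(bin_width_deg = bin_width_deg, breaks = breaks,
              counts = counts, n = length(a),
              median_direction = if (length(a) > 0) circular_median(a)
                                 else NA_real_,
              median_defined = length(a) > 0)
  class(out) <- "angle_histogram"
  out
}

#' Wallraff test of angular distances
#'
#' Nonparametric comparison of angular dispersions: each observation is
#' reduced to its circular distance from its own group's circular median,
#' and the two distance samples are compared with a two-sided
#' Mann-Whitney/Wilcoxon rank-sum test using midranks. For
#' `nA + nB <= 12` the permutation null of the rank-sum statistic is
#' enumerated exactly (ties handled by construction); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param group_a,group_b `angle_sample` objects (or numeric vectors of
#'   degrees); each needs at least 2 angles.
#' @return a `cw_test`: list with `statistic` (Mann-Whitney U of group A),
#'   `p_value`, `method`, `n` (per group), `exact` flag and a
#'   `degenerate` flag when all distances coincide.
#' @export
wallraff_test <- function(group_a, group_b) {
  a <- if (inherits(group_a, "angle_sample")) group_a$angles else group_a
  b <- if (inherits(group_b, "angle_sample")) group_b$angles else group_b
  if (length(a) < 2 || length(b) < 2)
    .stopf("wallraff_test needs at least 2 angles per group")
  da <- circular_distance(a, circular_median(a))
  db <- circular_distance(b, circular_median(b))
  rk <- rank_sum_test(da, db)
  out <- list(statistic = rk$statistic, df = NA_real_,
              p_value = rk$p_value,
              method = paste0("Wallraff test of angular distances (",
                              rk$method, ")"),
              n = c(length(a), length(b)),
              exact = rk$exact, degenerate = rk$degenerate)
  class(out) <- "cw_test"
  out
}

#' Two-sided Mann-Whitney rank-sum test with midranks
#'
#' Exact permutation enumeration when `length(x) + length(y) <= 12`,
#' otherwise the tie-corrected normal approximation (no continuity
#' correction; the test is used in the large-sample regime).
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (U of `x`), `p_value`, `exact`,
#'   `degenerate`, `method`.
#' @export
rank_sum_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(list(statistic = nx * ny / 2, p_value = 1, exact = TRUE,
                degenerate = TRUE, method = "degenerate"))
  r <- rank(pooled)  # midranks
  W <- sum(r[seq_len(nx)])
  U <- W - nx * (nx + 1) / 2
  N <- nx + ny
  EW <- nx * (N + 1) / 2
  if (N <= 12) {
    splits <- utils::combn(N, nx)
    Ws <- colSums(matrix(r[splits], nrow = nx))
    p <- mean(abs(Ws - EW) >= abs(W - EW) - 1e-9)
    return(list(statistic = U, p_value = p, exact = TRUE,
                degenerate = FALSE, method = "exact enumeration"))
  }
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (W - EW) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = U, p_value = p, exact = FALSE, degenerate = FALSE,
       method = "normal approximation")
}

#' Centre tracks at a reference time
#'
#' Subtracts each track's position at `t0_hpf` from all of its subsequent
#' positions, for displacement ("centred track") plots. Tracks absent at
#' `t0_hpf` are skipped; their number is reported in
#' `attr(, "n_skipped")`.
#'
#' @param tracks a track table (or `lineage_forest`).
#' @param t0_hpf reference time.
#' @return data.table with `cell_id`, `frame`, `t_hpf`, `dx_um`, `dy_um`,
#'   `dz_um`.
#' @export
center_tracks <- function(tracks, t0_hpf) {
  if (inherits(tracks, "lineage_forest")) tracks <- tracks$positions
  d <- data.table::as.data.table(tracks)
  tg <- sort(unique(d$t_hpf))
  f0 <- tg[.hpf_to_frame(t0_hpf, tg)]
  out <- list(); skipped <- 0L
  for (cid in unique(d$cell_id)) {
    s <- d[d$cell_id == cid]
    i0 <- which(abs(s$t_hpf - f0) < 1e-9)
    if (length(i0) == 0L) { skipped <- skipped + 1L; next }
    s <- s[s$t_hpf >= f0 - 1e-9]
    ref <- unlist(s[1, c("x_um", "y_um", "z_um")])
    out[[length(out) + 1L]] <- data.table::data.table(
      cell_id = cid, frame = s$frame, t_hpf = s$t_hpf,
      dx_um = s$x_um - ref[1], dy_um = s$y_um - ref[2],
      dz_um = s$z_um - ref[3])
  }
  res <- data.table::rbindlist(c(out, list(data.table::data.table(
    cell_id = integer(), frame = integer(), t_hpf = numeric(),
    dx_um = numeric(), dy_um = numeric(), dz_um = numeric()))))
  attr(res, "n_skipped") <- skipped
  res
}

#' @export
print.cw_test <- function(x, ...) {
  pv <- if (x$p_value < 2.2e-16) "p-value < 2.2e-16"
        else sprintf("p-value = %.4g", x$p_value)
  df <- if (!is.null(x$df) && !is.na(x$df)) sprintf(", df = %.4g", x$df)
        else ""
  cat(sprintf("<%s> statistic = %.4g%s, %s (n = %s)\n", x$method,
              x$statistic, df, pv, paste(x$n, collapse = "/")))
  invisible(x)
}
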