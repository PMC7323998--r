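#' Background subtraction
#'
#' Subtracts the per-slice (z-plane) median and clips negatives to zero.
#'
#' @param image 2D matrix or 3D array of counts.
#' @return array of the same shape.
#' @export
background_subtract <- function(image) {
  if (is.matrix(image)) {
    out <- image - stats::median(image)
  } else if (length(dim(image)) == 3L) {
    out <- image
    for (z in seq_len(dim(image)[3]))
      out[, , z] <- image[, , z] - stats::median(image[, , z])
  } else .stopf("image must be a 2D matrix or 3D array")
  out[out < 0] <- 0
  out
}

#' Multiply-colocalization of two channels
#'
#' Pixelwise product of the background-subtracted channels (the ImageJ
#' Image Calculator "Multiply" idiom), plus an optional per-cell score: the
#' mean product within a nuclear radius of each detection.
#'
#' @param channel_a,channel_b arrays of identical shape.
#' @param detections optional data.table with `x_um`, `y_um`, `z_um`.
#' @param imaging an [imaging_config()]; required when `detections` given.
#' @param radius_um nuclear radius for the per-cell score.
#' @param bit_depth bit depth for the rescaled image.
#' @return list with `product` (raw products), `scaled` (rescaled to the
#'   output bit depth) and `scores` (per detection, or NULL).
#' @export
colocalize <- function(channel_a, channel_b, detections = NULL,
                       imaging = NULL, radius_um = 3, bit_depth = 16L) {
  if (!identical(dim(channel_a), dim(channel_b)))
    .stopf("channel shapes differ: %s vs %s",
           paste(dim(channel_a), collapse = "x"),
           paste(dim(channel_b), collapse = "x"))
  prod <- background_subtract(channel_a) * background_subtract(channel_b)
  mx <- max(prod)
  scaled <- if (mx > 0) prod / mx * (2^bit_depth - 1) else prod
  scores <- NULL
  if (!is.null(detections) && nrow(detections) > 0) {
    if (is.null(imaging)) .stopf("imaging config required for per-cell scores")
    dims <- dim(prod)
    r_vox <- pmax(1L, as.integer(ceiling(radius_um / imaging$voxel_size_um)))
    scores <- vapply(seq_len(nrow(detections)), function(i) {
      v <- round(.um_to_vox(unlist(detections[i, c("x_um", "y_um", "z_um")]),
                            imaging))
      rngs <- lapply(1:3, function(a)
        max(1L, v[a] - r_vox[a]):min(dims[a], v[a] + r_vox[a]))
      mean(prod[rngs[[1]], rngs[[2]], rngs[[3]]])
    }, 0)
  }
  list(product = prod, scaled = scaled, scores = scores)
}

#' Classify sox10 expression state after photoconversion
#'
#' A cell is `active` when its recovered green fraction `G / (G + R)`
#' exceeds `ratio_threshold` at the evaluation time; with conversion at
#' 17 hpf this separates 1NC (promoter silenced from 16 hpf, red-only) from
#' 2NC (promoter active until 20 hpf, green-recovering) cells. Cells with
#' `G + R = 0` are `unclassifiable`.
#'
#' @param pool_green,pool_red pools at the evaluation time.
#' @param ratio_threshold green-fraction threshold (default 0.1).
#' @return character vector in `{active, silenced, unclassifiable}`.
#' @export
classify_expression_state <- function(pool_green, pool_red,
                                      ratio_threshold = 0.1) {
  tot <- pool_green + pool_red
  ifelse(tot <= 0, "unclassifiable",
         ifelse(pool_green / tot > ratio_threshold, "active", "silenced"))
}

#' Expression states of all cells of a converted embryo
#'
#' Convenience wrapper running [classify_expression_state()] on every cell
#' alive at `t_eval_hpf` of a photoconverted ground truth.
#'
#' @param truth a `ground_truth` after [apply_photoconversion()].
#' @param t_eval_hpf evaluation time (must be later than the conversion).
#' @param ratio_threshold see [classify_expression_state()].
#' @return data.table with `cell_id`, `population`, `pool_green`,
#'   `pool_red`, `state`.
#' @export
expression_states <- function(truth, t_eval_hpf, ratio_threshold = 0.1) {
  conv <- attr(truth, "converted_at_hpf")
  if (is.null(conv)) .stopf("truth has not been photoconverted")
  if (t_eval_hpf <= conv)
    .stopf("t_eval_hpf must be later than the conversion at %.2f hpf", conv)
  f <- .hpf_to_frame(t_eval_hpf, truth$t_hpf) - 1L
  rows <- list()
  for (cl in truth$cells) {
    if (f < cl$birth_frame || f > cl$end_frame) next
    k <- f - cl$birth_frame + 1L
    rows[[length(rows) + 1L]] <- data.table::data.table(
      cell_id = cl$cell_id, population = cl$population,
      pool_green = cl$pool_green[k], pool_red = cl$pool_red[k])
  }
  d <- data.table::rbindlist(rows)
  d[, "state" := classify_expression_state(d$pool_green, d$pool_red,
                                           ratio_threshold)]
  d[]
}

#' Fraction of reporter-positive cells
#'
#' @param values per-cell intensities.
#' @param threshold positivity threshold. The default is
#'   `median + 3 * MAD` of the values themselves.
#' @return list with `fraction`, `n_positive`, `n`, and a `"a/n"` string.
#' @export
positive_fraction <- function(values,
                              threshold = stats::median(values) +
                                3 * stats::mad(values)) {
  n <- length(values)
  if (n < 1) .stopf("positive_fraction needs at least one value")
  a <- sum(values > threshold)
  list(fraction = a / n, n_positive = a, n = n,
       counts = sprintf("%d/%d", a, n))
}

#' Reporter intensity-time profile
#'
#' Per timepoint, the mean over tracked cells of the per-cell summed channel
#' intensity, with the contributing cell count alongside. No smoothing is
#' applied.
#'
#' @param tracks a track table (or `lineage_forest`) with the channel
#'   column.
#' @param channel column name, e.g. `"ch_wnt"`.
#' @return data.table with `t_hpf`, `mean_intensity`, `n_cells`
#'   (`mean_intensity` is NA where no cell is alive).
#' @export
intensity_profile <- function(tracks, channel = "ch_wnt") {
  if (inherits(tracks, "lineage_forest")) tracks <- tracks$positions
  d <- data.table::as.data.table(tracks)
  if (!channel %in% names(d)) .stopf("no channel column '%s'", channel)
  v <- NULL # data.table NSE
  out <- d[, list(mean_intensity = mean(.SD[[1]]), n_cells = .N),
           by = "t_hpf", .SDcols = channel]
  data.table::setorderv(out, "t_hpf")
  out[]
}

#' Count detections inside a region
#'
#' @param detections data.table with `x_um`, `y_um`, `z_um` at one
#'   timepoint.
#' @param region a `region_spec`.
#' @return integer count.
#' @export
count_cells_in_region <- function(detections, region) {
  d <- data.table::as.data.table(detections)
  if (nrow(d) == 0L) return(0L)
  sum(region(as.matrix(d[, c("x_um", "y_um", "z_um")])))
}

#' Group summary (mean, SD, n)
#'
#' @param x numeric vector, or the mean when `sd` and `n` are given.
#' @param sd sample standard deviation (n-1 denominator).
#' @param n group size.
#' @return a `group_summary`.
#' @export
group_summary <- function(x, sd = NULL, n = NULL) {
  if (is.null(sd)) {
    if (length(x) < 2) .stopf("group_summary needs n >= 2")
    out <- list(mean = mean(x), sd = stats::sd(x), n = length(x))
  } else {
    if (n < 2) .stopf("group_summary needs n >= 2")
    if (sd < 0) .stopf("sd must be >= 0")
    out <- list(mean = x, sd = sd, n = n)
  }
  class(out) <- "group_summary"
  out
}

#' Format a group summary in "mean +/- SD (n = ...)" style
#'
#' @param x a `group_summary`.
#' @param digits digits after the decimal point.
#' @return character scalar.
#' @export
format_mean_sd <- function(x, digits = 1) {
  sprintf("%.*f ± %.*f (n = %d)", digits, x$mean, digits, x$sd, x$n)
}

#' Welch two-sample t test from group summaries
#'
#' `t = (m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p from the t
#' distribution. Standard deviations are sample SDs (n-1 denominator).
#'
#' @param a,b `group_summary` objects (or numeric raw samples).
#' @return a `cw_test` with `statistic` (t), `df`, `p_value`.
#' @export
welch_t_test <- function(a, b) {
  if (!inherits(a, "group_summary")) a <- group_summary(a)
  if (!inherits(b, "group_summary")) b <- group_summary(b)
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  se2 <- va + vb
  degenerate <- FALSE
  if (se2 <= 0) {
    degenerate <- TRUE
    tstat <- if (a$mean == b$mean) 0 else sign(a$mean - b$mean) * Inf
    df <- a$n + b$n - 2
    p <- if (a$mean == b$mean) 1 else 0
  } else {
    tstat <- (a$mean - b$mean) / sqrt(se2)
    df <- se2^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  out <- list(statistic = tstat, df = df, p_value = p,
              method = "Welch two sample t-test", n = c(a$n, b$n),
              degenerate = degenerate)
  class(out) <- "cw_test"
  out
}

#' Format a p value with the conventional reporting floor
#'
#' @param p numeric p value.
#' @return `"p-value < 2.2e-16"` below the floor, otherwise
#'   `"p-value = ..."`. The floor applies to formatting only; stored values
#'   are never truncated.
#' @export
format_p_value <- function(p) {
  if (p < 2.2e-16) "p-value < 2.2e-16" else sprintf("p-value = %.3g", p)
}
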