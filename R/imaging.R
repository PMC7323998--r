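#' Imaging configuration
#'
#' Light-sheet-like acquisition parameters: anisotropic voxels (0.4 um
#' lateral, 2.0 um axial by default) and a separable Gaussian PSF with
#' 1.5 um lateral and 6.6 um axial full width at half maximum.
#'
#' @param voxel_size_um length-3 voxel pitch (x, y, z) in micrometres.
#' @param psf_fwhm_um length-2 PSF FWHM (lateral, axial) in micrometres.
#' @param bit_depth output bit depth.
#' @param background_level camera background in counts.
#' @param gain counts per fluorophore unit (blob peak amplitude scale).
#' @param read_sigma Gaussian read-noise standard deviation in counts.
#' @param field_origin_um lower corner of the imaged field.
#' @param field_extent_um field size per axis in micrometres.
#' @return an `imaging_config`.
#' @export
imaging_config <- function(voxel_size_um = c(0.4, 0.4, 2.0),
                           psf_fwhm_um = c(1.5, 6.6),
                           bit_depth = 16L,
                           background_level = 100,
                           gain = 250,
                           read_sigma = 3,
                           field_origin_um = c(0, 0, 0),
                           field_extent_um = c(60, 60, 24)) {
  if (any(voxel_size_um <= 0)) .stopf("voxel sizes must be positive")
  if (psf_fwhm_um[1] < max(voxel_size_um[1:2]))
    .stopf("lateral PSF FWHM (%.2f) must be >= lateral voxel size (%.2f)",
           psf_fwhm_um[1], max(voxel_size_um[1:2]))
  cfg <- list(voxel_size_um = voxel_size_um, psf_fwhm_um = psf_fwhm_um,
              bit_depth = as.integer(bit_depth),
              background_level = background_level, gain = gain,
              read_sigma = read_sigma,
              field_origin_um = field_origin_um,
              field_extent_um = field_extent_um)
  class(cfg) <- "imaging_config"
  cfg
}

.psf_sigma_um <- function(imaging) {
  c(imaging$psf_fwhm_um[1], imaging$psf_fwhm_um[1],
    imaging$psf_fwhm_um[2]) / (2 * sqrt(2 * log(2)))
}

.field_dims <- function(imaging) {
  pmax(2L, as.integer(ceiling(imaging$field_extent_um /
                                imaging$voxel_size_um)))
}

# position (um) -> fractional voxel coordinate (1-based centres)
.um_to_vox <- function(p, imaging) {
  (p - imaging$field_origin_um) / imaging$voxel_size_um + 0.5
}

.vox_to_um <- function(v, imaging) {
  (v - 0.5) * imaging$voxel_size_um + imaging$field_origin_um
}

#' Render ground truth into 3D multi-channel image stacks
#'
#' Each live cell contributes an anisotropic Gaussian blob
#' (sigma = FWHM / 2.355 per axis) whose peak amplitude is
#' `gain * pool` for the channel (green/red EosFP pools, Wnt reporter).
#' Poisson shot noise plus Gaussian read noise is applied on top of the
#' background unless `noise = FALSE`. Rendering is deterministic given the
#' RNG state; call `set.seed()` (or pass `seed`) for reproducibility.
#'
#' @param truth a `ground_truth`.
#' @param imaging an [imaging_config()].
#' @param frames integer vector of 0-based frame indices to render.
#' @param channels subset of `c("green", "red", "wnt")`.
#' @param noise logical; apply the Poisson-Gaussian noise model.
#' @param seed optional seed for the noise.
#' @param dir if non-NULL, write one multi-page 16-bit TIFF per frame and
#'   channel (`{embryo}_t{frame:04d}_c{channel}.tif`) plus a sidecar JSON
#'   with voxel size, frame interval and channel names.
#' @param embryo_id filename prefix.
#' @return invisibly, a list `frames[[frame]][[channel]]` of 3D arrays in
#'   counts.
#' @export
render_frames <- function(truth, imaging, frames,
                          channels = c("green", "red", "wnt"),
                          noise = TRUE, seed = NULL, dir = NULL,
                          embryo_id = "sim") {
  stopifnot(inherits(truth, "ground_truth"), inherits(imaging, "imaging_config"))
  if (!is.null(seed)) set.seed(seed)
  channels <- match.arg(channels, several.ok = TRUE)
  dims <- .field_dims(imaging)
  sig_um <- .psf_sigma_um(imaging)
  sig_vox <- sig_um / imaging$voxel_size_um
  pool_col <- c(green = "pool_green", red = "pool_red", wnt = "wnt_intensity")
  # reject trajectories outside the field
  lo <- imaging$field_origin_um
  hi <- lo + imaging$field_extent_um
  offenders <- integer(0)
  for (cl in truth$cells) {
    sel <- cl$birth_frame <= max(frames) & cl$end_frame >= min(frames)
    if (!sel) next
    fr <- intersect(frames, cl$birth_frame:cl$end_frame)
    if (length(fr) == 0L) next
    P <- cl$pos[fr - cl$birth_frame + 1L, , drop = FALSE]
    if (any(t(P) < lo - 1e-9) || any(t(P) > hi + 1e-9))
      offenders <- c(offenders, cl$cell_id)
  }
  if (length(offenders) > 0)
    .stopf("field too small: cells outside the field: %s",
           paste(unique(offenders), collapse = ", "))
  out <- list()
  maxval <- 2^imaging$bit_depth - 1
  for (f in frames) {
    imgs <- lapply(channels, function(ch) {
      arr <- array(imaging$background_level, dim = dims)
      for (cl in truth$cells) {
        if (f < cl$birth_frame || f > cl$end_frame) next
        k <- f - cl$birth_frame + 1L
        amp <- imaging$gain * cl[[pool_col[[ch]]]][k]
        if (amp <= 0) next
        arr <- .add_blob(arr, .um_to_vox(cl$pos[k, ], imaging), sig_vox, amp)
      }
      if (noise) {
        arr[] <- stats::rpois(length(arr), lambda = pmax(arr, 0)) +
          stats::rnorm(length(arr), sd = imaging$read_sigma)
        arr[] <- pmin(pmax(round(arr), 0), maxval)
      }
      arr
    })
    names(imgs) <- channels
    out[[as.character(f)]] <- imgs
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      for (ch in channels) {
        fn <- file.path(dir, sprintf("%s_t%04d_c%s.tif", embryo_id, f, ch))
        slices <- lapply(seq_len(dims[3]), function(z)
          t(imgs[[ch]][, , z]) / maxval)
        tiff::writeTIFF(slices, fn, bits.per.sample = 16L)
      }
    }
  }
  if (!is.null(dir)) {
    meta <- list(voxel_size_um = imaging$voxel_size_um,
                 dt_s = truth$config$dt_s, channels = channels,
                 field_origin_um = imaging$field_origin_um,
                 bit_depth = imaging$bit_depth)
    jsonlite::write_json(meta, file.path(dir, sprintf("%s_meta.json", embryo_id)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

# add a separable gaussian blob (peak = amp) around voxel centre `cv`
.add_blob <- function(arr, cv, sig_vox, amp, extent = 4) {
  dims <- dim(arr)
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, floor(cv[a] - extent * sig_vox[a]))
    hi <- min(dims[a], ceiling(cv[a] + extent * sig_vox[a]))
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(rng) == 0L)) return(arr)
  gx <- exp(-(rng[[1]] - cv[1])^2 / (2 * sig_vox[1]^2))
  gy <- exp(-(rng[[2]] - cv[2])^2 / (2 * sig_vox[2]^2))
  gz <- exp(-(rng[[3]] - cv[3])^2 / (2 * sig_vox[3]^2))
  blob <- amp * outer(outer(gx, gy), gz)
  arr[rng[[1]], rng[[2]], rng[[3]]] <-
    arr[rng[[1]], rng[[2]], rng[[3]]] + blob
  arr
}

# separable FFT gaussian smoothing of a 3D array (circular boundary)
.gauss_smooth3 <- function(arr, sigma_vox) {
  dims <- dim(arr)
  out <- arr
  for (a in 1:3) {
    if (sigma_vox[a] <= 0) next
    n <- dims[a]
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * sigma_vox[a]^2))
    k <- k / sum(k)
    K <- stats::fft(k)
    perm <- c(a, setdiff(1:3, a))
    m <- aperm(out, perm)
    dm <- dim(m)
    m <- matrix(m, nrow = dm[1])
    M <- stats::mvfft(m)
    M <- M * K
    m <- Re(stats::mvfft(M, inverse = TRUE)) / dm[1]
    dim(m) <- dm
    out <- aperm(m, order(perm))
  }
  out
}

# negated Laplacian with physical spacings (second central differences,
# replicated edges)
.neg_laplacian3 <- function(arr, voxel) {
  shift <- function(a, axis, by) {
    d <- dim(a)
    idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
    if (axis == 1) a[idx, , , drop = FALSE]
    else if (axis == 2) a[, idx, , drop = FALSE]
    else a[, , idx, drop = FALSE]
  }
  out <- array(0, dim(arr))
  for (a in 1:3)
    out <- out + (shift(arr, a, 1L) + shift(arr, a, -1L) - 2 * arr) /
      voxel[a]^2
  -out
}

#' Detect nuclei in a 3D frame
#'
#' Scale-matched blob detection: anisotropic Gaussian smoothing at the PSF
#' scale, a negated Laplacian computed with physical voxel spacings, local
#' maxima above `median + k * MAD` of the response, non-maximum suppression
#' at the PSF scale, and sub-voxel refinement by intensity-weighted centre
#' of mass over a 3-voxel-radius neighbourhood of the background-subtracted
#' frame.
#'
#' @param frame 3D array of counts.
#' @param imaging an [imaging_config()]; supplies voxel anisotropy and the
#'   PSF scale. Required, never assumed isotropic.
#' @param k_mad detection threshold in MADs above the median response.
#' @param frame_index,t_hpf optional annotation columns.
#' @return data.table with columns `frame`, `t_hpf`, `x_um`, `y_um`, `z_um`,
#'   `intensity` and `quality`.
#' @export
detect_nuclei <- function(frame, imaging, k_mad = 5,
                          frame_index = NA_integer_, t_hpf = NA_real_) {
  if (missing(imaging) || !inherits(imaging, "imaging_config"))
    .stopf("anisotropy metadata missing: detect_nuclei requires an imaging_config")
  if (length(dim(frame)) != 3L) .stopf("frame must be a 3D array")
  voxel <- imaging$voxel_size_um
  sig_vox <- .psf_sigma_um(imaging) / voxel
  sm <- .gauss_smooth3(frame, sig_vox)
  resp <- .neg_laplacian3(sm, voxel)
  med <- stats::median(resp)
  # MAD-based threshold with a relative floor so that noise-free frames do
  # not promote numerical ripple to maxima
  thr <- max(med + k_mad * stats::mad(resp),
             med + 0.02 * (max(resp) - med),
             1e-9 * max(abs(frame), 1))
  cand <- .local_maxima3(resp, thr)
  if (nrow(cand) > 0L) {
    # drop candidates within one PSF sigma of the array faces, where the
    # circular smoothing and edge-replicated Laplacian create artifacts
    marg <- pmax(1L, ceiling(sig_vox))
    dims <- dim(frame)
    keep_m <- cand$x > marg[1] & cand$x <= dims[1] - marg[1] &
      cand$y > marg[2] & cand$y <= dims[2] - marg[2] &
      cand$z > marg[3] & cand$z <= dims[3] - marg[3]
    cand <- cand[keep_m, , drop = FALSE]
  }
  if (nrow(cand) == 0L)
    return(data.table::data.table(frame = integer(), t_hpf = numeric(),
                                  x_um = numeric(), y_um = numeric(),
                                  z_um = numeric(), intensity = numeric(),
                                  quality = numeric()))
  # non-maximum suppression within one PSF FWHM (elliptical metric)
  sup_um <- c(imaging$psf_fwhm_um[1], imaging$psf_fwhm_um[1],
              imaging$psf_fwhm_um[2])
  cand <- cand[order(-cand$value), ]
  pos_um <- t(apply(cand[, 1:3, drop = FALSE], 1,
                    function(v) .vox_to_um(v, imaging)))
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d2 <- ((pos_um[j, 1] - pos_um[i, 1]) / sup_um[1])^2 +
        ((pos_um[j, 2] - pos_um[i, 2]) / sup_um[2])^2 +
        ((pos_um[j, 3] - pos_um[i, 3]) / sup_um[3])^2
      keep[j[d2 < 1]] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  # background subtraction for the centroid weights
  bg <- background_subtract(frame)
  dims <- dim(frame)
  res <- lapply(seq_len(nrow(cand)), function(i) {
    v <- as.integer(cand[i, 1:3])
    r <- 3L
    rngs <- lapply(1:3, function(a)
      max(1L, v[a] - r):min(dims[a], v[a] + r))
    w <- bg[rngs[[1]], rngs[[2]], rngs[[3]], drop = FALSE]
    sw <- sum(w)
    # intensity-weighted centre of mass; fall back to the voxel maximum
    cv <- as.numeric(v)
    if (sw > 0) {
      ix <- slice.index(w, 1) + rngs[[1]][1] - 1L
      iy <- slice.index(w, 2) + rngs[[2]][1] - 1L
      iz <- slice.index(w, 3) + rngs[[3]][1] - 1L
      cv <- c(sum(w * ix), sum(w * iy), sum(w * iz)) / sw
    }
    p <- .vox_to_um(cv, imaging)
    data.table::data.table(frame = frame_index, t_hpf = t_hpf,
                           x_um = p[1], y_um = p[2], z_um = p[3],
                           intensity = frame[v[1], v[2], v[3]],
                           quality = cand[i, "value"])
  })
  data.table::rbindlist(res)
}

# local maxima over the 26-neighbourhood (>= all neighbours, > threshold)
.local_maxima3 <- function(resp, thr) {
  dims <- dim(resp)
  ok <- resp > thr
  shift <- function(a, dx, dy, dz) {
    ix <- pmin(pmax(seq_len(dims[1]) + dx, 1L), dims[1])
    iy <- pmin(pmax(seq_len(dims[2]) + dy, 1L), dims[2])
    iz <- pmin(pmax(seq_len(dims[3]) + dz, 1L), dims[3])
    a[ix, iy, iz, drop = FALSE]
  }
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (!any(ok)) break
    ok <- ok & (resp >= shift(resp, dx, dy, dz))
  }
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(x = integer(), y = integer(), z = integer(),
                      value = numeric()))
  data.frame(x = idx[, 1], y = idx[, 2], z = idx[, 3],
             value = resp[idx])
}

#' Match detections to ground truth
#'
#' Greedy nearest-neighbour matching within `r_match_um`, per frame.
#' By convention an empty detection set yields recall 0 and precision 1
#' with `precision_defined = FALSE` flagged in the per-frame table.
#'
#' @param detections data.table with `frame`, `x_um`, `y_um`, `z_um`.
#' @param truth a `ground_truth` (or a track table).
#' @param r_match_um matching radius in micrometres (default 2).
#' @return list with `matches` (detection row, frame, truth `cell_id`),
#'   `per_frame` (precision/recall per frame) and overall `precision`,
#'   `recall`.
#' @export
match_detections_to_truth <- function(detections, truth, r_match_um = 2) {
  det <- data.table::as.data.table(detections)
  tt <- if (inherits(truth, "ground_truth")) track_table(truth)
        else data.table::as.data.table(truth)
  frames <- sort(unique(det$frame))
  frames <- union(frames, sort(unique(tt$frame[tt$frame %in% frames])))
  matches <- list()
  pf <- list()
  for (f in sort(unique(c(det$frame, tt$frame)))) {
    d <- det[det$frame == f]
    g <- tt[tt$frame == f]
    if (nrow(g) == 0L && nrow(d) == 0L) next
    m <- .greedy_match(as.matrix(d[, c("x_um", "y_um", "z_um")]),
                       as.matrix(g[, c("x_um", "y_um", "z_um")]),
                       r_match_um)
    n_match <- nrow(m)
    prec_def <- nrow(d) > 0
    precision <- if (prec_def) n_match / nrow(d) else 1
    recall <- if (nrow(g) > 0) n_match / nrow(g) else NA_real_
    pf[[length(pf) + 1L]] <- data.table::data.table(
      frame = f, n_det = nrow(d), n_true = nrow(g), n_match = n_match,
      precision = precision, recall = recall, precision_defined = prec_def)
    if (n_match > 0)
      matches[[length(matches) + 1L]] <- data.table::data.table(
        frame = f, det_row = m[, 1], cell_id = g$cell_id[m[, 2]],
        dist_um = m[, 3])
  }
  per_frame <- data.table::rbindlist(pf)
  list(matches = data.table::rbindlist(matches),
       per_frame = per_frame,
       precision = if (sum(per_frame$n_det) > 0)
         sum(per_frame$n_match) / sum(per_frame$n_det) else 1,
       recall = if (sum(per_frame$n_true) > 0)
         sum(per_frame$n_match) / sum(per_frame$n_true) else NA_real_)
}

# greedy nearest-neighbour bipartite matching within radius r;
# returns matrix (row_a, row_b, dist)
.greedy_match <- function(A, B, r) {
  if (nrow(A) == 0L || nrow(B) == 0L)
    return(matrix(numeric(0), ncol = 3))
  D <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  D[D < 0] <- 0
  D <- sqrt(D)
  pairs <- which(D <= r, arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(matrix(numeric(0), ncol = 3))
  ord <- order(D[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  usedA <- logical(nrow(A)); usedB <- logical(nrow(B))
  out <- matrix(0, min(nrow(A), nrow(B)), 3)
  nm <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (usedA[i] || usedB[j]) next
    usedA[i] <- TRUE; usedB[j] <- TRUE
    nm <- nm + 1L
    out[nm, ] <- c(i, j, D[i, j])
  }
  out[seq_len(nm), , drop = FALSE]
}
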