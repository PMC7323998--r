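#' Build the geometric embryo frame
#'
#' Constructs the coordinate frame the simulator and the fate analysis share:
#' a spherical eye with the lens at its distal (lateral) pole, an orthonormal
#' anatomical basis, the two NC origin zones and the dorsal periocular
#' cluster centre. The proximodistal unit vector is
#' `u = normalize(lens_center - eye_center)`.
#'
#' Coordinates are micrometres in a right-handed frame with
#' `axis_ap = +x` (anterior), `axis_ml = +y` (lateral, toward the tracked
#' eye) and `axis_dv = +z` (dorsal). With `mirrored = TRUE` the contralateral
#' eye is modelled and `u` flips sign along `axis_ml`.
#'
#' @param config a [simulation_config()].
#' @return an object of class `embryo_model` with fields `eye_center`,
#'   `eye_radius`, `lens_center`, `axis_ap`, `axis_ml`, `axis_dv`, `u`,
#'   `origin_zone_1nc`, `origin_zone_2nc` (gaussian zones with `center` and
#'   `sd`), and `cluster_center`.
#' @export
build_embryo_model <- function(config = simulation_config()) {
  validate_sim_config(config)
  s <- if (config$mirrored) -1 else 1
  axis_ap <- c(1, 0, 0)
  axis_ml <- c(0, 1, 0)
  axis_dv <- c(0, 0, 1)
  R <- config$eye_radius_um
  eye_center <- c(0, s * 1.2 * R, 0)
  lens_center <- eye_center + s * R * axis_ml
  u <- .unit(lens_center - eye_center)
  model <- list(
    eye_center = eye_center,
    eye_radius = R,
    lens_center = lens_center,
    axis_ap = axis_ap, axis_ml = axis_ml, axis_dv = axis_dv,
    u = u,
    # 1NC: lateral stripe of the neural keel, anterior, on the proximal side
    origin_zone_1nc = list(center = eye_center +
                             c(0.6 * R, -s * 1.0 * R, 0),
                           sd = c(0.5 * R, 0.15 * R, 0.15 * R)),
    # 2NC: mediodorsal, diencephalon/mesencephalon level
    origin_zone_2nc = list(center = eye_center +
                             c(0.4 * R, -s * 1.0 * R, 0.9 * R),
                           sd = c(0.25 * R, 0.12 * R, 0.12 * R)),
    cluster_center = eye_center +
      (R + 18) * .unit(0.3 * s * axis_ml + 0.95 * axis_dv),
    mirrored = config$mirrored)
  class(model) <- "embryo_model"
  validate_embryo_model(model)
  model
}

#' @rdname build_embryo_model
#' @param model object to validate.
#' @export
validate_embryo_model <- function(model) {
  stopifnot(inherits(model, "embryo_model"))
  A <- rbind(model$axis_ap, model$axis_ml, model$axis_dv)
  if (max(abs(A %*% t(A) - diag(3))) > 1e-8)
    .stopf("embryo axes are not orthonormal")
  r <- .norm2(model$lens_center - model$eye_center)
  if (abs(r - model$eye_radius) > 1e-6 * model$eye_radius)
    .stopf("lens_center does not lie on the eye sphere (|d| = %.3f, R = %.3f)",
           r, model$eye_radius)
  if (.norm2(model$u) < 1e-12) .stopf("degenerate proximodistal axis")
  invisible(model)
}

#' Signed proximodistal coordinate
#'
#' Projection of positions onto the proximodistal axis, relative to the eye
#' centre; positive values are distal (lens-facing).
#'
#' @param pos numeric 3-vector or n x 3 matrix of positions (micrometres).
#' @param model an `embryo_model`.
#' @return numeric vector of projections.
#' @export
proximodistal_coord <- function(pos, model) {
  p <- if (is.matrix(pos)) pos else matrix(pos, ncol = 3)
  drop((p - matrix(model$eye_center, nrow(p), 3, byrow = TRUE)) %*% model$u)
}

# distance from the eye centre
.eye_dist <- function(pos, model) {
  p <- if (is.matrix(pos)) pos else matrix(pos, ncol = 3)
  sqrt(rowSums((p - matrix(model$eye_center, nrow(p), 3, byrow = TRUE))^2))
}
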