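#' Region specifications
#'
#' Composable, pure geometric predicates over embryo coordinates, used to
#' select cells and count cells in compartments. Each constructor returns a
#' function taking an n x 3 position matrix and returning a logical vector.
#'
#' `region_halfspace` selects the proximal or distal side of the equatorial
#' plane through the eye centre (perpendicular to the centre-to-lens axis);
#' `region_eye_shell` selects the spherical shell of half-thickness
#' `shell_um` around the eye surface; `region_sphere` and `region_box` are
#' primitives; `region_and`, `region_or`, `region_not` compose.
#'
#' @param model an `embryo_model`.
#' @param side `"proximal"` or `"distal"`.
#' @param margin_um dead zone around the equatorial plane.
#' @param shell_um shell half-thickness in micrometres.
#' @param center,radius_um,lower,upper primitive parameters.
#' @param ... regions to compose.
#' @param region a region to negate.
#' @return a predicate function with class `region_spec`.
#' @name region_spec
NULL

.region <- function(f) structure(f, class = c("region_spec", "function"))

#' @rdname region_spec
#' @export
region_halfspace <- function(model, side = c("distal", "proximal"),
                             margin_um = 0) {
  side <- match.arg(side)
  s <- if (side == "distal") 1 else -1
  .region(function(pos) s * proximodistal_coord(pos, model) > margin_um)
}

#' @rdname region_spec
#' @export
region_eye_shell <- function(model, shell_um = 6) {
  .region(function(pos) abs(.eye_dist(pos, model) - model$eye_radius) <=
            shell_um)
}

#' @rdname region_spec
#' @export
region_sphere <- function(center, radius_um) {
  .region(function(pos) {
    p <- if (is.matrix(pos)) pos else matrix(pos, ncol = 3)
    sqrt(rowSums((p - matrix(center, nrow(p), 3, byrow = TRUE))^2)) <=
      radius_um
  })
}

#' @rdname region_spec
#' @export
region_box <- function(lower, upper) {
  .region(function(pos) {
    p <- if (is.matrix(pos)) pos else matrix(pos, ncol = 3)
    apply(t(p) >= lower, 2, all) & apply(t(p) <= upper, 2, all)
  })
}

#' @rdname region_spec
#' @export
region_and <- function(...) {
  rs <- list(...)
  .region(function(pos) Reduce(`&`, lapply(rs, function(r) r(pos))))
}

#' @rdname region_spec
#' @export
region_or <- function(...) {
  rs <- list(...)
  .region(function(pos) Reduce(`|`, lapply(rs, function(r) r(pos))))
}

#' @rdname region_spec
#' @export
region_not <- function(region) .region(function(pos) !region(pos))

#' Build a region from a config description
#'
#' Named primitives with parameters, as stored in run-config JSON, e.g.
#' `list(type = "halfspace", side = "distal")` or
#' `list(type = "and", regions = list(...))`.
#'
#' @param spec list description.
#' @param model an `embryo_model` (needed by eye-relative primitives).
#' @return a `region_spec`.
#' @export
region_from_config <- function(spec, model = NULL) {
  switch(spec$type,
         halfspace = region_halfspace(model, spec$side,
                                      spec$margin_um %||% 0),
         eye_shell = region_eye_shell(model, spec$shell_um %||% 6),
         sphere = region_sphere(unlist(spec$center), spec$radius_um),
         box = region_box(unlist(spec$lower), unlist(spec$upper)),
         and = do.call(region_and, lapply(spec$regions, region_from_config,
                                          model = model)),
         or = do.call(region_or, lapply(spec$regions, region_from_config,
                                        model = model)),
         not = region_not(region_from_config(spec$region, model)),
         .stopf("unknown region type: %s", spec$type))
}

# positions of all segments alive at t_select
.positions_at <- function(forest, t_hpf) {
  p <- forest$positions
  tg <- sort(unique(p$t_hpf))
  f <- tg[.hpf_to_frame(t_hpf, tg)]
  p[p$t_hpf == f]
}

#' Select cells inside a region at a time point
#'
#' @param forest a `lineage_forest`.
#' @param region a `region_spec`.
#' @param t_select_hpf selection time.
#' @return integer vector of segment ids whose position at the nearest
#'   frame to `t_select_hpf` satisfies the region predicate. Warns when no
#'   cell is alive at the selection time.
#' @export
select_cells <- function(forest, region, t_select_hpf) {
  stopifnot(inherits(forest, "lineage_forest"))
  at <- .positions_at(forest, t_select_hpf)
  if (nrow(at) == 0L) {
    .warnf("no cells alive at %.2f hpf", t_select_hpf)
    return(integer(0))
  }
  ok <- region(as.matrix(at[, c("x_um", "y_um", "z_um")]))
  sort(at$cell_id[ok])
}

#' Propagate a selection backward or forward through the lineage forest
#'
#' Backward propagation follows the unique ancestor path of every selected
#' segment; forward propagation collects all descendants. Positions are
#' restricted to the requested time window for trajectory export.
#'
#' @param forest a `lineage_forest`.
#' @param selection integer vector of segment ids.
#' @param t_from,t_to window endpoints in hpf (`t_to < t_from` for
#'   backward, `t_to > t_from` for forward).
#' @param direction `"backward"` or `"forward"`.
#' @return a `lineage_forest` restricted to the propagated segments and the
#'   window.
#' @export
propagate_selection <- function(forest, selection, t_from, t_to,
                                direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  stopifnot(inherits(forest, "lineage_forest"))
  missing_ids <- setdiff(selection, forest$segments$cell_id)
  if (length(missing_ids) > 0)
    .stopf("selection ids absent from forest: %s",
           paste(missing_ids, collapse = ", "))
  if (direction == "backward" && t_to > t_from)
    .stopf("backward propagation requires t_to <= t_from")
  if (direction == "forward" && t_to < t_from)
    .stopf("forward propagation requires t_to >= t_from")
  segs <- forest$segments
  keep <- integer(0)
  if (direction == "backward") {
    for (id in selection) {
      cur <- id
      while (!is.na(cur)) {
        keep <- c(keep, cur)
        cur <- segs$parent_id[match(cur, segs$cell_id)]
      }
    }
  } else {
    kids <- .children_map(segs)
    stack <- as.list(selection)
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      keep <- c(keep, cur)
      for (k in kids[[as.character(cur)]] %||% integer(0))
        stack[[length(stack) + 1L]] <- k
    }
  }
  keep <- unique(keep)
  lo <- min(t_from, t_to); hi <- max(t_from, t_to)
  pos <- forest$positions
  pos <- pos[pos$cell_id %in% keep & pos$t_hpf >= lo - 1e-9 &
               pos$t_hpf <= hi + 1e-9]
  segs2 <- segs[segs$cell_id %in% unique(pos$cell_id)]
  # clip parents that fell outside the window to roots
  segs2 <- data.table::copy(segs2)
  segs2[!segs2$parent_id %in% segs2$cell_id, "parent_id" := NA_integer_]
  lineage_forest(segs2, pos)
}

#' Classify terminal destinations at an evaluation time
#'
#' A terminal cell at position `p` lies in the ocular shell iff
#' `abs(norm(p - c) - R) <= shell_um`; within the shell it is `distal` when
#' its proximodistal projection exceeds `margin_um`, `proximal` when below
#' `-margin_um`, and `proximal` on the equatorial tie (documented
#' convention). Cells outside the shell are `periocular`; terminals dead
#' before `t_eval_hpf` are `unlabelled`.
#'
#' @param forest a `lineage_forest`.
#' @param model an `embryo_model`.
#' @param t_eval_hpf evaluation time.
#' @param shell_um shell half-thickness.
#' @param margin_um equatorial dead zone.
#' @return named character vector (names = terminal segment ids) with
#'   values in `proximal`, `distal`, `periocular`, `unlabelled`.
#' @export
classify_destination <- function(forest, model, t_eval_hpf, shell_um = 6,
                                 margin_um = 0) {
  stopifnot(inherits(forest, "lineage_forest"))
  if (.norm2(model$u) < 1e-12) .stopf("degenerate proximodistal axis")
  terms <- terminal_cells(forest)
  at <- .positions_at(forest, t_eval_hpf)
  at <- at[at$cell_id %in% terms]
  lab <- stats::setNames(rep("unlabelled", length(terms)),
                         as.character(terms))
  if (nrow(at) > 0) {
    P <- as.matrix(at[, c("x_um", "y_um", "z_um")])
    r <- .eye_dist(P, model)
    inshell <- abs(r - model$eye_radius) <= shell_um
    proj <- proximodistal_coord(P, model)
    l <- ifelse(!inshell, "periocular",
                ifelse(proj > margin_um, "distal", "proximal"))
    lab[as.character(at$cell_id)] <- l
  }
  lab
}

#' Lineage homogeneity report
#'
#' A lineage (tree rooted at a founder) is homogeneous when all of its
#' labelled terminals share one label in `{proximal, distal}`, and mixed
#' when both occur. Periocular terminals are ignored for the dichotomy and
#' lineages with no proximal/distal terminal are excluded from the
#' denominator (counted separately).
#'
#' @param forest a `lineage_forest`.
#' @param labels labels from [classify_destination()] (or any named vector
#'   over the forest's terminals).
#' @return an object of class `homogeneity_report` with `n_lineages`,
#'   `n_homogeneous`, `n_mixed`, `n_excluded`, `fraction_homogeneous`,
#'   `percent_homogeneous`, `percent_mixed`, and `per_lineage` (data.table
#'   with label multisets).
#' @export
lineage_homogeneity <- function(forest, labels) {
  stopifnot(inherits(forest, "lineage_forest"))
  terms <- terminal_cells(forest)
  if (!all(as.character(terms) %in% names(labels)))
    .stopf("labels do not cover all terminal segments of the forest")
  lin <- forest$segments$lineage_id[match(terms, forest$segments$cell_id)]
  lab <- labels[as.character(terms)]
  per <- data.table::data.table(lineage_id = lin, label = lab)
  agg <- per[, list(
    n_proximal = sum(label == "proximal"),
    n_distal = sum(label == "distal"),
    n_periocular = sum(label == "periocular"),
    n_unlabelled = sum(label == "unlabelled"),
    labels = list(sort(label))), by = "lineage_id"]
  agg[, "class" := ifelse(agg$n_proximal > 0 & agg$n_distal > 0, "mixed",
                   ifelse(agg$n_proximal + agg$n_distal > 0, "homogeneous",
                          "excluded"))]
  n_hom <- sum(agg$class == "homogeneous")
  n_mix <- sum(agg$class == "mixed")
  n_lin <- n_hom + n_mix
  out <- list(n_lineages = n_lin, n_homogeneous = n_hom, n_mixed = n_mix,
              n_excluded = sum(agg$class == "excluded"),
              fraction_homogeneous = if (n_lin > 0) n_hom / n_lin else NA_real_,
              fraction_mixed = if (n_lin > 0) n_mix / n_lin else NA_real_,
              percent_homogeneous = if (n_lin > 0)
                round_half_up(100 * n_hom / n_lin) else NA_real_,
              percent_mixed = if (n_lin > 0)
                round_half_up(100 * n_mix / n_lin) else NA_real_,
              per_lineage = agg)
  class(out) <- "homogeneity_report"
  out
}

#' @export
print.homogeneity_report <- function(x, ...) {
  cat(sprintf(paste0("<homogeneity_report> %d lineages: %d homogeneous ",
                     "(%d%%), %d mixed (%d%%), %d excluded\n"),
              x$n_lineages, x$n_homogeneous, x$percent_homogeneous,
              x$n_mixed, x$percent_mixed, x$n_excluded))
  invisible(x)
}

#' Penetrance table
#'
#' Tabulates, per genotype, the fraction of embryos showing the migration
#' defect, formatted as `"x% (a/n)"` with the percentage rounded
#' half-away-from-zero to an integer.
#'
#' @param embryo_outcomes data.frame with columns `genotype` and `affected`
#'   (logical).
#' @return an object of class `penetrance_report`: data.table with
#'   `genotype`, `n_affected`, `n_total`, `percent`, `formatted`.
#' @export
penetrance_table <- function(embryo_outcomes) {
  d <- data.table::as.data.table(embryo_outcomes)
  if (!all(c("genotype", "affected") %in% names(d)))
    .stopf("embryo_outcomes needs columns genotype, affected")
  d[, "genotype" := factor(d$genotype, levels = unique(d$genotype))]
  affected <- NULL # data.table NSE
  out <- d[, list(n_affected = sum(affected), n_total = .N), by = "genotype"]
  out[, "percent" := round_half_up(100 * out$n_affected / out$n_total)]
  out[, "formatted" := sprintf("%d%% (%d/%d)", out$percent, out$n_affected,
                               out$n_total)]
  class(out) <- c("penetrance_report", class(out))
  out[]
}

#' Call the neural crest migration defect for one embryo
#'
#' An embryo is affected when fewer than `min_2nc_distal` 2NC-derived cells
#' are classified distal, or when more than `max_1nc_distal` 1NC-derived
#' cells are. The empty forest is affected by convention (flagged).
#'
#' @param forest a `lineage_forest` carrying `population_truth`.
#' @param labels labels from [classify_destination()].
#' @param model an `embryo_model` (unused beyond validation; kept for
#'   signature symmetry with the classification step).
#' @param criteria list with `min_2nc_distal` and `max_1nc_distal`.
#' @return logical; `attr(, "flag")` carries `"empty_forest"` when the
#'   convention was applied.
#' @export
defect_call <- function(forest, labels, model,
                        criteria = list(min_2nc_distal = 1,
                                        max_1nc_distal = 0)) {
  stopifnot(inherits(forest, "lineage_forest"))
  if (nrow(forest$segments) == 0L) {
    out <- TRUE
    attr(out, "flag") <- "empty_forest"
    return(out)
  }
  if (!"population_truth" %in% names(forest$segments))
    .stopf("defect_call needs a population_truth column in the forest")
  terms <- terminal_cells(forest)
  pop <- forest$segments$population_truth[match(terms,
                                                forest$segments$cell_id)]
  lab <- labels[as.character(terms)]
  n2d <- sum(pop == "2NC" & lab == "distal")
  n1d <- sum(pop == "1NC" & lab == "distal")
  n2d < criteria$min_2nc_distal || n1d > criteria$max_1nc_distal
}
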