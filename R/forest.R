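#' Lineage forests and track tables
#'
#' A `lineage_forest` is the division-aware forest all fate and homogeneity
#' statistics operate on. It holds `segments`, one row per cell segment
#' (a track between divisions) with `cell_id`, `parent_id` (NA for roots),
#' `lineage_id` (root id shared by a whole tree), `start_frame`, `end_frame`
#' and optional annotation columns (`population_truth`,
#' `destination_truth`), and `positions`, a long table with one row per
#' (segment, frame): `cell_id`, `frame`, `t_hpf`, `x_um`, `y_um`, `z_um`
#' plus any intensity columns.
#'
#' @param segments data.table/data.frame of segments.
#' @param positions data.table/data.frame of per-frame positions.
#' @return a `lineage_forest`.
#' @export
lineage_forest <- function(segments, positions) {
  segments <- data.table::as.data.table(segments)
  positions <- data.table::as.data.table(positions)
  need <- c("cell_id", "parent_id", "lineage_id", "start_frame", "end_frame")
  if (!all(need %in% names(segments)))
    .stopf("segments must contain columns: %s", paste(need, collapse = ", "))
  needp <- c("cell_id", "frame", "t_hpf", "x_um", "y_um", "z_um")
  if (!all(needp %in% names(positions)))
    .stopf("positions must contain columns: %s", paste(needp, collapse = ", "))
  bad <- setdiff(stats::na.omit(segments$parent_id), segments$cell_id)
  if (length(bad) > 0)
    .stopf("dangling parent_id: %s", paste(bad, collapse = ", "))
  out <- list(segments = segments, positions = positions)
  class(out) <- "lineage_forest"
  out
}

#' @export
print.lineage_forest <- function(x, ...) {
  cat(sprintf("<lineage_forest> %d segments, %d trees, frames %d..%d\n",
              nrow(x$segments), length(unique(x$segments$lineage_id)),
              min(x$positions$frame), max(x$positions$frame)))
  invisible(x)
}

#' Convert simulated ground truth to a lineage forest
#'
#' Every simulated cell record spans birth to division (or recording end),
#' so records map one-to-one onto forest segments.
#'
#' @param truth a `ground_truth` from [simulate_populations()].
#' @param embryo_id identifier written into the positions table.
#' @return a `lineage_forest` whose positions carry the reporter channels
#'   (`ch_green`, `ch_red`, `ch_wnt`) and truth annotations.
#' @export
as_lineage_forest <- function(truth, embryo_id = "sim") {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(truth$cells) == 0L)
    return(lineage_forest(
      data.table::data.table(cell_id = integer(), parent_id = integer(),
                             lineage_id = integer(), start_frame = integer(),
                             end_frame = integer(),
                             population_truth = character(),
                             destination_truth = character()),
      data.table::data.table(embryo_id = character(), cell_id = integer(),
                             frame = integer(), t_hpf = numeric(),
                             x_um = numeric(), y_um = numeric(),
                             z_um = numeric(), ch_green = numeric(),
                             ch_red = numeric(), ch_wnt = numeric())))
  segs <- data.table::rbindlist(lapply(truth$cells, function(cl)
    data.table::data.table(cell_id = cl$cell_id,
                           parent_id = cl$parent_id,
                           lineage_id = cl$lineage_id,
                           start_frame = cl$birth_frame,
                           end_frame = cl$end_frame,
                           population_truth = cl$population,
                           destination_truth = cl$destination_truth)))
  pos <- data.table::rbindlist(lapply(truth$cells, function(cl) {
    fr <- cl$birth_frame:cl$end_frame
    data.table::data.table(embryo_id = embryo_id,
                           cell_id = cl$cell_id,
                           frame = fr,
                           t_hpf = truth$t_hpf[fr + 1L],
                           x_um = cl$pos[, 1], y_um = cl$pos[, 2],
                           z_um = cl$pos[, 3],
                           ch_green = cl$pool_green,
                           ch_red = cl$pool_red,
                           ch_wnt = cl$wnt_intensity)
  }))
  lineage_forest(segs, pos)
}

#' Flatten a lineage forest (or ground truth) to a track table
#'
#' @param forest a `lineage_forest` or `ground_truth`.
#' @return a data.table in the track-table layout: `embryo_id`, `cell_id`,
#'   `parent_id`, `lineage_id`, `frame`, `t_hpf`, `x_um`, `y_um`, `z_um`,
#'   reporter channels where available, and truth annotations where
#'   available.
#' @export
track_table <- function(forest) {
  if (inherits(forest, "ground_truth")) forest <- as_lineage_forest(forest)
  stopifnot(inherits(forest, "lineage_forest"))
  pos <- data.table::copy(forest$positions)
  ann <- c("parent_id", "lineage_id",
           intersect(c("population_truth", "destination_truth"),
                     names(forest$segments)))
  tab <- merge(pos, forest$segments[, c("cell_id", ann), with = FALSE],
               by = "cell_id", sort = FALSE)
  if (!"embryo_id" %in% names(tab)) tab[, "embryo_id" := "sim"]
  data.table::setorderv(tab, c("cell_id", "frame"))
  front <- intersect(c("embryo_id", "cell_id", "parent_id", "lineage_id",
                       "frame", "t_hpf", "x_um", "y_um", "z_um",
                       "ch_green", "ch_red", "ch_wnt",
                       "population_truth", "destination_truth"), names(tab))
  data.table::setcolorder(tab, front)
  tab[]
}

#' Rebuild a lineage forest from a track table
#'
#' @param table a track table as produced by [track_table()] or read by
#'   [read_tracks()].
#' @return a `lineage_forest`.
#' @export
table_to_forest <- function(table) {
  tab <- data.table::as.data.table(table)
  frame <- NULL # data.table NSE
  segcols <- intersect(c("cell_id", "parent_id", "lineage_id",
                         "population_truth", "destination_truth"),
                       names(tab))
  segs <- tab[, c(list(start_frame = min(frame), end_frame = max(frame))),
              by = segcols]
  lineage_forest(segs, tab)
}

# children lookup: list mapping cell_id -> integer vector of child ids
.children_map <- function(segments) {
  kids <- split(segments$cell_id, segments$parent_id)
  kids
}

#' Terminal segments of a forest
#'
#' @param forest a `lineage_forest`.
#' @return integer vector of segment ids without children.
#' @export
terminal_cells <- function(forest) {
  setdiff(forest$segments$cell_id,
          stats::na.omit(forest$segments$parent_id))
}
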