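#' Read and write track tables
#'
#' Track tables are UTF-8 comma-separated files with a mandatory header,
#' "." decimal separator, coordinates in micrometres and times in hpf.
#' Validation rejects duplicate `(cell_id, frame)` rows and `parent_id`
#' values that reference no `cell_id`, reporting the offending rows/ids.
#'
#' @param table a track table (see [track_table()]).
#' @param path file path.
#' @return `read_tracks` returns a validated data.table; `write_tracks`
#'   returns `path` invisibly.
#' @export
write_tracks <- function(table, path) {
  tab <- data.table::as.data.table(table)
  .validate_track_table(tab)
  data.table::fwrite(tab, path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  tab <- data.table::fread(path)
  .validate_track_table(tab)
  tab
}

.validate_track_table <- function(tab) {
  need <- c("cell_id", "frame", "t_hpf", "x_um", "y_um", "z_um")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    .stopf("track table lacks columns: %s", paste(miss, collapse = ", "))
  if (nrow(tab) == 0L) return(invisible(tab))
  dup <- which(duplicated(tab[, c("cell_id", "frame")]))
  if (length(dup) > 0)
    .stopf("duplicate (cell_id, frame) at rows: %s",
           paste(utils::head(dup, 10), collapse = ", "))
  if ("parent_id" %in% names(tab)) {
    dangling <- setdiff(stats::na.omit(unique(tab$parent_id)),
                        unique(tab$cell_id))
    if (length(dangling) > 0)
      .stopf("parent_id references missing cell_id: %s",
             paste(dangling, collapse = ", "))
  }
  bad <- tab[, list(ok = !is.unsorted(t_hpf, strictly = TRUE)),
             by = "cell_id"]
  if (any(!bad$ok))
    .stopf("t_hpf not strictly increasing for cell_id: %s",
           paste(bad$cell_id[!bad$ok], collapse = ", "))
  invisible(tab)
}

# Newick lineage export ----------------------------------------------------

#' Write and read lineage forests as Newick
#'
#' One Newick string per tree, one tree per line. Labels are segment ids and
#' branch lengths are segment durations in hours. `read_lineage_newick`
#' recovers the topology and durations; single-segment trees (which standard
#' phylogenetics parsers reject as degenerate) are handled explicitly.
#'
#' @param forest a `lineage_forest`.
#' @param path file path.
#' @return `write_lineage_newick` returns `path` invisibly;
#'   `read_lineage_newick` returns a data.table with columns `label`,
#'   `parent_label` (NA for roots), `duration_h` and `tree`.
#' @export
write_lineage_newick <- function(forest, path) {
  stopifnot(inherits(forest, "lineage_forest"))
  segs <- forest$segments
  dt_h <- .frame_dt_hours(forest)
  kids <- .children_map(segs)
  dur <- function(id) {
    i <- match(id, segs$cell_id)
    (segs$end_frame[i] - segs$start_frame[i]) * dt_h
  }
  build <- function(id) {
    ch <- kids[[as.character(id)]]
    lab <- sprintf("%s:%.6g", id, dur(id))
    if (is.null(ch) || length(ch) == 0L) return(lab)
    sprintf("(%s)%s", paste(vapply(sort(ch), build, ""), collapse = ","), lab)
  }
  roots <- segs$cell_id[is.na(segs$parent_id)]
  writeLines(paste0(vapply(roots, build, ""), ";"), path)
  invisible(path)
}

.frame_dt_hours <- function(forest) {
  p <- forest$positions
  if (nrow(p) < 2L) return(1)
  tw <- sort(unique(p$t_hpf))
  if (length(tw) < 2L) return(1)
  stats::median(diff(tw))
}

#' @rdname write_lineage_newick
#' @export
read_lineage_newick <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!grepl(";$", ln))
      .stopf("Newick parse error in line %d: missing terminal ';'", i)
    if (!grepl("[(]", ln)) {
      # degenerate single-segment tree: "label:length;"
      m <- regmatches(ln, regexec("^([^(),:;]+):([0-9.eE+-]+);$", ln))[[1]]
      if (length(m) != 3)
        .stopf("Newick parse error in line %d near position 1", i)
      out[[i]] <- data.table::data.table(label = m[2],
                                         parent_label = NA_character_,
                                         duration_h = as.numeric(m[3]),
                                         tree = i)
    } else {
      tr <- tryCatch(ape::read.tree(text = ln), error = function(e) NULL)
      if (is.null(tr))
        .stopf("Newick parse error in line %d near position %d", i,
               regexpr("[(]", ln)[1])
      labs <- c(tr$tip.label, tr$node.label)
      ne <- nrow(tr$edge)
      child_lab <- labs[tr$edge[, 2]]
      parent_lab <- labs[tr$edge[, 1]]
      root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
      root_dur <- tr$root.edge %||% 0
      out[[i]] <- data.table::rbindlist(list(
        data.table::data.table(label = labs[root],
                               parent_label = NA_character_,
                               duration_h = root_dur, tree = i),
        data.table::data.table(label = child_lab,
                               parent_label = parent_lab,
                               duration_h = tr$edge.length %||% rep(NA_real_, ne),
                               tree = i)))
    }
  }
  data.table::rbindlist(out)
}

# config JSON ---------------------------------------------------------------

#' Read a run configuration from JSON
#'
#' The JSON object may contain a `simulation` block (keys of
#' [simulation_config()]), an `imaging` block (keys of [imaging_config()]),
#' an `analysis` block, plus top-level `seed` and `out_dir`. Unknown keys
#' are rejected with a schema message.
#'
#' @param path JSON file.
#' @return list with elements `simulation` (`sim_config`), `imaging`
#'   (`imaging_config`), `analysis` (list), `seed`, `out_dir`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .stopf("no such config file: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known_top <- c("simulation", "imaging", "analysis", "seed", "out_dir")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0)
    .stopf("unknown config keys: %s (allowed: %s)",
           paste(unknown, collapse = ", "), paste(known_top, collapse = ", "))
  sim_args <- raw$simulation %||% list()
  unknown <- setdiff(names(sim_args), names(formals(simulation_config)))
  if (length(unknown) > 0)
    .stopf("unknown simulation config keys: %s", paste(unknown, collapse = ", "))
  img_args <- raw$imaging %||% list()
  unknown <- setdiff(names(img_args), names(formals(imaging_config)))
  if (length(unknown) > 0)
    .stopf("unknown imaging config keys: %s", paste(unknown, collapse = ", "))
  if (!is.null(raw$seed)) sim_args$seed <- raw$seed
  list(simulation = do.call(simulation_config, sim_args),
       imaging = do.call(imaging_config, img_args),
       analysis = raw$analysis %||% list(),
       seed = raw$seed %||% sim_args$seed %||% 1L,
       out_dir = raw$out_dir %||% ".")
}

#' Export simulated ground truth to disk
#'
#' Writes the track CSV (`tracks.csv`), the Newick lineage file
#' (`lineages.nwk`) and the configuration (`config.json`) into `dir`.
#' The files round-trip losslessly through [read_tracks()] and
#' [read_lineage_newick()].
#'
#' @param truth a `ground_truth`.
#' @param dir output directory (created if needed).
#' @param embryo_id identifier column value.
#' @return named character vector of the written paths, invisibly.
#' @export
export_truth <- function(truth, dir, embryo_id = "sim") {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  forest <- as_lineage_forest(truth, embryo_id = embryo_id)
  paths <- c(tracks = file.path(dir, "tracks.csv"),
             lineages = file.path(dir, "lineages.nwk"),
             config = file.path(dir, "config.json"))
  if (nrow(forest$positions) == 0L) {
    data.table::fwrite(forest$positions, paths[["tracks"]])
    writeLines(character(0), paths[["lineages"]])
  } else {
    write_tracks(track_table(forest), paths[["tracks"]])
    write_lineage_newick(forest, paths[["lineages"]])
  }
  cfg <- truth$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
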