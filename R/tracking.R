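#' Link detections across frames into a division-aware track graph
#'
#' Frame-to-frame association solves, per consecutive frame pair, a gated
#' linear assignment problem: candidate pairs within `gate_um` enter with
#' cost equal to their squared distance, and every detection can instead
#' stay unmatched at cost `gate_um^2` (auxiliary rows/columns of the padded
#' cost matrix). The resulting matching maximises the number of gated links
#' while minimising total squared displacement. Detections at t+1 left
#' unassigned but lying within the daughter gate (`daughter_gate_factor *
#' gate_um`) of an already-matched predecessor are attached as second
#' children, marking a division (at most two successors per node). Remaining
#' unmatched detections start new tracks. Finally, track ends are re-joined
#' to later track starts across at most `max_gap_frames` skipped frames by
#' the same assignment rule, with a per-skipped-frame cost penalty.
#'
#' @param detections data.table with columns `frame`, `x_um`, `y_um`, `z_um`
#'   (additional columns are carried through), sorted by frame.
#' @param gate_um gating radius for frame-to-frame links.
#' @param max_gap_frames maximum number of skipped frames bridged by gap
#'   closing (0 disables it).
#' @param daughter_gate_factor multiple of `gate_um` within which a second
#'   daughter may attach to a dividing cell.
#' @param gap_penalty_um2 cost added per skipped frame when gap closing.
#' @return a `track_graph`: list with `nodes` (detections plus `node_id`)
#'   and `edges` (`from`, `to`, `gap` flag).
#' @export
link_frames <- function(detections, gate_um = 10, max_gap_frames = 2,
                        daughter_gate_factor = 1.5,
                        gap_penalty_um2 = gate_um^2 / 4) {
  det <- data.table::as.data.table(detections)
  if (nrow(det) == 0L) {
    g <- list(nodes = det, edges = data.table::data.table(
      from = integer(), to = integer(), gap = logical()))
    class(g) <- "track_graph"
    return(g)
  }
  data.table::setorderv(det, c("frame"))
  det[, "node_id" := seq_len(nrow(det))]
  frames <- sort(unique(det$frame))
  by_frame <- split(det, by = "frame", keep.by = TRUE)
  edges <- list()
  succ_count <- integer(nrow(det))
  pred_count <- integer(nrow(det))
  for (fi in seq_len(length(frames) - 1L)) {
    f0 <- frames[fi]; f1 <- frames[fi + 1L]
    if (f1 != f0 + 1L) next  # only consecutive frames here; gaps closed later
    a <- by_frame[[as.character(f0)]]
    b <- by_frame[[as.character(f1)]]
    A <- as.matrix(a[, c("x_um", "y_um", "z_um")])
    B <- as.matrix(b[, c("x_um", "y_um", "z_um")])
    m <- solve_gated_assignment(A, B, gate_um)
    if (nrow(m) > 0) {
      e <- data.table::data.table(from = a$node_id[m[, 1]],
                                  to = b$node_id[m[, 2]], gap = FALSE)
      edges[[length(edges) + 1L]] <- e
      succ_count[e$from] <- succ_count[e$from] + 1L
      pred_count[e$to] <- pred_count[e$to] + 1L
    }
    # division attachment: an unassigned detection at t+1 may join an
    # already-matched predecessor as its second child. Among candidates
    # within the daughter gate the one whose position best matches the
    # midpoint of the two would-be sisters is chosen (at cytokinesis the
    # mother lies between her daughters).
    un_b <- setdiff(seq_len(nrow(b)), if (nrow(m)) m[, 2] else integer(0))
    if (length(un_b) > 0 && nrow(m) > 0) {
      dgate <- daughter_gate_factor * gate_um
      amat <- m[, 1]; bmat <- m[, 2]
      ok <- succ_count[a$node_id[amat]] == 1L
      if (any(ok)) {
        Pk <- as.matrix(a[amat[ok], c("x_um", "y_um", "z_um"), drop = FALSE])
        S1 <- as.matrix(b[bmat[ok], c("x_um", "y_um", "z_um"), drop = FALSE])
        BIG <- 1e12
        C <- matrix(BIG, length(un_b), sum(ok))
        for (ji in seq_along(un_b)) {
          bj <- B[un_b[ji], ]
          d <- sqrt(rowSums((Pk - matrix(bj, nrow(Pk), 3, byrow = TRUE))^2))
          mid <- (S1 + matrix(bj, nrow(S1), 3, byrow = TRUE)) / 2
          score <- rowSums((Pk - mid)^2)
          C[ji, d <= dgate] <- score[d <= dgate]
        }
        ma <- .solve_padded_lap(C, unmatch_cost = dgate^2, big = BIG)
        if (nrow(ma) > 0) for (k in seq_len(nrow(ma))) {
          pid <- a$node_id[amat[ok][ma[k, 2]]]
          edges[[length(edges) + 1L]] <- data.table::data.table(
            from = pid, to = b$node_id[un_b[ma[k, 1]]], gap = FALSE)
          succ_count[pid] <- succ_count[pid] + 1L
          pred_count[b$node_id[un_b[ma[k, 1]]]] <-
            pred_count[b$node_id[un_b[ma[k, 1]]]] + 1L
        }
      }
    }
  }
  ed <- data.table::rbindlist(c(edges, list(data.table::data.table(
    from = integer(), to = integer(), gap = logical()))))
  # gap closing
  if (max_gap_frames > 0) {
    ends <- det$node_id[succ_count[det$node_id] == 0L &
                          det$frame < max(frames)]
    starts <- det$node_id[pred_count[det$node_id] == 0L &
                            det$frame > min(frames)]
    if (length(ends) > 0 && length(starts) > 0) {
      fe <- det$frame[match(ends, det$node_id)]
      fs <- det$frame[match(starts, det$node_id)]
      E <- as.matrix(det[match(ends, det$node_id),
                         c("x_um", "y_um", "z_um")])
      S <- as.matrix(det[match(starts, det$node_id),
                         c("x_um", "y_um", "z_um")])
      nE <- length(ends); nS <- length(starts)
      BIG <- 1e12
      C <- matrix(BIG, nE, nS)
      for (i in seq_len(nE)) {
        skip <- fs - fe[i] - 1L
        okj <- which(skip >= 1L & skip <= max_gap_frames)
        if (length(okj) == 0L) next
        d2 <- rowSums((S[okj, , drop = FALSE] -
                         matrix(E[i, ], length(okj), 3, byrow = TRUE))^2)
        allowed <- d2 <= (gate_um * (skip[okj] + 1L))^2
        C[i, okj[allowed]] <- d2[allowed] +
          gap_penalty_um2 * skip[okj][allowed]
      }
      m <- .solve_padded_lap(C, unmatch_cost = (2 * gate_um)^2, big = BIG)
      if (nrow(m) > 0) {
        ed <- data.table::rbindlist(list(ed, data.table::data.table(
          from = ends[m[, 1]], to = starts[m[, 2]], gap = TRUE)))
      }
    }
  }
  g <- list(nodes = det, edges = ed)
  class(g) <- "track_graph"
  validate_track_graph(g)
  g
}

#' Gated optimal assignment between two point sets
#'
#' Minimises `sum(d^2)` over matched pairs plus `gate_um^2` per unmatched
#' point, with pairs farther than `gate_um` forbidden. Equivalent to a
#' padded square linear assignment problem, solved exactly.
#'
#' @param A,B numeric matrices (n x 3, m x 3).
#' @param gate_um gating radius.
#' @return 2-column matrix of (row in A, row in B) matches.
#' @export
solve_gated_assignment <- function(A, B, gate_um) {
  n <- nrow(A); m <- nrow(B)
  if (n == 0L || m == 0L) return(matrix(integer(0), ncol = 2))
  D2 <- outer(rowSums(A^2), rep(1, m)) + outer(rep(1, n), rowSums(B^2)) -
    2 * A %*% t(B)
  D2[D2 < 0] <- 0
  BIG <- 1e12
  C <- ifelse(D2 <= gate_um^2, D2, BIG)
  .solve_padded_lap(C, unmatch_cost = gate_um^2, big = BIG)
}

# pad an n x m cost matrix with per-row/column unmatch costs and solve the
# square LAP exactly (Hungarian method via clue::solve_LSAP)
.solve_padded_lap <- function(C, unmatch_cost, big = 1e12) {
  n <- nrow(C); m <- ncol(C)
  if (n == 0L || m == 0L || all(C >= big)) return(matrix(integer(0), ncol = 2))
  P <- matrix(big, n + m, n + m)
  P[seq_len(n), seq_len(m)] <- C
  P[cbind(seq_len(n), m + seq_len(n))] <- unmatch_cost
  P[cbind(n + seq_len(m), seq_len(m))] <- unmatch_cost
  P[n + seq_len(m), m + seq_len(n)] <- 0
  sol <- clue::solve_LSAP(P)
  i <- seq_len(n)
  j <- as.integer(sol)[seq_len(n)]
  keep <- j <= m & C[cbind(i, pmin(j, m))] < big
  cbind(i[keep], j[keep])
}

#' @rdname link_frames
#' @param graph object to validate.
#' @export
validate_track_graph <- function(graph) {
  stopifnot(inherits(graph, "track_graph"))
  ed <- graph$edges
  if (nrow(ed) == 0L) return(invisible(graph))
  ns <- table(ed$from)
  if (any(ns > 2L)) .stopf("node with > 2 successors: %s",
                           paste(names(ns)[ns > 2L], collapse = ", "))
  np <- table(ed$to)
  if (any(np > 1L)) .stopf("node with > 1 predecessor: %s",
                           paste(names(np)[np > 1L], collapse = ", "))
  fr <- graph$nodes$frame[match(ed$from, graph$nodes$node_id)]
  to <- graph$nodes$frame[match(ed$to, graph$nodes$node_id)]
  if (any(to <= fr)) .stopf("edge pointing backwards in time")
  invisible(graph)
}

#' Assemble a lineage forest from a track graph
#'
#' Contracts linear chains of the graph into segments; nodes with two
#' successors become branch points whose children start new segments.
#' Children are ordered deterministically by the planar angle of their first
#' displacement from the parent end, then by node id.
#'
#' @param graph a `track_graph` from [link_frames()].
#' @return a `lineage_forest`; segment positions carry the detection
#'   columns.
#' @export
build_lineages <- function(graph) {
  validate_track_graph(graph)
  det <- graph$nodes
  ed <- graph$edges
  n <- nrow(det)
  # integer successor slots indexed by node_id (<= 2 successors, validated)
  succ1 <- rep(NA_integer_, n); succ2 <- rep(NA_integer_, n)
  if (nrow(ed) > 0) for (k in seq_len(nrow(ed))) {
    f <- ed$from[k]
    if (is.na(succ1[f])) succ1[f] <- ed$to[k] else succ2[f] <- ed$to[k]
  }
  succ_of <- function(id) {
    s <- c(succ1[id], succ2[id])
    s[!is.na(s)]
  }
  roots <- det$node_id[!(det$node_id %in% ed$to)]
  seg_rows <- list(); seg_meta <- list()
  seg_id <- 0L
  # iterative DFS over (start node, parent segment, lineage)
  stack <- lapply(roots, function(r) list(node = r, parent = NA_integer_,
                                          lineage = NA_integer_))
  while (length(stack) > 0L) {
    it <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    seg_id <- seg_id + 1L
    lineage <- if (is.na(it$lineage)) seg_id else it$lineage
    chain <- integer(n); chain[1L] <- it$node; clen <- 1L
    repeat {
      s <- succ_of(chain[clen])
      if (length(s) != 1L) break
      clen <- clen + 1L
      chain[clen] <- s
      if (length(succ_of(s)) == 2L) break
    }
    chain <- chain[seq_len(clen)]
    last <- chain[clen]
    ch <- succ_of(last)
    seg_meta[[seg_id]] <- data.table::data.table(
      cell_id = seg_id, parent_id = it$parent, lineage_id = lineage,
      start_frame = det$frame[match(chain[1], det$node_id)],
      end_frame = det$frame[match(last, det$node_id)])
    seg_rows[[seg_id]] <- data.table::data.table(node_id = chain,
                                                 cell_id = seg_id)
    if (!is.null(ch) && length(ch) == 2L) {
      p_end <- unlist(det[match(last, det$node_id),
                          c("x_um", "y_um", "z_um")])
      ang <- vapply(ch, function(nid) {
        q <- unlist(det[match(nid, det$node_id), c("x_um", "y_um", "z_um")])
        atan2(q[2] - p_end[2], q[1] - p_end[1])
      }, 0)
      ord <- order(ang, ch)
      for (k in rev(ord))
        stack[[length(stack) + 1L]] <- list(node = ch[k], parent = seg_id,
                                            lineage = lineage)
    } else if (!is.null(ch) && length(ch) > 2L) {
      .stopf("node with > 2 successors")
    }
  }
  segs <- data.table::rbindlist(seg_meta)
  map <- data.table::rbindlist(seg_rows)
  pos <- merge(map, det, by = "node_id", sort = FALSE)
  pos[, "node_id" := NULL]
  if (!"t_hpf" %in% names(pos)) pos[, "t_hpf" := as.numeric(pos$frame)]
  data.table::setorderv(pos, c("cell_id", "frame"))
  lineage_forest(segs, pos)
}

#' Score a tracking result against ground truth
#'
#' Detections of the reconstructed forest are matched to truth cells per
#' frame within `r_match_um`; predicted edges are counted correct when the
#' truth connects the two matched cells (same cell across frames, a
#' parent-to-daughter step, or the corresponding chain across a closed gap).
#' Division recall is the fraction of true divisions whose parent end is
#' reconstructed with exactly two successors matching the two daughters.
#'
#' @param truth a `ground_truth`.
#' @param forest a `lineage_forest` reconstructed from detections.
#' @param r_match_um matching radius.
#' @return a list of class `tracking_metrics`: `edge_precision`,
#'   `edge_recall`, `edge_f1`, `division_recall`, `track_purity`,
#'   `destination_misassignment_rate`, `n_pred_edges`, `n_true_edges`.
#' @export
evaluate_tracking <- function(truth, forest, r_match_um = 2) {
  stopifnot(inherits(truth, "ground_truth"), inherits(forest, "lineage_forest"))
  tt <- track_table(truth)
  pos <- forest$positions
  mm <- match_detections_to_truth(pos, tt, r_match_um = r_match_um)
  # map forest rows -> truth cell ids
  key <- rep(NA_integer_, nrow(pos))
  if (nrow(mm$matches) > 0) {
    for (f in unique(mm$matches$frame)) {
      rows_f <- which(pos$frame == f)
      sub <- mm$matches[mm$matches$frame == f]
      key[rows_f[sub$det_row]] <- sub$cell_id
    }
  }
  truth_of <- function(rows) key[rows]
  # predicted edges: consecutive present rows within a segment + parent links
  pr <- data.table::data.table(row = seq_len(nrow(pos)),
                               cell = pos$cell_id, frame = pos$frame)
  data.table::setorderv(pr, c("cell", "frame"))
  same <- pr$cell[-1] == pr$cell[-nrow(pr)]
  pe_from <- pr$row[-nrow(pr)][same]
  pe_to <- pr$row[-1][same]
  segs <- forest$segments
  for (i in seq_len(nrow(segs))) {
    pid <- segs$parent_id[i]
    if (is.na(pid)) next
    r_from <- pr$row[pr$cell == pid][sum(pr$cell == pid)]
    r_to <- pr$row[pr$cell == segs$cell_id[i]][1]
    pe_from <- c(pe_from, r_from); pe_to <- c(pe_to, r_to)
  }
  ta <- truth_of(pe_from); tb <- truth_of(pe_to)
  fa <- pos$frame[pe_from]; fb <- pos$frame[pe_to]
  # truth successor relation across >= 1 frames
  tsegs <- list()
  for (cl in truth$cells) tsegs[[cl$cell_id]] <- cl
  kids <- .children_map(data.table::rbindlist(lapply(truth$cells, function(cl)
    data.table::data.table(cell_id = cl$cell_id,
                           parent_id = cl$parent_id))))
  reachable <- function(cid, f_from, f_to) {
    # truth cells alive at f_to on the descendant path of cid
    res <- integer(0)
    walk <- function(id) {
      cl <- tsegs[[id]]
      if (f_to <= cl$end_frame) { res <<- c(res, id); return(invisible()) }
      for (k in kids[[as.character(id)]] %||% integer(0)) walk(k)
    }
    walk(cid)
    res
  }
  correct <- vapply(seq_along(pe_from), function(i) {
    if (is.na(ta[i]) || is.na(tb[i])) return(FALSE)
    tb[i] %in% reachable(ta[i], fa[i], fb[i])
  }, TRUE)
  n_pred <- length(pe_from)
  # true edges restricted to frames present in the forest reconstruction
  frames_present <- sort(unique(pos$frame))
  tt_sub <- tt[tt$frame %in% frames_present]
  tr <- data.table::data.table(cell = tt_sub$cell_id, frame = tt_sub$frame)
  data.table::setorderv(tr, c("cell", "frame"))
  same_t <- tr$cell[-1] == tr$cell[-nrow(tr)]
  n_true <- sum(same_t)
  truth_div <- 0L; div_found <- 0L
  for (cl in truth$cells) {
    ch <- kids[[as.character(cl$cell_id)]]
    if (is.null(ch) || length(ch) != 2L) next
    if (!(cl$end_frame %in% frames_present)) next
    truth_div <- truth_div + 1L
    n_true <- n_true + 2L
    # find predicted node matching the parent at its end frame
    rows_end <- which(pos$frame == cl$end_frame & key == cl$cell_id)
    ok <- FALSE
    for (r in rows_end) {
      seg <- pos$cell_id[r]
      if (pos$frame[r] != segs$end_frame[match(seg, segs$cell_id)]) next
      daughters <- segs$cell_id[!is.na(segs$parent_id) &
                                  segs$parent_id == seg]
      if (length(daughters) != 2L) next
      dt_truth <- vapply(daughters, function(dd) {
        r1 <- pr$row[pr$cell == dd][1]
        key[r1] %||% NA_integer_
      }, 0L)
      if (setequal(dt_truth[!is.na(dt_truth)], ch) &&
          !any(is.na(dt_truth))) ok <- TRUE
    }
    if (ok) div_found <- div_found + 1L
  }
  # track purity: per predicted segment, modal truth-cell fraction
  purity <- pr[, list(p = {
    kk <- key[row]
    kk <- kk[!is.na(kk)]
    if (length(kk) == 0L) NA_real_ else max(table(kk)) / length(kk)
  }), by = "cell"]
  # destination misassignment: predicted edges joining truth cells whose
  # programmed destinations differ (and which are not a true lineage step)
  dest <- vapply(truth$cells, function(cl) cl$destination_truth, "")
  mis <- vapply(seq_along(pe_from), function(i) {
    if (is.na(ta[i]) || is.na(tb[i])) return(NA)
    dest[ta[i]] != dest[tb[i]] && !correct[i]
  }, TRUE)
  out <- list(edge_precision = if (n_pred > 0) mean(correct) else NA_real_,
              edge_recall = if (n_true > 0) sum(correct) / n_true else NA_real_,
              division_recall = if (truth_div > 0)
                div_found / truth_div else NA_real_,
              track_purity = mean(purity$p, na.rm = TRUE),
              destination_misassignment_rate = mean(mis, na.rm = TRUE),
              n_pred_edges = n_pred, n_true_edges = n_true,
              n_true_divisions = truth_div)
  out$edge_f1 <- if (!is.na(out$edge_precision) && !is.na(out$edge_recall) &&
                     out$edge_precision + out$edge_recall > 0)
    2 * out$edge_precision * out$edge_recall /
      (out$edge_precision + out$edge_recall) else NA_real_
  class(out) <- "tracking_metrics"
  out
}

#' @export
print.tracking_metrics <- function(x, ...) {
  cat(sprintf(paste0("<tracking_metrics> edge P/R/F1 = %.3f/%.3f/%.3f, ",
                     "division recall = %.3f, purity = %.3f\n"),
              x$edge_precision, x$edge_recall, x$edge_f1,
              x$division_recall, x$track_purity))
  invisible(x)
}
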