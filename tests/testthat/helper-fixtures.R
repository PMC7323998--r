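# shared fixtures and independent oracles

# small, fast simulation configs
small_config <- function(...) {
  simulation_config(dt_s = 240, n_1nc = 12, n_2nc = 6, n_entering_2nc = 6,
                    seed = 11, ...)
}

coarse_config <- function(...) simulation_config(dt_s = 240, seed = 1, ...)

# a hand-built lineage forest: `spec` is a list of lineages, each a list of
# terminal labels; every lineage is a root with one segment per terminal
# (plus a root segment when there are >= 2 terminals)
make_label_forest <- function(spec) {
  segs <- list(); pos <- list(); labels <- c()
  nid <- 0L
  for (lin in seq_along(spec)) {
    labs <- spec[[lin]]
    nid <- nid + 1L
    root <- nid
    if (length(labs) == 1L) {
      segs[[length(segs) + 1L]] <- data.frame(
        cell_id = root, parent_id = NA_integer_, lineage_id = root,
        start_frame = 0L, end_frame = 10L)
      pos[[length(pos) + 1L]] <- data.frame(
        cell_id = root, frame = c(0L, 10L), t_hpf = c(0, 10),
        x_um = 0, y_um = 0, z_um = 0)
      labels[as.character(root)] <- labs
    } else {
      segs[[length(segs) + 1L]] <- data.frame(
        cell_id = root, parent_id = NA_integer_, lineage_id = root,
        start_frame = 0L, end_frame = 5L)
      pos[[length(pos) + 1L]] <- data.frame(
        cell_id = root, frame = c(0L, 5L), t_hpf = c(0, 5),
        x_um = 0, y_um = 0, z_um = 0)
      for (l in labs) {
        nid <- nid + 1L
        segs[[length(segs) + 1L]] <- data.frame(
          cell_id = nid, parent_id = root, lineage_id = root,
          start_frame = 6L, end_frame = 10L)
        pos[[length(pos) + 1L]] <- data.frame(
          cell_id = nid, frame = c(6L, 10L), t_hpf = c(6, 10),
          x_um = 0, y_um = 0, z_um = 0)
        labels[as.character(nid)] <- l
      }
    }
  }
  list(forest = lineage_forest(do.call(rbind, segs), do.call(rbind, pos)),
       labels = labels)
}

# brute-force oracle for the gated assignment objective:
# minimise sum(d^2 over matches) + gate^2 * (# unmatched on either side),
# pairs beyond the gate forbidden; returns the minimal total cost
brute_force_gated_cost <- function(A, B, gate) {
  n <- nrow(A); m <- nrow(B)
  D2 <- as.matrix(stats::dist(rbind(A, B)))[seq_len(n), n + seq_len(m),
                                            drop = FALSE]^2
  best <- Inf
  recur <- function(i, used_b, cost) {
    if (cost >= best) return(invisible())
    if (i > n) {
      total <- cost + gate^2 * sum(!used_b)
      if (total < best) best <<- total
      return(invisible())
    }
    # row i unmatched
    recur(i + 1L, used_b, cost + gate^2)
    for (j in seq_len(m)) {
      if (!used_b[j] && D2[i, j] <= gate^2) {
        ub <- used_b; ub[j] <- TRUE
        recur(i + 1L, ub, cost + D2[i, j])
      }
    }
  }
  recur(1L, rep(FALSE, m), 0)
  best
}

gated_assignment_cost <- function(A, B, gate) {
  m <- solve_gated_assignment(A, B, gate)
  n_un <- (nrow(A) - nrow(m)) + (nrow(B) - nrow(m))
  cost <- gate^2 * n_un
  if (nrow(m) > 0)
    cost <- cost + sum(rowSums((A[m[, 1], , drop = FALSE] -
                                  B[m[, 2], , drop = FALSE])^2))
  cost
}

# independent exact oracle for the two-sided rank-sum p value:
# per split, U from pairwise comparisons (+0.5 per tie), two-sided tail of
# |U - nm/2| over all C(N, n) label assignments
exact_ranksum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  N <- nx + ny
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(nx))
  splits <- utils::combn(N, nx)
  us <- apply(splits, 2, u_of)
  mean(abs(us - nx * ny / 2) >= abs(u_obs - nx * ny / 2) - 1e-9)
}

# grid oracle for the circular median objective
grid_median_cost <- function(angles) {
  grid <- 0:359
  min(vapply(grid, function(m)
    sum(crestwave::circular_distance(angles, m)), 0))
}
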