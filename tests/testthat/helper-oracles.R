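# Independent oracles used across the test files.  These deliberately share
# no code with the implementation paths they check.

# ---- lattice-Dijkstra geodesic oracle ---------------------------------------
# Shortest paths on a half-offset 1-mm lattice (no node falls on a wall line)
# with an extended neighbourhood (edges up to `neigh` mm), so the metric
# distortion of the lattice stays well below the comparison tolerance.
# Returns an environment holding the igraph graph and the node coordinates.
.oracle_cache <- new.env(parent = emptyenv())

grid_graph <- function(arena, spacing = 1, neigh = 5) {
  key <- paste(arena$outer_diameter, arena$n_compartments,
               arena$central_opening_diameter, spacing, neigh, sep = "_")
  if (!is.null(.oracle_cache[[key]])) return(.oracle_cache[[key]])
  R <- arena$radius
  xs <- seq(-R + spacing / 2, R, by = spacing)
  nodes <- expand.grid(x = xs, y = xs)
  nodes <- nodes[nodes$x^2 + nodes$y^2 < (R - 1e-6)^2, ]
  nodes$ix <- as.integer(floor((nodes$x + R) / spacing))
  nodes$iy <- as.integer(floor((nodes$y + R) / spacing))
  K <- length(xs) + 2L * neigh + 10L  # stride > max(iy) + neigh: no aliasing
  nodes$key <- nodes$ix * K + nodes$iy
  lookup <- integer(max(nodes$key) + 1L)
  lookup[nodes$key + 1L] <- seq_len(nrow(nodes))
  offs <- expand.grid(dx = -neigh:neigh, dy = 0:neigh)
  offs <- offs[(offs$dy > 0 | (offs$dy == 0 & offs$dx > 0)) &
                 offs$dx^2 + offs$dy^2 <= neigh^2, ]
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    nk <- (nodes$ix + offs$dx[r]) * K + (nodes$iy + offs$dy[r])
    ok <- nk >= 0 & nk < length(lookup)
    j <- integer(nrow(nodes)); j[ok] <- lookup[nk[ok] + 1L]
    has <- which(j > 0)
    if (length(has) == 0) next
    a <- has; b <- j[has]
    if (arena$n_compartments > 0) {
      blocked <- spiderling:::.crosses_any_wall(nodes$x[a], nodes$y[a],
                                                nodes$x[b], nodes$y[b], arena)
      a <- a[!blocked]; b <- b[!blocked]
    }
    from <- c(from, a); to <- c(to, b)
    w <- c(w, sqrt((nodes$x[a] - nodes$x[b])^2 + (nodes$y[a] - nodes$y[b])^2))
  }
  # wall tips as additional vertices so lattice paths can graze the
  # zero-thickness obstacle corners exactly, as continuous shortest paths do
  if (arena$n_compartments > 0) {
    tips <- arena$walls[, c("x1", "y1"), drop = FALSE]
    reach <- 2 * neigh * spacing
    for (k in seq_len(nrow(tips))) {
      tid <- nrow(nodes) + k
      near <- which((nodes$x - tips[k, 1])^2 + (nodes$y - tips[k, 2])^2
                    <= reach^2)
      blocked <- spiderling:::.crosses_any_wall(
        nodes$x[near], nodes$y[near],
        rep(tips[k, 1], length(near)), rep(tips[k, 2], length(near)), arena)
      near <- near[!blocked]
      from <- c(from, rep(tid, length(near)))
      to <- c(to, near)
      w <- c(w, sqrt((nodes$x[near] - tips[k, 1])^2 +
                       (nodes$y[near] - tips[k, 2])^2))
    }
    # tip-to-tip chords lie inside the central opening
    for (k1 in seq_len(nrow(tips) - 1)) for (k2 in (k1 + 1):nrow(tips)) {
      from <- c(from, nrow(nodes) + k1)
      to <- c(to, nrow(nodes) + k2)
      w <- c(w, sqrt(sum((tips[k1, ] - tips[k2, ])^2)))
    }
    nodes <- rbind(nodes,
                   data.frame(x = tips[, 1], y = tips[, 2],
                              ix = NA, iy = NA, key = NA))
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::E(g)$weight <- w
  out <- list(graph = g, nodes = nodes)
  .oracle_cache[[key]] <- out
  out
}

# geodesic distance between lattice nodes i and j (row indices into $nodes)
grid_distance <- function(gg, i, j) {
  as.numeric(igraph::distances(gg$graph, v = i, to = j,
                               algorithm = "dijkstra"))
}

# draw n random lattice nodes at least `margin` mm from walls and boundary
sample_grid_nodes <- function(gg, arena, n, margin = 1.5) {
  nd <- gg$nodes
  ok <- sqrt(nd$x^2 + nd$y^2) < arena$radius - margin
  if (arena$n_compartments > 0) {
    for (k in seq_len(nrow(arena$walls))) {
      ok <- ok & spiderling:::.point_seg_dist(cbind(nd$x, nd$y),
                                              arena$walls[k, 1:2],
                                              arena$walls[k, 3:4]) > margin
    }
  }
  sample(which(ok), n)
}

# ---- exhaustive permutation enumeration -------------------------------------
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# brute-force minimal-total-displacement matching by flat enumeration
brute_force_assignment <- function(frame_a, frame_b, arena) {
  A <- as.matrix(frame_a[, 1:2]); B <- as.matrix(frame_b[, 1:2])
  n <- nrow(A)
  cost <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cost[i, ] <- geodesic_distance(A[rep(i, n), , drop = FALSE], B, arena)
  }
  P <- all_perms(n)
  totals <- apply(P, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  list(total = min(totals), perm = P[which.min(totals), ])
}

# ---- run-length scan oracle -------------------------------------------------
# independent frame-by-frame scan for aggregate lifetimes
scan_lifetimes <- function(dist, dt, threshold, min_duration) {
  durs <- numeric(0); cens <- logical(0)
  run <- 0L
  for (i in seq_along(dist)) {
    if (dist[i] < threshold) {
      run <- run + 1L
    } else if (run > 0L) {
      if (run * dt > min_duration) {
        durs <- c(durs, run * dt); cens <- c(cens, FALSE)
      }
      run <- 0L
    }
  }
  if (run > 0L && run * dt > min_duration) {
    durs <- c(durs, run * dt); cens <- c(cens, TRUE)
  }
  list(durations = durs, censored = cens)
}

# ---- small constructors -----------------------------------------------------
# pair trajectory with a prescribed interindividual distance sequence
pair_from_distances <- function(dist, dt = 1) {
  n <- length(dist)
  a <- tibble::tibble(t_s = (seq_len(n) - 1) * dt, x_mm = 0, y_mm = 0)
  b <- tibble::tibble(t_s = (seq_len(n) - 1) * dt, x_mm = dist, y_mm = 0)
  build_virtual_pair(a, b)
}

# labeled snapshot series from per-step movement schedules; each element of
# `move_steps` gives the (1-based) step indices at which that individual
# displaces by `jump` mm
series_from_schedule <- function(n_frames, move_steps, cadence = 600,
                                 jump = 5) {
  out <- list()
  for (i in seq_along(move_steps)) {
    x <- numeric(n_frames)
    dx <- numeric(n_frames - 1)
    dx[move_steps[[i]]] <- jump
    x[-1] <- cumsum(dx) %% 20  # stay inside a small central patch
    out[[i]] <- tibble::tibble(
      t_s = (seq_len(n_frames) - 1) * cadence, id = i,
      x_mm = x - 10, y_mm = (i - 1) * 3 - 10
    )
  }
  dplyr::bind_rows(out)
}
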