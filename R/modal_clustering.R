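#' Counting-noise density floor
#'
#' Establishes the minimum density required to found a new cluster, so that
#' spurious modes in sparse regions (where the estimate is dominated by
#' counting noise) are suppressed. A window whose length equals the number
#' of grid cells covering the kernel spot (side 4W, i.e.
#' `round((4 W 256)^2)` grid points) slides over the grid points in
#' ascending density order; the floor is the density at the top of the
#' first window whose total event weight exceeds `sigma_noise^2` (9 events
#' at the default sigma = 3). If no window qualifies the floor is `+Inf`
#' and no clusters can be founded.
#'
#' @param density 257 x 257 density array.
#' @param weights Matching weight array (event mass per grid point).
#' @param kernel_sd Current kernel standard deviation W.
#' @param sigma_noise Noise parameter sigma (default 3).
#' @return Scalar density threshold.
#' @export
noise_floor <- function(density, weights, kernel_sd, sigma_noise = 3) {
  L <- max(1L, as.integer(round((4 * kernel_sd * 256)^2)))
  n <- length(density)
  ix <- (seq_len(n) - 1L) %% GRID_N
  iy <- (seq_len(n) - 1L) %/% GRID_N
  ord <- order(density, ix * GRID_N + iy)  # ascending, ties row-major
  w <- weights[ord]
  cs <- cumsum(w)
  if (L >= n) {
    return(if (cs[n] > sigma_noise^2) max(density) else Inf)
  }
  sums <- cs[L:n] - c(0, cs[seq_len(n - L)])
  k <- which(sums > sigma_noise^2)[1]
  if (is.na(k)) return(Inf)
  density[ord[k + L - 1L]]
}

#' Modal clustering of a density grid
#'
#' Partitions the grid into modal clusters above the counting-noise floor.
#' Grid points are visited in descending density order; a point with no
#' cluster-labelled 4-neighbour founds a new cluster (a mode), a point
#' whose labelled 4-neighbours span two clusters becomes a boundary point,
#' and any other point joins its neighbour's cluster. Points below the
#' floor are then absorbed onto the nearest significant cluster through the
#' contiguity marking (7 of 8 surrounding points, rotating the omitted
#' diagonal on a counter modulo 4).
#'
#' @param density 257 x 257 density array.
#' @param threshold Density floor from [noise_floor()].
#' @param config An [epp_config()] (uses `max_clusters`).
#' @return A list of class `epp_grid_labels`: `labels` (257 x 257 integer
#'   matrix; 0 marks boundary points), `n_clusters`, `modes` (tibble with
#'   grid coordinates and density of each founding mode), and `widen`
#'   (TRUE when more than `max_clusters` clusters were founded and the
#'   caller should widen the kernel and restart).
#' @export
cluster_grid <- function(density, threshold, config = epp_config()) {
  scan <- epp_cluster_scan(density, threshold, config$max_clusters)
  modes <- tibble::tibble(
    cluster = seq_along(scan$mode_idx),
    ix = scan$mode_idx %% GRID_N,       # 0-based grid coordinates
    iy = scan$mode_idx %/% GRID_N,
    density = scan$mode_density)
  structure(list(labels = scan$labels, n_clusters = scan$n_clusters,
                 modes = modes, noise_floor = threshold,
                 widen = scan$too_many),
            class = "epp_grid_labels")
}

# ---- cluster graph -------------------------------------------------------

# 8-neighbourhood shifts
NEIGH8 <- cbind(dx = c(1, -1, 0, 0, 1, 1, -1, -1),
                dy = c(0, 0, 1, -1, 1, -1, -1, 1))

# neighbour linear indices (NA outside the grid) for 0-based point indices
shift_idx <- function(idx0, dx, dy) {
  ix <- idx0 %% GRID_N + dx
  iy <- idx0 %/% GRID_N + dy
  out <- ix + GRID_N * iy
  out[ix < 0 | ix >= GRID_N | iy < 0 | iy >= GRID_N] <- NA_integer_
  out
}

# perimeter coordinate of a border grid point (0-based idx), for ordering
# border terminals cyclically
perimeter_pos <- function(idx0) {
  ix <- idx0 %% GRID_N; iy <- idx0 %/% GRID_N
  ifelse(iy == 0, ix,
    ifelse(ix == GRID_N - 1, (GRID_N - 1) + iy,
      ifelse(iy == GRID_N - 1, 2 * (GRID_N - 1) + (GRID_N - 1 - ix),
        3 * (GRID_N - 1) + (GRID_N - 1 - iy))))
}

components_from_pairs <- function(members, pair_a, pair_b) {
  # connected components over `members` (0-based point ids) given adjacency
  # pairs; returns integer component id per member
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(pair_a), to = as.character(pair_b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(members)))
  as.integer(igraph::components(g)$membership[as.character(members)])
}

#' Build the planar cluster graph
#'
#' Groups the boundary points of a modal clustering into edges (chains of
#' boundary points separating exactly two clusters), identifies vertices
#' (points where three or more clusters meet) and border terminations, and
#' verifies planarity through the Euler relation (with border arcs and the
#' exterior face counted when the boundary system touches the grid border).
#'
#' @param grid_labels Result of [cluster_grid()].
#' @param density 257 x 257 density array (for saddle densities).
#' @param config An [epp_config()] (uses `max_edges`).
#' @return A list of class `epp_cluster_graph` with `faces` (tibble:
#'   cluster id, mode position and density), `edges` (list; each edge has
#'   `id`, `faces`, `points` (0-based linear indices), `saddle_density`,
#'   `saddle_point`, `endpoints` (character keys: `"V<k>"` vertices,
#'   `"B<k>"` border terminals)), `n_vertices`, `labels`, and `status`
#'   (`"ok"`, `"widen"`, or `"drop"` when fewer than two clusters exist).
#' @export
build_cluster_graph <- function(grid_labels, density, config = epp_config()) {
  L <- grid_labels$labels
  k <- grid_labels$n_clusters
  out <- list(faces = NULL, edges = list(), n_vertices = 0L,
              labels = L, modes = grid_labels$modes, status = "ok")
  class(out) <- "epp_cluster_graph"
  if (k < 2) { out$status <- "drop"; return(out) }
  out$faces <- tibble::tibble(
    face = seq_len(k),
    mode_point = grid_labels$modes$ix + GRID_N * grid_labels$modes$iy,
    mode_density = grid_labels$modes$density)

  bp <- which(L == 0L) - 1L           # 0-based boundary point indices
  if (length(bp) == 0L) { out$status <- "drop"; return(out) }

  nb <- vapply(seq_len(nrow(NEIGH8)), function(s) {
    ni <- shift_idx(bp, NEIGH8[s, 1], NEIGH8[s, 2])
    val <- rep(NA_integer_, length(bp))
    ok <- !is.na(ni)
    val[ok] <- L[ni[ok] + 1L]
    val
  }, integer(length(bp)))
  if (length(bp) == 1L) nb <- matrix(nb, nrow = 1)

  face_sets <- apply(nb, 1, function(r) sort(unique(r[!is.na(r) & r > 0])),
                     simplify = FALSE)
  n_faces_seen <- lengths(face_sets)
  is_vertex_pt <- n_faces_seen != 2L
  pair_key <- rep(NA_character_, length(bp))
  pair_key[!is_vertex_pt] <- vapply(face_sets[!is_vertex_pt],
                                    function(f) paste(f, collapse = "-"), "")

  # adjacency among boundary points (8-connectivity; both directions kept,
  # harmless for component finding)
  adj_a <- integer(0); adj_b <- integer(0)
  for (s in seq_len(8)) {
    ni <- shift_idx(bp, NEIGH8[s, 1], NEIGH8[s, 2])
    m <- match(ni, bp)
    ok <- !is.na(m)
    adj_a <- c(adj_a, bp[ok]); adj_b <- c(adj_b, bp[m[ok]])
  }

  # vertex components
  v_pts <- bp[is_vertex_pt]
  v_comp <- rep(NA_integer_, length(bp))
  if (length(v_pts)) {
    sel <- adj_a %in% v_pts & adj_b %in% v_pts
    v_comp[is_vertex_pt] <- components_from_pairs(v_pts, adj_a[sel], adj_b[sel])
  }
  n_vertices <- if (length(v_pts)) max(v_comp, na.rm = TRUE) else 0L

  # edge components: same face pair, 8-connected
  e_pts <- bp[!is_vertex_pt]
  edges <- list()
  if (length(e_pts)) {
    both_edge <- adj_a %in% e_pts & adj_b %in% e_pts
    ka <- pair_key[match(adj_a, bp)]; kb <- pair_key[match(adj_b, bp)]
    sel <- both_edge & ka == kb
    comp <- components_from_pairs(e_pts, adj_a[sel], adj_b[sel])
    rm_key <- function(p) (p %% GRID_N) * GRID_N + p %/% GRID_N
    for (ci in sort(unique(comp))) {
      pts <- e_pts[comp == ci]
      dens <- density[pts + 1L]
      best <- order(-dens, rm_key(pts))[1]
      faces <- face_sets[[match(pts[1], bp)]]
      edges[[length(edges) + 1L]] <- list(
        id = length(edges) + 1L, faces = faces, points = pts,
        saddle_density = dens[best], saddle_point = pts[best],
        endpoints = character(0))
    }
  }
  if (length(edges) == 0L) { out$status <- "widen"; return(out) }
  if (length(edges) > config$max_edges) { out$status <- "widen"; return(out) }

  # endpoint keys per edge: chain terminals attach to adjacent vertex
  # components or to the border
  border_keys <- character(0); border_pos <- numeric(0)
  for (ei in seq_along(edges)) {
    pts <- edges[[ei]]$points
    # same-edge neighbour counts to find chain terminals
    if (length(pts) == 1L) {
      terminals <- pts
    } else {
      in_edge <- function(q) !is.na(match(q, pts))
      deg <- rowSums(vapply(seq_len(8), function(s) {
        ni <- shift_idx(pts, NEIGH8[s, 1], NEIGH8[s, 2])
        !is.na(ni) & in_edge(ni)
      }, logical(length(pts))))
      terminals <- pts[deg <= 1L]
    }
    keys <- character(0)
    for (tp in terminals) {
      vk <- unique(stats::na.omit(vapply(seq_len(8), function(s) {
        ni <- shift_idx(tp, NEIGH8[s, 1], NEIGH8[s, 2])
        if (is.na(ni)) return(NA_integer_)
        m <- match(ni, bp)
        if (is.na(m) || !is_vertex_pt[m]) return(NA_integer_)
        v_comp[m]
      }, integer(1))))
      on_border <- (tp %% GRID_N) %in% c(0L, GRID_N - 1L) ||
        (tp %/% GRID_N) %in% c(0L, GRID_N - 1L)
      if (length(vk)) {
        keys <- c(keys, paste0("V", vk))
      } else if (on_border) {
        bkey <- paste0("B", length(border_keys) + 1L)
        border_keys <- c(border_keys, bkey)
        border_pos <- c(border_pos, perimeter_pos(tp))
        keys <- c(keys, bkey)
      } else {
        keys <- c(keys, paste0("D", ei, "_", tp))  # dangling end
      }
    }
    keys <- if (length(keys) > 2L) unique(keys) else keys
    if (length(keys) == 1L && length(terminals) >= 2L) keys <- rep(keys, 2L)
    edges[[ei]]$endpoints <- keys
  }

  dangling <- any(vapply(edges, function(e) any(startsWith(e$endpoints, "D")), TRUE))
  bad_arity <- any(vapply(edges, function(e)
    !(length(e$endpoints) %in% c(0L, 2L)), TRUE))
  if (dangling || bad_arity) { out$status <- "widen"; return(out) }

  out$edges <- edges
  out$n_vertices <- n_vertices
  out$border <- list(keys = border_keys, pos = border_pos)
  if (!euler_ok(out, k)) out$status <- "widen"
  out
}

# Border-inclusive Euler check: V - E + F == 1 + #components, where border
# terminals are degree-1 vertices joined by arcs in cyclic perimeter order
# and the exterior face is counted only when the border is touched.
euler_ok <- function(graph, n_faces) {
  edges <- graph$edges
  ep <- lapply(edges, `[[`, "endpoints")
  loops <- vapply(ep, length, 1L) == 0L
  nodes <- unique(unlist(ep))
  from <- character(0); to <- character(0)
  for (i in seq_along(edges)) {
    if (loops[i]) {
      vn <- paste0("L", i)   # virtual vertex on a closed-loop edge
      nodes <- c(nodes, vn); from <- c(from, vn); to <- c(to, vn)
    } else {
      from <- c(from, ep[[i]][1]); to <- c(to, ep[[i]][2])
    }
  }
  t <- length(graph$border$keys)
  if (t > 0) {
    ordk <- graph$border$keys[order(graph$border$pos)]
    nxt <- c(ordk[-1], ordk[1])
    from <- c(from, ordk); to <- c(to, nxt)
  }
  g <- igraph::graph_from_data_frame(data.frame(from = from, to = to),
                                     directed = FALSE,
                                     vertices = data.frame(name = unique(nodes)))
  V <- length(unique(nodes))
  E <- length(from)
  F <- n_faces + (t > 0)
  C <- igraph::components(g)$no
  (V - E + F) == (1 + C)
}

#' Assign events to clusters
#'
#' Constant-time lookup: each event takes the cluster label of its nearest
#' grid node; boundary nodes are resolved deterministically to the
#' lowest-numbered adjacent cluster.
#'
#' @param x,y Unit-scale event coordinates for the projection.
#' @param labels 257 x 257 label matrix from [cluster_grid()] (0 =
#'   boundary).
#' @return Integer vector of cluster ids, one per event.
#' @export
assign_events <- function(x, y, labels) {
  resolved <- epp_resolve_labels(labels)
  ix <- pmin(pmax(as.integer(round(x * 256)), 0L), 256L)
  iy <- pmin(pmax(as.integer(round(y * 256)), 0L), 256L)
  resolved[cbind(ix + 1L, iy + 1L)]
}
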