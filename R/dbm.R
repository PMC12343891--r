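#' Saddle point of a cluster-graph edge
#'
#' The highest-density point along an edge's boundary chain; ties are
#' broken by row-major grid index. This is the quantity whose dip below the
#' two adjacent mode densities is tested for significance.
#'
#' @param density 257 x 257 density array.
#' @param points Integer vector of 0-based linear grid indices of the
#'   edge's boundary points.
#' @return List with `point` (0-based linear index) and `density`.
#' @export
edge_saddle <- function(density, points) {
  stopifnot(length(points) > 0)
  dens <- density[points + 1L]
  rm_key <- (points %% GRID_N) * GRID_N + points %/% GRID_N
  best <- order(-dens, rm_key)[1]
  list(point = points[best], density = dens[best])
}

#' Density-dip significance test
#'
#' Tests whether the density dip at an edge is statistically significant:
#' both mode densities must exceed the saddle density by `z` standard
#' errors, where `SE^2 = Var(f_mode) + Var(f_saddle)` with the pointwise
#' variance of the kernel estimate taken from the squared-kernel transform
#' pass, and `z` is the one-sided normal quantile at level `alpha`
#' (Bonferroni-corrected by the current number of edges).
#'
#' @param mode_densities Numeric length-2: densities at the two modes the
#'   edge separates.
#' @param mode_points Integer length-2: 0-based linear indices of the modes.
#' @param saddle List from [edge_saddle()].
#' @param variance 257 x 257 pointwise variance array (see
#'   [density_grid()]).
#' @param alpha One-sided significance level.
#' @param n_edges Current edge count for the Bonferroni correction.
#' @param correction `"bonferroni"` or `"none"`.
#' @return Logical: is the dip significant for both modes?
#' @export
dip_significant <- function(mode_densities, mode_points, saddle, variance,
                            alpha = 0.05, n_edges = 1L,
                            correction = "bonferroni") {
  a <- if (correction == "bonferroni") alpha / max(n_edges, 1L) else alpha
  zcrit <- stats::qnorm(1 - a)
  v_s <- variance[saddle$point + 1L]
  all(vapply(1:2, function(i) {
    se <- sqrt(variance[mode_points[i] + 1L] + v_s)
    d <- mode_densities[i] - saddle$density
    if (se == 0) d > 0 else d / se > zcrit
  }, TRUE))
}

# splice chains of edges meeting at degree-2 vertices that now bound the
# same face pair into single edges; drop edges whose two faces merged.
splice_graph <- function(edges) {
  repeat {
    edges <- Filter(function(e) e$faces[1] != e$faces[2], edges)
    if (length(edges) < 2) return(edges)
    # vertex keys (not border/loop) with exactly two incident edge-ends
    ends <- unlist(lapply(edges, `[[`, "endpoints"))
    vkeys <- ends[startsWith(ends, "V")]
    deg <- table(vkeys)
    spliced <- FALSE
    for (vk in names(deg)[deg == 2]) {
      inc <- which(vapply(edges, function(e) vk %in% e$endpoints, TRUE))
      if (length(inc) == 1) {
        # both ends of one edge at vk: it closes into a loop
        if (sum(edges[[inc]]$endpoints == vk) == 2) {
          edges[[inc]]$endpoints <- character(0)
          spliced <- TRUE
          break
        }
        next
      }
      e1 <- edges[[inc[1]]]; e2 <- edges[[inc[2]]]
      if (!setequal(e1$faces, e2$faces)) next   # pathological; leave as is
      rm_one <- function(keys) keys[-match(vk, keys)]  # drop one vk per side
      merged <- list(
        id = min(e1$id, e2$id), faces = e1$faces,
        points = c(e1$points, e2$points),
        endpoints = c(rm_one(e1$endpoints), rm_one(e2$endpoints)),
        mask = (e1$mask %||% 0) + (e2$mask %||% 0))
      edges[[inc[1]]] <- merged
      edges[[inc[2]]] <- NULL
      spliced <- TRUE
      break
    }
    if (!spliced) return(edges)
  }
}

#' Density-based merging of a cluster graph
#'
#' Processes edges in descending saddle-density order; the first edge whose
#' dip is not significant is removed, its two faces merged (the merged
#' face's representative mode is the higher-density of the two, and edges
#' left joining the merged face through a common degree-2 vertex are
#' spliced), and the scan restarts. Terminates when every remaining edge is
#' significant, or when no edges remain (single cluster; the projection is
#' dropped).
#'
#' @param graph An `epp_cluster_graph` from [build_cluster_graph()].
#' @param density 257 x 257 density array.
#' @param variance Matching pointwise variance array.
#' @param config An [epp_config()] (uses `alpha`,
#'   `multiplicity_correction`).
#' @return The pruned graph. `graph$face_map` maps original cluster ids to
#'   merged face ids; `graph$status` becomes `"drop"` if no edges survive.
#' @export
merge_insignificant <- function(graph, density, variance,
                                config = epp_config()) {
  stopifnot(inherits(graph, "epp_cluster_graph"))
  faces <- graph$faces
  face_map <- stats::setNames(faces$face, faces$face)
  edges <- graph$edges
  for (i in seq_along(edges)) {
    s <- edge_saddle(density, edges[[i]]$points)
    edges[[i]]$saddle_density <- s$density
    edges[[i]]$saddle_point <- s$point
  }
  repeat {
    if (length(edges) == 0) break
    ord <- order(-vapply(edges, `[[`, 0, "saddle_density"),
                 vapply(edges, `[[`, 0L, "id"))
    removed <- FALSE
    for (oi in ord) {
      e <- edges[[oi]]
      fa <- e$faces[1]; fb <- e$faces[2]
      ia <- match(fa, faces$face); ib <- match(fb, faces$face)
      sig <- dip_significant(
        mode_densities = c(faces$mode_density[ia], faces$mode_density[ib]),
        mode_points = c(faces$mode_point[ia], faces$mode_point[ib]),
        saddle = list(point = e$saddle_point, density = e$saddle_density),
        variance = variance, alpha = config$alpha,
        n_edges = length(edges), correction = config$multiplicity_correction)
      if (!sig) {
        keep <- min(fa, fb); gone <- max(fa, fb)
        ig <- match(gone, faces$face); ik <- match(keep, faces$face)
        if (faces$mode_density[ig] > faces$mode_density[ik]) {
          faces$mode_density[ik] <- faces$mode_density[ig]
          faces$mode_point[ik] <- faces$mode_point[ig]
        }
        faces <- faces[-ig, ]
        face_map[face_map == gone] <- keep
        edges[[oi]] <- NULL
        for (j in seq_along(edges)) {
          f <- edges[[j]]$faces
          f[f == gone] <- keep
          edges[[j]]$faces <- sort(f)
        }
        edges <- splice_graph(edges)
        for (j in seq_along(edges)) {
          s <- edge_saddle(density, edges[[j]]$points)
          edges[[j]]$saddle_density <- s$density
          edges[[j]]$saddle_point <- s$point
        }
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  graph$faces <- faces
  graph$edges <- edges
  graph$face_map <- face_map
  if (length(edges) == 0) graph$status <- "drop"
  graph
}
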