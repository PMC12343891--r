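#' Boundary score
#'
#' Estimated number of events within a strip of half-width W along the
#' boundary: the density integrated along the boundary grid points times
#' the strip width, scaled by the population size. The scaling is
#' approximate; only the ordering of scores matters for selection.
#'
#' @param density 257 x 257 density array.
#' @param n_events Population size.
#' @param points 0-based linear indices of all boundary grid points of the
#'   candidate.
#' @param kernel_sd Current kernel width W.
#' @return Nonnegative scalar score.
#' @export
score_boundary <- function(density, n_events, points, kernel_sd) {
  n_events * sum(density[points + 1L]) * (2 * kernel_sd * GRID_STEP)
}

#' Balance adjustment of a boundary score
#'
#' In `best_balance` mode the raw score is divided by the balance factor
#' `4 P (1 - P)`, penalizing unbalanced splits; in `best_separation` mode
#' the raw score is used as is.
#'
#' @param raw_score Raw boundary score.
#' @param P Fraction of events on the smaller-indexed side, in (0, 1).
#' @param mode `"best_balance"` or `"best_separation"`.
#' @return Adjusted score (`NA` for degenerate P of 0 or 1).
#' @export
balance_adjust <- function(raw_score, P, mode = "best_balance") {
  if (mode == "best_separation") return(raw_score)
  if (P <= 0 || P >= 1) return(NA_real_)
  raw_score / (4 * P * (1 - P))
}

#' Select the best split among scored candidates
#'
#' Minimum adjusted score wins; ties break deterministically by dimension
#' pair and then by the numeric value of the boundary's edge mask.
#'
#' @param candidates A data frame with columns `i`, `j`, `edge_mask`,
#'   `adjusted_score` (and any carry-along columns).
#' @return The winning row, or `NULL` if the list is empty.
#' @export
select_best_split <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NULL)
  candidates <- candidates[!is.na(candidates$adjusted_score), , drop = FALSE]
  if (nrow(candidates) == 0) return(NULL)
  ord <- order(candidates$adjusted_score, candidates$i, candidates$j,
               candidates$edge_mask)
  candidates[ord[1], , drop = FALSE]
}

# Full analysis of one projection: adaptive density estimation, modal
# clustering (widening on signals), DBM pruning, candidate enumeration and
# scoring. Returns status "none" (no usable separation) or "ok" plus the
# scored candidates and the event-to-face assignment.
pair_analysis <- function(x, y, config) {
  grid <- density_grid(x, y, config$initial_kernel_sd)
  repeat {
    nf <- noise_floor(grid$density, grid$weights, grid$kernel_sd,
                      config$sigma_noise)
    gl <- cluster_grid(grid$density, nf, config)
    status <- if (gl$widen) "widen" else "ok"
    graph <- NULL
    if (status == "ok") {
      if (gl$n_clusters < 2) return(list(status = "none", passes = grid$pass_count))
      graph <- build_cluster_graph(gl, grid$density, config)
      status <- graph$status
    }
    if (status == "widen") {
      if (grid$pass_count >= config$max_widening_passes)
        return(list(status = "none", passes = grid$pass_count))
      grid <- widen_kernel(grid, config$max_widening_passes)
      next
    }
    if (status == "drop") return(list(status = "none", passes = grid$pass_count))

    graph <- merge_insignificant(graph, grid$density, grid$variance, config)
    if (graph$status == "drop" || nrow(graph$faces) < 2)
      return(list(status = "none", passes = grid$pass_count))

    ev_cluster <- assign_events(x, y, graph$labels)
    face_of_event <- graph$face_map[as.character(ev_cluster)]
    face_weights <- table(factor(face_of_event, levels = graph$faces$face))

    # tag edges with their bit for mask bookkeeping
    for (k in seq_along(graph$edges)) graph$edges[[k]]$mask <- 2^(k - 1)
    cands <- enumerate_candidates(dualize(graph), graph)
    if (length(cands) == 0) return(list(status = "none", passes = grid$pass_count))

    scored <- purrr::map_dfr(cands, function(cd) {
      pts <- unlist(lapply(graph$edges[cd$edge_ids], `[[`, "points"))
      raw <- score_boundary(grid$density, grid$n_events, pts, grid$kernel_sd)
      wl <- sum(face_weights[as.character(cd$left)])
      P <- wl / grid$n_events
      tibble::tibble(edge_mask = cd$edge_mask,
                     edge_ids = list(cd$edge_ids),
                     left = list(cd$left), right = list(cd$right),
                     raw_score = raw, P = P,
                     adjusted_score = balance_adjust(raw, P, config$mode))
    })
    return(list(status = "ok", grid = grid, graph = graph,
                candidates = scored, ev_cluster = ev_cluster,
                face_of_event = face_of_event, passes = grid$pass_count))
  }
}

#' Exhaustive projection pursuit gating
#'
#' Recursively finds the statistically best two-dimensional split of the
#' event population across all qualified dimension pairs, terminating in
#' algorithmic phenotypes (leaves that admit no statistically supported
#' separation). Each node qualifies its dimensions, estimates the density
#' of every qualified pair, clusters it modally (widening the kernel on
#' overload), prunes insignificant separations by the density-dip test,
#' enumerates every continuous two-region boundary, scores them, and
#' applies the globally best split; both children are analyzed the same
#' way. The pipeline is deterministic: identical input and configuration
#' give an identical tree.
#'
#' @param events An `epp_events` table from [as_event_matrix()] /
#'   [read_events()], or any data frame of unit-scale values (all columns
#'   then count as phenotyping dimensions).
#' @param config An [epp_config()].
#' @return An `epp_fit` object; see [tidy.epp_fit()], [glance.epp_fit()],
#'   [epp_assignments()], [write_epp_outputs()].
#' @examples
#' ev <- generate_mixture(n_events = 2000, seed = 1)
#' fit <- epp(ev, epp_config(min_qualify_n = 100))
#' glance(fit)
#' @export
epp <- function(events, config = epp_config()) {
  if (!inherits(events, "epp_events")) events <- as_event_matrix(events)
  pheno <- phenotyping_dims(events)
  if (length(pheno) < 2)
    stop("at least 2 phenotyping dimensions are required")
  E <- as.matrix(events[, pheno, drop = FALSE])
  n_root <- nrow(E)
  state <- new.env(parent = emptyenv())
  state$nodes <- list()
  state$leaf_count <- 0L
  state$assignment <- integer(n_root)

  analyze <- function(rows, depth, parent) {
    id <- length(state$nodes) + 1L
    node <- list(id = id, parent = parent, depth = depth,
                 n_events = length(rows), rows = rows, is_leaf = TRUE,
                 phenotype = NA_integer_)
    state$nodes[[id]] <- node
    min_n <- max(config$min_events_absolute,
                 ceiling(config$min_events_relative * n_root), 2L)
    best <- NULL; pr <- NULL
    if (length(rows) >= min_n) {
      sub <- tibble::as_tibble(as.data.frame(E[rows, , drop = FALSE]))
      qp <- qualify_and_pair(sub, config)
      all_cands <- NULL; analyses <- list()
      for (pi in seq_len(nrow(qp$pairs))) {
        i <- qp$pairs[pi, 1]; j <- qp$pairs[pi, 2]
        pa <- pair_analysis(E[rows, i], E[rows, j], config)
        if (pa$status != "ok") next
        key <- paste(i, j)
        analyses[[key]] <- pa
        cc <- pa$candidates
        cc$i <- i; cc$j <- j
        all_cands <- dplyr::bind_rows(all_cands, cc)
      }
      best <- select_best_split(all_cands)
      if (!is.null(best)) pr <- analyses[[paste(best$i, best$j)]]
    }
    if (is.null(best)) {
      state$leaf_count <- state$leaf_count + 1L
      state$nodes[[id]]$phenotype <- state$leaf_count
      state$assignment[rows] <- state$leaf_count
      return(id)
    }
    left_faces <- best$left[[1]]
    on_left <- pr$face_of_event %in% left_faces
    gates <- gate_polygons(pr$graph$labels, pr$graph$face_map, left_faces,
                           tolerance = config$polygon_tolerance)
    node <- state$nodes[[id]]
    node$is_leaf <- FALSE
    node$pair <- c(best$i, best$j)
    node$pair_names <- pheno[c(best$i, best$j)]
    node$kernel_sd <- pr$grid$kernel_sd
    node$passes <- pr$passes
    node$raw_score <- best$raw_score
    node$adjusted_score <- best$adjusted_score
    node$P <- best$P
    node$edge_mask <- best$edge_mask
    node$boundary_points <- unlist(lapply(pr$graph$edges[best$edge_ids[[1]]],
                                          `[[`, "points"))
    node$gate_left <- gates$left
    node$gate_right <- gates$right
    state$nodes[[id]] <- node
    # depth-first, lower-weight child first
    kids <- list(left = rows[on_left], right = rows[!on_left])
    ord <- order(c(length(kids$left), length(kids$right)))
    child_ids <- c(NA_integer_, NA_integer_)
    for (kk in ord)
      child_ids[kk] <- analyze(kids[[kk]], depth + 1L, id)
    state$nodes[[id]]$children <- child_ids  # (left, right)
    id
  }
  analyze(seq_len(n_root), 0L, NA_integer_)
  structure(list(nodes = state$nodes, events = events, pheno = pheno,
                 assignment = state$assignment,
                 n_leaves = state$leaf_count, config = config),
            class = "epp_fit")
}

#' @export
print.epp_fit <- function(x, ...) {
  cat(sprintf("<epp_fit> %d events, %d nodes, %d algorithmic phenotypes\n",
              nrow(x$events), length(x$nodes), x$n_leaves))
  invisible(x)
}
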