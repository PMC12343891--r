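#' Ramer-Douglas-Peucker polyline simplification
#'
#' Reduces a vertex list while guaranteeing that every removed vertex lies
#' within `tolerance` (perpendicular distance) of the simplified polyline;
#' endpoints are always preserved. Used to report gate polygons at 1% of
#' full scale by default.
#'
#' @param points Two-column matrix of vertices (unit coordinates).
#' @param tolerance Maximum allowed deviation, as a fraction of full scale.
#' @return The simplified two-column matrix.
#' @export
simplify_polygon <- function(points, tolerance = 0.01) {
  points <- as.matrix(points)
  if (nrow(unique(points)) < 3) return(points)
  keep <- logical(nrow(points))
  keep[c(1, nrow(points))] <- TRUE
  rdp <- function(i1, i2) {
    if (i2 - i1 < 2) return()
    p1 <- points[i1, ]; p2 <- points[i2, ]
    seg <- p2 - p1
    len2 <- sum(seg^2)
    idx <- (i1 + 1):(i2 - 1)
    rel <- sweep(points[idx, , drop = FALSE], 2, p1)
    d <- if (len2 == 0) sqrt(rowSums(rel^2)) else
      abs(rel[, 1] * seg[2] - rel[, 2] * seg[1]) / sqrt(len2)
    k <- which.max(d)
    if (d[k] > tolerance) {
      keep[idx[k]] <<- TRUE
      rdp(i1, idx[k]); rdp(idx[k], i2)
    }
  }
  rdp(1, nrow(points))
  points[keep, , drop = FALSE]
}

# polygon outline of one side of a split, traced from the child-region
# grid mask by marching squares (grid padded with an exterior ring so
# regions touching the border close along it), then RDP-simplified.
region_polygon <- function(mask, tolerance) {
  P <- matrix(0, GRID_N + 2, GRID_N + 2)
  P[2:(GRID_N + 1), 2:(GRID_N + 1)] <- mask * 1
  xs <- (-1:GRID_N) / 256
  cl <- grDevices::contourLines(xs, xs, P, levels = 0.5)
  if (length(cl) == 0) return(NULL)
  area <- vapply(cl, function(cc) {
    x <- cc$x; y <- cc$y
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, 0)
  cc <- cl[[which.max(area)]]
  poly <- cbind(pmin(pmax(cc$x, 0), 1), pmin(pmax(cc$y, 0), 1))
  simplify_polygon(poly, tolerance)
}

# gate polygons for the two children of a split
gate_polygons <- function(labels, face_map, left_faces, tolerance = 0.01) {
  resolved <- epp_resolve_labels(labels)
  face_of_point <- matrix(face_map[as.character(resolved)], GRID_N, GRID_N)
  left_mask <- matrix(face_of_point %in% left_faces, GRID_N, GRID_N)
  list(left = region_polygon(left_mask, tolerance),
       right = region_polygon(!left_mask, tolerance))
}

# Mahalanobis distance from a population's center over the phenotyping
# dimensions; singular covariances are ridge-regularized.
mahal_distance <- function(X, center = colMeans(X), cov_mat = NULL) {
  X <- as.matrix(X)
  if (is.null(cov_mat)) cov_mat <- stats::cov(X)
  if (nrow(X) < 2 || any(!is.finite(cov_mat))) return(rep(0, nrow(X)))
  ok <- tryCatch({ solve(cov_mat); TRUE }, error = function(e) FALSE)
  if (!ok || min(eigen(cov_mat, only.values = TRUE)$values) < 1e-12) {
    warning("singular covariance; applying ridge regularization")
    cov_mat <- cov_mat + diag(1e-6 * sum(diag(cov_mat)), ncol(X))
  }
  sqrt(stats::mahalanobis(X, center, cov_mat))
}

#' Per-event phenotype assignments
#'
#' One row per retained event: the algorithmic-phenotype (leaf) identifier
#' and the Mahalanobis distance of the event from its leaf's center (mean
#' and covariance over the phenotyping dimensions of the leaf's events).
#'
#' @param fit An `epp_fit` from [epp()].
#' @return Tibble with columns `event_index`, `cluster_id`, `mahalanobis`.
#' @export
epp_assignments <- function(fit) {
  X <- as.matrix(fit$events[, fit$pheno, drop = FALSE])
  md <- numeric(nrow(X))
  for (leaf in sort(unique(fit$assignment))) {
    idx <- which(fit$assignment == leaf)
    md[idx] <- if (length(idx) > length(fit$pheno)) mahal_distance(X[idx, , drop = FALSE]) else 0
  }
  tibble::tibble(event_index = seq_len(nrow(X)),
                 cluster_id = fit$assignment,
                 mahalanobis = md)
}

# heuristic +/- leaf labels from leaf vs parent medians (non-normative)
leaf_label <- function(fit, node) {
  if (is.na(node$parent)) return("all")
  X <- as.matrix(fit$events[, fit$pheno, drop = FALSE])
  pm <- apply(X[fit$nodes[[node$parent]]$rows, , drop = FALSE], 2, stats::median)
  lm <- apply(X[node$rows, , drop = FALSE], 2, stats::median)
  paste0(fit$pheno, ifelse(lm >= pm, "+", "-"), collapse = "")
}

tree_to_list <- function(fit, id) {
  node <- fit$nodes[[id]]
  out <- list(node = node$id, n_events = node$n_events)
  if (node$is_leaf) {
    out$phenotype <- node$phenotype
    out$label <- leaf_label(fit, node)
  } else {
    poly_df <- function(p) if (is.null(p)) NULL else
      list(x = round(p[, 1], 6), y = round(p[, 2], 6))
    out$dimensions <- as.list(node$pair_names)
    out$score <- round(node$raw_score, 6)
    out$adjusted_score <- round(node$adjusted_score, 6)
    out$P <- round(node$P, 6)
    out$kernel_sd <- node$kernel_sd
    out$gates <- list(left = poly_df(node$gate_left),
                      right = poly_df(node$gate_right))
    out$children <- list(tree_to_list(fit, node$children[1]),
                         tree_to_list(fit, node$children[2]))
  }
  out
}

#' Write the gating tree and per-event assignments
#'
#' Serializes the gating tree as JSON (node ids, dimension pairs, boundary
#' scores, balance fractions, simplified gate polygons per child, leaf
#' phenotype ids with heuristic labels) and the per-event assignments as
#' CSV with columns `event_index`, `cluster_id`, `mahalanobis`. Both files
#' are byte-stable across reruns on the same input.
#'
#' @param fit An `epp_fit`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_epp_outputs <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tree_path <- file.path(dir, "gating_tree.json")
  csv_path <- file.path(dir, "assignments.csv")
  json <- jsonlite::toJSON(tree_to_list(fit, 1L), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  writeLines(json, tree_path)
  asg <- epp_assignments(fit)
  asg$mahalanobis <- round(asg$mahalanobis, 9)
  utils::write.csv(asg, csv_path, row.names = FALSE, quote = FALSE)
  invisible(c(tree = tree_path, csv = csv_path))
}

#' Match table between two partitions
#'
#' Counts shared events for every pair of populations across two
#' partitions of the same event universe (e.g. reference gating versus
#' algorithmic phenotypes).
#'
#' @param labels_a,labels_b Vectors of population labels, same length.
#' @return Tibble with columns `a`, `b`, `n`; row/column marginals equal
#'   the population sizes.
#' @export
match_table <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("partitions cover different event universes")
  tab <- table(a = labels_a, b = labels_b)
  out <- tibble::as_tibble(as.data.frame(tab, stringsAsFactors = FALSE))
  names(out) <- c("a", "b", "n")
  out
}

#' Jaccard similarity of two event sets
#'
#' `|A intersect B| / |A union B|`.
#'
#' @param a,b Vectors of event indices (or logical masks of equal length).
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  if (is.logical(a)) a <- which(a)
  if (is.logical(b)) b <- which(b)
  u <- length(union(a, b))
  if (u == 0) stop("Jaccard similarity of two empty sets is undefined")
  length(intersect(a, b)) / u
}

#' Central similarity of two event sets
#'
#' The Jaccard similarity restricted to the central fraction (default 80%)
#' of the union `A or B`, ranked by Mahalanobis distance from the union's
#' mean over the phenotyping dimensions. Peripheral disagreements between
#' two delineations of the same phenotype are discounted, so the central
#' similarity of two sets representing the same population is at least
#' their plain Jaccard similarity.
#'
#' @param a,b Vectors of event indices into `events`.
#' @param events Event table (an `epp_events` or data frame); phenotyping
#'   dimensions are used for the distance.
#' @param central_fraction Fraction of the union retained (default 0.8);
#'   1.0 reproduces the plain Jaccard similarity.
#' @return Similarity in `[0, 1]`.
#' @export
central_similarity <- function(a, b, events, central_fraction = 0.8) {
  u <- union(a, b)
  if (length(u) == 0) stop("central similarity of two empty sets is undefined")
  if (central_fraction >= 1) return(jaccard(a, b))
  dims <- if (inherits(events, "epp_events")) phenotyping_dims(events)
          else colnames(events)
  X <- as.matrix(events[u, dims, drop = FALSE])
  d <- mahal_distance(X)
  core <- u[d <= stats::quantile(d, central_fraction)]
  jaccard(intersect(a, core), intersect(b, core))
}
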