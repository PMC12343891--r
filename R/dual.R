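#' Dual of a cluster graph
#'
#' The graph-theoretic dual exchanges faces for nodes: one dual node per
#' cluster (face), one dual edge per cluster-graph edge. Dual edges carry a
#' composite bitmask over the original edges (singletons initially); nodes
#' carry the set of original faces they represent. Because at most 32
#' edges are allowed, masks fit exactly in a 32-bit word; they are stored
#' as doubles holding sums of distinct powers of two, so Boolean OR of the
#' always-disjoint composites is ordinary addition.
#'
#' @param graph An `epp_cluster_graph` (after [merge_insignificant()]).
#' @return A list of class `epp_dual`: `nodes` (list of face-id vectors),
#'   `eu`, `ev` (node indices per dual edge), `mask`, `min_bit`, `max_bit`
#'   (per dual edge), `removed_max`.
#' @export
dualize <- function(graph) {
  faces <- graph$faces$face
  edges <- graph$edges
  stopifnot(length(faces) >= 2, length(edges) >= 1, length(edges) <= 32)
  nodes <- as.list(faces)
  eu <- ev <- integer(length(edges))
  for (k in seq_along(edges)) {
    eu[k] <- match(edges[[k]]$faces[1], faces)
    ev[k] <- match(edges[[k]]$faces[2], faces)
  }
  structure(list(nodes = nodes, eu = eu, ev = ev,
                 mask = 2^(seq_along(edges) - 1),
                 min_bit = seq_along(edges) - 1L,
                 max_bit = seq_along(edges) - 1L,
                 removed_max = -1L),
            class = "epp_dual")
}

# merge parallel dual edges (same unordered node pair) by OR-ing masks
merge_parallel <- function(st) {
  a <- pmin(st$eu, st$ev); b <- pmax(st$eu, st$ev)
  key <- paste(a, b)
  if (!anyDuplicated(key)) return(st)
  grp <- match(key, unique(key))
  st$eu <- a[!duplicated(key)]
  st$ev <- b[!duplicated(key)]
  st$mask <- as.numeric(tapply(st$mask, grp, sum))
  st$min_bit <- as.integer(tapply(st$min_bit, grp, min))
  st$max_bit <- as.integer(tapply(st$max_bit, grp, max))
  st
}

#' One dual-graph simplification step
#'
#' Removes the `k`-th dual edge and merges its two endpoint nodes; any dual
#' edges that then join the same node pair merge by OR-ing their composite
#' masks (the cluster-graph counterpart is splicing two edges at a common
#' vertex). Node count decreases by exactly one.
#'
#' @param st An `epp_dual` state.
#' @param k Index of the dual edge to remove.
#' @return The simplified `epp_dual` state.
#' @export
simplify_step <- function(st, k) {
  a <- min(st$eu[k], st$ev[k]); b <- max(st$eu[k], st$ev[k])
  st$removed_max <- max(st$removed_max, st$max_bit[k])
  st$nodes[[a]] <- sort(c(st$nodes[[a]], st$nodes[[b]]))
  st$nodes[[b]] <- NULL
  keep <- seq_along(st$mask) != k
  remap <- function(v) { v[v == b] <- a; v - (v > b) }
  st$eu <- remap(st$eu[keep]); st$ev <- remap(st$ev[keep])
  st$mask <- st$mask[keep]
  st$min_bit <- st$min_bit[keep]; st$max_bit <- st$max_bit[keep]
  merge_parallel(st)
}

# does a set of cluster-graph edges form one continuous curve?
# (each shared endpoint joins exactly two cut edges; open ends only on the
# grid border, and then exactly two of them; single closed loops allowed)
cut_is_continuous <- function(edges, ids) {
  eps <- lapply(edges[ids], `[[`, "endpoints")
  if (any(lengths(eps) == 0)) return(length(ids) == 1)  # closed-loop edge
  keys <- unlist(eps)
  deg <- table(keys)
  if (any(deg > 2)) return(FALSE)
  open <- names(deg)[deg == 1]
  if (!(length(open) %in% c(0L, 2L))) return(FALSE)
  if (length(open) && !all(startsWith(open, "B"))) return(FALSE)
  if (length(ids) > 1) {
    df <- data.frame(
      from = rep(paste0("e", seq_along(ids)), lengths(eps)),
      to = keys)
    g <- igraph::graph_from_data_frame(df, directed = FALSE)
    if (igraph::components(g)$no != 1) return(FALSE)
  }
  TRUE
}

#' Enumerate candidate separations
#'
#' Depth-first stack search over ordered simplification paths of the dual
#' graph. Every fully simplified dual (a single composite edge between two
#' nodes) is the dual of a candidate boundary: the composite's edges form
#' the cut and the two node face-sets form the partition. Search paths only
#' remove dual edges whose composite bits all exceed every previously
#' removed bit, which visits each outcome once; duplicates are suppressed
#' defensively and each emitted candidate is re-verified geometrically
#' (continuous curve, both sides contiguous).
#'
#' @param dual An `epp_dual` from [dualize()].
#' @param graph The originating `epp_cluster_graph` (for the geometric
#'   check); if `NULL` the check is skipped.
#' @param max_states Safety cap on visited states.
#' @return A list of candidates: each has `edge_mask` (numeric), `edge_ids`
#'   (1-based indices into `graph$edges`), `left`, `right` (face-id
#'   vectors; `left` contains the smallest face id).
#' @export
enumerate_candidates <- function(dual, graph = NULL, max_states = 2e5) {
  stack <- list(merge_parallel(dual))
  seen <- character(0)
  out <- list()
  visited <- 0L
  while (length(stack)) {
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    visited <- visited + 1L
    if (visited > max_states)
      stop("candidate enumeration exceeded the state cap")
    if (length(st$mask) == 1L) {
      key <- sprintf("%.0f", st$mask)
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        ids <- which(bitwAnd_bits(st$mask))
        ok <- is.null(graph) || cut_is_continuous(graph$edges, ids)
        if (ok) {
          sides <- st$nodes[c(st$eu[1], st$ev[1])]
          left_first <- which.min(vapply(sides, min, 0))
          out[[length(out) + 1L]] <- list(
            edge_mask = st$mask, edge_ids = ids,
            left = sides[[left_first]], right = sides[[3 - left_first]])
        }
      }
      next
    }
    for (k in seq_along(st$mask)) {
      if (st$max_bit[k] > st$removed_max)
        stack[[length(stack) + 1L]] <- simplify_step(st, k)
    }
  }
  out
}

# bits set in a small nonnegative double mask (bit i -> position i+1)
bitwAnd_bits <- function(mask) {
  bits <- logical(32)
  for (i in 31:0) {
    p <- 2^i
    if (mask >= p) { bits[i + 1] <- TRUE; mask <- mask - p }
  }
  bits
}
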