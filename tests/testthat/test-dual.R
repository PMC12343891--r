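# hand-built cluster-graph stubs: edges carry faces + endpoint keys only
stub_graph <- function(faces, edges) {
  g <- list(faces = tibble::tibble(face = faces),
            edges = lapply(seq_along(edges), function(i) {
              e <- edges[[i]]
              list(id = i, faces = sort(e$faces), points = e$points %||% i,
                   endpoints = e$endpoints, mask = 2^(i - 1))
            }),
            status = "ok")
  class(g) <- "epp_cluster_graph"
  g
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# triangle: three mutually adjacent faces meeting at one interior vertex,
# each pairwise edge running from the vertex to the border
triangle_graph <- stub_graph(1:3, list(
  list(faces = c(1, 2), endpoints = c("V1", "B1")),
  list(faces = c(2, 3), endpoints = c("V1", "B2")),
  list(faces = c(1, 3), endpoints = c("V1", "B3"))))

# chain A - B - C: two border-to-border valleys
chain_graph <- stub_graph(1:3, list(
  list(faces = c(1, 2), endpoints = c("B1", "B2")),
  list(faces = c(2, 3), endpoints = c("B3", "B4"))))

test_that("dualization counts nodes and edges correctly", {
  d2 <- dualize(stub_graph(1:2, list(list(faces = c(1, 2),
                                          endpoints = c("B1", "B2")))))
  expect_equal(length(d2$nodes), 2)
  expect_equal(length(d2$mask), 1)
  dt <- dualize(triangle_graph)
  expect_equal(length(dt$nodes), 3)
  expect_equal(length(dt$mask), 3)
  expect_equal(dt$mask, 2^(0:2))
  # the dual of the dual's node count equals the original face count
  expect_equal(length(dt$nodes), nrow(triangle_graph$faces))
})

test_that("simplification steps merge nodes and parallel edges", {
  dt <- dualize(triangle_graph)
  s1 <- simplify_step(dt, 1)  # remove edge AB
  expect_equal(length(s1$nodes), 2)
  expect_equal(length(s1$mask), 1)         # AC and BC merged
  expect_equal(s1$mask, 2 + 4)             # composite of bits 1 and 2
  dc <- dualize(chain_graph)
  s2 <- simplify_step(dc, 1)  # remove AB
  expect_equal(length(s2$nodes), 2)
  expect_equal(length(s2$mask), 1)
  expect_equal(s2$mask, 2)                 # BC untouched
  # node count after k steps = initial - k
  expect_equal(length(simplify_step(dt, 2)$nodes), length(dt$nodes) - 1)
})

test_that("enumeration matches hand counts on canonical small graphs", {
  g2 <- stub_graph(1:2, list(list(faces = c(1, 2), endpoints = c("B1", "B2"))))
  c2 <- enumerate_candidates(dualize(g2), g2)
  expect_equal(length(c2), 1)
  expect_equal(c2[[1]]$edge_mask, 1)
  expect_equal(c2[[1]]$left, 1)
  expect_equal(c2[[1]]$right, 2)

  ct <- enumerate_candidates(dualize(triangle_graph), triangle_graph)
  expect_equal(length(ct), 3)
  expect_setequal(vapply(ct, `[[`, 0, "edge_mask"), c(3, 5, 6))
  expect_true(all(vapply(ct, function(x) length(x$edge_ids), 0L) == 2))

  cc <- enumerate_candidates(dualize(chain_graph), chain_graph)
  expect_equal(length(cc), 2)
  expect_setequal(vapply(cc, `[[`, 0, "edge_mask"), c(1, 2))
  # {B} vs {A, C} is excluded: the sides would not be contiguous
})

test_that("duplicate masks are never emitted and counts respect the bound", {
  for (seed in 1:5) {
    graph <- generate_planar_partition(sample(3:6, 1), seed = seed * 17)
    cands <- enumerate_candidates(dualize(graph), graph)
    masks <- vapply(cands, `[[`, 0, "edge_mask")
    expect_equal(anyDuplicated(masks), 0)
    expect_lte(length(cands), 2^(nrow(graph$faces) - 1) - 1)
    for (cd in cands)
      expect_setequal(c(cd$left, cd$right), graph$faces$face)
  }
})

test_that("enumeration equals the brute-force partition oracle", {
  set.seed(1)
  n_checked <- 0
  for (seed in 1:25) {
    nf <- 2 + (seed %% 5)
    graph <- tryCatch(generate_planar_partition(nf, seed = seed),
                      error = function(e) NULL)
    if (is.null(graph)) next
    cands <- enumerate_candidates(dualize(graph), graph)
    mine <- sort(vapply(cands, function(x) sprintf("%.0f", x$edge_mask), ""))
    expect_equal(mine, oracle_candidates(graph), info = paste("seed", seed))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 20)
})

test_that("the emitted set is invariant to edge relabeling", {
  graph <- generate_planar_partition(5, seed = 11)
  k <- length(graph$edges)
  cands <- enumerate_candidates(dualize(graph), graph)
  set.seed(2)
  perm <- sample(k)
  g2 <- graph
  g2$edges <- graph$edges[perm]
  for (i in seq_len(k)) {
    g2$edges[[i]]$id <- i
    g2$edges[[i]]$mask <- 2^(i - 1)
  }
  c2 <- enumerate_candidates(dualize(g2), g2)
  # map each candidate back to original edge ids
  to_orig <- function(cds, edge_list) {
    sort(vapply(cds, function(cd) {
      ids <- vapply(edge_list[cd$edge_ids], function(e) e$points[1], 0)
      paste(sort(ids), collapse = ",")
    }, ""))
  }
  expect_equal(to_orig(cands, graph$edges), to_orig(c2, g2$edges))
})
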