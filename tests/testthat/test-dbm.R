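pair_graph <- function(ev, W = 0.02, cfg = epp_config()) {
  g <- density_grid(ev[[1]], ev[[2]], W)
  nf <- noise_floor(g$density, g$weights, g$kernel_sd, cfg$sigma_noise)
  gl <- cluster_grid(g$density, nf, cfg)
  list(grid = g, labels = gl,
       graph = build_cluster_graph(gl, g$density, cfg))
}

test_that("edge saddles are maxima with deterministic tie-breaks", {
  d <- matrix(0, 257, 257)
  pts <- c(10 + 257 * 5, 11 + 257 * 5, 12 + 257 * 5)  # 0-based linear
  d[pts + 1] <- c(0.1, 0.4, 0.2)
  s <- edge_saddle(d, pts)
  expect_equal(s$density, 0.4)
  expect_equal(s$point, pts[2])
  expect_equal(edge_saddle(d, pts[1])$point, pts[1])
  # tie: row-major order decides
  d[pts + 1] <- 0.4
  expect_equal(edge_saddle(d, pts)$point, pts[1])
})

test_that("a zero dip is never significant", {
  v <- matrix(1e-4, 257, 257)
  expect_false(dip_significant(c(2, 2), c(100, 200),
                               list(point = 150, density = 2), v))
})

test_that("a deep dip between well-separated modes is significant", {
  ev <- fixture_two_comp(n = 50000, seed = 12)
  pg <- pair_graph(ev, W = 0.01)
  expect_equal(length(pg$graph$edges), 1)
  e <- pg$graph$edges[[1]]
  s <- edge_saddle(pg$grid$density, e$points)
  expect_lte(s$density, min(pg$graph$faces$mode_density) + 1e-9)
  # symmetric fixture: the saddle sits near the midline
  expect_lt(abs(s$point %% 257 / 256 - 0.5), 0.05)
  expect_true(dip_significant(pg$graph$faces$mode_density,
                              pg$graph$faces$mode_point, s,
                              pg$grid$variance))
})

test_that("merging keeps significant graphs unchanged and is idempotent", {
  ev <- fixture_two_comp(n = 50000, seed = 13)
  pg <- pair_graph(ev, W = 0.01)
  m1 <- merge_insignificant(pg$graph, pg$grid$density, pg$grid$variance,
                            epp_config())
  expect_equal(m1$status, "ok")
  expect_equal(length(m1$edges), length(pg$graph$edges))
  expect_equal(nrow(m1$faces), 2)
  m2 <- merge_insignificant(m1, pg$grid$density, pg$grid$variance,
                            epp_config())
  expect_equal(length(m2$edges), length(m1$edges))
  expect_equal(m2$faces$mode_density, m1$faces$mode_density)
})

test_that("an insignificant dip merges the graph down to one face", {
  # two heavily overlapping components: a weak sampling-noise dip splits
  # them into two modes that the significance test cannot support
  ev <- generate_mixture(tibble::tibble(
    weight = c(.5, .5), mean = list(c(.45, .5), c(.55, .5)), sd = 0.04),
    n_events = 2000, seed = 15)
  g <- density_grid(ev[[1]], ev[[2]], 0.015)
  nf <- noise_floor(g$density, g$weights, g$kernel_sd, 3)
  gl <- cluster_grid(g$density, nf, epp_config())
  expect_equal(gl$n_clusters, 2)
  graph <- build_cluster_graph(gl, g$density, epp_config())
  expect_equal(graph$status, "ok")
  m <- merge_insignificant(graph, g$density, g$variance, epp_config())
  expect_equal(m$status, "drop")
  expect_equal(length(m$edges), 0)
  expect_equal(nrow(m$faces), 1)
  expect_true(all(m$face_map == m$faces$face[1]))
})

test_that("a three-cluster chain with one weak dip merges onto the higher mode", {
  # strong left mode; two overlapping modes on the right whose mutual dip
  # is insignificant while the main valley stays significant
  ev <- generate_mixture(tibble::tibble(
    weight = c(.4, .3, .3),
    mean = list(c(.2, .5), c(.52, .5), c(.62, .5)),
    sd = c(.04, .045, .045)),
    n_events = 15000, seed = 16)
  cfg <- epp_config()
  g <- density_grid(ev[[1]], ev[[2]], 0.015)
  nf <- noise_floor(g$density, g$weights, g$kernel_sd, 3)
  gl <- cluster_grid(g$density, nf, cfg)
  expect_equal(gl$n_clusters, 3)
  graph <- build_cluster_graph(gl, g$density, cfg)
  expect_equal(graph$status, "ok")
  modes_before <- graph$faces$mode_density
  m <- merge_insignificant(graph, g$density, g$variance, cfg)
  expect_equal(nrow(m$faces), 2)
  expect_equal(length(m$edges), 1)
  merged_face <- names(which(table(m$face_map) == 2))
  merged_members <- as.integer(names(m$face_map)[m$face_map == merged_face])
  expect_equal(
    m$faces$mode_density[m$faces$face == as.integer(merged_face)],
    max(modes_before[merged_members]))
})

test_that("within the full pipeline a single Gaussian yields no significant split", {
  leaves <- vapply(1:10, function(s) {
    ev <- generate_mixture(n_events = 20000, seed = 300 + s)
    epp(ev)$n_leaves
  }, 0L)
  expect_gte(mean(leaves == 1), 0.9)
})
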