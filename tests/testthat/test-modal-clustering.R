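two_gauss_grid <- function(n = 20000, seed = 1, W = 0.02, sep = c(0.3, 0.7)) {
  ev <- generate_mixture(tibble::tibble(
    weight = c(.5, .5), mean = list(c(sep[1], .5), c(sep[2], .5)), sd = 0.04),
    n_events = n, seed = seed)
  density_grid(ev[[1]], ev[[2]], W)
}

test_that("noise floor equals the brute-force window-scan oracle", {
  set.seed(21)
  g <- density_grid(runif(10000), runif(10000), 0.01)
  nf <- noise_floor(g$density, g$weights, g$kernel_sd, 3)
  expect_equal(nf, oracle_noise_floor(g$density, g$weights, 0.01, 3))
  # clustered data: the floor stays below the mode densities
  g2 <- two_gauss_grid(n = 10000, seed = 21)
  nf2 <- noise_floor(g2$density, g2$weights, g2$kernel_sd, 3)
  expect_equal(nf2, oracle_noise_floor(g2$density, g2$weights, g2$kernel_sd, 3))
  expect_lt(nf2, max(g2$density) / 10)
  # vacuous data: no window can accumulate 9 events
  expect_equal(noise_floor(matrix(0, 257, 257), matrix(0, 257, 257), 0.01, 3),
               Inf)
})

test_that("a unimodal density yields one cluster and no boundary points", {
  set.seed(22)
  ev <- generate_mixture(n_events = 20000, seed = 22)
  g <- density_grid(ev[[1]], ev[[2]], 0.04)
  nf <- noise_floor(g$density, g$weights, g$kernel_sd, 3)
  gl <- cluster_grid(g$density, nf, epp_config())
  expect_equal(gl$n_clusters, 1)
  expect_equal(sum(gl$labels == 0), 0)
})

test_that("two separated components give two clusters with a boundary near the midline", {
  g <- two_gauss_grid(sep = c(0.4, 0.6))
  nf <- noise_floor(g$density, g$weights, g$kernel_sd, 3)
  gl <- cluster_grid(g$density, nf, epp_config())
  expect_equal(gl$n_clusters, 2)
  # where the density is non-negligible the boundary sits at the midline
  # (in the flat near-zero far field a watershed line can wander)
  bp <- which(gl$labels == 0)
  bx <- (bp - 1) %% 257 / 256
  informative <- g$density[bp] >= 0.01 * max(g$density)
  expect_true(any(informative))
  expect_true(all(abs(bx[informative] - 0.5) <= 0.05))
  # agreement with a greedy steepest-ascent watershed oracle
  ws <- oracle_watershed(g$density, nf)
  above <- g$density >= nf & gl$labels > 0 & ws > 0
  # align oracle label ids to scan ids by majority
  tab <- table(gl$labels[above], ws[above])
  agree <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gte(agree, 0.99)
})

test_that("too many well-separated point masses raise the widen signal", {
  pts <- expand.grid(x = c(.1, .3, .5, .7), y = c(.2, .5, .8))[1:13 %% 14, ]
  pts <- expand.grid(x = c(.1, .3, .5, .7), y = c(.2, .5, .8))
  pts <- rbind(pts, c(.9, .9))  # 13 sites
  x <- rep(pts$x, each = 200) + rnorm(2600, 0, 0.005)
  y <- rep(pts$y, each = 200) + rnorm(2600, 0, 0.005)
  g <- density_grid(pmin(pmax(x, 0), 1), pmin(pmax(y, 0), 1), 0.01)
  nf <- noise_floor(g$density, g$weights, g$kernel_sd, 3)
  gl <- cluster_grid(g$density, nf, epp_config())
  expect_true(gl$widen)
})

test_that("cluster count never increases along the widening sequence", {
  cfg <- epp_config()
  cfg$max_clusters <- 100L  # count clusters without triggering the cap
  set.seed(23)
  steps_ok <- 0; steps_all <- 0
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    means <- lapply(seq_len(k), function(i) runif(2, 0.15, 0.85))
    ev <- generate_mixture(tibble::tibble(weight = rep(1 / k, k),
                                          mean = means, sd = 0.03),
                           n_events = 5000, seed = 100 + rep)
    g <- density_grid(ev[[1]], ev[[2]], 0.01)
    prev <- Inf
    for (pass in 1:5) {
      nf <- noise_floor(g$density, g$weights, g$kernel_sd, 3)
      gl <- cluster_grid(g$density, nf, cfg)
      steps_all <- steps_all + 1
      if (gl$n_clusters <= prev) steps_ok <- steps_ok + 1
      prev <- gl$n_clusters
      g <- widen_kernel(g)
    }
  }
  expect_gte(steps_ok / steps_all, 0.95)
})

test_that("the scan is deterministic", {
  g <- two_gauss_grid(n = 5000, seed = 4)
  nf <- noise_floor(g$density, g$weights, g$kernel_sd, 3)
  a <- cluster_grid(g$density, nf, epp_config())
  b <- cluster_grid(g$density, nf, epp_config())
  expect_identical(a$labels, b$labels)
  expect_identical(a$modes, b$modes)
})

test_that("a two-cluster valley builds the simplest planar graph", {
  g <- two_gauss_grid()
  nf <- noise_floor(g$density, g$weights, g$kernel_sd, 3)
  gl <- cluster_grid(g$density, nf, epp_config())
  graph <- build_cluster_graph(gl, g$density, epp_config())
  expect_equal(graph$status, "ok")
  expect_equal(length(graph$edges), 1)
  expect_equal(nrow(graph$faces), 2)
  expect_equal(graph$n_vertices, 0)
  expect_setequal(graph$edges[[1]]$faces, c(1, 2))
  # both ends terminate on the grid border
  expect_true(all(startsWith(graph$edges[[1]]$endpoints, "B")))
})

test_that("three clusters meeting centrally give three edges and one vertex", {
  ev <- generate_mixture(tibble::tibble(
    weight = rep(1 / 3, 3),
    mean = list(c(.5, .75), c(.28, .3), c(.72, .3)), sd = 0.05),
    n_events = 30000, seed = 31)
  g <- density_grid(ev[[1]], ev[[2]], 0.03)
  nf <- noise_floor(g$density, g$weights, g$kernel_sd, 3)
  gl <- cluster_grid(g$density, nf, epp_config())
  expect_equal(gl$n_clusters, 3)
  graph <- build_cluster_graph(gl, g$density, epp_config())
  expect_equal(graph$status, "ok")
  expect_equal(length(graph$edges), 3)
  expect_equal(graph$n_vertices, 1)
  expect_equal(nrow(graph$faces), 3)
  # every edge endpoint is a vertex or a border termination
  for (e in graph$edges)
    expect_true(all(grepl("^[VB]", e$endpoints)))
})

test_that("event assignment matches the nearest-grid-node oracle and conserves totals", {
  g <- two_gauss_grid(n = 10000, seed = 6)
  nf <- noise_floor(g$density, g$weights, g$kernel_sd, 3)
  gl <- cluster_grid(g$density, nf, epp_config())
  set.seed(61)
  x <- runif(5000); y <- runif(5000)
  ids <- assign_events(x, y, gl$labels)
  expect_equal(length(ids), 5000)
  expect_true(all(ids >= 1 & ids <= gl$n_clusters))
  # off the boundary band the id equals the nearest node's label
  ix <- pmin(pmax(round(x * 256), 0), 256) + 1
  iy <- pmin(pmax(round(y * 256), 0), 256) + 1
  raw <- gl$labels[cbind(ix, iy)]
  off_boundary <- raw > 0
  expect_true(all(ids[off_boundary] == raw[off_boundary]))
  # events at the mode coordinates belong to their cluster
  expect_equal(assign_events(gl$modes$ix / 256, gl$modes$iy / 256, gl$labels),
               gl$modes$cluster)
})
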