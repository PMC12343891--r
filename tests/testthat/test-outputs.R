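test_that("polyline simplification honours its deviation contract", {
  # collinear points collapse to the two endpoints
  line <- cbind(seq(0, 1, length.out = 100), seq(0, 1, length.out = 100) * 0.5)
  expect_equal(nrow(simplify_polygon(line, 0.01)), 2)
  # a square's corners are extreme points and survive any small tolerance
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  expect_equal(simplify_polygon(sq, 0.2), sq)
  # dense circle: every removed vertex within tolerance of the output
  th <- seq(0, 2 * pi, length.out = 500)
  circ <- cbind(0.5 + 0.3 * cos(th), 0.5 + 0.3 * sin(th))
  simp <- simplify_polygon(circ, 0.01)
  expect_lt(nrow(simp), nrow(circ))
  seg_dist <- function(p, a, b) {
    ab <- b - a; t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - a - t * ab)^2))
  }
  dev <- apply(circ, 1, function(p)
    min(vapply(seq_len(nrow(simp) - 1), function(i)
      seg_dist(p, simp[i, ], simp[i + 1, ]), 0)))
  expect_lte(max(dev), 0.01)
  # degenerate input returned unchanged
  expect_equal(simplify_polygon(rbind(c(0, 0), c(1, 1)), 0.01),
               rbind(c(0, 0), c(1, 1)))
})

test_that("gate polygons enclose their child's events", {
  ev <- fixture_two_comp(n = 20000, seed = 51)
  fit <- epp(ev)
  nd <- fit$nodes[[1]]
  expect_false(nd$is_leaf)
  for (side in c("gate_left", "gate_right")) {
    poly <- nd[[side]]
    expect_true(all(poly >= 0 & poly <= 1))
  }
  # the left gate is in effect a half-plane rectangle up to tolerance:
  # events of each child fall inside their own polygon
  X <- as.matrix(ev)
  kids <- nd$children
  in_poly <- function(px, py, poly) {
    # ray casting
    n <- nrow(poly); inside <- rep(FALSE, length(px))
    j <- n
    for (i in seq_len(n)) {
      xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi + 1e-300) + xi)
      inside <- xor(inside, cross)
      j <- i
    }
    inside
  }
  for (k in 1:2) {
    rows <- fit$nodes[[kids[k]]]$rows
    poly <- if (k == 1) nd$gate_left else nd$gate_right
    frac <- mean(in_poly(X[rows, nd$pair[1]], X[rows, nd$pair[2]], poly))
    expect_gte(frac, 0.98)  # only the simplification band may leak
  }
})

test_that("outputs serialize consistently and round-trip", {
  ev <- fixture_two_comp(n = 10000, seed = 52)
  fit <- epp(ev)
  dir1 <- tempfile(); dir2 <- tempfile()
  p1 <- write_epp_outputs(fit, dir1)
  p2 <- write_epp_outputs(epp(ev), dir2)
  expect_identical(readLines(p1["tree"]), readLines(p2["tree"]))
  expect_identical(readLines(p1["csv"]), readLines(p2["csv"]))

  tree <- jsonlite::fromJSON(p1["tree"], simplifyDataFrame = FALSE)
  expect_equal(tree$n_events, 10000)
  expect_equal(length(tree$children), 2)
  expect_equal(tree$P, round(fit$nodes[[1]]$P, 6))

  asg <- read.csv(p1["csv"])
  expect_equal(nrow(asg), 10000)
  expect_setequal(names(asg), c("event_index", "cluster_id", "mahalanobis"))
  expect_true(all(asg$mahalanobis >= 0))
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("per-event Mahalanobis distances vanish at the leaf center", {
  ev <- fixture_two_comp(n = 5000, seed = 53)
  fit <- epp(ev)
  asg <- epp_assignments(fit)
  X <- as.matrix(ev)
  for (leaf in 1:fit$n_leaves) {
    idx <- asg$event_index[asg$cluster_id == leaf]
    mu <- colMeans(X[idx, ])
    S <- cov(X[idx, ])
    expect_equal(unname(sqrt(mahalanobis(rbind(mu), mu, S))[1]), 0)
    # distances computed for the events are the classical ones
    d <- sqrt(mahalanobis(X[idx, ], mu, S))
    expect_equal(asg$mahalanobis[asg$cluster_id == leaf], unname(d),
                 tolerance = 1e-8)
  }
})

test_that("match tables count shared events exactly", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(dplyr::filter(match_table(a, a), a == b)$n, c(2, 2, 2))
  expect_true(all(dplyr::filter(match_table(a, a), a != b)$n == 0))
  one <- match_table(rep("x", 6), a)
  expect_equal(sort(one$n), c(2, 2, 2))
  set.seed(54)
  la <- sample(3, 500, replace = TRUE); lb <- sample(4, 500, replace = TRUE)
  mt <- match_table(la, lb)
  for (r in seq_len(nrow(mt)))
    expect_equal(mt$n[r], sum(la == mt$a[r] & lb == mt$b[r]))
  expect_error(match_table(la, lb[-1]), "universe")
})

test_that("Jaccard similarity follows the set formula", {
  expect_equal(jaccard(1:100, 1:100), 1)
  expect_equal(jaccard(1:50, 51:100), 0)
  expect_equal(jaccard(1:100, 51:150), 50 / 150)
  expect_error(jaccard(integer(0), integer(0)), "undefined")
})

test_that("central similarity discounts peripheral disagreement", {
  set.seed(55)
  n <- 4000
  X <- data.frame(a = rnorm(n, 0.5, 0.05), b = rnorm(n, 0.5, 0.05))
  d <- sqrt(mahalanobis(X, colMeans(X), cov(X)))
  core <- which(d <= quantile(d, 0.7))
  shell <- which(d > quantile(d, 0.7))
  A <- c(core, shell[1:300])
  B <- c(core, shell[301:600])
  expect_equal(central_similarity(A, A, X), 1)
  # all disagreement beyond the central shell: perfect core agreement
  expect_equal(central_similarity(A, B, X, central_fraction = 0.7), 1)
  expect_gte(central_similarity(A, B, X, 0.8), jaccard(A, B))
  expect_equal(central_similarity(A, B, X, central_fraction = 1), jaccard(A, B))
})
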