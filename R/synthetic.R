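#' Generate a synthetic event matrix from a Gaussian mixture
#'
#' Seeded generator of cytometry-like event tables with ground-truth
#' component labels, for testing every stage of the pipeline without real
#' acquisitions. Fluorescence-like data are near-normal clusters on the
#' unit scale; in mass mode, dimensions where a component sits low are
#' replaced by zero-inflated exponentials (a spike at zero plus a roughly
#' exponential tail), emulating how low mass-channel counts behave.
#' Out-of-cube draws are resampled rather than clipped, so no artificial
#' boundary spikes are created.
#'
#' @param components A data frame (or tibble) with one row per mixture
#'   component: column `weight` plus list-columns `mean` (numeric vector in
#'   the open unit cube) and `cov` (positive-definite matrix), or, for the
#'   common spherical case, a numeric `sd` column. Defaults to a single
#'   central component.
#' @param dimensions Number of dimensions (used only to build the default
#'   component).
#' @param n_events Number of events.
#' @param seed Integer seed; the output is reproducible.
#' @param mass_mode Logical; zero-inflate low dimensions (see above).
#' @param zero_prob Probability of an exact zero in a mass-mode negative
#'   dimension.
#' @param low_threshold Component mean below which a mass-mode dimension
#'   counts as negative.
#' @return An `epp_events` tibble with a `.component` attribute
#'   (`true_labels(ev)`) giving each event's generating component.
#' @export
generate_mixture <- function(components = NULL, dimensions = 2L,
                             n_events = 10000L, seed = 1L,
                             mass_mode = FALSE, zero_prob = 0.3,
                             low_threshold = 0.2) {
  set.seed(seed)
  if (is.null(components))
    components <- tibble::tibble(weight = 1,
                                 mean = list(rep(0.5, dimensions)),
                                 sd = 0.05)
  components <- tibble::as_tibble(components)
  stopifnot(abs(sum(components$weight) - 1) < 1e-8)
  d <- length(components$mean[[1]])
  get_cov <- function(i) {
    if ("cov" %in% names(components))
      as.matrix(components$cov[[i]])
    else diag(components$sd[i]^2, d)
  }
  comp <- sample.int(nrow(components), n_events, replace = TRUE,
                     prob = components$weight)
  X <- matrix(NA_real_, n_events, d)
  for (i in seq_len(nrow(components))) {
    idx <- which(comp == i)
    if (!length(idx)) next
    mu <- components$mean[[i]]; S <- get_cov(i)
    draw <- function(m) MASS::mvrnorm(m, mu, S)
    Z <- draw(length(idx))
    if (length(idx) == 1) Z <- matrix(Z, 1)
    resampled <- 0L
    repeat {  # resample out-of-cube draws
      bad <- which(rowSums(Z < 0 | Z > 1) > 0)
      if (!length(bad)) break
      resampled <- resampled + length(bad)
      Znew <- draw(length(bad))
      if (length(bad) == 1) Znew <- matrix(Znew, 1)
      Z[bad, ] <- Znew
    }
    if (resampled > 0.1 * length(idx))
      warning(sprintf("component %d: >10%% of draws resampled; mass too close to the cube wall", i))
    if (mass_mode) {
      for (k in which(mu < low_threshold)) {
        m <- max(mu[k], 1e-3)
        z <- stats::rbinom(length(idx), 1, zero_prob) == 1
        v <- stats::rexp(length(idx), rate = 1 / m)
        v[v > 1] <- m  # rare overflow of the tail; fold back near the mean
        v[z] <- 0
        Z[, k] <- v
      }
    }
    X[idx, ] <- Z
  }
  colnames(X) <- paste0("M", seq_len(d))
  ev <- as_event_matrix(X, source = sprintf("synthetic mixture (seed %d)", seed))
  attr(ev, "component") <- comp
  ev
}

#' @rdname generate_mixture
#' @param events An event table produced by [generate_mixture()].
#' @export
true_labels <- function(events) attr(events, "component")

#' Random planar partition fixture
#'
#' Builds a cluster-graph fixture from a seeded random set of sites: the
#' density is an equal mixture of Gaussian bumps at the sites (whose modal
#' clustering is the Voronoi-like watershed partition of the grid), run
#' through the same clustering and graph construction as real data, so
#' every `epp_cluster_graph` invariant holds. Used to exercise boundary
#' enumeration against brute force.
#'
#' @param n_faces Number of faces (2 to 6).
#' @param seed Integer seed.
#' @param bump_sd Standard deviation of the site bumps.
#' @return An `epp_cluster_graph` with `n_faces` faces (sites are redrawn,
#'   up to 50 attempts, until the clustering yields exactly `n_faces`
#'   faces and a clean graph).
#' @export
generate_planar_partition <- function(n_faces, seed = 1L, bump_sd = 0.08) {
  stopifnot(n_faces >= 2, n_faces <= 6)
  set.seed(seed)
  cfg <- epp_config()
  gx <- (0:256) / 256
  for (attempt in 1:200) {
    sites <- matrix(stats::runif(2 * n_faces, 0.12, 0.88), ncol = 2)
    if (min(stats::dist(sites)) < 0.18) next
    dens <- matrix(0, GRID_N, GRID_N)
    for (s in seq_len(n_faces))
      dens <- dens + outer(stats::dnorm(gx, sites[s, 1], bump_sd),
                           stats::dnorm(gx, sites[s, 2], bump_sd))
    dens <- normalize_density(dens)
    gl <- cluster_grid(dens, 0, cfg)
    if (gl$widen || gl$n_clusters != n_faces) next
    graph <- build_cluster_graph(gl, dens, cfg)
    if (graph$status != "ok") next
    for (k in seq_along(graph$edges)) graph$edges[[k]]$mask <- 2^(k - 1)
    graph$density <- dens
    graph$face_map <- stats::setNames(graph$faces$face, graph$faces$face)
    return(graph)
  }
  stop("could not generate a clean planar partition for this seed")
}
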