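#' Divergence of a sample from a moment-matched reference distribution
#'
#' Estimates the Kullback-Leibler divergence (in nats) of the empirical
#' distribution of `values` from a normal or exponential reference with
#' moment-matched parameters (normal: sample mean and variance;
#' exponential: sample mean of the non-zero values). Dimensions whose
#' marginal looks like a single uniformly positive or negative stain score
#' near zero and are dropped from projection pursuit.
#'
#' The estimator discretizes both distributions onto `n_bins` equal
#' probability bins of the fitted reference and accumulates
#' `sum(p * log(p / q))` with a +0.5 pseudo-count in each bin. For a sample
#' genuinely drawn from the reference the expected value is about
#' `(n_bins - 1) / (2 n)`, far below the 0.04 qualification threshold at
#' the population sizes where splitting is attempted.
#'
#' @param values Numeric vector on the unit scale.
#' @param reference `"normal"` or `"exponential"`. The exponential
#'   reference is fitted to the non-zero values only (mass-cytometry
#'   negatives carry a spike at zero).
#' @param n_bins Number of equal-probability bins (default 256).
#' @param min_n Below this sample size the function returns 0 (the
#'   population is too small to qualify a dimension). Default 50.
#' @return Nonnegative scalar divergence estimate in nats.
#' @export
kld_from_reference <- function(values, reference = c("normal", "exponential"),
                               n_bins = 256L, min_n = 50L) {
  reference <- match.arg(reference)
  values <- values[is.finite(values)]
  if (reference == "exponential") values <- values[values > 0]
  n <- length(values)
  if (n < min_n) return(0)
  if (reference == "normal") {
    m <- mean(values); s <- stats::sd(values)
    if (s == 0) return(0)
    breaks <- stats::qnorm(seq(0, 1, length.out = n_bins + 1), m, s)
  } else {
    m <- mean(values)
    if (m <= 0) return(0)
    breaks <- stats::qexp(seq(0, 1, length.out = n_bins + 1), rate = 1 / m)
  }
  breaks[1] <- -Inf; breaks[n_bins + 1] <- Inf
  cnt <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                  nbins = n_bins)
  tot <- n + 0.5 * n_bins
  p <- (cnt + 0.5) / tot
  q <- (n / n_bins + 0.5) / tot
  max(sum(p * log(p / q)), 0)
}

#' Qualify dimensions and enumerate projection pairs
#'
#' Decides which phenotyping dimensions of the current population are
#' informative, by divergence of their marginal from a moment-matched
#' normal (and, in mass-cytometry mode, exponential) reference, and
#' enumerates the dimension pairs to examine:
#'
#' * every unordered pair of qualified dimensions;
#' * if exactly one dimension qualifies, it is paired with the unqualified
#'   dimension of highest normal divergence;
#' * if none qualify, the two dimensions of highest normal divergence form
#'   the single pair;
#'
#' so at least the most promising pair is always tried. The pair list is
#' deterministic and sorted by column index.
#'
#' @param events An `epp_events` table (or plain data frame, in which case
#'   all columns are phenotyping dimensions).
#' @param config An [epp_config()].
#' @return A list with `qualification`, a tibble with one row per
#'   phenotyping dimension (`dim`, `name`, `kld_normal`, `kld_exponential`,
#'   `qualified`), and `pairs`, a two-column integer matrix of column
#'   indices into `events`.
#' @export
qualify_and_pair <- function(events, config = epp_config()) {
  dims <- which(colnames(events) %in% phenotyping_dims(events))
  if (length(dims) < 2)
    stop("at least 2 phenotyping dimensions are required")
  kn <- vapply(dims, function(j)
    kld_from_reference(events[[j]], "normal", min_n = config$min_qualify_n),
    0)
  ke <- if (config$mass_mode)
    vapply(dims, function(j)
      kld_from_reference(events[[j]], "exponential",
                         min_n = config$min_qualify_n), 0)
  else rep(NA_real_, length(dims))
  qual <- kn >= config$kld_normal_threshold |
    (config$mass_mode & !is.na(ke) & ke >= config$kld_exponential_threshold)
  qualification <- tibble::tibble(
    dim = dims, name = colnames(events)[dims],
    kld_normal = kn, kld_exponential = ke, qualified = qual)
  qd <- dims[qual]
  if (length(qd) >= 2) {
    pairs <- t(utils::combn(sort(qd), 2))
  } else if (length(qd) == 1) {
    rest <- dims[!qual]
    partner <- rest[order(-kn[!qual], rest)][1]
    pairs <- matrix(sort(c(qd, partner)), ncol = 2)
  } else {
    top2 <- dims[order(-kn, dims)][1:2]
    pairs <- matrix(sort(top2), ncol = 2)
  }
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  list(qualification = qualification, pairs = pairs)
}
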