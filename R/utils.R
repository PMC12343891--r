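`%||%` <- function(a, b) if (is.null(a)) b else a

# Fixed analysis grid: 257 x 257 nodes at coordinates (i/256, j/256),
# 0-based inclusive endpoints.
GRID_N <- 257L
GRID_STEP <- 1 / 256

#' Algorithm configuration
#'
#' Collects every tunable parameter of the gating engine with the defaults
#' used throughout. All thresholds are in unit-scale (display) coordinates.
#'
#' @param mass_mode Logical; mass-cytometry mode. Switches the default
#'   initial kernel width to 0.025 and enables the exponential reference in
#'   dimension qualification.
#' @param kld_normal_threshold Kullback-Leibler divergence (nats) from the
#'   moment-matched normal above which a dimension qualifies. Default 0.04.
#' @param kld_exponential_threshold Divergence from the moment-matched
#'   exponential (non-zero values only, mass mode) above which a dimension
#'   qualifies. Default 0.2.
#' @param min_qualify_n Minimum population size for qualification; below
#'   this the divergence is reported as 0. Default 50.
#' @param initial_kernel_sd Initial Gaussian kernel standard deviation W as
#'   a fraction of full scale. Default 0.01 (fluorescence) or 0.025 (mass).
#' @param sigma_noise Counting-noise parameter sigma; founding a cluster
#'   requires a window of grid points holding more than sigma^2 events.
#'   Default 3 (9 events).
#' @param max_clusters Maximum modal clusters per projection before the
#'   kernel is widened. Default 12.
#' @param max_edges Maximum cluster-graph edges (bitmask width). Default 32.
#' @param max_widening_passes Cap on sqrt(2) kernel widenings per
#'   projection; at the cap the projection yields no split. Default 8.
#' @param alpha One-sided significance level for the density-dip test.
#'   Default 0.05.
#' @param multiplicity_correction `"bonferroni"` (over the current edge
#'   count) or `"none"`.
#' @param mode Split selection mode: `"best_balance"` (default; boundary
#'   score divided by the balance factor 4P(1-P)) or `"best_separation"`
#'   (raw boundary score).
#' @param min_events_absolute,min_events_relative Optional stopping rules:
#'   populations below the absolute count or below this fraction of the
#'   root population are not split further. Default 0 (off).
#' @param polygon_tolerance Ramer-Douglas-Peucker simplification tolerance
#'   for reported gate polygons, as a fraction of full scale. Default 0.01.
#' @param central_fraction Central fraction used by [central_similarity()].
#'   Default 0.8.
#' @return A list of class `epp_config`.
#' @export
epp_config <- function(mass_mode = FALSE,
                       kld_normal_threshold = 0.04,
                       kld_exponential_threshold = 0.2,
                       min_qualify_n = 50L,
                       initial_kernel_sd = NULL,
                       sigma_noise = 3,
                       max_clusters = 12L,
                       max_edges = 32L,
                       max_widening_passes = 8L,
                       alpha = 0.05,
                       multiplicity_correction = c("bonferroni", "none"),
                       mode = c("best_balance", "best_separation"),
                       min_events_absolute = 0L,
                       min_events_relative = 0,
                       polygon_tolerance = 0.01,
                       central_fraction = 0.8) {
  if (is.null(initial_kernel_sd))
    initial_kernel_sd <- if (mass_mode) 0.025 else 0.01
  stopifnot(kld_normal_threshold >= 0, kld_exponential_threshold >= 0,
            initial_kernel_sd >= GRID_STEP, sigma_noise > 0,
            max_clusters >= 1, max_edges >= max_clusters,
            max_edges <= 32, alpha > 0, alpha < 1)
  structure(list(
    mass_mode = mass_mode,
    kld_normal_threshold = kld_normal_threshold,
    kld_exponential_threshold = kld_exponential_threshold,
    min_qualify_n = as.integer(min_qualify_n),
    initial_kernel_sd = initial_kernel_sd,
    sigma_noise = sigma_noise,
    max_clusters = as.integer(max_clusters),
    max_edges = as.integer(max_edges),
    max_widening_passes = as.integer(max_widening_passes),
    alpha = alpha,
    multiplicity_correction = match.arg(multiplicity_correction),
    mode = match.arg(mode),
    min_events_absolute = as.integer(min_events_absolute),
    min_events_relative = min_events_relative,
    polygon_tolerance = polygon_tolerance,
    central_fraction = central_fraction
  ), class = "epp_config")
}
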