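#' Two-sample Kolmogorov-Smirnov location test on gene-body positions
#'
#' Compares the gene-body positions (fractions in [0, 1] from TSS to TTS)
#' of two groups of retention events, typically IRI-up vs IRI-down introns.
#' Two-sided; the exact p-value is used when both samples have at most 25
#' observations, the asymptotic one otherwise. Ties are handled by the
#' standard ECDF sup-difference without jittering.
#'
#' @param sample_up,sample_down Numeric vectors of positions in [0, 1].
#' @return List with \code{statistic} (D), \code{p_value}, \code{n_up},
#'   \code{n_down}.
#' @export
ks_location_test <- function(sample_up, sample_down) {
  if (!length(sample_up) || !length(sample_down))
    stop("both position samples must be non-empty")
  if (any(sample_up < 0 | sample_up > 1) || any(sample_down < 0 | sample_down > 1))
    stop("positions must lie in [0, 1]")
  exact <- length(sample_up) <= 25 && length(sample_down) <= 25
  kt <- suppressWarnings(
    stats::ks.test(sample_up, sample_down, exact = if (exact) TRUE else NULL))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n_up = length(sample_up), n_down = length(sample_down))
}

#' Empirical cumulative distribution curves
#'
#' Step-function ECDF of each sample evaluated at its observed positions,
#' ready for cumulative plots.
#'
#' @param samples Named list of numeric position vectors.
#' @return \code{data.frame} with columns \code{group}, \code{x},
#'   \code{ecdf}.
#' @export
ecdf_curves <- function(samples) {
  if (is.numeric(samples)) samples <- list(sample = samples)
  do.call(rbind, lapply(names(samples), function(k) {
    x <- sort(samples[[k]])
    if (!length(x)) stop("empty sample: ", k)
    data.frame(group = k, x = x, ecdf = seq_along(x) / length(x))
  }))
}

#' Binned density of positions over [0, 1]
#'
#' @param sample Numeric vector of positions in [0, 1].
#' @param n_bins Number of equal-width bins (>= 2).
#' @return \code{data.frame} with bin \code{mid}, \code{count} and
#'   \code{density} (counts normalised so that sum(density) * width = 1).
#' @export
position_histogram <- function(sample, n_bins = 20) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(sample, breaks, rightmost.closed = TRUE), 1),
              n_bins)
  count <- tabulate(idx, nbins = n_bins)
  width <- 1 / n_bins
  data.frame(mid = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
             count = count,
             density = count / (sum(count) * width))
}
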