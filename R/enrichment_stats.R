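#' Fit the Poisson null to a mutation spectrum
#'
#' The null hypothesis is that selected-clone mutations fall uniformly over
#' the region, so the per-position count is Poisson with mean
#' `lambda = total_mutations / n_positions`.
#'
#' @param spectrum A `MutationSpectrum`.
#' @return A `PoissonNull`: list with `lambda`, `n_positions`,
#'   `total_mutations`.
#' @export
fit_null <- function(spectrum) {
  stopifnot(inherits(spectrum, "MutationSpectrum"))
  L <- length(spectrum$counts)
  if (L < 1L) stop("spectrum has no positions")
  structure(list(lambda = spectrum$total_mutations / L,
                 n_positions = L,
                 total_mutations = spectrum$total_mutations),
            class = "PoissonNull")
}

#' Null probability mass at a mutations-per-position value
#'
#' @param null A [fit_null()] result.
#' @param m Non-negative integer count(s).
#' @return `dpois(m, lambda)`; for `lambda = 0`, a point mass at 0.
#' @export
null_pmf <- function(null, m) {
  stopifnot(inherits(null, "PoissonNull"))
  stats::dpois(m, null$lambda)
}

#' Histogram of mutations-per-position values
#'
#' @param spectrum A `MutationSpectrum`.
#' @return Data frame with `m` (0 .. max observed count) and `n_positions`;
#'   the `n_positions` column sums to the region's residue count.
#' @export
histogram_counts <- function(spectrum) {
  stopifnot(inherits(spectrum, "MutationSpectrum"))
  m_max <- max(spectrum$counts, 0L)
  m <- 0:m_max
  data.frame(m = m,
             n_positions = vapply(m, function(v) sum(spectrum$counts == v), 0L))
}

#' Chi-square goodness of fit of the spectrum against its Poisson null
#'
#' Observed bins are the mutations-per-position values 0..max(observed) plus
#' a closing tail bin carrying the remaining expected mass. With
#' `pooling = "none"` tiny expected counts are used as-is, which reproduces
#' the very large statistics typical of heavy-tailed selected spectra; with
#' `pooling = "min_expected"` adjacent bins are merged (left to right) until
#' each pooled bin has expected count at least `min_expected`, giving a
#' calibrated test. Degrees of freedom are `bins - 2`: one constraint for
#' the total and one for the mean estimated from the data.
#'
#' @param spectrum A `MutationSpectrum`.
#' @param null A `PoissonNull`; defaults to [fit_null()] of the spectrum.
#' @param pooling `"none"` (default) or `"min_expected"`.
#' @param min_expected Minimum pooled expected count (default 5).
#' @return List with `statistic`, `dof`, `p_value`, and the binned `table`
#'   (observed and expected per pooled bin).
#' @export
chi_square_gof <- function(spectrum, null = fit_null(spectrum),
                           pooling = c("none", "min_expected"),
                           min_expected = 5) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(spectrum, "MutationSpectrum"), inherits(null, "PoissonNull"))
  L <- length(spectrum$counts)
  if (L < 2L) stop("need at least 2 positions for a goodness-of-fit test")
  h <- histogram_counts(spectrum)
  m_max <- max(h$m)
  obs <- c(h$n_positions, 0)                       # closing tail bin, observed 0
  expd <- c(L * stats::dpois(0:m_max, null$lambda),
            L * stats::ppois(m_max, null$lambda, lower.tail = FALSE))
  labels <- c(as.character(0:m_max), paste0(">", m_max))
  if (pooling == "min_expected") {
    pooled_o <- numeric(0); pooled_e <- numeric(0); pooled_lab <- character(0)
    acc_o <- 0; acc_e <- 0; acc_lab <- character(0)
    for (i in seq_along(obs)) {
      acc_o <- acc_o + obs[i]; acc_e <- acc_e + expd[i]
      acc_lab <- c(acc_lab, labels[i])
      if (acc_e >= min_expected) {
        pooled_o <- c(pooled_o, acc_o); pooled_e <- c(pooled_e, acc_e)
        pooled_lab <- c(pooled_lab, paste(acc_lab, collapse = ","))
        acc_o <- 0; acc_e <- 0; acc_lab <- character(0)
      }
    }
    if (acc_e > 0 || acc_o > 0) {                  # fold leftovers into last bin
      if (length(pooled_o)) {
        n <- length(pooled_o)
        pooled_o[n] <- pooled_o[n] + acc_o
        pooled_e[n] <- pooled_e[n] + acc_e
        pooled_lab[n] <- paste(c(pooled_lab[n], acc_lab), collapse = ",")
      } else {
        pooled_o <- acc_o; pooled_e <- acc_e
        pooled_lab <- paste(acc_lab, collapse = ",")
      }
    }
    obs <- pooled_o; expd <- pooled_e; labels <- pooled_lab
  }
  if (any(expd == 0 & obs > 0)) {
    warning("observed counts in bins with zero expected mass; statistic is Inf")
    stat <- Inf
  } else {
    nz <- expd > 0
    stat <- sum((obs[nz] - expd[nz])^2 / expd[nz])
  }
  dof <- length(obs) - 2L
  p <- if (dof >= 1L && is.finite(stat)) {
    stats::pchisq(stat, dof, lower.tail = FALSE)
  } else if (is.infinite(stat)) 0 else NA_real_
  list(statistic = stat, dof = dof, p_value = p,
       table = data.frame(bin = labels, observed = obs, expected = expd,
                          stringsAsFactors = FALSE))
}

#' Fold-over-null enrichment threshold
#'
#' Finds the minimal mutations-per-position value `m_star` at which the
#' observed spectrum exceeds the Poisson null by at least `fold` (default
#' 10). In the default cumulative mode, `m_star` is the smallest `m >= 1`
#' such that the number of positions with count `>= m` is at least
#' `fold * L * P(X >= m)` under the null, which yields a well-defined
#' ">= m_star" calling rule; the pointwise mode compares exact-count bins
#' instead.
#'
#' @param spectrum A `MutationSpectrum`.
#' @param null A `PoissonNull` (defaults to [fit_null()] of the spectrum).
#' @param fold Enrichment factor (> 1).
#' @param mode `"cumulative"` (default) or `"pointwise"`.
#' @return The integer threshold, or `NA` if no value qualifies.
#' @export
enrichment_threshold <- function(spectrum, null = fit_null(spectrum),
                                 fold = 10, mode = c("cumulative", "pointwise")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spectrum, "MutationSpectrum"), inherits(null, "PoissonNull"))
  if (fold <= 1) stop("fold must be > 1")
  L <- length(spectrum$counts)
  m_max <- max(spectrum$counts, 0L)
  if (m_max < 1L) return(NA_integer_)
  for (m in 1:m_max) {
    if (mode == "cumulative") {
      observed <- sum(spectrum$counts >= m)
      expected <- L * stats::ppois(m - 1L, null$lambda, lower.tail = FALSE)
    } else {
      observed <- sum(spectrum$counts == m)
      expected <- L * stats::dpois(m, null$lambda)
    }
    if (observed >= fold * expected && observed > 0) return(as.integer(m))
  }
  NA_integer_
}

#' Positions at or above the enrichment threshold
#'
#' @param spectrum A `MutationSpectrum`.
#' @param m_star Threshold from [enrichment_threshold()]; `NA` yields an
#'   empty set.
#' @return Integer vector of enriched positions in protein coordinates.
#' @export
enriched_positions <- function(spectrum, m_star) {
  stopifnot(inherits(spectrum, "MutationSpectrum"))
  if (is.na(m_star)) return(integer(0))
  spectrum$positions[spectrum$counts >= m_star]
}

#' Simulate a mutation spectrum directly
#'
#' Draws iid Poisson(`lambda`) counts per position and optionally overwrites
#' planted hotspot positions with specified counts. Used for calibration and
#' power studies of the enrichment rule without simulating full clone
#' libraries.
#'
#' @param n_positions Region length in residues.
#' @param lambda Null mean mutations per position.
#' @param hotspot_positions Indices (1-based within the region) to plant.
#' @param hotspot_counts Counts for the planted positions (recycled).
#' @param seed Optional integer seed.
#' @return A `MutationSpectrum` with positions `1:n_positions`.
#' @export
simulate_spectrum <- function(n_positions, lambda, hotspot_positions = NULL,
                              hotspot_counts = NULL, seed = NULL) {
  stopifnot(n_positions >= 1L, lambda >= 0)
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rpois(n_positions, lambda)
  if (length(hotspot_positions)) {
    stopifnot(all(hotspot_positions >= 1L), all(hotspot_positions <= n_positions))
    counts[hotspot_positions] <- rep_len(hotspot_counts, length(hotspot_positions))
  }
  mutation_spectrum(counts, region = "simulated")
}
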