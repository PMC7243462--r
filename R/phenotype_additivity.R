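#' Normalization controls for the two-anchor reporter scaling
#'
#' Autocrine signal is scaled between the strong-exporter control (set to 1)
#' and the empty plasmid (set to 0); transporter expression between the
#' wild-type transporter (1) and the empty plasmid (0).
#'
#' @param empty_autocrine,sc_autocrine Raw autocrine medians of the empty
#'   plasmid and the strong-exporter control (arbitrary units; must differ).
#' @param empty_expression,yl_expression Raw expression medians of the empty
#'   plasmid and the wild-type transporter (must differ).
#' @return A `NormalizationControls` list.
#' @export
normalization_controls <- function(empty_autocrine, sc_autocrine,
                                   empty_expression, yl_expression) {
  if (sc_autocrine == empty_autocrine) {
    stop("degenerate autocrine controls: positive and empty anchors coincide")
  }
  if (yl_expression == empty_expression) {
    stop("degenerate expression controls: positive and empty anchors coincide")
  }
  structure(list(empty_autocrine = empty_autocrine, sc_autocrine = sc_autocrine,
                 empty_expression = empty_expression, yl_expression = yl_expression),
            class = "NormalizationControls")
}

#' Normalize a raw autocrine measurement
#'
#' @param raw Raw autocrine value(s), arbitrary units.
#' @param controls A [normalization_controls()].
#' @return `(raw - empty) / (positive - empty)`; values outside [0, 1] are
#'   permitted.
#' @export
normalize_autocrine <- function(raw, controls) {
  stopifnot(inherits(controls, "NormalizationControls"))
  (raw - controls$empty_autocrine) /
    (controls$sc_autocrine - controls$empty_autocrine)
}

#' Normalize a raw transporter-expression measurement
#'
#' @inheritParams normalize_autocrine
#' @return `(raw - empty) / (positive - empty)` with the wild-type
#'   transporter anchor.
#' @export
normalize_expression <- function(raw, controls) {
  stopifnot(inherits(controls, "NormalizationControls"))
  (raw - controls$empty_expression) /
    (controls$yl_expression - controls$empty_expression)
}

#' Signal difference relative to the wild type
#'
#' @param sample_signal,wt_signal Normalized signals.
#' @return `sample_signal - wt_signal`.
#' @export
signal_difference <- function(sample_signal, wt_signal) {
  sample_signal - wt_signal
}

#' Additive prediction for a multi-mutant's signal difference
#'
#' Under the additive model, the signal difference of a genotype is the sum
#' of its component single mutations' differences.
#'
#' @param genotype Character vector of substitution labels (e.g.
#'   `c("G259D", "Q263R")`), or a single `"+"`-joined string.
#' @param single_deltas Named numeric vector mapping each single mutation to
#'   its signal difference.
#' @return The predicted delta; the empty genotype predicts 0. If any
#'   single's delta is missing the result is `NA` with attribute `missing`
#'   listing the absent mutations.
#' @export
additive_prediction <- function(genotype, single_deltas) {
  muts <- parse_genotype(genotype)
  if (!length(muts)) return(0)
  missing <- setdiff(muts, names(single_deltas))
  if (length(missing)) {
    out <- NA_real_
    attr(out, "missing") <- missing
    return(out)
  }
  sum(single_deltas[muts])
}

#' Epistasis residual of an observed multi-mutant
#'
#' @param observed_delta,predicted_delta Observed and additive-model signal
#'   differences.
#' @param observed_sd,predicted_sd Optional replicate SDs; the residual SD
#'   is their root sum of squares.
#' @return List with `residual` (= observed - predicted) and `sd`.
#' @export
epistasis_residual <- function(observed_delta, predicted_delta,
                               observed_sd = 0, predicted_sd = 0) {
  list(residual = observed_delta - predicted_delta,
       sd = sqrt(observed_sd^2 + predicted_sd^2))
}

#' Parse a genotype label into its component substitutions
#'
#' @param genotype Character vector of mutation labels or a `"+"`-joined
#'   string; `""`, `"WT"` and `NA` denote the wild type.
#' @return Character vector of mutation labels (possibly empty).
#' @export
parse_genotype <- function(genotype) {
  if (length(genotype) == 0L) return(character(0))
  if (length(genotype) == 1L) {
    if (is.na(genotype) || genotype == "" || toupper(genotype) == "WT") {
      return(character(0))
    }
    return(strsplit(genotype, "+", fixed = TRUE)[[1L]])
  }
  as.character(genotype)
}

#' Canonical key for a subset of mutations
#'
#' @param muts Character vector of mutation labels.
#' @return `"WT"` for the empty set, otherwise the sorted labels joined with
#'   `"+"`.
#' @export
subset_key <- function(muts) {
  if (!length(muts)) "WT" else paste(sort(muts), collapse = "+")
}

# all permutations of 1..k as a k! x k matrix (insertion construction)
permutations <- function(k) {
  if (k == 1L) return(matrix(1L))
  p <- permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, p + (p >= i))
  }))
}

#' Enumerate evolutionary trajectories of a multi-mutation clone
#'
#' A trajectory is an order in which the clone's `k` mutations accumulate
#' one at a time, starting from the wild type; there are `k!` orderings
#' (24 for a four-mutation clone). A step is acceptable when the signal of
#' the larger subset is at least the previous subset's signal minus the
#' measurement uncertainty `epsilon` (default rule), or strictly greater
#' (`rule = "strict"`); a trajectory is monotone when all `k` steps are
#' acceptable.
#'
#' @param mutations Character vector of the clone's mutation labels.
#' @param subset_signals Named numeric vector of normalized signals for all
#'   `2^k` subsets, keyed by [subset_key()] (wild type keyed `"WT"`).
#' @param epsilon Measurement-uncertainty tolerance on the normalized scale
#'   (default 0.02).
#' @param rule `"within_epsilon"` (default) or `"strict"`.
#' @return List with `n_orderings`, `n_monotone`, `monotone` (logical per
#'   ordering), and `steps` (per-ordering, per-step audit trail with from /
#'   to subsets, their signals, and whether the step passed).
#' @export
enumerate_trajectories <- function(mutations, subset_signals, epsilon = 0.02,
                                   rule = c("within_epsilon", "strict")) {
  rule <- match.arg(rule)
  if (epsilon < 0) stop("epsilon must be non-negative")
  mutations <- unique(as.character(mutations))
  k <- length(mutations)
  if (k < 1L) stop("need at least one mutation")
  if (k > 8L) stop("trajectory enumeration supports at most 8 mutations (k! orderings)")
  needed <- unlist(lapply(0:k, function(j) {
    if (j == 0L) return("WT")
    apply(utils::combn(mutations, j), 2L, function(x) subset_key(x))
  }))
  missing <- setdiff(needed, names(subset_signals))
  if (length(missing)) {
    stop("missing subset signal(s): ", paste(missing, collapse = ", "))
  }
  perms <- permutations(k)
  n_ord <- nrow(perms)
  monotone <- logical(n_ord)
  steps <- vector("list", n_ord)
  for (o in seq_len(n_ord)) {
    order_muts <- mutations[perms[o, ]]
    from_key <- "WT"
    rec <- data.frame(ordering = integer(k), step = integer(k),
                      from = character(k), to = character(k),
                      signal_from = numeric(k), signal_to = numeric(k),
                      ok = logical(k), stringsAsFactors = FALSE)
    for (s in seq_len(k)) {
      to_key <- subset_key(order_muts[seq_len(s)])
      sf <- subset_signals[[from_key]]
      st <- subset_signals[[to_key]]
      ok <- if (rule == "within_epsilon") st >= sf - epsilon else st > sf
      rec[s, ] <- list(o, s, from_key, to_key, sf, st, ok)
      from_key <- to_key
    }
    monotone[o] <- all(rec$ok)
    steps[[o]] <- rec
  }
  list(n_orderings = n_ord, n_monotone = sum(monotone), monotone = monotone,
       steps = do.call(rbind, steps))
}

#' Exported pheromone per cell from an endpoint-dilution bioassay
#'
#' The quantity of exported pheromone is the last fold-dilution of extract
#' that still arrests responder-cell growth, divided by the number of cells
#' in the collection culture, reported in log10 units (serial dilution
#' limits the precision).
#'
#' @param last_arresting_dilution_factor Fold dilution (>= 1).
#' @param cell_count Cells in the collection culture (> 0).
#' @return `log10(dilution / cells)`.
#' @export
afactor_export_units <- function(last_arresting_dilution_factor, cell_count) {
  if (last_arresting_dilution_factor < 1) stop("dilution factor must be >= 1")
  if (cell_count <= 0) stop("cell_count must be positive")
  log10(last_arresting_dilution_factor / cell_count)
}

#' Mating efficiency relative to the wild-type control
#'
#' @param n_diploids_sample Diploid count for the sample (>= 0).
#' @param mean_n_diploids_control Mean diploid count of the wild-type
#'   control matings (> 0; its average is set to 1).
#' @return `n_diploids_sample / mean_n_diploids_control`.
#' @export
mating_efficiency <- function(n_diploids_sample, mean_n_diploids_control) {
  if (mean_n_diploids_control <= 0) stop("control mean must be positive")
  if (n_diploids_sample < 0) stop("sample diploid count must be non-negative")
  n_diploids_sample / mean_n_diploids_control
}

#' Normalize a plate of raw flow measurements using its control rows
#'
#' Takes a long table of replicate measurements (one row per sample x
#' replicate) including control rows whose `genotype` is tagged `"empty"`,
#' `"ScSte6"` (strong autocrine anchor) or `"YlSte6"` (wild-type transporter
#' and expression anchor), derives the plate's normalization controls from
#' the control medians, and returns the table with normalized columns.
#'
#' @param measurements Data frame with columns `sample_id`, `genotype`,
#'   `replicate`, `raw_autocrine`, `raw_expression`.
#' @return The input with added `autocrine` and `expression` (normalized)
#'   columns, and the derived controls as attribute `"controls"`.
#' @export
normalize_measurements <- function(measurements) {
  req <- c("sample_id", "genotype", "replicate", "raw_autocrine", "raw_expression")
  if (!all(req %in% names(measurements))) {
    stop("measurements must have columns: ", paste(req, collapse = ", "))
  }
  g <- measurements$genotype
  need <- c("empty", "ScSte6", "YlSte6")
  if (!all(need %in% g)) {
    stop("control rows required for genotypes: ", paste(need, collapse = ", "))
  }
  controls <- normalization_controls(
    empty_autocrine = stats::median(measurements$raw_autocrine[g == "empty"]),
    sc_autocrine = stats::median(measurements$raw_autocrine[g == "ScSte6"]),
    empty_expression = stats::median(measurements$raw_expression[g == "empty"]),
    yl_expression = stats::median(measurements$raw_expression[g == "YlSte6"])
  )
  measurements$autocrine <- normalize_autocrine(measurements$raw_autocrine, controls)
  measurements$expression <- normalize_expression(measurements$raw_expression, controls)
  attr(measurements, "controls") <- controls
  measurements
}

#' Aggregate replicate measurements per genotype
#'
#' Replicates are biological; each raw value is already a population median,
#' so aggregation is the mean across replicates with its SD.
#'
#' @param normalized Output of [normalize_measurements()] (or any data frame
#'   with `genotype` and `autocrine` columns).
#' @return Data frame with `genotype`, `mean`, `sd`, `n`.
#' @export
aggregate_genotypes <- function(normalized) {
  stopifnot(all(c("genotype", "autocrine") %in% names(normalized)))
  sp <- split(normalized$autocrine, normalized$genotype)
  data.frame(genotype = names(sp),
             mean = vapply(sp, mean, numeric(1)),
             sd = vapply(sp, stats::sd, numeric(1)),
             n = vapply(sp, length, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Single-mutation signal differences from aggregated measurements
#'
#' Subtracts the wild-type transporter's signal from each single mutant's
#' aggregated signal, propagating the standard errors of both means.
#'
#' @param aggregated Output of [aggregate_genotypes()].
#' @param wt Genotype label of the wild-type transporter (default
#'   `"YlSte6"`).
#' @return Data frame `mutation`, `delta`, `se`; one row per genotype
#'   containing exactly one mutation label.
#' @export
single_mutant_deltas <- function(aggregated, wt = "YlSte6") {
  wt_row <- aggregated[aggregated$genotype == wt, , drop = FALSE]
  if (nrow(wt_row) != 1L) stop("wild-type genotype '", wt, "' not found (or duplicated)")
  controls <- c("empty", "ScSte6", "YlSte6", "WT")
  singles <- aggregated[!aggregated$genotype %in% controls &
                          !grepl("+", aggregated$genotype, fixed = TRUE), , drop = FALSE]
  wt_se2 <- (wt_row$sd / sqrt(wt_row$n))^2
  data.frame(mutation = singles$genotype,
             delta = singles$mean - wt_row$mean,
             se = sqrt((singles$sd / sqrt(singles$n))^2 + wt_se2),
             row.names = NULL, stringsAsFactors = FALSE)
}
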