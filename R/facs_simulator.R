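#' Derive two-channel sorting gates from control populations
#'
#' The expression threshold is set so that a stated fraction (default ~5%)
#' of the autocrine-OFF control passes; the autocrine threshold so that a
#' stated fraction (default ~1%) of the negative-transport control passes.
#' Thresholds are empirical quantiles of the control event sets; an event
#' passes a gate when it strictly exceeds the threshold.
#'
#' @param off_control Event set (data frame with an `expression` column) of
#'   the autocrine-OFF population, the negative control for transporter
#'   expression.
#' @param neg_control Event set (data frame with an `autocrine` column) of
#'   the negative-transport control.
#' @param pass_fractions Named vector `c(expression = , autocrine = )` of
#'   intended control pass fractions in (0, 1).
#' @return A `GatePair`: list with `expression_threshold`,
#'   `autocrine_threshold`, `pass_fractions`.
#' @export
derive_gates <- function(off_control, neg_control,
                         pass_fractions = c(expression = 0.05, autocrine = 0.01)) {
  if (!nrow(off_control) || !nrow(neg_control)) stop("empty control event set")
  p <- pass_fractions
  if (any(p <= 0) || any(p >= 1)) stop("pass fractions must lie in (0, 1)")
  structure(list(
    expression_threshold = stats::quantile(off_control$expression,
                                           1 - p[["expression"]], type = 1,
                                           names = FALSE),
    autocrine_threshold = stats::quantile(neg_control$autocrine,
                                          1 - p[["autocrine"]], type = 1,
                                          names = FALSE),
    pass_fractions = p), class = "GatePair")
}

#' Apply a gate pair to a population of events
#'
#' A cell survives the sort iff its event strictly exceeds both thresholds.
#'
#' @param events Data frame with `autocrine` and `expression` columns (and
#'   any identity columns, e.g. `genotype`).
#' @param gates A [derive_gates()] result.
#' @return The surviving rows of `events`.
#' @export
sort_population <- function(events, gates) {
  stopifnot(inherits(gates, "GatePair"))
  events[events$autocrine > gates$autocrine_threshold &
           events$expression > gates$expression_threshold, , drop = FALSE]
}

#' Library composition table for the enrichment simulator
#'
#' @param genotype Genotype labels (unique).
#' @param autocrine,expression Latent normalized channel signals per
#'   genotype.
#' @param count Initial cell count per genotype.
#' @return Data frame of class `LibraryComposition`.
#' @export
library_composition <- function(genotype, autocrine, expression, count) {
  stopifnot(!anyDuplicated(genotype), all(count >= 0), sum(count) > 0,
            length(genotype) == length(autocrine),
            length(genotype) == length(expression),
            length(genotype) == length(count))
  structure(data.frame(genotype = as.character(genotype),
                       autocrine = autocrine, expression = expression,
                       count = as.integer(count), stringsAsFactors = FALSE),
            class = c("LibraryComposition", "data.frame"))
}

#' Simulate iterative sort-and-expand enrichment
#'
#' Each round, every cell of the working population produces one two-channel
#' event (log-normal around its genotype's latent means, channels
#' independent), cells passing both gates are kept, and the survivors are
#' expanded back to the working population size by neutral multinomial
#' resampling. Four rounds is the default, matching the published protocol.
#'
#' @param composition A [library_composition()] giving genotypes, latent
#'   signals and starting counts; the working population size is the sum of
#'   counts.
#' @param gates A [derive_gates()] result (fixed across rounds).
#' @param n_rounds Number of enrichment rounds (>= 1, default 4).
#' @param cv Per-event coefficient of variation (default 0.3).
#' @param anchors Fluorescence anchors, as [default_anchors()].
#' @param seed Optional integer seed.
#' @return List with `summary` (per-round rows: round, n_sorted, n_unique,
#'   mean_latent_autocrine; round 0 is the input), `frequencies` (genotype x
#'   round matrix), and `extinct` (`TRUE` when a round produced no
#'   survivors, in which case the tables are partial).
#' @export
run_enrichment <- function(composition, gates, n_rounds = 4L, cv = 0.3,
                           anchors = default_anchors(), seed = NULL) {
  stopifnot(inherits(composition, "LibraryComposition"),
            inherits(gates, "GatePair"))
  if (n_rounds < 1L) stop("n_rounds must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  nG <- nrow(composition)
  N <- sum(composition$count)
  raw_a <- norm_to_raw(composition$autocrine, anchors$autocrine)
  raw_e <- norm_to_raw(composition$expression, anchors$expression)
  sdlog <- sqrt(log1p(cv^2))
  counts <- composition$count
  freq <- matrix(0, nG, n_rounds + 1L,
                 dimnames = list(composition$genotype, paste0("round", 0:n_rounds)))
  freq[, 1L] <- counts / N
  summary <- data.frame(round = 0L, n_sorted = NA_integer_,
                        n_unique = sum(counts > 0L),
                        mean_latent_autocrine = sum(counts * composition$autocrine) / N)
  extinct <- FALSE
  for (r in seq_len(n_rounds)) {
    cells <- rep.int(seq_len(nG), counts)
    if (cv > 0) {
      ev_a <- stats::rlnorm(length(cells), log(raw_a[cells]), sdlog)
      ev_e <- stats::rlnorm(length(cells), log(raw_e[cells]), sdlog)
    } else {
      ev_a <- raw_a[cells]
      ev_e <- raw_e[cells]
    }
    surv <- cells[ev_a > gates$autocrine_threshold &
                    ev_e > gates$expression_threshold]
    if (!length(surv)) {
      extinct <- TRUE
      warning("no survivors in round ", r, "; enrichment halted")
      break
    }
    surv_counts <- tabulate(surv, nbins = nG)
    counts <- as.vector(stats::rmultinom(1L, N, surv_counts))
    freq[, r + 1L] <- counts / N
    summary <- rbind(summary, data.frame(
      round = r, n_sorted = length(surv), n_unique = sum(counts > 0L),
      mean_latent_autocrine = sum(counts * composition$autocrine) / N))
  }
  done <- summary$round
  list(summary = summary, frequencies = freq[, seq_along(done), drop = FALSE],
       extinct = extinct)
}

#' One-round fold enrichment of one genotype over another
#'
#' Simulates a single sort of a two-genotype mix and reports the ratio of
#' post- to pre-sort frequency odds of genotype 1 over genotype 2, i.e.
#' `(f1_post / f2_post) / (f1_pre / f2_pre)`.
#'
#' @param composition A two-row [library_composition()].
#' @param gates A [derive_gates()] result.
#' @inheritParams run_enrichment
#' @return List with `fold` (may be `Inf` when genotype 2 is lost in the
#'   sort, or 0 when genotype 1 is), `pre` and `post` frequency vectors, and
#'   `n_sorted`.
#' @export
fold_enrichment <- function(composition, gates, cv = 0.3,
                            anchors = default_anchors(), seed = NULL) {
  stopifnot(inherits(composition, "LibraryComposition"),
            nrow(composition) == 2L, all(composition$count > 0L))
  if (!is.null(seed)) set.seed(seed)
  raw_a <- norm_to_raw(composition$autocrine, anchors$autocrine)
  raw_e <- norm_to_raw(composition$expression, anchors$expression)
  sdlog <- sqrt(log1p(cv^2))
  cells <- rep.int(1:2, composition$count)
  if (cv > 0) {
    ev_a <- stats::rlnorm(length(cells), log(raw_a[cells]), sdlog)
    ev_e <- stats::rlnorm(length(cells), log(raw_e[cells]), sdlog)
  } else {
    ev_a <- raw_a[cells]
    ev_e <- raw_e[cells]
  }
  surv <- cells[ev_a > gates$autocrine_threshold &
                  ev_e > gates$expression_threshold]
  post_counts <- tabulate(surv, nbins = 2L)
  pre <- composition$count / sum(composition$count)
  post <- if (length(surv)) post_counts / length(surv) else c(NA_real_, NA_real_)
  fold <- if (!length(surv)) {
    NA_real_
  } else if (post_counts[2L] == 0L && post_counts[1L] > 0L) {
    Inf
  } else if (post_counts[1L] == 0L) {
    0
  } else {
    (post[1L] / post[2L]) / (pre[1L] / pre[2L])
  }
  list(fold = fold, pre = pre, post = post, n_sorted = length(surv))
}
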