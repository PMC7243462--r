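#' Error-prone PCR mutation model
#'
#' Describes the mutational load of an error-prone PCR library: the expected
#' number of nucleotide substitutions per clone (a Poisson mean, set
#' experimentally by the Mn2+ concentration during amplification) and the
#' substitution spectrum over the three alternate bases for each reference
#' base. The default spectrum is uniform; a 4x4 weight matrix (rows =
#' reference base, columns = alternate base, rows summing to 1 with zero
#' diagonal) can be supplied for a polymerase-specific bias.
#'
#' @param mean_mutations_per_clone Non-negative Poisson mean of nucleotide
#'   substitutions per clone.
#' @param substitution_weights Optional 4x4 numeric matrix with dimnames
#'   `c("A","C","G","T")`; row i gives the probability of each alternate base
#'   given reference base i. Defaults to uniform (1/3 each off-diagonal).
#' @return An object of class `MutationModel`.
#' @export
mutation_model <- function(mean_mutations_per_clone,
                           substitution_weights = NULL) {
  if (!is.numeric(mean_mutations_per_clone) || length(mean_mutations_per_clone) != 1L ||
      is.na(mean_mutations_per_clone) || mean_mutations_per_clone < 0) {
    stop("mean_mutations_per_clone must be a single non-negative number")
  }
  bases <- c("A", "C", "G", "T")
  if (is.null(substitution_weights)) {
    substitution_weights <- matrix(1 / 3, 4, 4, dimnames = list(bases, bases))
    diag(substitution_weights) <- 0
  } else {
    substitution_weights <- as.matrix(substitution_weights)
    if (!identical(dim(substitution_weights), c(4L, 4L)) ||
        !identical(rownames(substitution_weights), bases) ||
        !identical(colnames(substitution_weights), bases)) {
      stop("substitution_weights must be a 4x4 matrix with dimnames A,C,G,T")
    }
    if (any(substitution_weights < 0) || any(diag(substitution_weights) != 0)) {
      stop("substitution_weights must be non-negative with a zero diagonal")
    }
    rs <- rowSums(substitution_weights)
    if (any(abs(rs - 1) > 1e-8)) stop("substitution_weights rows must sum to 1")
  }
  structure(list(mean_mutations_per_clone = mean_mutations_per_clone,
                 substitution_weights = substitution_weights),
            class = "MutationModel")
}

#' Simulate one error-prone PCR clone
#'
#' Draws the number of nucleotide substitutions from
#' `Poisson(mean_mutations_per_clone)`, places them uniformly without
#' replacement over the region's nucleotide positions, draws each alternate
#' base from the model's substitution weights, and calls the resulting
#' amino-acid substitutions and flags against the wild type.
#'
#' @param region A [region()].
#' @param model A [mutation_model()].
#' @param seed Optional integer seed; the same (region, model, seed) always
#'   yields the identical clone.
#' @param clone_id Label for the clone.
#' @return A `CloneRecord`: list with `clone_id`, `region`, `nt_sequence`,
#'   `substitutions` (data frame position / wt_aa / mut_aa in full-protein
#'   coordinates), `flags` (`wt`, `nonsense`, `frameshift_suspected`),
#'   `nt_changes` (the planted nucleotide substitutions: nt_pos / ref / alt)
#'   and `true_signal` (filled in by [genotype_signal()] if desired).
#' @export
simulate_eppcr_clone <- function(region, model, seed = NULL, clone_id = "clone_1") {
  stopifnot(inherits(region, "Region"), inherits(model, "MutationModel"))
  if (!is.null(seed)) set.seed(seed)
  wt <- strsplit(region$wt_nt, "", fixed = TRUE)[[1L]]
  .simulate_clone_chars(wt, region, model, clone_id)
}

# core clone simulator on a pre-split wild-type character vector
.simulate_clone_chars <- function(wt, region, model, clone_id) {
  L <- length(wt)
  n_mut <- stats::rpois(1L, model$mean_mutations_per_clone)
  n_mut <- min(n_mut, L)
  if (n_mut > 0L) {
    pos <- sort(sample.int(L, n_mut))
    ref <- wt[pos]
    w <- model$substitution_weights
    bases <- colnames(w)
    alt <- character(n_mut)
    for (i in seq_len(n_mut)) {
      alt[i] <- sample(bases, 1L, prob = w[ref[i], ])
    }
    mutated <- wt
    mutated[pos] <- alt
    nt_changes <- data.frame(nt_pos = pos, ref = ref, alt = alt,
                             stringsAsFactors = FALSE)
    nt <- paste(mutated, collapse = "")
  } else {
    nt_changes <- data.frame(nt_pos = integer(), ref = character(),
                             alt = character(), stringsAsFactors = FALSE)
    nt <- region$wt_nt
  }
  calls <- call_substitutions(nt, region, clone_id = clone_id)
  structure(list(clone_id = clone_id, region = region$name, nt_sequence = nt,
                 substitutions = calls$substitutions, flags = calls$flags,
                 nt_changes = nt_changes, true_signal = NA_real_),
            class = "CloneRecord")
}

#' @export
print.CloneRecord <- function(x, ...) {
  fl <- names(Filter(isTRUE, x$flags))
  cat("<CloneRecord> ", x$clone_id, " (", x$region, "): ",
      nrow(x$substitutions), " aa substitution(s)",
      if (length(fl)) paste0(" [", paste(fl, collapse = ","), "]"), "\n", sep = "")
  invisible(x)
}

# deterministic per-clone seed derived from a master seed; stays below 2^31
clone_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) %% 2147483629 * 1000003 +
                as.numeric(index) * 7919) %% 2147483629)
}

#' Simulate an error-prone PCR clone library
#'
#' Generates `n_clones` independent clones. Per-clone seeds are derived
#' deterministically from the master seed, so a library is reproducible and
#' `simulate_library(..., n_clones = 1)` equals [simulate_eppcr_clone()] with
#' the derived seed.
#'
#' @inheritParams simulate_eppcr_clone
#' @param n_clones Number of clones (>= 1).
#' @param id_prefix Prefix for clone ids.
#' @return A list of `CloneRecord`s with class `CloneLibrary`.
#' @export
simulate_library <- function(region, model, n_clones, seed = NULL,
                             id_prefix = "clone") {
  stopifnot(inherits(region, "Region"), inherits(model, "MutationModel"))
  if (!is.numeric(n_clones) || n_clones < 1L) {
    stop("n_clones must be at least 1")
  }
  n_clones <- as.integer(n_clones)
  wt <- strsplit(region$wt_nt, "", fixed = TRUE)[[1L]]
  clones <- vector("list", n_clones)
  for (i in seq_len(n_clones)) {
    if (!is.null(seed)) set.seed(clone_seed(seed, i))
    clones[[i]] <- .simulate_clone_chars(wt, region, model,
                                         sprintf("%s_%05d", id_prefix, i))
  }
  structure(clones, class = "CloneLibrary", region = region$name)
}

#' Plant ground-truth phenotype effects on a region
#'
#' Chooses `n_specificity_positions` distinct residue positions and assigns
#' each `favorable_per_position` mutant amino acids (drawn from the
#' non-synonymous single-base neighbours of the wild-type codon, so planted
#' effects are reachable by error-prone PCR) with positive effect sizes on
#' the normalized autocrine scale drawn from a gamma distribution. All other
#' substitutions have effect 0 unless a deleterious background is requested.
#'
#' @param region A [region()].
#' @param n_specificity_positions Number of positions carrying favorable
#'   mutations (must not exceed the region length).
#' @param favorable_per_position Favorable mutant amino acids per chosen
#'   position (the target-size model's `a`; 1 or 2 in practice).
#' @param effect_mean,effect_shape Mean and gamma shape of the positive
#'   effect-size distribution (normalized signal units).
#' @param deleterious_fraction,deleterious_effect Fraction of the remaining
#'   single-base-reachable substitutions assigned a (typically small
#'   negative) effect, and that effect's value.
#' @param expression_penalty_per_mutation Per-substitution multiplicative
#'   expression penalty used by [genotype_expression()].
#' @param seed Optional integer seed.
#' @return An `EffectTable`: data frame (position, wt_aa, mut_aa, effect)
#'   with the expression penalty stored as an attribute.
#' @export
plant_effects <- function(region, n_specificity_positions,
                          favorable_per_position = 1L,
                          effect_mean = 0.12, effect_shape = 4,
                          deleterious_fraction = 0, deleterious_effect = -0.02,
                          expression_penalty_per_mutation = 0.05,
                          seed = NULL) {
  stopifnot(inherits(region, "Region"))
  n_res <- region_length(region)
  if (n_specificity_positions > n_res) {
    stop("requested ", n_specificity_positions, " specificity positions but the ",
         "region has only ", n_res, " residues")
  }
  if (favorable_per_position < 1L) stop("favorable_per_position must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  tab <- data.frame(position = integer(), wt_aa = character(),
                    mut_aa = character(), effect = numeric(),
                    stringsAsFactors = FALSE)
  if (n_specificity_positions > 0L) {
    idx <- sort(sample.int(n_res, n_specificity_positions))
    rows <- lapply(idx, function(i) {
      neigh <- codon_neighbor_aas(region$wt_codons[i])
      if (length(neigh) < favorable_per_position) {
        stop("codon ", region$wt_codons[i], " at residue ",
             region$start_residue + i - 1L, " has only ", length(neigh),
             " non-synonymous single-base neighbour amino acid(s)")
      }
      mut <- sample(neigh, favorable_per_position)
      data.frame(position = region$start_residue + i - 1L,
                 wt_aa = region$wt_aa[i], mut_aa = mut,
                 effect = stats::rgamma(length(mut), shape = effect_shape,
                                        rate = effect_shape / effect_mean),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
  }
  if (deleterious_fraction > 0) {
    all_idx <- seq_len(n_res)
    others <- do.call(rbind, lapply(all_idx, function(i) {
      neigh <- codon_neighbor_aas(region$wt_codons[i])
      if (!length(neigh)) return(NULL)
      data.frame(position = region$start_residue + i - 1L,
                 wt_aa = region$wt_aa[i], mut_aa = neigh,
                 stringsAsFactors = FALSE)
    }))
    key <- paste(others$position, others$mut_aa)
    planted <- paste(tab$position, tab$mut_aa)
    others <- others[!key %in% planted, , drop = FALSE]
    n_del <- round(deleterious_fraction * nrow(others))
    if (n_del > 0L) {
      pick <- others[sample.int(nrow(others), n_del), , drop = FALSE]
      pick$effect <- deleterious_effect
      tab <- rbind(tab, pick)
    }
  }
  stopifnot(all(tab$mut_aa != tab$wt_aa))
  rownames(tab) <- NULL
  structure(tab, class = c("EffectTable", "data.frame"),
            expression_penalty_per_mutation = expression_penalty_per_mutation)
}

# distinct non-synonymous, non-stop amino acids reachable from a codon by one
# nucleotide change
codon_neighbor_aas <- function(codon) {
  wt_aa <- translate_codons(codon)
  chars <- strsplit(codon, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (p in 1:3) {
    for (b in setdiff(bases, chars[p])) {
      mutant <- chars
      mutant[p] <- b
      aa <- translate_codons(paste(mutant, collapse = ""))
      if (aa != "*" && aa != wt_aa) out <- c(out, aa)
    }
  }
  unique(out)
}

#' Latent autocrine signal of a genotype under the additive model
#'
#' The latent signal is `baseline + sum(effects over the clone's
#' substitutions) + Gaussian measurement noise`. Nonsense or
#' frameshift-suspected clones have truncated, non-functional transporters
#' and get the empty-plasmid level (0) as their latent value regardless of
#' planted effects. Signals are not clamped to [0, 1] by default: the
#' normalization anchors are conventions, not physical bounds.
#'
#' @param clone A `CloneRecord`.
#' @param effects An `EffectTable` from [plant_effects()].
#' @param baseline Wild-type normalized autocrine signal (the starting
#'   transporter's weak activity for the non-cognate pheromone).
#' @param noise_sd Gaussian measurement noise SD on the normalized scale.
#' @param seed Optional integer seed.
#' @param clamp If `TRUE`, clamp the returned signal to [0, 1].
#' @return A single normalized signal value.
#' @export
genotype_signal <- function(clone, effects, baseline = 0.05, noise_sd = 0,
                            seed = NULL, clamp = FALSE) {
  stopifnot(inherits(clone, "CloneRecord"))
  if (!is.null(seed)) set.seed(seed)
  if (isTRUE(clone$flags$nonsense) || isTRUE(clone$flags$frameshift_suspected)) {
    latent <- 0
  } else {
    latent <- baseline + sum(effect_lookup(clone$substitutions, effects))
  }
  sig <- latent + if (noise_sd > 0) stats::rnorm(1L, 0, noise_sd) else 0
  if (clamp) sig <- min(1, max(0, sig))
  sig
}

# effect sizes for a substitution table; unplanted substitutions contribute 0
effect_lookup <- function(substitutions, effects) {
  if (!nrow(substitutions)) return(numeric(0))
  key <- paste(substitutions$position, substitutions$mut_aa)
  ekey <- paste(effects$position, effects$mut_aa)
  out <- effects$effect[match(key, ekey)]
  out[is.na(out)] <- 0
  out
}

#' Latent transporter expression of a genotype
#'
#' Expression decays multiplicatively with the number of amino-acid
#' substitutions, `(1 - penalty)^n`, capturing the observation that median
#' transporter expression of a library falls as its average mutation count
#' rises. Truncated (nonsense/frameshift) clones get expression 0.
#'
#' @param clone A `CloneRecord`.
#' @param penalty_per_mutation Per-substitution fractional expression loss,
#'   in [0, 1).
#' @return Normalized expression (wild type = 1, empty plasmid = 0).
#' @export
genotype_expression <- function(clone, penalty_per_mutation = 0.05) {
  stopifnot(inherits(clone, "CloneRecord"),
            penalty_per_mutation >= 0, penalty_per_mutation < 1)
  if (isTRUE(clone$flags$nonsense) || isTRUE(clone$flags$frameshift_suspected)) {
    return(0)
  }
  (1 - penalty_per_mutation)^nrow(clone$substitutions)
}

#' Latent signals for every clone of a library
#'
#' Convenience wrapper applying [genotype_signal()] and
#' [genotype_expression()] across a `CloneLibrary`, with per-clone seeds
#' derived from the master seed when noise is simulated.
#'
#' @inheritParams genotype_signal
#' @param library A `CloneLibrary`.
#' @return Data frame with one row per clone: clone_id, n_substitutions,
#'   nonsense, autocrine, expression.
#' @export
library_signals <- function(library, effects, baseline = 0.05, noise_sd = 0,
                            seed = NULL) {
  stopifnot(inherits(library, "CloneLibrary"))
  penalty <- attr(effects, "expression_penalty_per_mutation")
  if (is.null(penalty)) penalty <- 0.05
  n <- length(library)
  auto <- numeric(n)
  expr <- numeric(n)
  for (i in seq_len(n)) {
    s <- if (!is.null(seed)) clone_seed(seed, i) else NULL
    auto[i] <- genotype_signal(library[[i]], effects, baseline, noise_sd, seed = s)
    expr[i] <- genotype_expression(library[[i]], penalty)
  }
  data.frame(clone_id = vapply(library, `[[`, "", "clone_id"),
             n_substitutions = vapply(library, function(cl) nrow(cl$substitutions), 0L),
             nonsense = vapply(library, function(cl) isTRUE(cl$flags$nonsense), TRUE),
             autocrine = auto, expression = expr, stringsAsFactors = FALSE)
}

#' Default fluorescence anchors linking normalized signals to raw units
#'
#' Raw fluorescence is an affine map of the normalized scale:
#' `raw = empty + normalized * (positive - empty)`. The autocrine channel is
#' anchored by the empty-plasmid (0) and strong-exporter (1) controls; the
#' expression channel by empty plasmid (0) and the wild-type transporter (1).
#'
#' @return Named list with `autocrine` and `expression` anchor pairs
#'   (`empty`, `positive`) in arbitrary fluorescence units.
#' @export
default_anchors <- function() {
  list(autocrine = c(empty = 100, positive = 2000),
       expression = c(empty = 100, positive = 2000))
}

norm_to_raw <- function(normalized, anchor) {
  pmax(1, anchor[["empty"]] + normalized * (anchor[["positive"]] - anchor[["empty"]]))
}

#' Simulate two-channel cytometry events for one sample
#'
#' Events are log-normally distributed around the sample's latent channel
#' means with coefficient of variation `cv`; the log-normal is parameterized
#' so its median equals the latent raw value, hence the median of a large
#' event set recovers the latent signal. `cv = 0` is the degenerate limit in
#' which every event equals the latent mean.
#'
#' @param latent_autocrine,latent_expression Latent normalized signals.
#' @param n_events Number of events (>= 1).
#' @param cv Per-event coefficient of variation (>= 0).
#' @param anchors Anchor list as from [default_anchors()].
#' @param seed Optional integer seed.
#' @param sample_id Sample label.
#' @return Data frame (class `CytometryEventSet`) with columns `sample_id`,
#'   `autocrine`, `expression`; all values positive.
#' @export
simulate_cytometry <- function(latent_autocrine, latent_expression,
                               n_events = 30000L, cv = 0.3,
                               anchors = default_anchors(), seed = NULL,
                               sample_id = "sample") {
  if (n_events < 1L) stop("n_events must be >= 1")
  if (!is.numeric(cv) || length(cv) != 1L || is.na(cv) || cv < 0) {
    stop("cv must be a single non-negative number")
  }
  if (!is.null(seed)) set.seed(seed)
  mu_a <- norm_to_raw(latent_autocrine, anchors$autocrine)
  mu_e <- norm_to_raw(latent_expression, anchors$expression)
  if (cv == 0) {
    a <- rep(mu_a, n_events)
    e <- rep(mu_e, n_events)
  } else {
    sdlog <- sqrt(log1p(cv^2))
    a <- stats::rlnorm(n_events, meanlog = log(mu_a), sdlog = sdlog)
    e <- stats::rlnorm(n_events, meanlog = log(mu_e), sdlog = sdlog)
  }
  structure(data.frame(sample_id = sample_id, autocrine = a, expression = e,
                       stringsAsFactors = FALSE),
            class = c("CytometryEventSet", "data.frame"))
}
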