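#' Call amino-acid substitutions in a clone against the wild-type region
#'
#' Codon-by-codon comparison of an in-frame clone sequence to the region's
#' wild type. Synonymous changes are ignored; positions are reported in
#' full-protein coordinates. A premature stop codon sets the `nonsense`
#' flag (the stop is reported with `mut_aa = "*"`); a clone whose length
#' differs from the reference is flagged `frameshift_suspected` and yields
#' no calls.
#'
#' @param clone_nt Clone nucleotide sequence (A/C/G/T).
#' @param region A [region()].
#' @param clone_id Optional label used in error messages.
#' @return List with `substitutions` (data frame position / wt_aa / mut_aa)
#'   and `flags` (`wt`, `nonsense`, `frameshift_suspected`).
#' @export
call_substitutions <- function(clone_nt, region, clone_id = NULL) {
  stopifnot(inherits(region, "Region"))
  clone_nt <- toupper(as.character(clone_nt))
  if (!nzchar(clone_nt)) stop("empty clone sequence",
                              if (!is.null(clone_id)) paste0(" for record '", clone_id, "'"))
  if (grepl("[^ACGT]", clone_nt)) {
    stop("non-ACGT character in record '",
         if (is.null(clone_id)) "<unnamed>" else clone_id, "'")
  }
  flags <- list(wt = FALSE, nonsense = FALSE, frameshift_suspected = FALSE)
  empty <- data.frame(position = integer(), wt_aa = character(),
                      mut_aa = character(), stringsAsFactors = FALSE)
  if (nchar(clone_nt) != nchar(region$wt_nt)) {
    flags$frameshift_suspected <- TRUE
    return(list(substitutions = empty, flags = flags))
  }
  clone_codons <- nt_to_codons(clone_nt)
  diff <- which(clone_codons != region$wt_codons)
  if (!length(diff)) {
    flags$wt <- TRUE
    return(list(substitutions = empty, flags = flags))
  }
  wt_aa <- region$wt_aa[diff]
  mut_aa <- translate_codons(clone_codons[diff])
  flags$nonsense <- any(mut_aa == "*")
  keep <- mut_aa != wt_aa
  subs <- data.frame(position = region$start_residue + diff[keep] - 1L,
                     wt_aa = wt_aa[keep], mut_aa = mut_aa[keep],
                     stringsAsFactors = FALSE)
  if (!nrow(subs) && !flags$nonsense) flags$wt <- TRUE
  list(substitutions = subs, flags = flags)
}

#' Build a CloneRecord from a raw sequence
#'
#' Ingestion path for sequenced colonies: wraps [call_substitutions()] into
#' the same record structure the simulator produces (without ground-truth
#' nucleotide changes).
#'
#' @inheritParams call_substitutions
#' @return A `CloneRecord`.
#' @export
clone_record <- function(clone_nt, region, clone_id = "clone") {
  calls <- call_substitutions(clone_nt, region, clone_id = clone_id)
  nt_pos <- integer(0); ref <- alt <- character(0)
  if (nchar(clone_nt) == nchar(region$wt_nt)) {
    a <- strsplit(toupper(clone_nt), "", fixed = TRUE)[[1L]]
    b <- strsplit(region$wt_nt, "", fixed = TRUE)[[1L]]
    nt_pos <- which(a != b)
    ref <- b[nt_pos]; alt <- a[nt_pos]
  }
  structure(list(clone_id = clone_id, region = region$name,
                 nt_sequence = toupper(clone_nt),
                 substitutions = calls$substitutions, flags = calls$flags,
                 nt_changes = data.frame(nt_pos = nt_pos, ref = ref, alt = alt,
                                         stringsAsFactors = FALSE),
                 true_signal = NA_real_),
            class = "CloneRecord")
}

#' Deduplicate clones by their differences from the reference
#'
#' Clone identity defaults to the exact set of nucleotide differences from
#' the wild type, so two clones producing the same amino-acid changes via
#' different codons remain distinct (Sanger data resolves them); an
#' amino-acid-level mode is available. Length-mismatched clones are keyed on
#' their full sequence.
#'
#' @param clones List of `CloneRecord`s (e.g. a `CloneLibrary`), all from
#'   one region.
#' @param region The common [region()].
#' @param by `"nucleotide"` (default) or `"protein"`.
#' @return List with `unique_clones` (one representative per genotype, in
#'   order of first appearance) and `multiplicity` (data frame key /
#'   clone_id of the representative / n). Multiplicities sum to the input
#'   count.
#' @export
dedupe_clones <- function(clones, region, by = c("nucleotide", "protein")) {
  by <- match.arg(by)
  stopifnot(inherits(region, "Region"))
  if (!length(clones)) {
    return(list(unique_clones = list(),
                multiplicity = data.frame(key = character(), clone_id = character(),
                                          n = integer(), stringsAsFactors = FALSE)))
  }
  regions <- vapply(clones, `[[`, "", "region")
  if (length(unique(regions)) > 1L || unique(regions) != region$name) {
    stop("clones come from more than one region (or not from '", region$name, "')")
  }
  keys <- vapply(clones, clone_key, "", region = region, by = by)
  first <- !duplicated(keys)
  unique_clones <- clones[first]
  tab <- table(factor(keys, levels = keys[first]))
  list(unique_clones = unique_clones,
       multiplicity = data.frame(key = names(tab),
                                 clone_id = vapply(unique_clones, `[[`, "", "clone_id"),
                                 n = as.integer(tab), stringsAsFactors = FALSE))
}

clone_key <- function(clone, region, by) {
  if (isTRUE(clone$flags$frameshift_suspected)) {
    return(paste0("seq:", clone$nt_sequence))
  }
  if (by == "nucleotide") {
    a <- strsplit(clone$nt_sequence, "", fixed = TRUE)[[1L]]
    b <- strsplit(region$wt_nt, "", fixed = TRUE)[[1L]]
    d <- which(a != b)
    if (!length(d)) return("wt")
    paste(d, a[d], sep = ":", collapse = ";")
  } else {
    s <- clone$substitutions
    if (!nrow(s)) return("wt")
    o <- order(s$position, s$mut_aa)
    paste(s$position[o], s$mut_aa[o], sep = ":", collapse = ";")
  }
}

#' Mutations-per-position spectrum over unique clones
#'
#' Counts, at each residue of the region, the number of unique clones
#' carrying a non-synonymous substitution there (a clone contributes at most
#' once per position under the default clone tally; the `"event"` tally
#' counts raw substitution calls). Clones flagged nonsense or
#' frameshift-suspected are excluded by default: truncated transporters were
#' not among the functional selected clones.
#'
#' @param unique_clones List of deduplicated `CloneRecord`s.
#' @param region The common [region()].
#' @param include_nonsense Keep nonsense-flagged clones' missense calls?
#' @param tally `"clone"` (default) or `"event"`.
#' @return A `MutationSpectrum`: list with `region`, `positions`
#'   (full-protein coordinates), `counts`, `n_unique_clones` (clones
#'   tallied) and `total_mutations` (= sum of counts).
#' @export
per_position_counts <- function(unique_clones, region,
                                include_nonsense = FALSE,
                                tally = c("clone", "event")) {
  tally <- match.arg(tally)
  stopifnot(inherits(region, "Region"))
  positions <- seq.int(region$start_residue, region$end_residue)
  counts <- integer(length(positions))
  used <- 0L
  for (clone in unique_clones) {
    if (isTRUE(clone$flags$frameshift_suspected)) next
    if (!include_nonsense && isTRUE(clone$flags$nonsense)) next
    used <- used + 1L
    s <- clone$substitutions
    if (!nrow(s)) next
    pos <- s$position
    if (tally == "clone") pos <- unique(pos)
    idx <- pos - region$start_residue + 1L
    stopifnot(all(idx >= 1L & idx <= length(positions)))
    tab <- tabulate(idx, nbins = length(positions))
    counts <- counts + tab
  }
  mutation_spectrum(counts, positions, region = region$name,
                    n_unique_clones = used)
}

#' Construct a mutation spectrum object
#'
#' @param counts Integer vector of per-position non-synonymous mutation
#'   counts.
#' @param positions Full-protein coordinates (defaults to `1:length(counts)`).
#' @param region Region label.
#' @param n_unique_clones Number of unique clones tallied (may be `NA` for
#'   directly simulated spectra).
#' @return A `MutationSpectrum`.
#' @export
mutation_spectrum <- function(counts, positions = seq_along(counts),
                              region = "region", n_unique_clones = NA_integer_) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == length(positions), all(counts >= 0L))
  structure(list(region = region, positions = as.integer(positions),
                 counts = counts, n_unique_clones = n_unique_clones,
                 total_mutations = sum(counts)),
            class = "MutationSpectrum")
}

#' @export
print.MutationSpectrum <- function(x, ...) {
  cat("<MutationSpectrum> ", x$region, ": ", x$total_mutations,
      " mutations over ", length(x$counts), " positions",
      if (!is.na(x$n_unique_clones)) paste0(" (", x$n_unique_clones, " unique clones)"),
      "\n", sep = "")
  invisible(x)
}

#' Per-column mean pairwise identity of a protein alignment
#'
#' For each alignment column that is non-gap in the reference row, computes
#' the fraction of unordered pairs of non-gap residues that are identical.
#' Gaps do not participate (they are neither match nor mismatch); columns
#' with fewer than two non-gap rows are reported as `NA`.
#'
#' @param msa Aligned protein sequences: an `AAStringSet`, or a character
#'   vector of equal-length aligned strings. Gap characters are `-` and `.`.
#' @param reference Index or name of the reference row whose non-gap columns
#'   are kept.
#' @return Data frame (class `ConservationProfile`) with `column` (1-based
#'   index along the ungapped reference) and `identity` in [0, 1] or `NA`.
#' @export
column_mean_pairwise_identity <- function(msa, reference = 1L) {
  if (methods::is(msa, "XStringSet")) msa <- as.character(msa)
  stopifnot(is.character(msa), length(msa) >= 1L)
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L) stop("ragged alignment: rows differ in length")
  if (is.character(reference)) {
    reference <- match(reference, names(msa))
    if (is.na(reference)) stop("reference row not found in alignment")
  }
  if (reference < 1L || reference > length(msa)) stop("reference row out of range")
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  gap <- mat == "-" | mat == "."
  keep <- which(!gap[reference, ])
  identity <- vapply(keep, function(j) {
    res <- mat[!gap[, j], j]
    n <- length(res)
    if (n < 2L) return(NA_real_)
    tab <- table(res)
    sum(choose(tab, 2)) / choose(n, 2)
  }, numeric(1))
  structure(data.frame(column = seq_along(keep), identity = identity),
            class = c("ConservationProfile", "data.frame"))
}

#' Correlate autocrine signal change with mutation count
#'
#' Pearson correlation between per-clone mutation count and normalized
#' signal difference, optionally restricted to mutation-count bins holding
#' more than `bin_min_clones` clones (as used when sparse high-count bins
#' would dominate).
#'
#' @param mutation_counts Integer vector, one per clone.
#' @param signal_deltas Normalized signal differences (clone minus wild
#'   type), same length.
#' @param bin_min_clones If non-`NULL`, keep only clones whose mutation
#'   count value occurs in more than this many clones.
#' @return Pearson r, or `NA` (with a warning) when either variable has zero
#'   variance or fewer than 3 clones remain.
#' @export
correlate_signal_mutcount <- function(mutation_counts, signal_deltas,
                                      bin_min_clones = NULL) {
  stopifnot(length(mutation_counts) == length(signal_deltas))
  ok <- is.finite(mutation_counts) & is.finite(signal_deltas)
  x <- mutation_counts[ok]
  y <- signal_deltas[ok]
  if (!is.null(bin_min_clones)) {
    tab <- table(x)
    keepv <- as.integer(names(tab)[tab > bin_min_clones])
    sel <- x %in% keepv
    x <- x[sel]; y <- y[sel]
  }
  if (length(x) < 3L) {
    warning("fewer than 3 clones with finite values; correlation undefined")
    return(NA_real_)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}
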