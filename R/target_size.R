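#' Exact binomial coefficient
#'
#' Multiplicative-formula evaluation of C(n, k) in which every intermediate
#' value is an exact integer (division by `i` at step `i` is always exact).
#' All quantities handled by the target-size model stay far below 2^53, so
#' the arithmetic is exact; an integrality check guards each step.
#'
#' @param n,k Non-negative integers with `k <= n`.
#' @return C(n, k) as an exact integer-valued numeric.
#' @examples
#' nchoosek(160, 3)  # 669920
#' @export
nchoosek <- function(n, k) {
  if (any(c(n, k) < 0) || k > n || n != round(n) || k != round(k)) {
    stop("require integers 0 <= k <= n")
  }
  k <- min(k, n - k)
  res <- 1
  for (i in seq_len(k)) {
    res <- res * (n - k + i) / i
    if (res != round(res)) stop("binomial coefficient arithmetic lost exactness")
    if (res > 2^53) stop("binomial coefficient exceeds exact double range")
  }
  res
}

#' Size of the k-mutant nucleotide sequence space
#'
#' Number of distinct clones with non-synonymous single-base substitutions
#' at exactly `k` of `L` codons, with `s` non-synonymous single-base
#' substitutions available per codon: `C(L, k) * s^k`. The default `s = 6`
#' comes from the simplification that the first two codon positions each
#' admit three non-synonymous alternate bases while third-position changes
#' are synonymous.
#'
#' @param L Region length in codons.
#' @param k Number of mutated codons.
#' @param s Non-synonymous single-base substitutions per codon.
#' @return List with `exact` (integer-valued) and `rounded` (3 significant
#'   figures, as reported in print).
#' @examples
#' space_size(160, 3, 6)  # 144,702,720 exact; 1.45e8 rounded
#' @export
space_size <- function(L, k, s) {
  if (any(c(L, k, s) < 0) || any(c(L, k, s) != round(c(L, k, s)))) {
    stop("L, k, s must be non-negative integers")
  }
  if (k > L) stop("k must not exceed L")
  exact <- nchoosek(L, k) * s^k
  list(exact = exact, rounded = signif(exact, 3))
}

#' Observed hit fraction of a selection
#'
#' @param n_hits Independent selected clones (0 <= n_hits <= library_size).
#' @param library_size Library complexity (> 0).
#' @return `n_hits / library_size`.
#' @export
hit_fraction <- function(n_hits, library_size) {
  if (library_size <= 0) stop("library_size must be positive")
  if (n_hits < 0 || n_hits > library_size) {
    stop("n_hits must lie in [0, library_size]")
  }
  n_hits / library_size
}

#' Number of clones in sequence space that satisfy the selection
#'
#' @param f Hit fraction in [0, 1].
#' @param space Sequence-space size (exact or rounded).
#' @return `f * space`.
#' @export
favorable_clones <- function(f, space) {
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  f * space
}

#' Favorable mutation combinations per set of k positions
#'
#' With `a` favorable mutant amino acids at each of `k` positions there are
#' `a^k` favorable combinations per position set.
#'
#' @param a Favorable amino acids per position (>= 1).
#' @param k Number of positions (>= 0).
#' @return `a^k`, exact.
#' @export
favorable_combinations_per_set <- function(a, k) {
  if (a < 1 || k < 0 || a != round(a) || k != round(k)) {
    stop("require integers a >= 1, k >= 0")
  }
  res <- 1
  for (i in seq_len(k)) res <- res * a
  res
}

#' Invert the combinatorial model for the number of specificity positions
#'
#' Finds the smallest integer `P` such that `C(P, k) * a^k >= H`, i.e. the
#' number of positions able to mutate toward the new specificity that is
#' just large enough for the favorable k-mutant count to reach the observed
#' `H`. This inversion rule reproduces the printed answers for both one and
#' two favorable amino acids per position.
#'
#' @param H Favorable clone count (> 0).
#' @param k Required number of mutated positions (>= 1).
#' @param a Favorable amino acids per position (>= 1).
#' @param cap Largest `P` searched (default 1600); beyond it the model is
#'   reported unsatisfiable.
#' @return List with `P`, `achieved` (= C(P,k) * a^k) and `satisfiable`;
#'   `P = NA` when no `P <= cap` works.
#' @examples
#' infer_positions(72500, 3, 1)$P  # 77
#' infer_positions(72500, 3, 2)$P  # 39
#' @export
infer_positions <- function(H, k, a, cap = 1600L) {
  if (H <= 0) stop("H must be positive")
  if (k < 1 || a < 1) stop("require k >= 1 and a >= 1")
  ak <- favorable_combinations_per_set(a, k)
  for (P in k:cap) {
    achieved <- nchoosek(P, k) * ak
    if (achieved >= H) {
      return(list(P = as.integer(P), achieved = achieved, satisfiable = TRUE))
    }
  }
  list(P = NA_integer_, achieved = NA_real_, satisfiable = FALSE)
}

#' Full target-size calculation chain
#'
#' Runs the combinatorial estimate end to end: sequence-space size, hit
#' fraction, favorable clone count, and the inferred number of specificity
#' positions for each assumed number of favorable amino acids per position.
#' By default the favorable-clone count uses the 3-significant-figure space
#' (following the published arithmetic); the exact-space alternative is
#' reported alongside.
#'
#' @param L Region length in codons (default 160).
#' @param k Required number of mutated positions (default 3).
#' @param s Non-synonymous single-base substitutions per codon (default 6).
#' @param n_hits Independent selected clones (default 50).
#' @param library_size Library complexity (default 1e5).
#' @param a Favorable amino acids per position; may be a vector (default
#'   `c(1, 2)`).
#' @param use_rounded_space Use the rounded space for the favorable-clone
#'   count (default `TRUE`).
#' @return List of every intermediate quantity: `combinations` (C(L,k)),
#'   `per_set` (s^k), `space_exact`, `space_rounded`, `hit_fraction`,
#'   `favorable_rounded`, `favorable_exact`, and `positions` (data frame
#'   with a, P, achieved).
#' @export
target_size_report <- function(L = 160L, k = 3L, s = 6L, n_hits = 50L,
                               library_size = 1e5, a = c(1L, 2L),
                               use_rounded_space = TRUE) {
  comb <- nchoosek(L, k)
  per_set <- favorable_combinations_per_set(s, k)
  space <- space_size(L, k, s)
  f <- hit_fraction(n_hits, library_size)
  H_rounded <- favorable_clones(f, space$rounded)
  H_exact <- favorable_clones(f, space$exact)
  H_used <- if (use_rounded_space) H_rounded else H_exact
  pos <- do.call(rbind, lapply(a, function(ai) {
    inv <- infer_positions(H_used, k, ai)
    data.frame(a = ai, P = inv$P, achieved = inv$achieved)
  }))
  list(L = L, k = k, s = s, n_hits = n_hits, library_size = library_size,
       combinations = comb, per_set = per_set,
       space_exact = space$exact, space_rounded = space$rounded,
       hit_fraction = f, favorable_rounded = H_rounded,
       favorable_exact = H_exact, favorable_used = H_used,
       positions = pos)
}

#' Codon-aware non-synonymous substitution count
#'
#' Exact per-codon enumeration of single-base changes that alter the encoded
#' amino acid (excluding changes to stop codons), as a refinement of the
#' fixed `s = 6` simplification for a supplied reference region.
#'
#' @param region A [region()].
#' @return Integer vector, one count per codon.
#' @export
nonsynonymous_per_codon <- function(region) {
  stopifnot(inherits(region, "Region"))
  vapply(region$wt_codons, function(codon) {
    wt_aa <- translate_codons(codon)
    chars <- strsplit(codon, "", fixed = TRUE)[[1L]]
    bases <- c("A", "C", "G", "T")
    n <- 0L
    for (p in 1:3) {
      for (b in setdiff(bases, chars[p])) {
        mutant <- chars
        mutant[p] <- b
        aa <- translate_codons(paste(mutant, collapse = ""))
        if (aa != "*" && aa != wt_aa) n <- n + 1L
      }
    }
    n
  }, integer(1), USE.NAMES = FALSE)
}
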