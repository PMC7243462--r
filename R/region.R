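#' Define a mutagenized region of the wild-type transporter gene
#'
#' A `Region` holds the in-frame wild-type nucleotide sequence of one
#' mutagenized segment together with its coordinates in full-protein
#' numbering. The two regions used in the selection experiments this package
#' models are transmembrane helices 4-6 (residues 199-359) and 10-12
#' (residues 851-1012) of a fungal pheromone exporter; any in-frame segment
#' without an internal stop codon is accepted.
#'
#' @param name Label for the region (e.g. `"TM4-6"`).
#' @param start_residue 1-based position of the region's first codon in
#'   full-protein coordinates.
#' @param wt_nt Wild-type nucleotide sequence, in frame; length must be a
#'   multiple of 3 and the translation must contain no stop codon.
#' @param end_residue Optional; if given, must equal
#'   `start_residue + nchar(wt_nt)/3 - 1`.
#'
#' @return An object of class `Region` with fields `name`, `start_residue`,
#'   `end_residue`, `wt_nt`, and cached `wt_codons` / `wt_aa`.
#' @examples
#' r <- region("toy", 199, "ATGCTGGGT")
#' r$wt_aa
#' @export
region <- function(name, start_residue, wt_nt, end_residue = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  wt_nt <- toupper(as.character(wt_nt))
  if (grepl("[^ACGT]", wt_nt)) {
    stop("wild-type sequence for region '", name, "' contains non-ACGT characters")
  }
  if (nchar(wt_nt) %% 3L != 0L) {
    stop("wild-type sequence length (", nchar(wt_nt), ") is not a multiple of 3")
  }
  wt_codons <- nt_to_codons(wt_nt)
  wt_aa <- translate_codons(wt_codons)
  if (any(wt_aa == "*")) {
    stop("wild-type sequence for region '", name, "' contains an internal stop codon")
  }
  n_res <- length(wt_codons)
  start_residue <- as.integer(start_residue)
  computed_end <- start_residue + n_res - 1L
  if (!is.null(end_residue) && as.integer(end_residue) != computed_end) {
    stop("end_residue (", end_residue, ") inconsistent with start_residue and ",
         "sequence length (expected ", computed_end, ")")
  }
  structure(
    list(name = name, start_residue = start_residue, end_residue = computed_end,
         wt_nt = wt_nt, wt_codons = wt_codons, wt_aa = wt_aa),
    class = "Region"
  )
}

#' @export
print.Region <- function(x, ...) {
  cat("<Region> ", x$name, ": residues ", x$start_residue, "-", x$end_residue,
      " (", length(x$wt_codons), " codons, ", nchar(x$wt_nt), " nt)\n", sep = "")
  invisible(x)
}

#' Number of residues in a region
#' @param region A [region()] object.
#' @return Integer count of codons/residues.
#' @export
region_length <- function(region) {
  stopifnot(inherits(region, "Region"))
  length(region$wt_codons)
}

#' Generate a random stop-free in-frame region
#'
#' Draws codons uniformly from the 61 sense codons of the standard genetic
#' code. Used to build synthetic wild-type references for simulation studies
#' at the scale of the real mutagenized segments (about 160 codons).
#'
#' @inheritParams region
#' @param n_codons Number of codons (default 160).
#' @param seed Optional integer seed.
#' @return A `Region`.
#' @export
random_region <- function(n_codons = 160L, name = "TM4-6", start_residue = 199L,
                          seed = NULL) {
  stopifnot(n_codons >= 1L)
  if (!is.null(seed)) set.seed(seed)
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  region(name, start_residue, paste(sample(sense, n_codons, replace = TRUE),
                                    collapse = ""))
}

# split an in-frame nucleotide string into codon strings
nt_to_codons <- function(nt) {
  n <- nchar(nt)
  substring(nt, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
}

# standard genetic code lookup; stop codons translate to "*"
translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) stop("cannot translate codon(s): ",
                      paste(unique(codons[is.na(aa)]), collapse = ", "))
  aa
}
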