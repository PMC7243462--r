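#' Read a wild-type region from a FASTA file
#'
#' The first record supplies the wild-type nucleotide sequence; the region
#' name defaults to the record id.
#'
#' @param file Path to a FASTA file.
#' @param start_residue 1-based protein coordinate of the region's first
#'   codon.
#' @param name Optional region name overriding the record id.
#' @return A [region()].
#' @export
read_region_fasta <- function(file, start_residue, name = NULL) {
  seqs <- Biostrings::readDNAStringSet(file)
  if (!length(seqs)) stop("no records in ", file)
  id <- if (is.null(name)) sub("\\s.*$", "", names(seqs)[1L]) else name
  region(id, start_residue, as.character(seqs[[1L]]))
}

#' Read clone sequences from a FASTA file
#'
#' One record per sequenced clone; record ids become clone ids.
#'
#' @param file Path to a FASTA file of clone nucleotide sequences.
#' @param region The [region()] the clones were amplified from.
#' @return A `CloneLibrary` (list of `CloneRecord`s).
#' @export
read_clones_fasta <- function(file, region) {
  seqs <- Biostrings::readDNAStringSet(file)
  ids <- sub("\\s.*$", "", names(seqs))
  clones <- lapply(seq_along(seqs), function(i) {
    clone_record(as.character(seqs[[i]]), region, clone_id = ids[i])
  })
  structure(clones, class = "CloneLibrary", region = region$name)
}

#' Write clone sequences to a FASTA file
#'
#' @param clones A `CloneLibrary` or list of `CloneRecord`s.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_clones_fasta <- function(clones, file) {
  seqs <- Biostrings::DNAStringSet(vapply(clones, `[[`, "", "nt_sequence"))
  names(seqs) <- vapply(clones, `[[`, "", "clone_id")
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}

#' Read a protein multiple sequence alignment from FASTA
#'
#' @param file Path to an aligned protein FASTA file.
#' @return A named character vector of aligned sequences.
#' @export
read_msa_fasta <- function(file) {
  seqs <- Biostrings::readAAStringSet(file)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write / read an effect table as tab-separated text
#'
#' Columns: position, wt_aa, mut_aa, effect. The expression penalty is kept
#' in a `# expression_penalty_per_mutation:` header comment.
#'
#' @param effects An `EffectTable`.
#' @param file Path.
#' @return `file` invisibly (write) or an `EffectTable` (read).
#' @export
write_effect_table <- function(effects, file) {
  pen <- attr(effects, "expression_penalty_per_mutation")
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(pen)) {
    writeLines(paste0("# expression_penalty_per_mutation: ", pen), con)
  }
  utils::write.table(as.data.frame(effects), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_effect_table
#' @export
read_effect_table <- function(file) {
  first <- readLines(file, n = 1L)
  pen <- 0.05
  if (startsWith(first, "#")) {
    pen <- as.numeric(sub(".*:", "", first))
  }
  tab <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  structure(tab, class = c("EffectTable", "data.frame"),
            expression_penalty_per_mutation = pen)
}

#' Write / read a mutation spectrum as tab-separated text
#'
#' Columns: position, count.
#'
#' @param spectrum A `MutationSpectrum`.
#' @param file Path.
#' @param region Region label for the read spectrum.
#' @return `file` invisibly (write) or a `MutationSpectrum` (read).
#' @export
write_spectrum <- function(spectrum, file) {
  stopifnot(inherits(spectrum, "MutationSpectrum"))
  utils::write.table(data.frame(position = spectrum$positions,
                                count = spectrum$counts),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(file, region = "region") {
  tab <- utils::read.table(file, header = TRUE, sep = "\t")
  mutation_spectrum(tab$count, tab$position, region = region)
}

#' Write / read cytometry event sets as CSV
#'
#' Columns: sample_id, autocrine, expression.
#'
#' @param events A `CytometryEventSet` (or compatible data frame).
#' @param file Path.
#' @return `file` invisibly (write) or a `CytometryEventSet` (read).
#' @export
write_events_csv <- function(events, file) {
  utils::write.csv(as.data.frame(events)[, c("sample_id", "autocrine", "expression")],
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  structure(tab, class = c("CytometryEventSet", "data.frame"))
}

#' Read a simulation configuration file
#'
#' A YAML file with keys `region` (name, start_residue, and either `wt_nt`
#' or `n_codons` for a random reference), `mutation_model`
#' (mean_mutations_per_clone), `effects` (n_specificity_positions,
#' favorable_per_position, ...), `noise` (baseline, noise_sd) and `seed`.
#'
#' @param file Path to the YAML config.
#' @return The parsed configuration list.
#' @export
read_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  need <- c("region", "mutation_model")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) stop("config missing keys: ", paste(missing, collapse = ", "))
  cfg
}

#' Run a library simulation from a configuration
#'
#' Builds the region, mutation model and planted effects described by a
#' [read_config()] list, simulates the library and its latent signals.
#'
#' @param cfg Configuration list from [read_config()].
#' @param n_clones Number of clones to simulate (default from the config's
#'   `n_clones`, falling back to 1000).
#' @return List with `region`, `model`, `effects`, `library`, `signals`.
#' @export
simulate_from_config <- function(cfg, n_clones = NULL) {
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else NULL
  rg <- cfg$region
  reg <- if (!is.null(rg$wt_nt)) {
    region(rg$name, rg$start_residue, rg$wt_nt)
  } else {
    random_region(n_codons = if (is.null(rg$n_codons)) 160L else rg$n_codons,
                  name = rg$name, start_residue = rg$start_residue, seed = seed)
  }
  model <- mutation_model(cfg$mutation_model$mean_mutations_per_clone)
  eff_cfg <- cfg$effects
  effects <- if (is.null(eff_cfg)) {
    plant_effects(reg, 0L, seed = seed)
  } else {
    do.call(plant_effects, c(list(region = reg, seed = seed),
                             eff_cfg[intersect(names(eff_cfg),
                                               names(formals(plant_effects)))]))
  }
  if (is.null(n_clones)) {
    n_clones <- if (!is.null(cfg$n_clones)) cfg$n_clones else 1000L
  }
  lib <- simulate_library(reg, model, n_clones, seed = seed)
  noise <- cfg$noise
  sig <- library_signals(lib, effects,
                         baseline = if (is.null(noise$baseline)) 0.05 else noise$baseline,
                         noise_sd = if (is.null(noise$noise_sd)) 0 else noise$noise_sd,
                         seed = seed)
  list(region = reg, model = model, effects = effects, library = lib,
       signals = sig)
}
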