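# shared fixtures: small regions, hand-built effect tables, and an
# independent translation oracle

make_region <- function(n_codons = 50L, seed = 7L, name = "TM4-6",
                        start = 199L) {
  random_region(n_codons, name = name, start_residue = start, seed = seed)
}

# independent amino-acid oracle: Biostrings whole-sequence C translation,
# not the package's per-codon lookup path
aa_oracle <- function(nt) {
  strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(nt),
                          no.init.codon = TRUE, if.fuzzy.codon = "error")),
    "", fixed = TRUE)[[1L]]
}

# replace one codon of a region's wild type, returning the full nt string
mutate_codon <- function(region, codon_index, new_codon) {
  codons <- region$wt_codons
  codons[codon_index] <- new_codon
  paste(codons, collapse = "")
}

# hand-built effect table
make_effect_table <- function(position, wt_aa, mut_aa, effect, penalty = 0.05) {
  structure(data.frame(position = position, wt_aa = wt_aa, mut_aa = mut_aa,
                       effect = effect, stringsAsFactors = FALSE),
            class = c("EffectTable", "data.frame"),
            expression_penalty_per_mutation = penalty)
}
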