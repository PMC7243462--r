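test_that("substitution calling handles identity, missense, silent and error cases", {
  reg <- region("TM4-6", 199, "ATGCTGGGTAAACCA")
  wt <- call_substitutions(reg$wt_nt, reg)
  expect_true(wt$flags$wt)
  expect_equal(nrow(wt$substitutions), 0L)

  # ATG -> ATA at region codon 1 of a region starting at residue 199
  mis <- call_substitutions(mutate_codon(reg, 1, "ATA"), reg)
  expect_equal(mis$substitutions,
               data.frame(position = 199L, wt_aa = "M", mut_aa = "I",
                          stringsAsFactors = FALSE))
  expect_false(mis$flags$nonsense)

  # CTG -> CTA is synonymous (both Leu)
  silent <- call_substitutions(mutate_codon(reg, 2, "CTA"), reg)
  expect_equal(nrow(silent$substitutions), 0L)
  expect_true(silent$flags$wt)

  # premature stop sets the nonsense flag
  stopc <- call_substitutions(mutate_codon(reg, 4, "TAA"), reg)
  expect_true(stopc$flags$nonsense)
  expect_equal(stopc$substitutions$mut_aa, "*")

  # length mismatch is a suspected frameshift with no calls
  fs <- call_substitutions(paste0(reg$wt_nt, "A"), reg)
  expect_true(fs$flags$frameshift_suspected)
  expect_equal(nrow(fs$substitutions), 0L)

  expect_error(call_substitutions("ATGNTG", reg, clone_id = "bad_clone"),
               "bad_clone")
})

test_that("called substitutions round-trip the simulator's nucleotide ground truth", {
  reg <- make_region(50, seed = 23)
  lib <- simulate_library(reg, mutation_model(4), 2000, seed = 24)
  wt_aa_o <- aa_oracle(reg$wt_nt)
  for (clone in lib) {
    mut_aa_o <- aa_oracle(clone$nt_sequence)
    diff <- which(mut_aa_o != wt_aa_o)
    expect_identical(clone$flags$nonsense, any(mut_aa_o == "*"))
    expected <- data.frame(position = reg$start_residue + diff - 1L,
                           wt_aa = wt_aa_o[diff], mut_aa = mut_aa_o[diff],
                           stringsAsFactors = FALSE)
    expect_identical(clone$substitutions, expected)
  }
})

test_that("deduplication keys on nucleotide differences with an amino-acid option", {
  reg <- region("TM4-6", 199, "ATGCTGGGTAAACCA")
  c1 <- clone_record(mutate_codon(reg, 1, "ATA"), reg, "c1")
  c2 <- clone_record(mutate_codon(reg, 1, "ATA"), reg, "c2")
  c3 <- clone_record(mutate_codon(reg, 1, "ATA"), reg, "c3")
  dd <- dedupe_clones(list(c1, c2, c3), reg)
  expect_equal(length(dd$unique_clones), 1L)
  expect_equal(dd$multiplicity$n, 3L)

  # same amino-acid change via different codons: distinct at nt level,
  # identical at protein level (ATG -> ATA and ATG -> ATC are both M -> I)
  c4 <- clone_record(mutate_codon(reg, 1, "ATC"), reg, "c4")
  expect_equal(length(dedupe_clones(list(c1, c4), reg)$unique_clones), 2L)
  expect_equal(length(dedupe_clones(list(c1, c4), reg, by = "protein")$unique_clones), 1L)

  # resampling with replacement from known genotypes recovers their number
  genotypes <- lapply(1:7, function(i) {
    clone_record(mutate_codon(reg, 2, c("CAG", "CCG", "CGG", "ATG", "GTG",
                                        "TTA", "CTC")[i]), reg, paste0("g", i))
  })
  set.seed(31)
  resampled <- genotypes[sample.int(7, 60, replace = TRUE)]
  dd2 <- dedupe_clones(resampled, reg)
  expect_equal(length(dd2$unique_clones),
               length(unique(vapply(resampled, `[[`, "", "nt_sequence"))))
  expect_equal(sum(dd2$multiplicity$n), 60L)

  empty <- dedupe_clones(list(), reg)
  expect_equal(length(empty$unique_clones), 0L)

  other <- clone_record(reg$wt_nt, reg, "x")
  other$region <- "TM10-12"
  expect_error(dedupe_clones(list(c1, other), reg), "more than one region")
})

test_that("per-position spectra agree with a brute-force tally", {
  reg <- make_region(40, seed = 33)
  empty_spec <- per_position_counts(list(), reg)
  expect_true(all(empty_spec$counts == 0L))
  expect_equal(empty_spec$total_mutations, 0L)

  lib <- simulate_library(reg, mutation_model(3), 500, seed = 34)
  uniq <- dedupe_clones(lib, reg)$unique_clones
  spec <- per_position_counts(uniq, reg)

  # independent tally over clone substitution sets
  kept <- Filter(function(cl) !cl$flags$nonsense && !cl$flags$frameshift_suspected,
                 uniq)
  tally <- integer(region_length(reg))
  for (cl in kept) {
    for (p in unique(cl$substitutions$position)) {
      tally[p - reg$start_residue + 1L] <- tally[p - reg$start_residue + 1L] + 1L
    }
  }
  expect_identical(spec$counts, tally)
  expect_equal(spec$total_mutations, sum(spec$counts))
  expect_equal(spec$total_mutations,
               sum(vapply(kept, function(cl) length(unique(cl$substitutions$position)), 0L)))
  expect_equal(spec$n_unique_clones, length(kept))

  # nonsense clones are excluded by default but can be kept
  spec_all <- per_position_counts(uniq, reg, include_nonsense = TRUE)
  expect_gte(spec_all$n_unique_clones, spec$n_unique_clones)
})

test_that("two clones mutating the same residue both count there", {
  reg <- region("TM4-6", 199, "ATGCTGGGTAAACCA")
  a <- clone_record(mutate_codon(reg, 3, "AGT"), reg, "a")  # G201S
  b <- clone_record(mutate_codon(reg, 3, "CGT"), reg, "b")  # G201R
  spec <- per_position_counts(list(a, b), reg)
  expect_equal(spec$counts[spec$positions == 201], 2L)
})

test_that("column mean pairwise identity matches pair counting with gap exclusion", {
  msa <- c(ref = "MKL-V", s2 = "MKAAV", s3 = "MTA-V")
  prof <- column_mean_pairwise_identity(msa, reference = "ref")
  # reference has 4 non-gap columns; col2 {K,K,T} -> 1/3; col3 {L,A,A} -> 1/3
  expect_equal(nrow(prof), 4L)
  expect_equal(prof$identity, c(1, 1 / 3, 1 / 3, 1))

  # all-identical alignment is 1 everywhere
  same <- rep("MKLV", 5)
  expect_true(all(column_mean_pairwise_identity(same)$identity == 1))

  # two rows with different residues give 0
  expect_equal(column_mean_pairwise_identity(c("A", "T"))$identity, 0)

  # a column with fewer than two non-gap rows is undefined
  gappy <- c("AV", "A-", "A-")
  expect_true(is.na(column_mean_pairwise_identity(gappy)$identity[2]))
  expect_equal(column_mean_pairwise_identity(gappy)$identity[1], 1)

  expect_error(column_mean_pairwise_identity(c("AA", "A")), "ragged")
})

test_that("signal-mutation count correlation behaves at the boundaries", {
  counts <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_signal_mutcount(counts, 0.1 * counts), 1)

  set.seed(41)
  n <- 2000
  x <- rpois(n, 3)
  y <- rnorm(n)
  expect_lt(abs(correlate_signal_mutcount(x, y)), 3 / sqrt(n))

  expect_warning(r <- correlate_signal_mutcount(counts, rep(0.3, 5)), "zero variance")
  expect_true(is.na(r))

  # binned mode keeps only mutation-count values held by > 5 clones
  xc <- c(rep(1, 10), rep(2, 10), 7)
  yc <- c(rnorm(10, 0.1, 0.01), rnorm(10, 0.2, 0.01), 99)
  r_all <- correlate_signal_mutcount(xc, yc)
  r_bin <- correlate_signal_mutcount(xc, yc, bin_min_clones = 5)
  expect_false(isTRUE(all.equal(r_all, r_bin)))
  expect_lt(r_bin, 1)
})
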