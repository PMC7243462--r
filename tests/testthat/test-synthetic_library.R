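test_that("zero mutation rate yields the wild type and fixed seeds reproduce clones", {
  reg <- make_region(30)
  clone0 <- simulate_eppcr_clone(reg, mutation_model(0), seed = 1)
  expect_identical(clone0$nt_sequence, reg$wt_nt)
  expect_equal(nrow(clone0$substitutions), 0L)
  expect_true(clone0$flags$wt)

  mm <- mutation_model(3)
  a <- simulate_eppcr_clone(reg, mm, seed = 42)
  b <- simulate_eppcr_clone(reg, mm, seed = 42)
  expect_identical(a, b)

  lib1 <- simulate_library(reg, mm, 20, seed = 1)
  lib2 <- simulate_library(reg, mm, 20, seed = 1)
  lib3 <- simulate_library(reg, mm, 20, seed = 2)
  expect_identical(lib1, lib2)
  expect_false(identical(lapply(lib1, `[[`, "nt_sequence"),
                         lapply(lib3, `[[`, "nt_sequence")))

  # a one-clone library equals the single-clone simulator at the derived seed
  one <- simulate_library(reg, mm, 1, seed = 99)
  direct <- simulate_eppcr_clone(reg, mm, seed = abcselect:::clone_seed(99, 1),
                                 clone_id = "clone_00001")
  expect_identical(one[[1L]], direct)

  expect_error(mutation_model(-1), "non-negative")
  expect_error(simulate_library(reg, mm, 0), "at least 1")
})

test_that("substitution load is Poisson and sites are uniform over the region", {
  reg <- make_region(50, seed = 3)
  lambda <- 3
  n <- 10000L
  lib <- simulate_library(reg, mutation_model(lambda), n, seed = 11)
  n_mut <- vapply(lib, function(cl) nrow(cl$nt_changes), 0L)

  # sample mean within 3 standard errors of the Poisson mean
  expect_lt(abs(mean(n_mut) - lambda), 3 * sqrt(lambda / n))

  # chi-square GOF against Poisson(lambda) with pooled tails, alpha = 0.01
  m_max <- max(n_mut)
  obs <- tabulate(n_mut + 1L, m_max + 1L)
  expd <- n * dpois(0:m_max, lambda)
  expd[m_max + 1L] <- expd[m_max + 1L] + n * ppois(m_max, lambda, lower.tail = FALSE)
  while (length(expd) > 2L && expd[length(expd)] < 5) {
    k <- length(expd)
    expd[k - 1L] <- expd[k - 1L] + expd[k]
    obs[k - 1L] <- obs[k - 1L] + obs[k]
    expd <- expd[-k]; obs <- obs[-k]
  }
  stat <- sum((obs - expd)^2 / expd)
  expect_gt(pchisq(stat, length(obs) - 2L, lower.tail = FALSE), 0.01)

  # per-nucleotide-position substitution counts pass a uniformity chi-square
  pos <- unlist(lapply(lib, function(cl) cl$nt_changes$nt_pos))
  pos_counts <- tabulate(pos, nchar(reg$wt_nt))
  expect_gt(chisq.test(pos_counts)$p.value, 0.01)
})

test_that("nonsense fraction matches the per-codon stop-enumeration expectation", {
  reg <- make_region(160, seed = 11)
  lambda <- 4.5
  n <- 10000L
  lib <- simulate_library(reg, mutation_model(lambda), n, seed = 42)
  observed <- mean(vapply(lib, function(cl) isTRUE(cl$flags$nonsense), TRUE))

  # oracle: exhaustive enumeration of stop-creating single-base changes
  wt <- strsplit(reg$wt_nt, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  n_stop <- 0L
  for (i in seq_along(wt)) {
    cod <- ceiling(i / 3)
    for (b in setdiff(bases, wt[i])) {
      mut <- wt[(cod * 3 - 2):(cod * 3)]
      mut[i - (cod - 1L) * 3L] <- b
      if (Biostrings::GENETIC_CODE[[paste(mut, collapse = "")]] == "*") {
        n_stop <- n_stop + 1L
      }
    }
  }
  q <- n_stop / (3L * length(wt))
  expected <- 1 - exp(-lambda * q)
  expect_lt(abs(observed - expected),
            3 * sqrt(expected * (1 - expected) / n))
})

test_that("planted effect tables have the requested structure and are reproducible", {
  reg <- make_region(160, seed = 5)
  expect_equal(nrow(plant_effects(reg, 0)), 0L)

  eff <- plant_effects(reg, 77, favorable_per_position = 1, seed = 8)
  expect_equal(nrow(eff), 77L)
  expect_true(all(eff$effect > 0))
  expect_equal(length(unique(eff$position)), 77L)
  expect_true(all(eff$mut_aa != eff$wt_aa))
  expect_true(all(eff$position >= reg$start_residue &
                    eff$position <= reg$end_residue))
  expect_identical(eff, plant_effects(reg, 77, favorable_per_position = 1, seed = 8))

  eff2 <- plant_effects(reg, 10, favorable_per_position = 2, seed = 8)
  expect_equal(nrow(eff2), 20L)
  expect_error(plant_effects(reg, 161), "only")
})

test_that("genotype signals are additive with truncations pinned to the empty level", {
  reg <- make_region(30, seed = 9)
  # construct a double mutant with known planted effects 0.2 and 0.3
  n1 <- setdiff(abcselect:::codon_neighbor_aas(reg$wt_codons[2]), reg$wt_aa[2])[1]
  n2 <- setdiff(abcselect:::codon_neighbor_aas(reg$wt_codons[5]), reg$wt_aa[5])[1]
  eff <- make_effect_table(position = reg$start_residue + c(1L, 4L),
                           wt_aa = reg$wt_aa[c(2, 5)], mut_aa = c(n1, n2),
                           effect = c(0.2, 0.3))
  # find single-base codon variants encoding those amino acids
  variant_for <- function(codon, aa) {
    chars <- strsplit(codon, "", fixed = TRUE)[[1L]]
    for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), chars[p])) {
      v <- chars; v[p] <- b
      if (Biostrings::GENETIC_CODE[[paste(v, collapse = "")]] == aa) {
        return(paste(v, collapse = ""))
      }
    }
    stop("no variant")
  }
  codons <- reg$wt_codons
  codons[2] <- variant_for(codons[2], n1)
  codons[5] <- variant_for(codons[5], n2)
  dbl <- clone_record(paste(codons, collapse = ""), reg, "dbl")
  expect_equal(genotype_signal(dbl, eff, baseline = 0.1, noise_sd = 0), 0.6)

  wt_clone <- clone_record(reg$wt_nt, reg, "wt")
  expect_equal(genotype_signal(wt_clone, eff, baseline = 0.1, noise_sd = 0), 0.1)

  # nonsense clone: empty-plasmid level regardless of effects
  stop_codons <- reg$wt_codons
  stop_codons[2] <- "TAA"
  nonsense <- clone_record(paste(stop_codons, collapse = ""), reg, "stop")
  expect_true(nonsense$flags$nonsense)
  expect_equal(genotype_signal(nonsense, eff, baseline = 0.1, noise_sd = 0), 0)

  # replicate noise recovers the requested measurement SD
  set.seed(21)
  draws <- replicate(1000, genotype_signal(wt_clone, eff, 0.1, noise_sd = 0.02))
  expect_lt(abs(sd(draws) - 0.02), 3 * 0.02 / sqrt(2 * 999))
})

test_that("multi-mutant latent signals equal baseline plus the singles' differences exactly", {
  reg <- make_region(40, seed = 13)
  eff <- plant_effects(reg, 12, seed = 14)
  lib <- simulate_library(reg, mutation_model(3), 200, seed = 15)
  multi <- Filter(function(cl) nrow(cl$substitutions) >= 2 &&
                    !cl$flags$nonsense, lib)[1:5]
  baseline <- 0.05
  for (clone in multi) {
    total <- genotype_signal(clone, eff, baseline, noise_sd = 0)
    singles <- vapply(seq_len(nrow(clone$substitutions)), function(i) {
      s <- clone$substitutions[i, ]
      idx <- s$position - reg$start_residue + 1L
      cl_codons <- abcselect:::nt_to_codons(clone$nt_sequence)
      single_nt <- mutate_codon(reg, idx, cl_codons[idx])
      genotype_signal(clone_record(single_nt, reg, "single"), eff, baseline, 0)
    }, numeric(1))
    expect_equal(total, baseline + sum(singles - baseline))
  }
})

test_that("median library expression falls as the mutation load rises", {
  reg <- make_region(50, seed = 17)
  eff <- plant_effects(reg, 5, seed = 18)
  med <- vapply(c(0.5, 2, 4.5), function(lambda) {
    lib <- simulate_library(reg, mutation_model(lambda), 500, seed = 19)
    median(library_signals(lib, eff)$expression)
  }, numeric(1))
  expect_true(all(diff(med) <= 0))
})

test_that("cytometry events are log-normal around the latent value with median recovery", {
  ev0 <- simulate_cytometry(0.4, 0.8, n_events = 100, cv = 0)
  anchors <- default_anchors()
  expect_true(all(ev0$autocrine == abcselect:::norm_to_raw(0.4, anchors$autocrine)))
  expect_true(all(ev0$expression == abcselect:::norm_to_raw(0.8, anchors$expression)))

  ev <- simulate_cytometry(0.4, 0.8, n_events = 30000, cv = 0.3, seed = 4)
  latent <- abcselect:::norm_to_raw(0.4, anchors$autocrine)
  expect_lt(abs(median(ev$autocrine) - latent) / latent, 0.01)
  expect_true(all(ev$autocrine > 0) && all(ev$expression > 0))

  expect_identical(simulate_cytometry(0.4, 0.8, 100, 0.3, seed = 9),
                   simulate_cytometry(0.4, 0.8, 100, 0.3, seed = 9))
  expect_error(simulate_cytometry(0.4, 0.8, 100, cv = -1), "non-negative")
})
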