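test_that("high-quality adapter-free reads are left untouched", {
  r <- make_reads("ACGTACGTAC", phred_string(rep(30L, 10)))
  out <- trim_reads(r, adapter = "TTTTT", q_cutoff = 20)
  expect_identical(out$sequence, r$sequence)
  expect_identical(out$quality, r$quality)
})

test_that("running-sum trimming removes a low-quality 3' tail", {
  q <- c(rep(35L, 50), rep(2L, 6))
  r <- make_reads(strrep("A", 56), phred_string(q))
  out <- trim_reads(r, q_cutoff = 20)
  expect_equal(out$trimmed_length, 50L)
  expect_equal(nchar(out$sequence), 50L)
})

test_that("the adapter suffix is removed before quality trimming", {
  adapter <- "AGATCGGAAGAGC"
  body <- strrep("C", 40)
  r <- make_reads(paste0(body, adapter),
                  phred_string(rep(35L, 40 + nchar(adapter))))
  out <- trim_reads(r, adapter = adapter, q_cutoff = 20)
  expect_identical(out$sequence, body)
  # one substitution inside the adapter is tolerated
  adap_mut <- sub("G", "T", adapter)
  r2 <- make_reads(paste0(body, adap_mut),
                   phred_string(rep(35L, 40 + nchar(adapter))))
  out2 <- trim_reads(r2, adapter = adapter, adapter_mismatches = 1)
  expect_identical(out2$sequence, body)
})

test_that("trimming never lengthens reads and is idempotent", {
  withr::local_seed(301)
  n <- 200
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 56, replace = TRUE), collapse = "")
  }, character(1))
  quals <- vapply(seq_len(n), function(i) {
    phred_string(sample(0:40, 56, replace = TRUE))
  }, character(1))
  r <- make_reads(seqs, quals)
  once <- trim_reads(r, q_cutoff = 20)
  expect_true(all(nchar(once$sequence) <= 56))
  twice <- trim_reads(once, q_cutoff = 20)
  expect_identical(twice$sequence, once$sequence)
  expect_identical(twice$quality, once$quality)
})

test_that("running-sum trimming matches the brute-force oracle", {
  withr::local_seed(302)
  for (i in 1:200) {
    L <- sample(10:60, 1)
    q <- sample(0:40, L, replace = TRUE)
    r <- make_reads(strrep("A", L), phred_string(q))
    out <- trim_reads(r, q_cutoff = 20)
    expect_equal(out$trimmed_length, trim_oracle_length(q, 20))
  }
})

test_that("codons are extracted from error-free reads of known genotype", {
  gt <- tibble::tibble(genotype_id = 1L, peptide = "FWL",
                       codon_1 = "TTT", codon_2 = "TGG", codon_3 = "TTG",
                       frequency = 1)
  attr(gt, "pool") <- "bright"
  reads <- simulate_reads(gt, default_syntax, 20, error_rate = 0,
                          degraded_fraction = 0, seed = 303)
  ex <- extract_codons(reads, default_syntax)
  expect_true(all(ex$status == "ok"))
  expect_true(all(ex$codon_1 == "TTT" & ex$codon_2 == "TGG" &
                    ex$codon_3 == "TTG"))
  expect_identical(translate_codon(ex$codon_1[1]), "F")
})

test_that("anchor mismatches beyond the allowance reject the read", {
  gt <- tibble::tibble(genotype_id = 1L, peptide = "FWL",
                       codon_1 = "TTT", codon_2 = "TGG", codon_3 = "TTG",
                       frequency = 1)
  attr(gt, "pool") <- "bright"
  reads <- simulate_reads(gt, default_syntax, 1, error_rate = 0,
                          degraded_fraction = 0, seed = 304)
  # two substitutions inside the first anchor
  s <- reads$sequence
  substr(s, 2, 2) <- "N"
  substr(s, 4, 4) <- "N"
  reads$sequence <- s
  ex <- extract_codons(reads, default_syntax, max_mismatches = 1)
  expect_identical(ex$status, "anchor_mismatch")
  # the same read passes when two mismatches per anchor are allowed
  ex2 <- extract_codons(reads, default_syntax, max_mismatches = 2)
  expect_identical(ex2$status, "ok")
  expect_identical(ex2$codon_1, "TTT")
})

test_that("reads shorter than the layout are rejected as truncated", {
  gt <- tibble::tibble(genotype_id = 1L, peptide = "FWL",
                       codon_1 = "TTT", codon_2 = "TGG", codon_3 = "TTG",
                       frequency = 1)
  attr(gt, "pool") <- "bright"
  reads <- simulate_reads(gt, default_syntax, 1, error_rate = 0,
                          degraded_fraction = 0, seed = 305)
  reads$sequence <- substr(reads$sequence, 1, 40)
  reads$quality <- substr(reads$quality, 1, 40)
  ex <- extract_codons(reads, default_syntax)
  expect_identical(ex$status, "truncated")
  rej <- attr(ex, "rejections")
  expect_equal(sum(rej$n), 1L)
  expect_equal(rej$n[rej$reason == "truncated"], 1L)
})

test_that("multiple valid layout placements are rejected as ambiguous", {
  # a degenerate syntax whose single anchor occurs twice in the read
  syn <- default_syntax
  syn$anchors <- "AAAA"
  syn$anchor_starts <- 1L
  syn$slot_starts <- 5L
  syn$layout_length <- 7L
  r <- make_reads("AAAACCCAAAACCC")
  ex <- extract_codons(r, syn, max_mismatches = 0)
  expect_identical(ex$status, "ambiguous")
})

test_that("rejection reasons partition the rejected reads", {
  gt <- tibble::tibble(genotype_id = 1L, peptide = "FWL",
                       codon_1 = "TTT", codon_2 = "TGG", codon_3 = "TTG",
                       frequency = 1)
  attr(gt, "pool") <- "input"
  reads <- simulate_reads(gt, default_syntax, 300, error_rate = 0.05,
                          degraded_fraction = 0.5, seed = 306)
  trimmed <- trim_reads(reads, q_cutoff = 20)
  ex <- extract_codons(trimmed, default_syntax)
  rej <- attr(ex, "rejections")
  expect_equal(sum(rej$n), sum(ex$status != "ok"))
})

test_that("tabulation produces consistent joint and marginal frequencies", {
  ex <- tibble::tibble(
    read_id = sprintf("r%d", 1:6),
    status = "ok",
    codon_1 = c("TTT", "TTT", "TTT", "TTT", "TTT", "TAG"),
    codon_2 = c("TGG", "TGG", "TGG", "GGG", "GGG", "TGG"),
    codon_3 = c("TTG", "CTG", "CTT", "TTG", "TTG", "TTG")
  )
  ft <- tabulate_codons(ex, pool = "demo")
  # the stop-containing tuple is excluded from peptide frequencies
  expect_equal(ft$n_stop, 1L)
  expect_equal(ft$n_reads_used, 5L)
  expect_equal(sum(ft$per_peptide$frequency), 1)
  fwl <- ft$per_peptide[ft$per_peptide$peptide == "FWL", ]
  expect_equal(fwl$count, 3L)
  expect_equal(fwl$n_genotypes_observed, 3L)
  # per-position marginals each sum to 1 and agree with the joint
  for (p in 1:3) {
    marg <- ft$per_position[ft$per_position$position == p, ]
    expect_equal(sum(marg$frequency), 1)
  }
  pos1_f <- ft$per_position$frequency[
    ft$per_position$position == 1 & ft$per_position$residue == "F"]
  expect_equal(pos1_f, 1)
  # a single tuple gives frequency 1
  ft1 <- tabulate_codons(ex[1, ], pool = "one")
  expect_equal(ft1$per_peptide$frequency, 1)
})

test_that("fold-enrichment reproduces ratio arithmetic and flags missing input", {
  b <- data.frame(peptide = c("FWL", "AAA"), frequency = c(0.21, 0.0001))
  i <- data.frame(peptide = c("FWL", "AAA"), frequency = c(0.00043, 0.0001))
  d <- data.frame(peptide = "FWL", frequency = 0.00079)
  e <- enrichment(b, i, d)
  fwl <- e[e$peptide == "FWL", ]
  expect_equal(round(fwl$fold), 488)
  expect_equal(round(fwl$freq_dark / fwl$freq_input, 1), 1.8)
  expect_equal(fwl$rank, 1L)
  # identical pools give fold 1 everywhere
  same <- enrichment(i, i)
  expect_true(all(same$fold == 1))
  # peptides missing from the input pool are flagged, not divided
  b2 <- data.frame(peptide = c("FWL", "ZZZ"), frequency = c(0.5, 0.5))
  e2 <- enrichment(b2, i)
  expect_identical(e2$flag[e2$peptide == "ZZZ"], "undefined_input")
  expect_true(is.na(e2$fold[e2$peptide == "ZZZ"]))
})

test_that("bootstrap ratio confidence intervals flag true enrichment only", {
  # strong enrichment: CI excludes 1 and brackets the normal-approximation CI
  x <- enrichment_significance(2100, 1e4, 43, 1e5, n_boot = 2000, seed = 401)
  expect_false(x$undefined)
  expect_true(x$enriched)
  expect_gt(x$lower, 1)
  # independent oracle: delta-method CI on the log ratio
  est <- (2100 / 1e4) / (43 / 1e5)
  se_log <- sqrt(1 / 2100 - 1 / 1e4 + 1 / 43 - 1 / 1e5)
  expect_equal(log(x$estimate), log(est), tolerance = 1e-12)
  expect_equal(log(x$lower), log(est) - 1.96 * se_log, tolerance = 0.15)
  expect_equal(log(x$upper), log(est) + 1.96 * se_log, tolerance = 0.15)

  # symmetric null: CI contains 1
  y <- enrichment_significance(50, 1e4, 50, 1e4, n_boot = 2000, seed = 402)
  expect_false(y$enriched)
  expect_lt(y$lower, 1)
  expect_gt(y$upper, 1)

  # zero reference count is undefined
  z <- enrichment_significance(10, 100, 0, 100)
  expect_true(z$undefined)
})

test_that("dark-pool enrichment of the designated binder is not significant", {
  # counts consistent with dark 0.079% vs input 0.043% at moderate depth
  x <- enrichment_significance(8, 10000, 4, 10000, n_boot = 2000, seed = 403)
  expect_false(x$enriched)
})
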