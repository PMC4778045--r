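# Shared fixtures, built in code.

default_design <- library_design()
default_syntax <- extraction_syntax(default_design)

# brute-force oracle for running-sum 3' quality trimming: try every cut
# position, remove the suffix maximising the removed sum of (cutoff - q),
# preferring the shortest removal on ties
trim_oracle_length <- function(q, cutoff) {
  L <- length(q)
  removed_gain <- vapply(0:L, function(m) {
    if (m == 0) 0 else sum(cutoff - q[(L - m + 1):L])
  }, numeric(1))
  best <- max(removed_gain)
  if (best <= 0) return(L)
  m <- min(which(removed_gain == best)) - 1L
  L - m
}

# build a read-pool tibble from raw sequence/quality vectors
make_reads <- function(sequence, quality = NULL) {
  if (is.null(quality)) {
    quality <- vapply(nchar(sequence), function(n) {
      paste(rep(rawToChar(as.raw(35 + 33)), n), collapse = "")
    }, character(1))
  }
  tibble::tibble(
    read_id = sprintf("r%03d", seq_along(sequence)),
    sequence = sequence,
    quality = quality
  )
}

phred_string <- function(q) rawToChar(as.raw(q + 33L))

# hand-built sort_result holding given per-genotype molecule counts in one
# pool, for unit-testing amplification in isolation
make_sort_result <- function(genotypes, template_counts, leaked_counts = 0L,
                             pool = "bright") {
  leaked_counts <- rep_len(leaked_counts, nrow(genotypes))
  molecules <- tibble::tibble(
    drop = 1L,
    genotype_id = c(rep.int(genotypes$genotype_id, template_counts),
                    rep.int(genotypes$genotype_id, leaked_counts)),
    peptide = c(rep.int(genotypes$peptide, template_counts),
                rep.int(genotypes$peptide, leaked_counts)),
    kind = rep(c("template", "leaked"),
               c(sum(template_counts), sum(leaked_counts))),
    pool = pool
  )
  gt <- genotypes
  gt$prob <- rep(1 / nrow(gt), nrow(gt))
  structure(
    list(molecules = molecules, genotypes = gt, drops = NULL,
         summary = NULL, bright_fraction = NA_real_, threshold = 1.3,
         config = NULL),
    class = "sort_result"
  )
}
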