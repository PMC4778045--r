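#' RT-PCR amplification model
#'
#' A single expressed DNA template yields on the order of hundreds of mRNA
#' copies before amplification, whereas a leaked pre-encapsulation
#' transcript enters as a single molecule; `transcripts_per_template` sets
#' that weight ratio. Per-genotype amplification efficiency varies
#' log-normally, collapsing the RT step and all PCR cycles into one bias
#' stage.
#'
#' @param transcripts_per_template Mean mRNA copies per expressed DNA
#'   template (molecule-weight ratio of a template to a leaked transcript).
#' @param efficiency_sd Standard deviation of per-genotype log-normal
#'   amplification efficiency (0 = unbiased).
#' @param cycles PCR cycle count, kept as metadata.
#' @return An object of class `amplification_model`.
#' @export
amplification_model <- function(transcripts_per_template = 300,
                                efficiency_sd = 1.0, cycles = 35L) {
  stopifnot(transcripts_per_template >= 1, efficiency_sd >= 0)
  structure(
    list(transcripts_per_template = transcripts_per_template,
         efficiency_sd = efficiency_sd, cycles = as.integer(cycles)),
    class = "amplification_model"
  )
}

#' Amplify a sorted drop pool into per-genotype molecule abundances
#'
#' For the `bright` and `dark` pools, each genotype's pre-amplification
#' weight is (expressed templates x `transcripts_per_template` + leaked
#' transcripts x 1) summed over the pool's drops; the `input` pool is the
#' unsorted library itself, weighted by the library sampling probabilities.
#' Weights are then multiplied by a per-genotype log-normal amplification
#' efficiency and normalised to probabilities.
#'
#' Amplification bias is sequence-dependent, so when several pools from the
#' same run are amplified, the per-genotype efficiencies should be drawn
#' once and reused across pools (as [run_pipeline()] does via
#' `efficiencies`); the bias then cancels out of between-pool frequency
#' ratios, which is what makes fold-enrichment interpretable.
#'
#' @param sort_result A [sort_drops()] result.
#' @param pool `"bright"`, `"dark"` or `"input"`.
#' @param model An [amplification_model()].
#' @param seed Optional RNG seed for the per-genotype efficiencies.
#' @param efficiencies Optional numeric vector of per-genotype
#'   amplification efficiencies, parallel to the genotype table; drawn
#'   log-normally when omitted.
#' @return A tibble of class `pool_abundance` with columns `genotype_id`,
#'   `peptide`, the `codon_<i>` columns and `frequency` (summing to 1);
#'   attribute `pool` records the pool label. An empty pool returns an
#'   empty tibble with a warning.
#' @export
amplify_pool <- function(sort_result, pool = c("bright", "dark", "input"),
                         model = amplification_model(), seed = NULL,
                         efficiencies = NULL) {
  stopifnot(inherits(sort_result, "sort_result"),
            inherits(model, "amplification_model"))
  pool <- match.arg(pool)
  if (!is.null(seed)) set.seed(seed)
  gt <- sort_result$genotypes
  if (is.null(efficiencies)) {
    efficiencies <- if (model$efficiency_sd > 0) {
      rlnorm(nrow(gt), meanlog = 0, sdlog = model$efficiency_sd)
    } else {
      rep(1, nrow(gt))
    }
  }
  stopifnot(length(efficiencies) == nrow(gt), all(efficiencies > 0))

  if (pool == "input") {
    weight <- gt$prob
    ids <- gt$genotype_id
  } else {
    mol <- dplyr::filter(sort_result$molecules, .data$pool == !!pool)
    if (nrow(mol) == 0L) {
      warning("pool '", pool, "' contains no molecules", call. = FALSE)
      out <- tibble::tibble(genotype_id = integer(), peptide = character(),
                            frequency = numeric())
      attr(out, "pool") <- pool
      class(out) <- c("pool_abundance", class(out))
      return(out)
    }
    w <- mol |>
      dplyr::count(.data$genotype_id, .data$kind) |>
      tidyr::pivot_wider(names_from = "kind", values_from = "n",
                         values_fill = 0L)
    if (!"template" %in% names(w)) w$template <- 0L
    if (!"leaked" %in% names(w)) w$leaked <- 0L
    ids <- w$genotype_id
    weight <- w$template * model$transcripts_per_template + w$leaked
  }

  weight <- weight * efficiencies[match(ids, gt$genotype_id)]
  keep <- weight > 0
  ids <- ids[keep]
  weight <- weight[keep]

  out <- gt[match(ids, gt$genotype_id),
            c("genotype_id", "peptide", grep("^codon_", names(gt), value = TRUE))]
  out$frequency <- weight / sum(weight)
  out <- tibble::as_tibble(out)
  attr(out, "pool") <- pool
  class(out) <- c("pool_abundance", class(out))
  out
}

## per-read quality vectors: constant base quality, with a configurable
## fraction of reads carrying an exponential 3' decay that dips below Q20
simulate_qualities <- function(n_reads, read_length, base_quality = 35L,
                               min_quality = 2L, degraded_fraction = 0.2,
                               decay_scale = 5) {
  q <- matrix(base_quality, nrow = n_reads, ncol = read_length)
  degraded <- runif(n_reads) < degraded_fraction
  if (any(degraded)) {
    amp <- runif(sum(degraded), base_quality - 10, base_quality - min_quality)
    decay <- exp(-(read_length - seq_len(read_length)) / decay_scale)
    q[degraded, ] <- pmax(
      round(base_quality - outer(amp, decay)), min_quality
    )
  }
  q
}

phred_to_string <- function(q_matrix) {
  apply(q_matrix + 33L, 1L, function(row) rawToChar(as.raw(row)))
}

#' Simulate amplicon reads from pool abundances
#'
#' Draws reads multinomially from the genotype abundances; each read is the
#' fixed amplicon window of its source template covering all variable
#' codons, with independent per-base substitution errors and Phred
#' qualities that include a configurable fraction of degraded 3' tails.
#'
#' @param abundances A [amplify_pool()] result (or any tibble with
#'   `genotype_id`, `peptide`, `codon_<i>` and `frequency` columns).
#' @param syntax An [extraction_syntax()] defining the amplicon window.
#' @param n_reads Number of reads to draw.
#' @param error_rate Per-base substitution probability.
#' @param base_quality,min_quality,degraded_fraction,decay_scale Quality
#'   model: constant `base_quality` with an exponential 3' decay (scale
#'   `decay_scale` bases, floor `min_quality`) on a `degraded_fraction` of
#'   reads.
#' @param seed Optional RNG seed.
#' @return A tibble of class `read_pool` with columns `read_id`,
#'   `sequence`, `quality` and the true `genotype_id`/`peptide`; attribute
#'   `pool` is carried over from the abundances.
#' @export
simulate_reads <- function(abundances, syntax, n_reads,
                           error_rate = 0.005, base_quality = 35L,
                           min_quality = 2L, degraded_fraction = 0.2,
                           decay_scale = 5, seed = NULL) {
  stopifnot(inherits(syntax, "extraction_syntax"), n_reads >= 0,
            error_rate >= 0, error_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  pool <- attr(abundances, "pool") %||% "unknown"
  empty <- tibble::tibble(read_id = character(), sequence = character(),
                          quality = character(), genotype_id = integer(),
                          peptide = character())
  if (n_reads == 0L || nrow(abundances) == 0L) {
    attr(empty, "pool") <- pool
    class(empty) <- c("read_pool", class(empty))
    return(empty)
  }
  counts <- as.vector(rmultinom(1L, n_reads, abundances$frequency))
  src <- rep.int(seq_len(nrow(abundances)), counts)
  src <- src[sample.int(length(src))]  # shuffle read order
  windows <- genotype_windows(syntax, abundances)
  L <- syntax$layout_length
  seqs <- windows[src]

  if (error_rate > 0) {
    n_total <- n_reads * L
    err <- which(runif(n_total) < error_rate)
    if (length(err) > 0L) {
      read_i <- ((err - 1L) %/% L) + 1L
      pos_i <- ((err - 1L) %% L) + 1L
      old <- substring(seqs[read_i], pos_i, pos_i)
      bases <- c("A", "C", "G", "T")
      new <- vapply(old, function(b) sample(setdiff(bases, b), 1L), character(1))
      for (j in seq_along(err)) {
        substr(seqs[read_i[j]], pos_i[j], pos_i[j]) <- new[j]
      }
    }
  }
  q <- simulate_qualities(n_reads, L, base_quality, min_quality,
                          degraded_fraction, decay_scale)
  out <- tibble::tibble(
    read_id = sprintf("%s_read_%06d", pool, seq_len(n_reads)),
    sequence = seqs,
    quality = phred_to_string(q),
    genotype_id = abundances$genotype_id[src],
    peptide = abundances$peptide[src]
  )
  attr(out, "pool") <- pool
  class(out) <- c("read_pool", class(out))
  out
}

#' Write a read pool to FASTQ (Phred+33)
#'
#' @param reads A tibble with `read_id`, `sequence`, `quality` columns.
#' @param path Output FASTQ path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id)),
    path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality)
  )
  invisible(path)
}

#' Read a FASTQ file into a read-pool tibble
#'
#' @param path FASTQ path (Phred+33).
#' @param pool Optional pool label to attach.
#' @return A tibble of class `read_pool` with `read_id`, `sequence` and
#'   `quality` columns.
#' @export
read_fastq <- function(path, pool = NULL) {
  qs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  out <- tibble::tibble(
    read_id = names(qs) %||% as.character(seq_along(qs)),
    sequence = unname(as.character(qs)),
    quality = unname(as.character(S4Vectors::mcols(qs)$qualities))
  )
  attr(out, "pool") <- pool
  class(out) <- c("read_pool", class(out))
  out
}
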