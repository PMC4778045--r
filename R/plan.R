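#' Screen-design calculator for Poisson-loaded drop screens
#'
#' Computes the number of drops required to cover a library of `n_library`
#' members at mean per-variant coverage `target_coverage` when loading at
#' mean occupancy `lam`, together with the doublet fraction P(2) and the
#' screening overhead (drops generated per library molecule screened,
#' `target_coverage / lam`). At lam = 0.1 the overhead is the familiar
#' 10 drops per molecule: ~9% of drops carry one molecule, ~90% are empty
#' and under 0.5% carry two or more.
#'
#' Warns when `lam` exceeds 0.1 (doublet co-encapsulation inflates
#' false-positive bright drops; the warning quotes the computed doublet
#' fraction, e.g. 3.9% at lam = 0.33 -- note this rounds to 4%, not 3%)
#' and when `lam` is below 0.1 (mostly-empty drops cost throughput).
#'
#' @param n_library Library size.
#' @param lam Mean templates per drop.
#' @param target_coverage Expected templates screened per library member.
#' @return A one-row tibble of class `screen_plan`: `n_library`, `lam`,
#'   `target_coverage`, `drops_required`, `doublet_fraction`,
#'   `screening_overhead`.
#' @examples
#' plan_screen(8000, 0.1, 1) # 80,000 drops, overhead 10
#' @export
plan_screen <- function(n_library, lam = 0.1, target_coverage = 1) {
  stopifnot(n_library > 0, lam > 0, target_coverage > 0)
  doublet <- dpois(2L, lam)
  if (lam > 0.1) {
    warning(sprintf(
      paste0("lam = %.2g risks false positives from multi-template drops: ",
             "%.1f%% of drops carry exactly two molecules"),
      lam, 100 * doublet), call. = FALSE)
  } else if (lam < 0.1) {
    warning(sprintf(
      paste0("lam = %.2g lowers throughput: %.0f%% of drops are empty, so ",
             "%.0f drops must be screened per library molecule"),
      lam, 100 * dpois(0L, lam), target_coverage / lam), call. = FALSE)
  }
  out <- tibble::tibble(
    n_library = n_library,
    lam = lam,
    target_coverage = target_coverage,
    drops_required = target_coverage * n_library / lam,
    doublet_fraction = doublet,
    screening_overhead = target_coverage / lam
  )
  class(out) <- c("screen_plan", class(out))
  out
}

## derive independent stage seeds from one master seed (kept below 2^31)
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  (seed * 7L + stage * 104729L) %% .Machine$integer.max
}

#' Run the full screen pipeline: simulate, sort, sequence, analyse
#'
#' Executes encapsulation, fluorescence, sorting, per-pool amplification,
#' read simulation, trimming, codon extraction, tabulation and enrichment
#' in one deterministic pass. Per-genotype amplification efficiencies are
#' drawn once per run and shared across the bright, dark and input pools
#' (sequence-dependent bias), so the bias cancels out of fold-enrichment
#' ratios. When `out_dir` is given, per-stage tables
#' (occupancy, sort summary, frequency and enrichment TSVs, FASTQ files,
#' JSON run summary) are written there.
#'
#' @param config A [screen_config()]; its `seed` drives every stage.
#' @param n_reads Reads simulated per pool: a single count or a named
#'   vector over `bright`, `dark`, `input`. The default sequences the
#'   input library five times deeper than the sorted pools, so that even a
#'   1-in-8000 member is covered by enough input reads for its frequency
#'   (and hence fold-enrichment) to be defined.
#' @param amplification An [amplification_model()].
#' @param error_rate Per-base substitution rate of simulated reads.
#' @param syntax Optional [extraction_syntax()]; defaults to the design's
#'   standard 56-nt window.
#' @param out_dir Optional output directory.
#' @return A list of class `screen_run`: the population, sort result, per
#'   pool frequency tables, the enrichment table and a `summary` list
#'   (predicted vs realised occupancy, bright fraction, top peptides,
#'   seed).
#' @export
run_pipeline <- function(config,
                         n_reads = c(bright = 2e4, dark = 2e4, input = 1e5),
                         amplification = amplification_model(),
                         error_rate = 0.005, syntax = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "screen_config"))
  if (is.null(config$seed)) {
    stop("run_pipeline() requires a seeded config for reproducibility",
         call. = FALSE)
  }
  syntax <- syntax %||% extraction_syntax(config$design)
  pools <- c("bright", "dark", "input")
  if (length(n_reads) == 1L && is.null(names(n_reads))) {
    n_reads <- setNames(rep(n_reads, 3L), pools)
  }
  if (!all(pools %in% names(n_reads))) {
    stop("n_reads must be a single count or named over bright/dark/input",
         call. = FALSE)
  }

  pop <- simulate_encapsulation(config)
  pop <- simulate_fluorescence(pop)
  sorted <- sort_drops(pop)

  # amplification bias is a property of the genotype's sequence, so the
  # per-genotype efficiencies are drawn once and shared by all three pools;
  # the bias then cancels out of the bright/input frequency ratio
  set.seed(stage_seed(config$seed, 4L))
  eff <- if (amplification$efficiency_sd > 0) {
    rlnorm(nrow(sorted$genotypes), meanlog = 0,
           sdlog = amplification$efficiency_sd)
  } else {
    rep(1, nrow(sorted$genotypes))
  }

  freq_tables <- list()
  read_pools <- list()
  for (j in seq_along(pools)) {
    p <- pools[j]
    ab <- amplify_pool(sorted, p, amplification,
                       seed = stage_seed(config$seed, j),
                       efficiencies = eff)
    reads <- simulate_reads(ab, syntax, n_reads[[p]], error_rate = error_rate,
                            seed = stage_seed(config$seed, 10L + j))
    trimmed <- trim_reads(reads, q_cutoff = 20L)
    extracted <- extract_codons(trimmed, syntax)
    freq_tables[[p]] <- tabulate_codons(extracted, pool = p)
    read_pools[[p]] <- reads
  }
  enr <- enrichment(freq_tables$bright, freq_tables$input, freq_tables$dark)

  occ_pred <- poisson_occupancy(config$lam)
  occ_obs <- occupancy_histogram(pop)
  summary <- list(
    seed = config$seed,
    n_drops = config$n_drops,
    lam = config$lam,
    occupancy_predicted = occ_pred,
    occupancy_observed = occ_obs,
    predicted_bright_fraction = 1 - dpois(0L, config$lam),
    observed_bright_fraction = sorted$bright_fraction,
    n_bright = sum(sorted$drops$pool == "bright"),
    top_peptides = head(enr, 5L)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(occ_pred, file.path(out_dir, "occupancy_predicted.tsv"))
    readr::write_tsv(occ_obs, file.path(out_dir, "occupancy_observed.tsv"))
    readr::write_tsv(sorted$summary, file.path(out_dir, "sort_summary.tsv"))
    for (p in pools) {
      write_fastq(read_pools[[p]], file.path(out_dir, paste0(p, ".fastq")))
      export_frequency_table(freq_tables[[p]],
                             file.path(out_dir, paste0("frequencies_", p, ".tsv")))
    }
    readr::write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    json <- list(
      seed = config$seed, n_drops = config$n_drops, lam = config$lam,
      threshold = config$threshold,
      n_bright = summary$n_bright,
      observed_bright_fraction = summary$observed_bright_fraction,
      predicted_bright_fraction = summary$predicted_bright_fraction,
      reads_per_pool = as.list(n_reads),
      reads_used = lapply(freq_tables, function(ft) ft$n_reads_used),
      reads_rejected = lapply(freq_tables, function(ft) ft$n_reads_rejected),
      top_peptide = enr$peptide[1L]
    )
    jsonlite::write_json(json, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  structure(
    list(population = pop, sorted = sorted, frequency_tables = freq_tables,
         enrichment = enr, summary = summary, config = config),
    class = "screen_run"
  )
}

#' @export
print.screen_run <- function(x, ...) {
  s <- x$summary
  cat("<screen_run> ", s$n_drops, " drops at lam = ", s$lam,
      " (seed ", s$seed, ")\n", sep = "")
  cat("  bright drops: ", s$n_bright, " (fraction ",
      format(s$observed_bright_fraction, digits = 3),
      "; occupied-drop fraction predicted ",
      format(s$predicted_bright_fraction, digits = 3), ")\n", sep = "")
  cat("  top enriched peptide: ", x$enrichment$peptide[1L], " (",
      format(x$enrichment$fold[1L], digits = 4), "-fold)\n", sep = "")
  invisible(x)
}
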