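#' Poisson occupancy distribution of templates per drop
#'
#' Under Poisson loading at mean `lam` templates per drop, the probability
#' of a drop containing exactly k templates is `exp(-lam) lam^k / k!`. The
#' tail mass at and above `k_max` is lumped into the final row.
#'
#' @param lam Mean templates per drop (lambda, dimensionless).
#' @param k_max Occupancy at which the tail is lumped.
#' @return A tibble with columns `k`, `prob` and `at_least` (TRUE for the
#'   lumped tail row). Probabilities sum to 1.
#' @examples
#' poisson_occupancy(0.1, 2)
#' @export
poisson_occupancy <- function(lam, k_max = 4L) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0) {
    stop("lam must be a single non-negative number", call. = FALSE)
  }
  k_max <- as.integer(k_max)
  stopifnot(k_max >= 1L)
  kk <- c(0:(k_max - 1L), k_max)
  pp <- c(dpois(0:(k_max - 1L), lam),
          ppois(k_max - 1L, lam, lower.tail = FALSE))
  tibble::tibble(k = kk, prob = pp,
                 at_least = c(rep(FALSE, k_max), TRUE))
}

#' Expected number of drops carrying a given single library member
#'
#' With `n_drops` drops loaded at mean occupancy `lam` from a library of
#' `n_library` equally abundant members, the expected number of drops
#' containing the member of interest is `n_drops * lam / n_library`.
#'
#' @param n_drops Total drops generated.
#' @param lam Mean templates per drop.
#' @param n_library Library size (distinct members).
#' @return A tibble with `expected` (the exact value), `rounded` (nearest
#'   integer convenience value) and `drops_per_hit` (`n_drops / expected`,
#'   the expected spacing between drops carrying the member).
#' @examples
#' expected_binder_drops(3e6, 0.1, 8000) # expected 37.5, rounded 38
#' @export
expected_binder_drops <- function(n_drops, lam, n_library) {
  stopifnot(n_drops > 0, lam > 0)
  if (!is.numeric(n_library) || n_library <= 0) {
    stop("n_library must be positive", call. = FALSE)
  }
  expected <- n_drops * lam / n_library
  tibble::tibble(
    n_drops = n_drops, lam = lam, n_library = n_library,
    expected = expected,
    rounded = round(expected),
    drops_per_hit = n_drops / expected
  )
}

#' Drop volume from diameter
#'
#' @param diameter_um Drop diameter in micrometers.
#' @return Volume in picoliters (`pi/6 d^3`, with 1000 um^3 = 1 pL).
#' @examples
#' drop_volume_from_diameter(24) # ~7.24 pL
#' @export
drop_volume_from_diameter <- function(diameter_um) {
  stopifnot(all(diameter_um > 0))
  (pi / 6) * diameter_um^3 / 1000
}

#' Fluorescence response model of a drop
#'
#' Normalized per-drop fluorescence is generated directly on the scale on
#' which the empty-drop population peak sits at 1.0. A drop containing k
#' high-affinity binder templates has mean fluorescence
#' `baseline + increment * k^cooperativity`; with the defaults this puts
#' single-template drops at ~2.0 and two-template drops at ~3.55, above the
#' 3.5 level characteristic of multi-template drops. Noise is a truncated
#' normal: deviations are capped at `noise_limit` standard deviations, so
#' empty drops never stray into the bright gate -- spurious bright empties
#' are not a feature of the detector histograms being emulated. Low-affinity
#' templates and leaked transcripts contribute no signal. A fraction of
#' drops fails the detector pulse-width gate (merged or split drops),
#' independent of content.
#'
#' @param baseline Mean normalized fluorescence of drops with no
#'   high-affinity template.
#' @param increment Fluorescence added by a single high-affinity template.
#' @param cooperativity Exponent h in the `k^h` response.
#' @param noise_sd Standard deviation of the per-drop noise.
#' @param noise_limit Truncation of the noise, in standard deviations.
#' @param width_gate_outlier_rate Fraction of drops excluded by the
#'   pulse-width gate.
#' @return An object of class `fluorescence_model`.
#' @export
fluorescence_model <- function(baseline = 1.0, increment = 1.0,
                               cooperativity = 1.35, noise_sd = 0.10,
                               noise_limit = 3, width_gate_outlier_rate = 0.01) {
  stopifnot(baseline > 0, increment > 0, noise_sd > 0, noise_limit > 0,
            width_gate_outlier_rate >= 0, width_gate_outlier_rate < 1)
  structure(
    list(baseline = baseline, increment = increment,
         cooperativity = cooperativity, noise_sd = noise_sd,
         noise_limit = noise_limit,
         width_gate_outlier_rate = width_gate_outlier_rate),
    class = "fluorescence_model"
  )
}

#' Configuration of a droplet screen
#'
#' Bundles the library design, loading density, drop count, sorting gate
#' and noise models that define one simulated screen. Defaults reproduce
#' the reference screen: an 8000-member NNK triad library with a single
#' high-affinity member (`FWL`), loaded at lambda = 0.1 into one million
#' 7.2-pL drops and sorted at a normalized-fluorescence threshold of 1.3,
#' with 0.2 leaked pre-encapsulation transcripts per drop.
#'
#' @param design A [library_design()].
#' @param lam Mean templates per drop.
#' @param n_drops Number of drops.
#' @param threshold Normalized fluorescence gate for bright drops.
#' @param binders Character vector of high-affinity residue combinations.
#' @param weights Per-peptide abundance weights: `"uniform"` (default,
#'   every library member equally abundant -- the assumption behind the
#'   `n_drops * lam / n_library` coverage formula), `"codon"` (each stop-free
#'   codon combination equally likely, so peptides are weighted by genotype
#'   multiplicity as in uniform NNK synthesis), or a named numeric vector
#'   over residue combinations. Normalised to sum to 1.
#' @param leakage_rate Mean leaked transcripts per drop. Leaked transcripts
#'   carry genotype information into sequencing but never add fluorescence:
#'   they model transcription that occurred in bulk before encapsulation.
#' @param drop_volume_pl Drop volume in picoliters (metadata).
#' @param fluorescence A [fluorescence_model()].
#' @param seed RNG seed used by the simulation stages.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(design = library_design(), lam = 0.1,
                          n_drops = 1e6, threshold = 1.3,
                          binders = "FWL", weights = "uniform",
                          leakage_rate = 0.2, drop_volume_pl = 7.2,
                          fluorescence = fluorescence_model(),
                          seed = NULL) {
  stopifnot(inherits(design, "library_design"), lam > 0, n_drops >= 1,
            threshold > 0, leakage_rate >= 0,
            inherits(fluorescence, "fluorescence_model"))
  variants <- enumerate_library(design)
  if (is.character(weights) && length(weights) == 1L) {
    weights <- match.arg(weights, c("uniform", "codon"))
    weights <- if (weights == "uniform") {
      setNames(rep(1 / nrow(variants), nrow(variants)), variants$peptide)
    } else {
      setNames(variants$expected_freq, variants$peptide)
    }
  } else {
    if (is.null(names(weights)) || !all(names(weights) %in% variants$peptide)) {
      stop("weights must be named by residue combinations in the library",
           call. = FALSE)
    }
    w <- setNames(numeric(nrow(variants)), variants$peptide)
    w[names(weights)] <- weights
    weights <- w / sum(w)
  }
  weights <- weights / sum(weights)
  unknown <- setdiff(binders, variants$peptide)
  if (length(unknown) > 0L && !identical(binders, character(0))) {
    stop("binder(s) not in the library: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(design = design, lam = lam, n_drops = as.integer(n_drops),
         threshold = threshold, binders = binders, weights = weights,
         leakage_rate = leakage_rate, drop_volume_pl = drop_volume_pl,
         fluorescence = fluorescence, seed = seed),
    class = "screen_config"
  )
}

## genotype table with per-genotype sampling probabilities implied by the
## per-peptide weights (genotypes are uniform within a peptide)
genotype_weights <- function(config) {
  gt <- library_genotypes(config$design)
  per_pep <- table(gt$peptide)
  gt$prob <- as.numeric(config$weights[gt$peptide]) /
    as.numeric(per_pep[gt$peptide])
  gt
}

## truncated standard normal deviates via inverse CDF; support (-limit, limit)
rnorm_truncated <- function(n, limit) {
  lo <- pnorm(-limit)
  qnorm(runif(n, lo, 1 - lo))
}

#' Simulate Poisson encapsulation of a library into drops
#'
#' Each drop receives a Poisson(`lam`) number of DNA templates whose
#' identities are drawn from the library abundance weights, plus a
#' Poisson(`leakage_rate`) number of leaked pre-encapsulation transcripts
#' drawn from the same weights.
#'
#' @param config A [screen_config()].
#' @return An object of class `drop_population`: a list with `drops` (one
#'   row per drop: `drop`, `n_templates`, `n_binders`, `n_leaked`,
#'   `gate_pass`, `fluorescence`), `molecules` (one row per molecule:
#'   `drop`, `genotype_id`, `peptide`, `kind` in template/leaked), the
#'   genotype table and the config.
#' @export
simulate_encapsulation <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_drops
  gt <- genotype_weights(config)

  n_templates <- rpois(n, config$lam)
  total_t <- sum(n_templates)
  idx_t <- sample.int(nrow(gt), total_t, replace = TRUE, prob = gt$prob)

  n_leaked <- if (config$leakage_rate > 0) rpois(n, config$leakage_rate) else integer(n)
  total_l <- sum(n_leaked)
  idx_l <- if (total_l > 0) {
    sample.int(nrow(gt), total_l, replace = TRUE, prob = gt$prob)
  } else integer(0)

  molecules <- tibble::tibble(
    drop = c(rep.int(seq_len(n), n_templates), rep.int(seq_len(n), n_leaked)),
    genotype_id = c(idx_t, idx_l),
    peptide = gt$peptide[c(idx_t, idx_l)],
    kind = rep(c("template", "leaked"), c(total_t, total_l))
  )

  is_binder <- gt$peptide[idx_t] %in% config$binders
  n_binders <- integer(n)
  if (any(is_binder)) {
    tab <- tabulate(rep.int(seq_len(n), n_templates)[is_binder], nbins = n)
    n_binders <- tab
  }
  gate_pass <- runif(n) >= config$fluorescence$width_gate_outlier_rate

  drops <- tibble::tibble(
    drop = seq_len(n),
    n_templates = n_templates,
    n_binders = n_binders,
    n_leaked = n_leaked,
    gate_pass = gate_pass,
    fluorescence = NA_real_
  )
  structure(
    list(drops = drops, molecules = molecules, genotypes = gt, config = config),
    class = "drop_population"
  )
}

#' @export
print.drop_population <- function(x, ...) {
  cat("<drop_population> ", nrow(x$drops), " drops, ",
      nrow(x$molecules), " molecules (",
      sum(x$molecules$kind == "template"), " templates, ",
      sum(x$molecules$kind == "leaked"), " leaked)\n", sep = "")
  if (!all(is.na(x$drops$fluorescence))) {
    cat("  fluorescence assigned\n")
  }
  invisible(x)
}

#' Assign in-drop reporter fluorescence
#'
#' The number k of high-affinity binder templates in a drop sets its mean
#' normalized fluorescence `baseline + increment * k^cooperativity`;
#' truncated-normal noise of sd `noise_sd` is added (see
#' [fluorescence_model()]). Leaked transcripts and low-affinity templates
#' contribute nothing.
#'
#' @param population A [simulate_encapsulation()] result.
#' @param model A [fluorescence_model()]; defaults to the one in the
#'   population's config.
#' @return The population with the `fluorescence` column filled.
#' @export
simulate_fluorescence <- function(population, model = NULL) {
  stopifnot(inherits(population, "drop_population"))
  model <- model %||% population$config$fluorescence
  k <- population$drops$n_binders
  mu <- model$baseline + model$increment * k^model$cooperativity
  f <- mu + model$noise_sd * rnorm_truncated(length(k), model$noise_limit)
  population$drops$fluorescence <- pmax(f, .Machine$double.eps)
  population
}

#' Sort drops at a normalized-fluorescence threshold
#'
#' Partitions every drop into `bright` (gate-passing, fluorescence at or
#' above the threshold), `dark` (gate-passing, below threshold) or
#' `excluded` (pulse-width gate failure).
#'
#' @param population A population with fluorescence assigned.
#' @param threshold Gate value; defaults to the config's threshold.
#' @return An object of class `sort_result`: the per-drop table gains a
#'   `pool` column; `summary` tabulates pool sizes; `bright_fraction` is
#'   computed over gate-passing drops; `molecules` carry their drop's pool.
#' @export
sort_drops <- function(population, threshold = NULL) {
  stopifnot(inherits(population, "drop_population"))
  if (all(is.na(population$drops$fluorescence))) {
    stop("fluorescence not assigned; run simulate_fluorescence() first",
         call. = FALSE)
  }
  threshold <- threshold %||% population$config$threshold
  drops <- population$drops
  drops$pool <- dplyr::case_when(
    !drops$gate_pass ~ "excluded",
    drops$fluorescence >= threshold ~ "bright",
    TRUE ~ "dark"
  )
  summary <- drops |>
    dplyr::count(.data$pool, name = "n_drops") |>
    tidyr::complete(pool = c("bright", "dark", "excluded"),
                    fill = list(n_drops = 0L)) |>
    dplyr::mutate(fraction = .data$n_drops / sum(.data$n_drops))
  n_pass <- sum(drops$pool != "excluded")
  bright_fraction <- if (n_pass > 0) sum(drops$pool == "bright") / n_pass else NA_real_
  molecules <- dplyr::left_join(
    population$molecules,
    dplyr::select(drops, "drop", "pool"),
    by = "drop"
  )
  structure(
    list(drops = drops, molecules = molecules, summary = summary,
         bright_fraction = bright_fraction, threshold = threshold,
         genotypes = population$genotypes, config = population$config),
    class = "sort_result"
  )
}

#' @export
print.sort_result <- function(x, ...) {
  cat("<sort_result> threshold ", x$threshold, "\n", sep = "")
  print(x$summary)
  cat("bright fraction (gate-passing): ",
      format(x$bright_fraction, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Empirical occupancy distribution of a simulated population
#'
#' @param population A [simulate_encapsulation()] result.
#' @param k_max Tail lumping as in [poisson_occupancy()].
#' @return A tibble matching the layout of [poisson_occupancy()], with an
#'   extra `n` column of drop counts.
#' @export
occupancy_histogram <- function(population, k_max = 4L) {
  stopifnot(inherits(population, "drop_population"))
  k_max <- as.integer(k_max)
  nt <- pmin(population$drops$n_templates, k_max)
  counts <- tabulate(nt + 1L, nbins = k_max + 1L)
  tibble::tibble(
    k = 0:k_max,
    n = counts,
    prob = counts / sum(counts),
    at_least = c(rep(FALSE, k_max), TRUE)
  )
}
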