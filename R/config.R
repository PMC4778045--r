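#' Read a screen configuration from a YAML file
#'
#' A single structured file carries the library design, screen parameters
#' and read-simulation settings, one section per pipeline stage. Any
#' omitted field falls back to the package default. Scalar overrides can be
#' supplied programmatically (mirroring command-line flag overrides).
#'
#' @param path YAML file path.
#' @param overrides Named list of scalar overrides applied to the `screen`
#'   section (e.g. `list(lam = 0.2, seed = 7)`).
#' @return A list with elements `config` (a [screen_config()]), `syntax`
#'   (an [extraction_syntax()]), `amplification` (an
#'   [amplification_model()]), `n_reads` and `error_rate`.
#' @export
read_screen_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  dsec <- raw$design %||% list()
  design <- library_design(
    scaffold = dsec$scaffold %||% "TSFAEYWNLLSP",
    variable_positions = dsec$variable_positions %||% c(3L, 7L, 10L),
    codons = dsec$codons %||% "NNK",
    orientation = dsec$orientation %||% "sense",
    flank_5p = dsec$flank_5p %||% default_flank_5p,
    flank_3p = dsec$flank_3p %||% default_flank_3p
  )
  ssec <- raw$screen %||% list()
  for (nm in names(overrides)) ssec[[nm]] <- overrides[[nm]]
  fsec <- raw$fluorescence %||% list()
  fluor <- fluorescence_model(
    baseline = fsec$baseline %||% 1.0,
    increment = fsec$increment %||% 1.0,
    cooperativity = fsec$cooperativity %||% 1.35,
    noise_sd = fsec$noise_sd %||% 0.10,
    noise_limit = fsec$noise_limit %||% 3,
    width_gate_outlier_rate = fsec$width_gate_outlier_rate %||% 0.01
  )
  config <- screen_config(
    design = design,
    lam = ssec$lam %||% 0.1,
    n_drops = ssec$n_drops %||% 1e6,
    threshold = ssec$threshold %||% 1.3,
    binders = ssec$binders %||% "FWL",
    leakage_rate = ssec$leakage_rate %||% 0.2,
    drop_volume_pl = ssec$drop_volume_pl %||% 7.2,
    fluorescence = fluor,
    seed = ssec$seed
  )
  asec <- raw$amplification %||% list()
  amp <- amplification_model(
    transcripts_per_template = asec$transcripts_per_template %||% 300,
    efficiency_sd = asec$efficiency_sd %||% 1.0,
    cycles = asec$cycles %||% 35L
  )
  rsec <- raw$reads %||% list()
  syntax <- extraction_syntax(
    design,
    read_length = rsec$read_length %||% 56L,
    upstream_context = rsec$upstream_context %||% 10L,
    max_mismatches_per_anchor = rsec$max_mismatches_per_anchor %||% 1L
  )
  list(
    config = config, syntax = syntax, amplification = amp,
    n_reads = rsec$n_reads %||% 2e4,
    error_rate = rsec$error_rate %||% 0.005
  )
}
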