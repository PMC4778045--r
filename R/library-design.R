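#' Expand a degenerate IUPAC codon into its concrete codons
#'
#' A degenerate codon such as `"NNK"` stands for the set of all codons
#' obtainable by substituting each IUPAC symbol with one of the bases it
#' denotes (N = A/C/G/T, K = G/T, ...). Degenerate codons written on the
#' antisense strand (e.g. `"MNN"`, as synthesised on a reverse
#' oligonucleotide) are reverse-complemented to their sense form before
#' expansion, so `expand_degenerate_codon("MNN", "antisense")` equals
#' `expand_degenerate_codon("NNK")`.
#'
#' @param codon A length-3 string of IUPAC nucleotide codes.
#' @param orientation `"sense"` (default) or `"antisense"`.
#' @return A character vector of concrete codons, sorted; its length is the
#'   product of the per-position base-set sizes (32 for NNK).
#' @examples
#' length(expand_degenerate_codon("NNK")) # 32
#' identical(
#'   expand_degenerate_codon("MNN", "antisense"),
#'   expand_degenerate_codon("NNK")
#' )
#' @export
expand_degenerate_codon <- function(codon, orientation = c("sense", "antisense")) {
  orientation <- match.arg(orientation)
  stopifnot(is.character(codon), length(codon) == 1L)
  codon <- toupper(codon)
  if (nchar(codon) != 3L) {
    stop("a codon must have exactly 3 symbols, got '", codon, "'", call. = FALSE)
  }
  syms <- strsplit(codon, "")[[1L]]
  bad <- setdiff(syms, names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad) > 0L) {
    stop("invalid IUPAC symbol(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  if (orientation == "antisense") {
    codon <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(codon)))
    syms <- strsplit(codon, "")[[1L]]
  }
  sets <- lapply(syms, function(s) strsplit(Biostrings::IUPAC_CODE_MAP[[s]], "")[[1L]])
  grid <- expand.grid(sets[[3L]], sets[[2L]], sets[[1L]], stringsAsFactors = FALSE)
  sort(paste0(grid[[3L]], grid[[2L]], grid[[1L]]))
}

#' Translate concrete codons under the standard genetic code
#'
#' @param codons Character vector of unambiguous 3-base codons.
#' @return Character vector of single-letter amino acids, with `"*"` for the
#'   three stop codons.
#' @examples
#' translate_codon(c("TGG", "TAG", "TTG")) # "W" "*" "L"
#' @export
translate_codon <- function(codons) {
  codons <- toupper(codons)
  bad <- !grepl("^[ACGT]{3}$", codons)
  if (any(bad)) {
    stop("codons must be 3 unambiguous bases; offending: ",
         paste(unique(codons[bad]), collapse = ", "), call. = FALSE)
  }
  unname(Biostrings::GENETIC_CODE[codons])
}

## Fixed codon used for each invariant scaffold residue when building DNA
## templates. One deterministic choice per amino acid; common E. coli codons.
scaffold_codon_table <- c(
  A = "GCT", C = "TGC", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAC",
  P = "CCG", Q = "CAG", R = "CGT", S = "TCT", T = "ACC", V = "GTT",
  W = "TGG", Y = "TAT"
)

## Synthetic flank placeholders: a T7 promoter/5' context and the start of a
## DNA-binding-domain fusion plus terminator context. Real constructs differ;
## these give templates of realistic, constant length and are configurable.
default_flank_5p <- paste0(
  "GCGAAATTAATACGACTCACTATAGGGAGACCACAACGGTTTCCCTCT",
  "AGAAATAATTTTGTTTAACTTTAAGAAGGAGATATACATATG"
)
default_flank_3p <- paste0(
  "GGTTCTGGCGGTATGGAACAACGCATTACCCTGAAAGATTACGCTATG",
  "CGCTTTGGTCAGACCAAGACGGCTAAAGATCTGGGCGTTTATCAAAGC",
  "GCGATTAACTAAGC"
)

#' Describe a degenerate-codon peptide library
#'
#' Defines a scaffold peptide, the positions randomised with degenerate
#' codons, and the DNA context in which the coding sequence sits. The
#' default reproduces a duodecimal MDM2-inhibitor scaffold (`TSFAEYWNLLSP`)
#' with its hydrophobic triad (F3, W7, L10) randomised by NNK codons,
#' giving a 20 x 20 x 20 = 8000-member peptide library.
#'
#' @param scaffold Amino-acid string of the scaffold peptide.
#' @param variable_positions 1-based peptide positions randomised.
#' @param codons Degenerate codon per variable position (recycled).
#' @param orientation Orientation in which `codons` are written.
#' @param scaffold_codons Named character vector giving the fixed codon used
#'   for each amino acid at invariant positions.
#' @param flank_5p,flank_3p DNA flanks placed around the peptide coding
#'   sequence in every template (promoter side and fusion/terminator side).
#'   The defaults are synthetic placeholder sequences of realistic length.
#' @return An object of class `library_design`.
#' @examples
#' d <- library_design()
#' nrow(enumerate_library(d)) # 8000
#' @export
library_design <- function(scaffold = "TSFAEYWNLLSP",
                           variable_positions = c(3L, 7L, 10L),
                           codons = "NNK",
                           orientation = "sense",
                           scaffold_codons = scaffold_codon_table,
                           flank_5p = default_flank_5p,
                           flank_3p = default_flank_3p) {
  stopifnot(is.character(scaffold), length(scaffold) == 1L, nchar(scaffold) > 0L)
  variable_positions <- as.integer(variable_positions)
  if (anyDuplicated(variable_positions) ||
      any(variable_positions < 1L | variable_positions > nchar(scaffold))) {
    stop("variable_positions must be distinct indices within the scaffold",
         call. = FALSE)
  }
  k <- length(variable_positions)
  codons <- rep_len(toupper(codons), k)
  aa <- strsplit(scaffold, "")[[1L]]
  fixed <- setdiff(seq_along(aa), variable_positions)
  missing_aa <- setdiff(aa[fixed], names(scaffold_codons))
  if (length(missing_aa) > 0L) {
    stop("no scaffold codon defined for residue(s): ",
         paste(missing_aa, collapse = ", "), call. = FALSE)
  }
  ## concrete codon set and encodable amino-acid multiplicities per position
  per_position <- lapply(codons, function(cd) {
    conc <- expand_degenerate_codon(cd, orientation)
    aa_tab <- table(translate_codon(conc))
    list(codons = conc, aa_counts = aa_tab)
  })
  structure(
    list(
      scaffold = scaffold,
      variable_positions = variable_positions,
      codons = codons,
      orientation = orientation,
      scaffold_codons = scaffold_codons,
      flank_5p = toupper(flank_5p),
      flank_3p = toupper(flank_3p),
      per_position = per_position
    ),
    class = "library_design"
  )
}

#' @export
print.library_design <- function(x, ...) {
  k <- length(x$variable_positions)
  sizes <- vapply(x$per_position, function(p) {
    sum(p$aa_counts[names(p$aa_counts) != "*"] > 0)
  }, integer(1))
  cat("<library_design>\n")
  cat("  scaffold:          ", x$scaffold, "\n", sep = "")
  cat("  variable positions:", paste(x$variable_positions, collapse = ", "), "\n")
  cat("  codon scheme:      ", paste(x$codons, collapse = ", "), "\n")
  cat("  peptide variants:  ", prod(sizes), "\n")
  invisible(x)
}

## amino acids (excluding stop) encodable at each variable position, with the
## number of concrete codons encoding each
position_aa_counts <- function(design) {
  lapply(design$per_position, function(p) {
    tab <- p$aa_counts[names(p$aa_counts) != "*"]
    tab[order(names(tab))]
  })
}

#' Enumerate all peptide variants of a library design
#'
#' Lists every distinct residue combination at the variable positions that
#' is encodable without a stop codon, together with its genotype
#' multiplicity (number of concrete codon combinations encoding it) and its
#' expected frequency under uniform codon synthesis. The expected frequency
#' is the genotype count divided by the total number of stop-free codon
#' combinations, i.e. the null against which observed input-library
#' frequencies can be compared.
#'
#' @param design A [library_design()].
#' @return A tibble with one row per peptide variant, ordered
#'   lexicographically by the residues at the variable positions, with
#'   columns `peptide` (residues at the variable positions), `full_peptide`,
#'   `n_genotypes` and `expected_freq`.
#' @export
enumerate_library <- function(design) {
  stopifnot(inherits(design, "library_design"))
  counts <- position_aa_counts(design)
  if (length(counts) == 0L) {
    return(tibble::tibble(
      peptide = "", full_peptide = design$scaffold,
      n_genotypes = 1L, expected_freq = 1
    ))
  }
  grid <- expand.grid(rev(lapply(counts, names)),
                      stringsAsFactors = FALSE)[rev(seq_along(counts))]
  peptide <- do.call(paste0, grid)
  mult <- Reduce(`*`, lapply(seq_along(counts), function(i) {
    as.numeric(counts[[i]][grid[[i]]])
  }))
  total <- prod(vapply(counts, sum, numeric(1)))
  scaffold_chars <- strsplit(design$scaffold, "")[[1L]]
  full <- vapply(seq_along(peptide), function(i) {
    s <- scaffold_chars
    s[design$variable_positions] <- strsplit(peptide[i], "")[[1L]]
    paste(s, collapse = "")
  }, character(1))
  out <- tibble::tibble(
    peptide = peptide,
    full_peptide = full,
    n_genotypes = as.integer(mult),
    expected_freq = mult / total
  )
  dplyr::arrange(out, .data$peptide)
}

#' Enumerate genotypes (codon combinations) of a library design
#'
#' @param design A [library_design()].
#' @param peptides Optional character vector restricting output to the
#'   genotypes encoding these residue combinations.
#' @return A tibble with columns `genotype_id`, `peptide`, and one
#'   `codon_<i>` column per variable position; stop-containing combinations
#'   are excluded. Rows are ordered lexicographically by peptide then
#'   genotype.
#' @export
library_genotypes <- function(design, peptides = NULL) {
  stopifnot(inherits(design, "library_design"))
  k <- length(design$variable_positions)
  if (k == 0L) {
    return(tibble::tibble(genotype_id = 1L, peptide = ""))
  }
  sets <- lapply(design$per_position, function(p) {
    cd <- p$codons
    cd[translate_codon(cd) != "*"]
  })
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)[rev(seq_len(k))]
  names(grid) <- paste0("codon_", seq_len(k))
  pep <- do.call(paste0, lapply(grid, translate_codon))
  out <- tibble::as_tibble(grid)
  out$peptide <- pep
  out <- dplyr::arrange(out, .data$peptide, dplyr::across(dplyr::starts_with("codon_")))
  if (!is.null(peptides)) {
    out <- dplyr::filter(out, .data$peptide %in% peptides)
  }
  out$genotype_id <- seq_len(nrow(out))
  dplyr::select(out, "genotype_id", "peptide", dplyr::starts_with("codon_"))
}

#' Expected frequency of residue combinations under uniform codon synthesis
#'
#' @param design A [library_design()].
#' @param residues Character vector of residue combinations, each as long as
#'   the number of variable positions.
#' @return A numeric vector of probabilities; combinations not encodable
#'   under the codon scheme get 0 with a warning.
#' @examples
#' d <- library_design()
#' expected_variant_frequency(d, "FWL") # 3 / 29791
#' @export
expected_variant_frequency <- function(design, residues) {
  stopifnot(inherits(design, "library_design"))
  counts <- position_aa_counts(design)
  k <- length(counts)
  total <- prod(vapply(counts, sum, numeric(1)))
  bad_len <- nchar(residues) != k
  if (any(bad_len)) {
    stop("each residue string must have length ", k, call. = FALSE)
  }
  out <- vapply(residues, function(r) {
    ch <- strsplit(r, "")[[1L]]
    m <- vapply(seq_len(k), function(i) {
      v <- counts[[i]][ch[i]]
      if (is.na(v)) 0 else as.numeric(v)
    }, numeric(1))
    prod(m) / total
  }, numeric(1))
  if (any(out == 0)) {
    warning("residue combination(s) not encodable under the codon scheme: ",
            paste(residues[out == 0], collapse = ", "), call. = FALSE)
  }
  unname(out)
}

## coding sequence of the scaffold with the given codons substituted at the
## variable positions; `codons` is a character vector, one per position
peptide_cds <- function(design, codons) {
  aa <- strsplit(design$scaffold, "")[[1L]]
  cds <- design$scaffold_codons[aa]
  cds[design$variable_positions] <- toupper(codons)
  paste(cds, collapse = "")
}

#' Build the full-length DNA template for a genotype
#'
#' Concatenates the 5' flank, the scaffold coding sequence with the
#' genotype's codons substituted at the variable positions, and the 3'
#' flank. All templates of one design have equal length.
#'
#' @param design A [library_design()].
#' @param genotype Character vector of concrete codons, one per variable
#'   position (e.g. `c("TTT", "TGG", "TTG")`), or a single row of
#'   [library_genotypes()].
#' @return A single DNA string.
#' @export
build_template <- function(design, genotype) {
  stopifnot(inherits(design, "library_design"))
  if (is.data.frame(genotype)) {
    stopifnot(nrow(genotype) == 1L)
    genotype <- unlist(genotype[grep("^codon_", names(genotype))], use.names = FALSE)
  }
  k <- length(design$variable_positions)
  if (length(genotype) != k) {
    stop("genotype must supply ", k, " codons", call. = FALSE)
  }
  genotype <- toupper(genotype)
  ok <- vapply(seq_len(k), function(i) {
    genotype[i] %in% design$per_position[[i]]$codons
  }, logical(1))
  if (!all(ok)) {
    stop("codon(s) not admitted by the design scheme: ",
         paste(genotype[!ok], collapse = ", "), call. = FALSE)
  }
  paste0(design$flank_5p, peptide_cds(design, genotype), design$flank_3p)
}

#' Write all full-length library templates to a FASTA file
#'
#' One record per genotype; record IDs are `<peptide>|<codon1>-<codon2>-...`.
#'
#' @param design A [library_design()].
#' @param path Output FASTA path.
#' @param genotypes Optional subset from [library_genotypes()].
#' @return The path, invisibly.
#' @export
write_library_fasta <- function(design, path, genotypes = NULL) {
  gt <- genotypes %||% library_genotypes(design)
  codon_cols <- grep("^codon_", names(gt), value = TRUE)
  seqs <- vapply(seq_len(nrow(gt)), function(i) {
    build_template(design, unlist(gt[i, codon_cols], use.names = FALSE))
  }, character(1))
  ids <- paste0(gt$peptide, "|",
                apply(gt[codon_cols], 1L, paste, collapse = "-"))
  x <- Biostrings::DNAStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Export the variant table of a design as TSV
#'
#' @param design A [library_design()].
#' @param path Output TSV path.
#' @return The enumerated variant tibble, invisibly.
#' @export
export_variant_table <- function(design, path) {
  tab <- enumerate_library(design)
  readr::write_tsv(tab, path)
  invisible(tab)
}
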