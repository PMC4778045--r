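#' Amplicon window and extraction syntax of a library design
#'
#' Short sequencing reads cover a fixed window of the template containing
#' all randomised codons. The window is anchored a fixed number of bases
#' upstream of the peptide coding sequence, so the layout alternates
#' constant anchor segments (scaffold codons and flank context) with
#' 3-nt variable slots, one per randomised position. The same layout drives
#' both read simulation and codon extraction.
#'
#' @param design A [library_design()].
#' @param read_length Window (and read) length in bases.
#' @param upstream_context Bases of 5' flank included before the coding
#'   sequence.
#' @param max_mismatches_per_anchor Substitutions tolerated in each anchor
#'   during extraction.
#' @return An object of class `extraction_syntax`: anchor sequences with
#'   their window offsets, slot offsets, the window start on the template
#'   and the layout length.
#' @export
extraction_syntax <- function(design, read_length = 56L,
                              upstream_context = 10L,
                              max_mismatches_per_anchor = 1L) {
  stopifnot(inherits(design, "library_design"), read_length > 0,
            upstream_context >= 0)
  k <- length(design$variable_positions)
  cds_start <- nchar(design$flank_5p) + 1L
  win_start <- cds_start - upstream_context
  if (win_start < 1L) {
    stop("upstream_context exceeds the 5' flank length", call. = FALSE)
  }
  ## slot offsets within the window (1-based), one per variable position
  pos <- sort(design$variable_positions)
  slot_starts <- upstream_context + 3L * (pos - 1L) + 1L
  if (k > 0L && max(slot_starts) + 2L > read_length) {
    stop("read_length too short to cover all variable codons", call. = FALSE)
  }
  ref <- build_template(design, vapply(design$per_position, function(p) {
    cd <- p$codons
    cd[translate_codon(cd) != "*"][1L]
  }, character(1)))
  if (win_start + read_length - 1L > nchar(ref)) {
    stop("read_length extends past the template 3' end", call. = FALSE)
  }
  window_ref <- substr(ref, win_start, win_start + read_length - 1L)
  ## constant segments between/around the slots
  bounds_lo <- c(1L, slot_starts + 3L)
  bounds_hi <- c(slot_starts - 1L, read_length)
  anchors <- substring(window_ref, bounds_lo, bounds_hi)
  keep <- nchar(anchors) > 0L
  structure(
    list(
      anchors = anchors[keep],
      anchor_starts = bounds_lo[keep],
      slot_starts = slot_starts,
      layout_length = read_length,
      window_start = win_start,
      max_mismatches_per_anchor = as.integer(max_mismatches_per_anchor),
      variable_positions = pos
    ),
    class = "extraction_syntax"
  )
}

#' @export
print.extraction_syntax <- function(x, ...) {
  cat("<extraction_syntax> layout ", x$layout_length, " nt, ",
      length(x$slot_starts), " slots at offsets ",
      paste(x$slot_starts, collapse = ", "), "\n", sep = "")
  cat("  anchors: ", paste(x$anchors, collapse = " | "), "\n", sep = "")
  invisible(x)
}

## window sequences for a genotype table: constant segments interleaved with
## each genotype's codons
genotype_windows <- function(syntax, genotypes) {
  codon_cols <- grep("^codon_", names(genotypes), value = TRUE)
  k <- length(syntax$slot_starts)
  stopifnot(length(codon_cols) == k)
  ## reconstruct the full set of constant pieces, including empty ones
  pieces <- character(2L * k + 1L)
  ref_anchor <- setNames(syntax$anchors, syntax$anchor_starts)
  bounds_lo <- c(1L, syntax$slot_starts + 3L)
  for (i in seq_along(bounds_lo)) {
    key <- as.character(bounds_lo[i])
    pieces[2L * i - 1L] <- if (key %in% names(ref_anchor)) ref_anchor[[key]] else ""
  }
  args <- vector("list", 2L * k + 1L)
  for (i in seq_len(k)) {
    args[[2L * i - 1L]] <- pieces[2L * i - 1L]
    args[[2L * i]] <- genotypes[[codon_cols[i]]]
  }
  args[[2L * k + 1L]] <- pieces[2L * k + 1L]
  do.call(paste0, args)
}
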