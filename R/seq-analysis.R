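## quality string -> integer Phred vector
decode_quality <- function(q) utf8ToInt(q) - 33L

## running-sum 3' quality trimming: subtract the cutoff from each quality,
## form suffix sums S(i) = sum_{j >= i} (q_j - cutoff), and cut from the
## index with the minimal (most negative) suffix sum; ties resolved to the
## rightmost index, so the least sequence is removed. No trimming when all
## suffix sums are non-negative. This is the BWA-style algorithm used by
## common adapter/quality trimmers, not a naive "first base below Q20" cut.
quality_trim_length <- function(q, cutoff) {
  s <- rev(cumsum(rev(q - cutoff)))
  m <- min(s)
  if (m >= 0) length(q) else max(which(s == m)) - 1L
}

## number of mismatches between two equal-length strings
string_mismatches <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Trim adapter and low-quality 3' ends from reads
#'
#' First removes the adapter when it matches the read's 3' suffix within
#' `adapter_mismatches` substitutions; then trims low-quality 3' bases with
#' the running-sum algorithm at cutoff `q_cutoff` (see Details). Never
#' lengthens a read and is idempotent. Fully trimmed reads are retained
#' with empty sequence and counted as rejected downstream.
#'
#' @details Quality trimming subtracts `q_cutoff` from every quality,
#' computes partial sums from the 3' end, and cuts at the position with the
#' minimal sum (rightmost on ties); nothing is cut when all sums are
#' non-negative.
#'
#' @param reads A read-pool tibble (`read_id`, `sequence`, `quality`).
#' @param adapter Optional adapter sequence to strip from the 3' end.
#' @param q_cutoff Phred quality cutoff (default 20).
#' @param adapter_mismatches Substitutions tolerated in the adapter match.
#' @return The tibble with `sequence` and `quality` trimmed and a
#'   `trimmed_length` column added.
#' @export
trim_reads <- function(reads, adapter = NULL, q_cutoff = 20L,
                       adapter_mismatches = 1L) {
  stopifnot(is.data.frame(reads),
            all(c("sequence", "quality") %in% names(reads)))
  seqs <- reads$sequence
  quals <- reads$quality
  if (any(nchar(seqs) != nchar(quals))) {
    stop("sequence and quality lengths differ", call. = FALSE)
  }
  n <- length(seqs)
  if (!is.null(adapter)) {
    adapter <- toupper(adapter)
    a_len <- nchar(adapter)
    lens <- nchar(seqs)
    can <- lens >= a_len
    if (any(can)) {
      suffix <- substring(seqs[can], lens[can] - a_len + 1L, lens[can])
      mm <- vapply(suffix, string_mismatches, integer(1), b = adapter)
      hit <- which(can)[mm <= adapter_mismatches]
      if (length(hit) > 0L) {
        keep_len <- nchar(seqs[hit]) - a_len
        seqs[hit] <- substr(seqs[hit], 1L, keep_len)
        quals[hit] <- substr(quals[hit], 1L, keep_len)
      }
    }
  }
  new_len <- integer(n)
  for (i in seq_len(n)) {
    if (nchar(quals[i]) == 0L) { new_len[i] <- 0L; next }
    new_len[i] <- quality_trim_length(decode_quality(quals[i]), q_cutoff)
  }
  reads$sequence <- substr(seqs, 1L, new_len)
  reads$quality <- substr(quals, 1L, new_len)
  reads$trimmed_length <- new_len
  reads
}

#' Extract randomised codons from reads by anchor scanning
#'
#' Scans each read for the constant anchor segments of the amplicon layout,
#' in order and at the fixed spacings implied by the 3-nt variable slots,
#' tolerating up to `max_mismatches_per_anchor` substitutions per anchor.
#' The layout may start at any offset within the read; a read with more
#' than one valid placement is rejected as ambiguous, a read too short to
#' hold the layout as truncated, and a read with no anchor-compatible
#' placement as an anchor mismatch.
#'
#' @param reads A (possibly trimmed) read-pool tibble.
#' @param syntax An [extraction_syntax()].
#' @param max_mismatches Override of the syntax's per-anchor mismatch
#'   allowance.
#' @return A tibble with `read_id`, `status` (`ok`, `truncated`,
#'   `anchor_mismatch` or `ambiguous`) and `codon_<i>` columns (NA unless
#'   `ok`). Attribute `rejections` tabulates the non-ok statuses.
#' @export
extract_codons <- function(reads, syntax, max_mismatches = NULL) {
  stopifnot(is.data.frame(reads), inherits(syntax, "extraction_syntax"))
  max_mm <- max_mismatches %||% syntax$max_mismatches_per_anchor
  L <- syntax$layout_length
  k <- length(syntax$slot_starts)
  n <- nrow(reads)
  status <- rep("truncated", n)
  codons <- matrix(NA_character_, nrow = n, ncol = k)

  lens <- nchar(reads$sequence)
  anchor_chars <- lapply(syntax$anchors, function(a) strsplit(a, "")[[1L]])

  for (len in unique(lens[lens >= L])) {
    idx <- which(lens == len)
    mat <- matrix(unlist(strsplit(reads$sequence[idx], ""), use.names = FALSE),
                  nrow = length(idx), byrow = TRUE)
    n_place <- integer(length(idx))
    place_off <- integer(length(idx))
    for (off in 0:(len - L)) {
      ok <- rep(TRUE, length(idx))
      for (a in seq_along(syntax$anchors)) {
        cols <- off + syntax$anchor_starts[a] + seq_along(anchor_chars[[a]]) - 1L
        mm <- rowSums(mat[, cols, drop = FALSE] !=
                        matrix(anchor_chars[[a]], nrow = length(idx),
                               ncol = length(cols), byrow = TRUE))
        ok <- ok & (mm <= max_mm)
        if (!any(ok)) break
      }
      first <- ok & n_place == 0L
      place_off[first] <- off
      n_place <- n_place + ok
    }
    status[idx[n_place == 0L]] <- "anchor_mismatch"
    status[idx[n_place > 1L]] <- "ambiguous"
    hit <- n_place == 1L
    status[idx[hit]] <- "ok"
    if (any(hit)) {
      for (s in seq_len(k)) {
        cols0 <- syntax$slot_starts[s] - 1L
        codons[idx[hit], s] <- vapply(which(hit), function(j) {
          paste(mat[j, place_off[j] + cols0 + 1:3], collapse = "")
        }, character(1))
      }
    }
  }

  out <- tibble::tibble(read_id = reads$read_id, status = status)
  for (s in seq_len(k)) out[[paste0("codon_", s)]] <- codons[, s]
  rej <- table(factor(status[status != "ok"],
                      levels = c("truncated", "anchor_mismatch", "ambiguous")))
  attr(out, "rejections") <- tibble::tibble(
    reason = names(rej), n = as.integer(rej)
  )
  out
}

#' Tabulate extracted codons into peptide and positional frequencies
#'
#' Translates each accepted codon tuple; tuples containing a stop codon are
#' counted as a separate class (expected under NNK randomisation, which
#' admits the amber stop) and excluded from peptide frequencies. Records
#' the joint per-peptide frequencies, per-position amino-acid marginals and
#' the genotype (distinct DNA) diversity observed per peptide.
#'
#' @param extracted An [extract_codons()] result.
#' @param pool Pool label for the table.
#' @return An object of class `frequency_table`: `per_peptide` (peptide,
#'   count, frequency, n_genotypes_observed), `per_position` (position,
#'   residue, frequency), and counts of used, stop-containing and rejected
#'   reads (by reason).
#' @export
tabulate_codons <- function(extracted, pool = "pool") {
  stopifnot(is.data.frame(extracted), "status" %in% names(extracted))
  codon_cols <- grep("^codon_", names(extracted), value = TRUE)
  k <- length(codon_cols)
  ok <- dplyr::filter(extracted, .data$status == "ok")
  if (nrow(ok) == 0L) {
    warning("no accepted reads to tabulate; returning an empty table",
            call. = FALSE)
    return(structure(
      list(
        per_peptide = tibble::tibble(peptide = character(), count = integer(),
                                     n_genotypes_observed = integer(),
                                     frequency = numeric()),
        per_position = tibble::tibble(position = integer(),
                                      residue = character(),
                                      count = integer(), frequency = numeric()),
        pool = pool, n_reads_used = 0L, n_stop = 0L,
        n_reads_rejected = sum(extracted$status != "ok"),
        rejections = attr(extracted, "rejections") %||%
          tibble::tibble(reason = character(), n = integer())
      ),
      class = "frequency_table"
    ))
  }
  aa <- lapply(codon_cols, function(cc) translate_codon(ok[[cc]]))
  has_stop <- Reduce(`|`, lapply(aa, function(x) x == "*"))
  peptide <- do.call(paste0, aa)
  genotype <- do.call(paste, c(ok[codon_cols], sep = "-"))

  keep <- !has_stop
  pep_tab <- tibble::tibble(peptide = peptide[keep], genotype = genotype[keep]) |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(count = dplyr::n(),
                     n_genotypes_observed = dplyr::n_distinct(.data$genotype),
                     .groups = "drop") |>
    dplyr::mutate(frequency = .data$count / sum(.data$count)) |>
    dplyr::arrange(dplyr::desc(.data$count))

  per_position <- purrr::map_dfr(seq_len(k), function(i) {
    x <- aa[[i]][keep]
    tab <- table(x)
    tibble::tibble(position = i, residue = names(tab),
                   count = as.integer(tab),
                   frequency = as.integer(tab) / length(x))
  })

  rejections <- attr(extracted, "rejections") %||%
    tibble::tibble(reason = character(), n = integer())
  structure(
    list(per_peptide = pep_tab, per_position = per_position,
         pool = pool, n_reads_used = sum(keep), n_stop = sum(has_stop),
         n_reads_rejected = sum(extracted$status != "ok"),
         rejections = rejections),
    class = "frequency_table"
  )
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("<frequency_table> pool '", x$pool, "': ", x$n_reads_used,
      " reads used, ", x$n_stop, " stop-containing, ",
      x$n_reads_rejected, " rejected\n", sep = "")
  print(head(x$per_peptide, 5L))
  invisible(x)
}

## coerce a frequency_table or a data frame with peptide/frequency columns
as_peptide_frequencies <- function(x, what) {
  if (inherits(x, "frequency_table")) {
    out <- x$per_peptide[, c("peptide", "frequency")]
    if ("count" %in% names(x$per_peptide)) out$count <- x$per_peptide$count
    return(out)
  }
  if (is.data.frame(x) && all(c("peptide", "frequency") %in% names(x))) {
    return(tibble::as_tibble(x))
  }
  stop(what, " must be a frequency_table or a data frame with columns ",
       "'peptide' and 'frequency'", call. = FALSE)
}

#' Fold-enrichment of peptides between sorted pools
#'
#' Computes, for every peptide seen in any pool, its frequency in the
#' bright, input and (optionally) dark pools and the fold-enrichment
#' bright/input. Peptides absent from the input pool are flagged
#' (`undefined_input`) rather than divided by zero. Rows are ranked by
#' descending fold.
#'
#' @param bright,input,dark Frequency tables ([tabulate_codons()] results)
#'   or data frames with `peptide` and `frequency` columns; `dark` is
#'   optional.
#' @return A tibble of class `enrichment_table` with columns `peptide`,
#'   `freq_bright`, `freq_input`, `freq_dark`, `fold`, `rank` and `flag`.
#' @examples
#' b <- data.frame(peptide = "FWL", frequency = 0.21)
#' i <- data.frame(peptide = "FWL", frequency = 0.00043)
#' enrichment(b, i)$fold # ~488
#' @export
enrichment <- function(bright, input, dark = NULL) {
  b <- as_peptide_frequencies(bright, "bright")
  i <- as_peptide_frequencies(input, "input")
  out <- dplyr::full_join(
    dplyr::select(b, "peptide", freq_bright = "frequency"),
    dplyr::select(i, "peptide", freq_input = "frequency"),
    by = "peptide"
  )
  if (!is.null(dark)) {
    d <- as_peptide_frequencies(dark, "dark")
    out <- dplyr::left_join(
      out, dplyr::select(d, "peptide", freq_dark = "frequency"),
      by = "peptide"
    )
  } else {
    out$freq_dark <- NA_real_
  }
  out <- out |>
    dplyr::mutate(
      freq_bright = tidyr::replace_na(.data$freq_bright, 0),
      fold = dplyr::if_else(
        !is.na(.data$freq_input) & .data$freq_input > 0,
        .data$freq_bright / .data$freq_input, NA_real_
      ),
      flag = dplyr::if_else(
        is.na(.data$freq_input) | .data$freq_input == 0,
        "undefined_input", "ok"
      )
    ) |>
    dplyr::arrange(dplyr::desc(.data$fold)) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::relocate("peptide", "freq_bright", "freq_dark", "freq_input",
                    "fold", "rank", "flag")
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Bootstrap significance of a frequency ratio between two pools
#'
#' Percentile bootstrap of the ratio of a peptide's frequency in a focal
#' pool over a reference pool, resampling read counts binomially at the
#' observed depths. The peptide is flagged enriched when the confidence
#' interval excludes 1.
#'
#' @param count_focal,n_focal Peptide read count and total reads in the
#'   focal pool (e.g. bright).
#' @param count_ref,n_ref Same for the reference pool (e.g. input).
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Optional RNG seed.
#' @return A one-row tibble: `estimate`, `lower`, `upper`, `enriched`,
#'   `undefined` (TRUE when the reference count is zero).
#' @export
enrichment_significance <- function(count_focal, n_focal, count_ref, n_ref,
                                    n_boot = 2000L, conf = 0.95,
                                    seed = NULL) {
  stopifnot(count_focal >= 0, count_ref >= 0,
            n_focal >= count_focal, n_ref >= count_ref)
  if (!is.null(seed)) set.seed(seed)
  if (count_ref == 0L) {
    return(tibble::tibble(estimate = NA_real_, lower = NA_real_,
                          upper = NA_real_, enriched = NA,
                          undefined = TRUE))
  }
  est <- (count_focal / n_focal) / (count_ref / n_ref)
  bf <- rbinom(n_boot, n_focal, count_focal / n_focal) / n_focal
  br <- rbinom(n_boot, n_ref, count_ref / n_ref) / n_ref
  ratio <- bf / br
  ratio <- ratio[is.finite(ratio)]
  alpha <- (1 - conf) / 2
  ci <- quantile(ratio, c(alpha, 1 - alpha), names = FALSE)
  tibble::tibble(
    estimate = est, lower = ci[1], upper = ci[2],
    enriched = ci[1] > 1 || ci[2] < 1,
    undefined = FALSE
  )
}

#' Export a frequency table as TSV
#'
#' @param freq_table A [tabulate_codons()] result.
#' @param path Output TSV path.
#' @return The per-peptide tibble, invisibly.
#' @export
export_frequency_table <- function(freq_table, path) {
  stopifnot(inherits(freq_table, "frequency_table"))
  tab <- dplyr::mutate(freq_table$per_peptide, pool = freq_table$pool,
                       .before = 1L)
  readr::write_tsv(tab, path)
  invisible(tab)
}
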