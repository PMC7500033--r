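## Sequence-context annotation of deletions: terminal microhomology (TMH)
## and repeat-tract membership.
##
## TMH is the total length of identical sequence shared between one
## deletion terminus and the flank of the other terminus (a direct repeat
## at the junction).  It is computed as the sum of two exact extensions,
## which makes it agnostic to the direction of the underlying mechanism,
## and reproduces the 13-bp direct repeat of the common deletion.

TMH_CAP <- 100L

#' Terminal microhomology length of deletion spans
#'
#' For each span, `r` is the maximal exact match comparing the sequence
#' starting at `ls5` (first deleted base) with the sequence starting at
#' `hs5 + 1` (first retained base after the deletion), and `l` the maximal
#' exact match comparing the sequences ending at `ls5 - 1` and `hs5`; both
#' use circular indexing and are capped at `r TMH_CAP` bp.  TMH is
#' `r + l` and is invariant under the choice of equivalent (left-aligned
#' or not) representation.
#'
#' @param span Span data.frame ([deletion_span()]).
#' @param ref A [circular_reference()].
#' @param cap Maximum extension per side (bp).
#' @return Integer vector of TMH lengths.
#' @export
tmh_length <- function(span, ref, cap = TMH_CAP) {
  validate_span(span, ref)
  L <- ref$length
  chars <- ref_chars(ref)
  at <- function(p) chars[((p - 1L) %% L) + 1L]
  vapply(seq_len(nrow(span)), function(i) {
    ls5 <- span$ls5[i]; hs5 <- span$hs5[i]
    r <- 0L
    while (r < cap && at(ls5 + r) == at(hs5 + 1L + r)) r <- r + 1L
    l <- 0L
    while (l < cap && at(ls5 - 1L - l) == at(hs5 - l)) l <- l + 1L
    r + l
  }, integer(1))
}

ref_chars <- function(ref) {
  env <- ref_char_cache
  key <- paste0(ref$name, "#", ref$length)
  if (is.null(env[[key]])) env[[key]] <- strsplit(ref$seq, "")[[1L]]
  env[[key]]
}
ref_char_cache <- new.env(parent = emptyenv())

#' Is a deletion a contraction of a perfect local repeat?
#'
#' TRUE when the terminal microhomology is at least as long as the
#' deletion itself, i.e., the deletion removes one unit of a perfect
#' repeat (homopolymer-run or tandem-repeat contraction).
#'
#' @inheritParams tmh_length
#' @return Logical vector.
#' @export
repeat_tract_flag <- function(span, ref, cap = TMH_CAP) {
  tmh_length(span, ref, cap) >= span_length(span, ref)
}

TMH_BINS <- c(as.character(0:9), ">=10")

tmh_bin <- function(tmh) {
  factor(ifelse(tmh >= 10L, ">=10", as.character(tmh)), levels = TMH_BINS)
}

#' Annotate a frequency table or span set with sequence context
#'
#' @param spans Span data.frame (e.g., the `table` of a
#'   `frequency_table`).
#' @param ref A [circular_reference()].
#' @return data.frame: `ls5`, `hs5`, `tmh`, `in_repeat_tract`, `tmh_bin`,
#'   `tmh_class` (1: TMH <= 3; 2: TMH >= 10; 3: intermediate — a
#'   convenience mapping of qualitative mechanism classes: ligation-like,
#'   slippage-like, and the residue).
#' @export
annotate_context <- function(spans, ref) {
  tmh <- tmh_length(spans, ref)
  data.frame(ls5 = spans$ls5, hs5 = spans$hs5, tmh = tmh,
             in_repeat_tract = tmh >= span_length(spans, ref),
             tmh_bin = tmh_bin(tmh),
             tmh_class = ifelse(tmh <= 3L, 1L, ifelse(tmh >= 10L, 2L, 3L)))
}

#' Frequency spectrum by terminal-microhomology bin
#'
#' Sums background-subtracted frequencies into TMH bins 0..9 and ">=10"
#' over deletions of at least `min_span` bp (small deletions are the most
#' frequent short-read sequencing artifact and are excluded from
#' context-specific summaries).
#'
#' @param freqs A `frequency_table`.
#' @param annotations Output of [annotate_context()] covering its rows.
#' @param min_span Minimum deleted length (bp), default 20.
#' @return List: `spectrum` (named numeric over the TMH bins),
#'   `fraction_with_tmh` (share of qualifying junctions with TMH >= 1).
#' @export
tmh_spectrum <- function(freqs, annotations, min_span = 20L) {
  tab <- freqs$table
  m <- match(paste(tab$ls5, tab$hs5),
             paste(annotations$ls5, annotations$hs5))
  if (anyNA(m)) stop("annotations do not cover all frequency-table rows")
  keep <- tab$length >= min_span
  spec <- setNames(numeric(length(TMH_BINS)), TMH_BINS)
  if (any(keep)) {
    agg <- tapply(tab$f_i_bg[keep], annotations$tmh_bin[m][keep], sum)
    spec[names(agg)] <- ifelse(is.na(agg), 0, agg)
    frac <- mean(annotations$tmh[m][keep] >= 1L)
  } else frac <- NA_real_
  list(spectrum = spec, fraction_with_tmh = frac)
}
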