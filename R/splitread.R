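## Split-read deletion detection on a circular genome.
##
## Reads are aligned against two copies of the reference arranged in
## tandem (so alignments may cross the coordinate origin); junctions are
## called from two-anchor split alignments, left-aligned to a canonical
## representation, and reconciled across mate pairs.

DEFAULT_K <- 16L
DEFAULT_MIN_ANCHOR <- 20L
DEFAULT_MAX_MM <- 2L
POSSIBLE_INSERTION_BP <- 15000L

## ---- FASTQ input and quality filtering ----------------------------------

read_fastq_pair <- function(fq1, fq2) {
  r1 <- Biostrings::readDNAStringSet(fq1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fq2, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("mate FASTQ files differ in read count: ", fq1, " vs ", fq2)
  list(r1 = r1, r2 = r2)
}

mean_phred <- function(quals) {
  qs <- as.character(quals)
  n <- nchar(qs)
  if (length(unique(n)) == 1L) {   # fast path: uniform read length
    v <- utf8ToInt(paste(qs, collapse = "")) - 33L
    colMeans(matrix(v, nrow = n[1L]))
  } else {
    vapply(qs, function(s) mean(utf8ToInt(s)) - 33, 0, USE.NAMES = FALSE)
  }
}

#' Filter read pairs on mean base quality
#'
#' Pairs are retained only when *both* mates have a mean Phred score at or
#' above the threshold (default 20); pair-level filtering keeps the mate
#' reconciliation logic simple.
#'
#' @param pair List with DNAStringSets `r1`, `r2` (qualities attached),
#'   as returned by the internal FASTQ reader.
#' @param min_mean_q Minimum mean Phred score per mate.
#' @return The filtered pair list; attribute `n_dropped` records how many
#'   pairs were removed.
#' @export
quality_filter <- function(pair, min_mean_q = 20) {
  if (length(pair$r1) == 0L) {
    attr(pair, "n_dropped") <- 0L
    return(pair)
  }
  q1 <- mean_phred(S4Vectors::mcols(pair$r1)$qualities)
  q2 <- mean_phred(S4Vectors::mcols(pair$r2)$qualities)
  keep <- q1 >= min_mean_q & q2 >= min_mean_q
  out <- list(r1 = pair$r1[keep], r2 = pair$r2[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

## ---- alignment -----------------------------------------------------------

align_batch <- function(reads, ref, k = DEFAULT_K,
                        min_anchor = DEFAULT_MIN_ANCHOR,
                        max_mm = DEFAULT_MAX_MM) {
  ref2 <- paste0(ref$seq, ref$seq)
  res <- cpp_align_batch(as.character(reads), ref2, ref$length,
                         as.integer(k), as.integer(min_anchor),
                         as.integer(max_mm))
  as.data.frame(res)
}

#' Align a single read, reporting a split alignment if present
#'
#' Finds maximal exact-seeded, mismatch-tolerant anchors on the doubled
#' reference.  Returns a two-anchor split when the read's flanks anchor at
#' distinct loci with a positive reference gap, a one-anchor contiguous
#' alignment when one anchor covers the read, and `NULL` when the read is
#' unalignable.
#'
#' @param read Character scalar DNA sequence.
#' @param ref A [circular_reference()].
#' @param k Seed k-mer size.
#' @param min_anchor Minimum anchor length per side (bp).
#' @param max_mm Maximum mismatches tolerated per extension.
#' @return A list of class `split_alignment` with elements `type`
#'   (`"contiguous"` or `"split"`), `strand`, `anchors` (matrix of doubled
#'   reference intervals), and `gap_on_reference`, or `NULL`.
#' @export
align_split <- function(read, ref, k = DEFAULT_K,
                        min_anchor = DEFAULT_MIN_ANCHOR,
                        max_mm = DEFAULT_MAX_MM) {
  if (nchar(read) < 2L * min_anchor)
    stop("read shorter than 2 * min_anchor")
  a <- align_batch(read, ref, k, min_anchor, max_mm)
  if (a$type == 0L) return(NULL)
  anchors <- rbind(c(a$s1, a$e1))
  gap <- 0L
  if (a$type == 2L) {
    anchors <- rbind(anchors, c(a$s2, a$e2))
    gap <- a$s2 - a$e1 - 1L
  }
  colnames(anchors) <- c("ref_start", "ref_end")
  structure(list(type = if (a$type == 2L) "split" else "contiguous",
                 strand = if (a$strand > 0L) "+" else "-",
                 anchors = anchors, gap_on_reference = gap),
            class = "split_alignment")
}

#' Call a deletion span from a two-anchor split alignment
#'
#' `ls5` is the canonicalized position after the first anchor's reference
#' end and `hs5` the position before the second anchor's start, i.e., the
#' last missing bases on either side of the junction.
#'
#' @param split A `split_alignment` with exactly two anchors.
#' @param ref A [circular_reference()].
#' @return A one-row span data.frame ([deletion_span()]).
#' @export
call_junction <- function(split, ref) {
  if (is.null(split) || split$type != "split")
    stop("call_junction requires a two-anchor split alignment")
  if (split$gap_on_reference <= 0L)
    stop("ambiguous junction: anchors overlap on the reference")
  ls5 <- canonicalize(split$anchors[1L, "ref_end"] + 1L, ref)
  hs5 <- canonicalize(split$anchors[2L, "ref_start"] - 1L, ref)
  deletion_span(ls5, hs5, wraps = ls5 > hs5)
}

#' Left-align deletion spans to their canonical representation
#'
#' When the deleted sequence sits in a repeat context, several (ls5, hs5)
#' pairs describe the same deletant molecule.  The span is shifted down
#' while the base preceding `ls5` equals the base at `hs5` (circularly),
#' which preserves the post-deletion sequence; the leftmost representation
#' is canonical.
#'
#' @param span Span data.frame ([deletion_span()]), any number of rows.
#' @param ref A [circular_reference()].
#' @return Span data.frame of the same shape, left-aligned.
#' @export
left_align <- function(span, ref) {
  validate_span(span, ref)
  L <- ref$length
  len <- span_length(span, ref)
  out <- span
  for (i in seq_len(nrow(span))) {
    ls5 <- span$ls5[i]
    for (step in seq_len(L)) {   # bounded walk; full-circle repeats impossible
      hs5 <- ((ls5 + len[i] - 2L) %% L) + 1L
      prev <- ((ls5 - 2L) %% L) + 1L
      if (ref_base(ref, prev) != ref_base(ref, hs5)) break
      ls5 <- ((ls5 - 2L) %% L) + 1L
    }
    hs5 <- ((ls5 + len[i] - 2L) %% L) + 1L
    out$ls5[i] <- ls5
    out$hs5[i] <- hs5
    out$wraps[i] <- ls5 > hs5
  }
  out
}

## ---- mate reconciliation -------------------------------------------------

## does a contiguous doubled-reference interval [s, e] cross the circular
## p|p+1 boundary with at least `margin` bases on both sides?  The margin
## guards against mismatch-tolerant alignment tails drifting a base or
## two past a junction by chance.
covers_boundary <- function(s, e, p, L, margin = 6L) {
  # the boundary occurs twice on the doubled axis
  for (off in c(0L, L)) {
    b1 <- p + off
    if (s <= b1 - margin + 1L && e >= b1 + margin) return(TRUE)
  }
  FALSE
}

#' Reconcile junction calls across a mate pair
#'
#' A junction is suppressed when the partner mate aligns contiguously
#' across the junction locus (covering the boundary between the last
#' retained and first deleted base on either side), since both mates
#' derive from one fragment and cannot disagree about a deletion.
#' Otherwise each supporting mate contributes one supporting read.
#'
#' @param m1,m2 One-row alignment results for the two mates (internal
#'   format from the batch aligner).
#' @param spans1,spans2 Left-aligned spans called from each mate (or NULL).
#' @param ref A [circular_reference()].
#' @return A span data.frame of supported junctions, one row per
#'   supporting mate (possibly zero rows).
#' @keywords internal
reconcile_pair <- function(m1, m2, spans1, spans2, ref) {
  L <- ref$length
  check <- function(span, other) {
    if (is.null(span)) return(NULL)
    if (other$type == 1L) {
      conflict <-
        covers_boundary(other$s1, other$e1, ((span$ls5 - 2L) %% L) + 1L, L) ||
        covers_boundary(other$s1, other$e1, span$hs5, L)
      if (conflict) return(NULL)
    }
    span
  }
  rbind(check(spans1, m2), check(spans2, m1))
}

## ---- catalog construction ------------------------------------------------

empty_calls <- function() {
  data.frame(ls5 = integer(), hs5 = integer(), length = integer(),
             x_i = integer(), wraps = logical(),
             possible_insertion = logical())
}

#' Build a deletion catalog from paired FASTQ files
#'
#' Runs the full detection chain: quality filtering, split-read alignment
#' to the doubled reference, junction calling, left-alignment, and mate
#' reconciliation; accumulates a per-position depth profile, the total
#' mapped-mate count `r_t`, and the mean aligned read length `L_r`.
#' Deterministic given its inputs.
#'
#' @param fq1,fq2 Paths to the paired FASTQ files (optionally gzipped).
#' @param ref A [circular_reference()].
#' @param min_mean_q Mean-quality threshold for [quality_filter()].
#' @param k,min_anchor,max_mm Aligner parameters.
#' @param sample_id Sample label carried into outputs.
#' @return A `deletion_catalog`: list with `calls` (data.frame `ls5`,
#'   `hs5`, `length`, `x_i`, `wraps`, `possible_insertion`), `depth`
#'   (integer vector over `[1, L_u]`), `r_t`, `L_r`, `sample_id`.
#' @export
build_catalog <- function(fq1, fq2, ref, min_mean_q = 20,
                          k = DEFAULT_K, min_anchor = DEFAULT_MIN_ANCHOR,
                          max_mm = DEFAULT_MAX_MM, sample_id = "sample") {
  pair <- quality_filter(read_fastq_pair(fq1, fq2), min_mean_q)
  L <- ref$length
  n <- length(pair$r1)
  if (n == 0L) {
    return(new_catalog(empty_calls(), integer(L), 0L, 0, sample_id,
                       min_anchor = min_anchor))
  }
  a1 <- align_batch(pair$r1, ref, k, min_anchor, max_mm)
  a2 <- align_batch(pair$r2, ref, k, min_anchor, max_mm)

  call_spans <- function(a) {
    idx <- which(a$type == 2L)
    if (!length(idx)) return(NULL)
    ls5 <- canonicalize(a$e1[idx] + 1L, ref)
    hs5 <- canonicalize(a$s2[idx] - 1L, ref)
    sp <- deletion_span(ls5, hs5, wraps = ls5 > hs5)
    sp <- left_align_cached(sp, ref)
    sp$row <- idx
    sp
  }
  sp1 <- call_spans(a1)
  sp2 <- call_spans(a2)

  # reconcile only pairs that carry at least one split call
  pairs_with_calls <- sort(unique(c(sp1$row, sp2$row)))
  supported <- NULL
  for (i in pairs_with_calls) {
    s1 <- if (!is.null(sp1)) sp1[sp1$row == i, c("ls5", "hs5", "wraps")] else NULL
    s2 <- if (!is.null(sp2)) sp2[sp2$row == i, c("ls5", "hs5", "wraps")] else NULL
    if (!is.null(s1) && nrow(s1) == 0L) s1 <- NULL
    if (!is.null(s2) && nrow(s2) == 0L) s2 <- NULL
    sup <- reconcile_pair(a1[i, ], a2[i, ], s1, s2, ref)
    supported <- rbind(supported, sup)
  }

  if (is.null(supported) || nrow(supported) == 0L) {
    calls <- empty_calls()
  } else {
    key <- paste(supported$ls5, supported$hs5)
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    first <- supported[!duplicated(key), , drop = FALSE]
    first <- first[match(agg$key, paste(first$ls5, first$hs5)), ]
    len <- span_length(first, ref)
    calls <- data.frame(ls5 = first$ls5, hs5 = first$hs5, length = len,
                        x_i = as.integer(agg$Freq), wraps = first$wraps,
                        possible_insertion = len > POSSIBLE_INSERTION_BP)
    calls <- calls[order(calls$ls5, calls$hs5), , drop = FALSE]
    rownames(calls) <- NULL
  }

  # depth from all aligned segments (both anchors of split reads)
  seg_s <- c(a1$s1[a1$type >= 1L], a2$s1[a2$type >= 1L],
             a1$s2[a1$type == 2L], a2$s2[a2$type == 2L])
  seg_e <- c(a1$e1[a1$type >= 1L], a2$e1[a2$type >= 1L],
             a1$e2[a1$type == 2L], a2$e2[a2$type == 2L])
  depth <- depth_from_segments(seg_s, seg_e, L)
  mapped <- c(a1$alen[a1$type >= 1L], a2$alen[a2$type >= 1L])
  new_catalog(calls, depth, length(mapped),
              if (length(mapped)) mean(mapped) else 0, sample_id,
              min_anchor = min_anchor)
}

## left-align only unique raw spans, then map back
left_align_cached <- function(sp, ref) {
  key <- paste(sp$ls5, sp$hs5)
  uniq <- !duplicated(key)
  la <- left_align(sp[uniq, , drop = FALSE], ref)
  idx <- match(key, key[uniq])
  data.frame(ls5 = la$ls5[idx], hs5 = la$hs5[idx], wraps = la$wraps[idx])
}

depth_from_segments <- function(s, e, L) {
  if (!length(s)) return(integer(L))
  # unfold doubled-reference segments onto the circle
  crosses <- s <= L & e > L
  starts <- c(ifelse(s > L, s - L, s), rep(1L, sum(crosses)))
  ends <- c(ifelse(s > L, e - L, pmin(e, L)), e[crosses] - L)
  cov <- IRanges::coverage(IRanges::IRanges(start = starts, end = ends),
                           width = L)
  as.integer(cov)
}

new_catalog <- function(calls, depth, r_t, L_r, sample_id,
                        min_anchor = NULL) {
  structure(list(calls = calls, depth = depth, r_t = as.integer(r_t),
                 L_r = L_r, sample_id = sample_id, min_anchor = min_anchor),
            class = "deletion_catalog")
}

#' @export
print.deletion_catalog <- function(x, ...) {
  cat(sprintf(
    "<deletion_catalog> %s: %d unique junctions, sum x_i = %d, r_t = %d, L_r = %.1f\n",
    x$sample_id, nrow(x$calls), sum(x$calls$x_i), x$r_t, x$L_r))
  invisible(x)
}

#' Deletion load of a catalog
#'
#' Junction-supporting reads per megabase mapped to the reference
#' (`sum(x_i) / (r_t * L_r) * 1e6`), plus the per-read ratio
#' `sum(x_i) / r_t`.
#'
#' @param catalog A `deletion_catalog`.
#' @return List with `per_mbp` and `per_read`.
#' @export
deletion_load <- function(catalog) {
  if (catalog$r_t <= 0L) stop("deletion load undefined: no mapped reads")
  sx <- sum(catalog$calls$x_i)
  list(per_mbp = sx / (catalog$r_t * catalog$L_r) * 1e6,
       per_read = sx / catalog$r_t)
}

#' Write catalog artifacts (calls TSV, depth TSV, run-summary JSON)
#'
#' @param catalog A `deletion_catalog`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_catalog <- function(catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  calls_path <- file.path(dir, "catalog.tsv")
  write.table(catalog$calls, calls_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  depth_path <- file.path(dir, "depth.tsv")
  write.table(data.frame(pos = seq_along(catalog$depth),
                         depth = catalog$depth),
              depth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  summ_path <- file.path(dir, "run_summary.json")
  load <- if (catalog$r_t > 0L) deletion_load(catalog) else
    list(per_mbp = NA, per_read = NA)
  jsonlite::write_json(list(sample_id = catalog$sample_id,
                            r_t = catalog$r_t, L_r = catalog$L_r,
                            min_anchor = catalog$min_anchor,
                            load_per_mbp = load$per_mbp,
                            load_per_read = load$per_read),
                       summ_path, auto_unbox = TRUE, digits = NA)
  invisible(c(calls_path, depth_path, summ_path))
}

#' Read a catalog written by [write_catalog()]
#' @param dir Directory containing `catalog.tsv`, `depth.tsv`,
#'   `run_summary.json`.
#' @return A `deletion_catalog`.
#' @export
read_catalog <- function(dir) {
  calls <- read.delim(file.path(dir, "catalog.tsv"))
  if (nrow(calls) == 0L) calls <- empty_calls()
  depth <- read.delim(file.path(dir, "depth.tsv"))$depth
  summ <- jsonlite::read_json(file.path(dir, "run_summary.json"))
  ma <- summ$min_anchor
  if (length(ma) == 0L) ma <- NULL else ma <- as.numeric(ma)
  new_catalog(calls, as.integer(depth), summ$r_t, summ$L_r, summ$sample_id,
              min_anchor = ma)
}
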