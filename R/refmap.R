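#' @useDynLib mitoarc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median prcomp rnorm rexp runif sd setNames aggregate
#'   as.dendrogram cutree dist hclust optim quantile rbinom
#' @importFrom utils read.delim write.table head tail
NULL

## ---- circular reference -------------------------------------------------

#' Construct a circular reference genome
#'
#' A `circular_reference` holds the genome sequence of a closed circular
#' molecule (such as the 16,571-bp human mitochondrial genome), its length
#' `L_u`, and a name.  All coordinates in the package are 1-based and
#' inclusive on `[1, L_u]`.
#'
#' @param sequence Character scalar: uppercase DNA sequence (A/C/G/T/N).
#' @param name Name of the reference.
#' @return An object of class `circular_reference` with elements
#'   `name`, `seq` (character scalar), and `length`.
#' @export
circular_reference <- function(sequence, name = "mtDNA") {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L)
    stop("reference sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence))
    stop("reference sequence alphabet must be within {A,C,G,T,N}")
  structure(list(name = name, seq = sequence, length = nchar(sequence)),
            class = "circular_reference")
}

#' @export
print.circular_reference <- function(x, ...) {
  cat(sprintf("<circular_reference> %s: %d bp\n", x$name, x$length))
  invisible(x)
}

#' Read a circular reference from a single-record FASTA file
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @return A [circular_reference()].
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("reference FASTA must contain exactly one record, found ", length(ss))
  circular_reference(as.character(ss[[1L]]), name = names(ss)[1L])
}

#' Bundled synthetic human-mtDNA-like reference
#'
#' Loads the 16,571-bp synthetic reference bundled with the package
#' (`inst/extdata/synthetic_mtDNA_ref.fasta`).  The sequence is a
#' computer-generated stand-in for the human mitochondrial genome with the
#' same length, base composition, the 13-bp direct repeat flanking the
#' common deletion (positions 8471-8483 and 13448-13460), and the
#' control-region poly-C tracts at positions 303 and 16,184.  It is *not*
#' the human sequence; see [synthetic_mt_sequence()] for its construction.
#'
#' @return A [circular_reference()] of length 16,571.
#' @export
default_reference <- function() {
  read_reference(system.file("extdata", "synthetic_mtDNA_ref.fasta",
                             package = "mitoarc", mustWork = TRUE))
}

## ---- coordinate arithmetic ----------------------------------------------

#' Map a position on the tandem-doubled reference back to `[1, L_u]`
#'
#' Split-read alignment runs against two copies of the genome arranged in
#' tandem; indices are afterwards adjusted to the circular coordinate
#' system.
#'
#' @param pos Integer vector of positions in `[1, 2 * L_u]`.
#' @param ref A [circular_reference()].
#' @return Integer vector of positions in `[1, L_u]`.
#' @export
canonicalize <- function(pos, ref) {
  L <- ref$length
  if (any(pos < 1L | pos > 2L * L))
    stop("position outside the doubled reference range [1, ", 2L * L, "]")
  ((as.integer(pos) - 1L) %% L) + 1L
}

#' Deletion spans
#'
#' A deletion is identified by the positions of the last missing bases in
#' the light-strand 5' direction (`ls5`) and the heavy-strand 5' direction
#' (`hs5`), both 1-based inclusive on the reference.  Spans whose deleted
#' arc crosses reference position 1 carry `wraps = TRUE`; non-wrapping
#' spans satisfy `ls5 <= hs5`.
#'
#' @param ls5,hs5 Integer vectors of terminal positions.
#' @param wraps Logical vector; whether the deleted arc crosses position 1.
#' @return A data.frame with columns `ls5`, `hs5`, `wraps`.
#' @export
deletion_span <- function(ls5, hs5, wraps = FALSE) {
  n <- max(length(ls5), length(hs5))
  df <- data.frame(ls5 = as.integer(rep_len(ls5, n)),
                   hs5 = as.integer(rep_len(hs5, n)),
                   wraps = rep_len(as.logical(wraps), n))
  if (any(!df$wraps & df$ls5 > df$hs5))
    stop("non-wrapping spans require ls5 <= hs5")
  df
}

validate_span <- function(span, ref) {
  if (any(span$ls5 < 1L | span$ls5 > ref$length |
          span$hs5 < 1L | span$hs5 > ref$length))
    stop("span positions outside [1, ", ref$length, "]")
  invisible(span)
}

#' Number of deleted bases of a span
#'
#' Both termini are inclusive ("last missing bases"), so the common
#' deletion (8471, 13447) spans 4977 bp.
#'
#' @param span A span data.frame from [deletion_span()].
#' @param ref A [circular_reference()].
#' @return Integer vector of deleted lengths in `[1, L_u - 1]`.
#' @export
span_length <- function(span, ref) {
  validate_span(span, ref)
  L <- ref$length
  ifelse(span$wraps,
         L - span$ls5 + span$hs5 + 1L,
         span$hs5 - span$ls5 + 1L)
}

## circular containment: does the deleted arc of `span` cover position p?
span_covers <- function(span, p, ref) {
  ifelse(span$wraps,
         p >= span$ls5 | p <= span$hs5,
         p >= span$ls5 & p <= span$hs5)
}

## ---- feature map ---------------------------------------------------------

FEATURE_CATEGORIES <- c("origin", "control_region", "gene", "tRNA", "rRNA",
                        "promoter", "terminator", "arc")

#' Construct a feature map for a circular reference
#'
#' @param features data.frame with columns `name`, `start`, `end`,
#'   `category` (1-based inclusive; `start > end` denotes a feature that
#'   wraps position 1).
#' @param oriL_pos Position of the light-strand replication origin.
#' @param sevenS3_pos Position of the 7S-DNA 3' terminus (heavy-strand
#'   origin region).
#' @param ref Optional [circular_reference()] used to bounds-check.
#' @return A `feature_map`: the feature data.frame with attributes
#'   `oriL_pos` and `sevenS3_pos`.
#' @export
feature_map <- function(features, oriL_pos = 5780L, sevenS3_pos = 16070L,
                        ref = NULL) {
  stopifnot(all(c("name", "start", "end", "category") %in% names(features)))
  bad <- setdiff(unique(features$category), FEATURE_CATEGORIES)
  if (length(bad))
    stop("unknown feature categories: ", paste(bad, collapse = ", "))
  if (!is.null(ref) &&
      any(features$start < 1L | features$end < 1L |
          features$start > ref$length | features$end > ref$length))
    stop("feature coordinates outside [1, L_u]")
  for (p in c(oriL_pos, sevenS3_pos)) {
    ori <- features[features$category == "origin", , drop = FALSE]
    inside <- ifelse(ori$start <= ori$end,
                     p >= ori$start & p <= ori$end,
                     p >= ori$start | p <= ori$end)
    if (sum(inside) != 1L)
      stop("origin position ", p,
           " must lie in exactly one annotated origin feature")
  }
  structure(features, oriL_pos = as.integer(oriL_pos),
            sevenS3_pos = as.integer(sevenS3_pos),
            class = c("feature_map", "data.frame"))
}

#' Read a feature map from a BED-like tab-separated file
#'
#' Expected columns (with header): `name`, `start`, `end`, `category`,
#' 1-based inclusive coordinates.
#'
#' @inheritParams feature_map
#' @param path Path to the TSV file.
#' @export
read_feature_map <- function(path, oriL_pos = 5780L, sevenS3_pos = 16070L,
                             ref = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  feature_map(df, oriL_pos = oriL_pos, sevenS3_pos = sevenS3_pos, ref = ref)
}

#' Bundled default feature map for the synthetic mtDNA reference
#' @export
default_feature_map <- function() {
  read_feature_map(system.file("extdata", "mtDNA_features.tsv",
                               package = "mitoarc", mustWork = TRUE))
}

#' Classify a deletion span by the arc of the genome it removes
#'
#' The two replication origins (oriL and the 7S-DNA 3' terminus) divide
#' the circle into the minor arc (through position 1 / the control region)
#' and the major arc.  A deletion is `major` or `minor` if its deleted arc
#' lies strictly inside the respective arc without touching either origin,
#' `origin_spanning` if it covers either origin position, and
#' `control_spanning` if it crosses position 1 without covering an origin.
#'
#' @param span Span data.frame ([deletion_span()]).
#' @param fmap A [feature_map()].
#' @param ref A [circular_reference()].
#' @return Character vector in
#'   `{minor, major, origin_spanning, control_spanning}`.
#' @export
arc_class <- function(span, fmap, ref) {
  validate_span(span, ref)
  oriL <- attr(fmap, "oriL_pos")
  s7 <- attr(fmap, "sevenS3_pos")
  cov_o <- span_covers(span, oriL, ref) | span_covers(span, s7, ref)
  out <- rep("origin_spanning", nrow(span))
  # major arc runs from oriL to 7S-3' not crossing position 1 (oriL < s7)
  major <- !cov_o & !span$wraps & span$ls5 > oriL & span$hs5 < s7
  out[major] <- "major"
  ctrl <- !cov_o & span$wraps
  out[ctrl] <- "control_spanning"
  minor <- !cov_o & !major & !ctrl
  out[minor] <- "minor"
  out
}

## circular substring indexing: base at circular position p (vectorized)
ref_base <- function(ref, p) {
  p <- ((as.integer(p) - 1L) %% ref$length) + 1L
  substring(ref$seq, p, p)
}
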