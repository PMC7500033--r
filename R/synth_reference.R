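## Synthetic stand-in for the human mitochondrial reference sequence.
## Generated, not biological: same length (16,571 bp) and approximate base
## composition as human mtDNA, with the sequence landmarks the package's
## coordinate/context arithmetic depends on implanted at their human
## positions.

#' Generate the synthetic human-mtDNA-like reference sequence
#'
#' Produces a deterministic 16,571-bp random DNA sequence (fixed internal
#' RNG stream, independent of the caller's RNG state) with:
#' * a 13-bp direct repeat at positions 8471-8483 and 13448-13460, so the
#'   common deletion (8471, 13447) is flanked by 13 identical bases and is
#'   stable under left-alignment;
#' * poly-C tracts at positions 303 and 16,184 (control-region
#'   homopolymer runs whose contractions dominate real samples);
#' * guard bases ensuring the common-deletion terminal microhomology is
#'   exactly 13 bp.
#'
#' This is a synthetic stand-in for GenBank AF347015.1 (chrM), suitable
#' for exercising circular-coordinate, alignment, and sequence-context
#' logic; it carries no human genetic information.
#'
#' @param length Genome length (default 16,571 bp).
#' @return Character scalar DNA sequence.
#' @export
synthetic_mt_sequence <- function(length = 16571L) {
  stopifnot(length >= 16500L)
  rng <- local_rng(20200917L)
  on.exit(rng())
  # approximate human mtDNA (heavy-strand reference) base composition
  base <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c(0.309, 0.313, 0.131, 0.247))
  put <- function(x, at, s) {
    x[at:(at + nchar(s) - 1L)] <- strsplit(s, "")[[1L]]
    x
  }
  # control-region poly-C tracts (positions 303 and 16,184)
  base <- put(base, 303L, "CCCCCCCC")
  base <- put(base, 16184L, "CCCCCCCCC")
  # 13-bp direct repeat flanking the common deletion
  rep13 <- "ACCTCCCTCACCA"
  base <- put(base, 8471L, rep13)
  base <- put(base, 13448L, rep13)
  # guards: terminal microhomology of (8471, 13447) must stop at 13 bp
  alt <- function(b) c(A = "G", C = "T", G = "A", T = "C")[[b]]
  if (base[8470L] == base[13447L]) base[13447L] <- alt(base[13447L])
  if (base[8484L] == base[13461L]) base[13461L] <- alt(base[13461L])
  paste(base, collapse = "")
}

## run code under a private RNG stream, restoring the caller's state
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write the bundled synthetic reference and feature map
#'
#' Regenerates the package's `inst/extdata` fixtures (used at build time;
#' exported for reproducibility).
#'
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_bundled_data <- function(dir) {
  seq <- synthetic_mt_sequence()
  fa <- file.path(dir, "synthetic_mtDNA_ref.fasta")
  ss <- Biostrings::DNAStringSet(setNames(seq, "synthetic_mtDNA"))
  Biostrings::writeXStringSet(ss, fa, width = 70L)
  ft <- file.path(dir, "mtDNA_features.tsv")
  write.table(default_feature_table(), ft, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fa, ft))
}

## Feature coordinates follow the standard human mtDNA annotation layout
## (gene order and approximate positions); adequate for feature-set
## ablation arithmetic on the synthetic reference.
default_feature_table <- function() {
  tab <- rbind(
    c("control_region", 16024, 575, "control_region"),
    c("oriL",           5721,  5798, "origin"),
    c("7S_3prime",      16024, 16106, "origin"),
    c("minor_arc",      16071, 5779, "arc"),
    c("major_arc",      5781,  16069, "arc"),
    c("PL_promoter",    392,   445,  "promoter"),
    c("PH_promoter",    545,   567,  "promoter"),
    c("RNR1",           648,   1601, "rRNA"),
    c("RNR2",           1671,  3229, "rRNA"),
    c("TERM_L1",        3230,  3256, "terminator"),
    c("TF",             577,   647,  "tRNA"),
    c("TV",             1602,  1670, "tRNA"),
    c("TL1",            3257,  3304, "tRNA"),
    c("ND1",            3307,  4262, "gene"),
    c("ND2",            4470,  5511, "gene"),
    c("CO1",            5904,  7445, "gene"),
    c("CO2",            7586,  8269, "gene"),
    c("TK",             8295,  8364, "tRNA"),
    c("ATP8",           8366,  8572, "gene"),
    c("ATP6",           8527,  9207, "gene"),
    c("CO3",            9208,  9990, "gene"),
    c("ND3",            10059, 10404, "gene"),
    c("ND4L",           10470, 10766, "gene"),
    c("ND4",            10767, 12137, "gene"),
    c("TH",             12138, 12206, "tRNA"),
    c("TS2",            12207, 12265, "tRNA"),
    c("TL2",            12266, 12336, "tRNA"),
    c("ND5",            12337, 14148, "gene"),
    c("ND6",            14149, 14673, "gene"),
    c("TE",             14674, 14742, "tRNA"),
    c("CYB",            14747, 15887, "gene"),
    c("TT",             15888, 15953, "tRNA"),
    c("TP",             15956, 16023, "tRNA"))
  data.frame(name = tab[, 1], start = as.integer(tab[, 2]),
             end = as.integer(tab[, 3]), category = tab[, 4],
             stringsAsFactors = FALSE)
}
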