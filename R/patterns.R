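## Deletion-pattern summaries: binned breakpoint matrices, hierarchical
## clustering, PCA, length spectra, and LS5'/HS5' terminus histograms.

T_REGION <- list(
  # age-independent artifact zones excluded from pattern analysis:
  # ls5-range x hs5-range pairs
  list(ls5 = c(1L, 5700L), hs5 = c(15949L, 16156L)),
  list(ls5 = c(3107L, 3314L), hs5 = c(12000L, 16156L)))

in_t_region <- function(ls5, hs5, regions = T_REGION) {
  hit <- rep(FALSE, length(ls5))
  for (r in regions)
    hit <- hit | (ls5 >= r$ls5[1] & ls5 <= r$ls5[2] &
                  hs5 >= r$hs5[1] & hs5 <= r$hs5[2])
  hit
}

genome_bin <- function(pos, L, n_bins) {
  w <- L %/% n_bins
  pmin((as.integer(pos) - 1L) %/% w + 1L, n_bins)
}

#' Binned breakpoint matrix of a sample
#'
#' Bins breakpoints into an `n_bins` x `n_bins` grid by (LS5'-bin,
#' HS5'-bin) after excluding (a) spans whose termini are within
#' `min_span` bp (suspect small-indel artifacts) and (b) spans in the
#' T-shaped artifact region of the terminus plane.  The matrix is
#' normalized by the total binned breakpoint weight.
#'
#' @param x A `deletion_catalog` or `frequency_table`.
#' @param ref A [circular_reference()].
#' @param use `"counts"` (weight = supporting reads `x_i`; default, as
#'   pattern analyses use deletion fractions rather than population
#'   frequencies) or `"frequencies"` (weight = `f_i_bg`).
#' @param n_bins Grid size per axis (default 80).
#' @param min_span Exclusion threshold on deleted length (default 40 bp).
#' @param t_region Exclusion zones; a list of `ls5`/`hs5` range pairs
#'   (set to `list()` to disable; configurable for other references).
#' @return A `pattern_matrix`: list with `bins` (matrix, entries sum to 1
#'   when any breakpoint survives), `sample_id`, `excluded_mass`.
#' @export
bin_breakpoints <- function(x, ref, use = c("counts", "frequencies"),
                            n_bins = 80L, min_span = 40L,
                            t_region = T_REGION) {
  use <- match.arg(use)
  if (inherits(x, "deletion_catalog")) {
    tab <- x$calls
    w <- tab$x_i
    if (use == "frequencies")
      stop("frequency weighting requires a frequency_table")
    sid <- x$sample_id
  } else {
    tab <- x$table
    w <- if (use == "counts") tab$x_i else tab$f_i_bg
    sid <- x$sample_id
  }
  keep <- rep(TRUE, nrow(tab))
  if (nrow(tab)) {
    keep <- tab$length >= min_span & !in_t_region(tab$ls5, tab$hs5, t_region)
  }
  total <- sum(w)
  bins <- matrix(0, n_bins, n_bins)
  if (any(keep) && sum(w[keep]) > 0) {
    bi <- genome_bin(tab$ls5[keep], ref$length, n_bins)
    bj <- genome_bin(tab$hs5[keep], ref$length, n_bins)
    for (i in seq_along(bi)) bins[bi[i], bj[i]] <- bins[bi[i], bj[i]] + w[keep][i]
    bins <- bins / sum(bins)
  } else {
    warning("no breakpoints survive pattern filtering; all-zero matrix")
  }
  structure(list(bins = bins, sample_id = sid,
                 excluded_mass = if (total > 0) 1 - sum(w[keep]) / total else 0),
            class = "pattern_matrix")
}

flatten_matrices <- function(matrices) {
  ids <- vapply(matrices, `[[`, "", "sample_id")
  o <- order(ids)
  m <- t(vapply(matrices[o], function(p) as.numeric(p$bins),
                numeric(length(matrices[[1]]$bins))))
  rownames(m) <- ids[o]
  m
}

#' Complete-linkage hierarchical clustering of sample deletion patterns
#'
#' Flattens each sample's breakpoint matrix to a vector and clusters
#' samples by Euclidean distance with complete linkage.  Samples are
#' ordered by id before clustering, so the result does not depend on
#' input order.
#'
#' @param matrices List of `pattern_matrix` objects (>= 2).
#' @return List: `hclust` (the tree), `newick` (Newick string via
#'   [ape::as.phylo()]), `merge_heights`.
#' @export
cluster_samples <- function(matrices) {
  if (length(matrices) < 2L) stop("clustering requires at least 2 samples")
  m <- flatten_matrices(matrices)
  hc <- hclust(dist(m, method = "euclidean"), method = "complete")
  list(hclust = hc,
       newick = ape::write.tree(ape::as.phylo(hc)),
       merge_heights = hc$height)
}

#' Principal component analysis of sample deletion patterns
#'
#' Mean-centered (unscaled: inputs are already normalized fractions on a
#' common scale) PCA of the flattened breakpoint matrices.
#'
#' @param matrices List of `pattern_matrix` objects
#'   (>= `n_components + 1`).
#' @param n_components Number of components retained (default 3).
#' @return List: `weights` (list of component weight matrices reshaped to
#'   the bin grid, unit norm), `scores` (samples x components),
#'   `sdev` (component standard deviations).
#' @export
pca_patterns <- function(matrices, n_components = 3L) {
  if (length(matrices) < n_components + 1L)
    stop("PCA requires at least n_components + 1 samples")
  m <- flatten_matrices(matrices)
  if (all(apply(m, 2, sd) == 0))
    stop("zero-variance input: all sample patterns identical")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  nb <- nrow(matrices[[1]]$bins)
  weights <- lapply(seq_len(k), function(j)
    matrix(pc$rotation[, j], nb, nb))
  list(weights = weights,
       scores = pc$x[, seq_len(k), drop = FALSE],
       sdev = pc$sdev[seq_len(k)])
}

#' Deletion length spectrum
#'
#' Sums background-subtracted frequencies by deleted-length bin.
#'
#' @param freqs A `frequency_table`.
#' @param bin_bp Bin width in bp (1 or 400 are the conventional choices).
#' @return List: `breaks` (bin lower edges), `freq` (summed frequency per
#'   bin), `possible_insertion_mass` (frequency in the > 15 kbp tail,
#'   where junctions are indistinguishable from insertions).
#' @export
length_spectrum <- function(freqs, bin_bp = 400L) {
  tab <- freqs$table
  n_bins <- ceiling(freqs$L_u / bin_bp)
  freq <- numeric(n_bins)
  if (nrow(tab)) {
    b <- pmin((tab$length - 1L) %/% bin_bp + 1L, n_bins)
    agg <- tapply(tab$f_i_bg, b, sum)
    freq[as.integer(names(agg))] <- agg
  }
  list(breaks = (seq_len(n_bins) - 1L) * bin_bp + 1L, freq = freq,
       possible_insertion_mass = sum(tab$f_i_bg[tab$length > POSSIBLE_INSERTION_BP]))
}

#' LS5'/HS5' terminus-frequency histograms (the "double bowtie")
#'
#' Sums weights of LS5' and HS5' terminus positions separately into
#' genome bins, excluding deletions with extensive terminal microhomology
#' (default TMH > 9 bp, which belong to the slippage-like class rather
#' than the replication-fountain pattern).
#'
#' @param freqs A `frequency_table`.
#' @param annotations Output of [annotate_context()]; required when
#'   `tmh_max` is finite.
#' @param bin_bp Bin width (default 250 bp).
#' @param tmh_max Maximum TMH retained (default 9).
#' @return A `terminus_histogram`: list with `breaks`, `ls5_freq`,
#'   `hs5_freq`, `bin_size`.
#' @export
terminus_histogram <- function(freqs, annotations = NULL, bin_bp = 250L,
                               tmh_max = 9L) {
  tab <- freqs$table
  keep <- rep(TRUE, nrow(tab))
  if (is.finite(tmh_max) && nrow(tab)) {
    if (is.null(annotations))
      stop("annotations required to filter on TMH")
    m <- match(paste(tab$ls5, tab$hs5),
               paste(annotations$ls5, annotations$hs5))
    if (anyNA(m)) stop("annotations do not cover all frequency-table rows")
    keep <- annotations$tmh[m] <= tmh_max
  }
  terminus_histogram_spans(tab$ls5[keep], tab$hs5[keep], tab$f_i_bg[keep],
                           freqs$L_u, bin_bp)
}

## shared binning core (also used for simulated deletion sets)
terminus_histogram_spans <- function(ls5, hs5, weight, L, bin_bp = 250L) {
  n_bins <- ceiling(L / bin_bp)
  bin_of <- function(p) pmin((as.integer(p) - 1L) %/% bin_bp + 1L, n_bins)
  acc <- function(p) {
    v <- numeric(n_bins)
    if (length(p)) {
      agg <- tapply(weight, bin_of(p), sum)
      v[as.integer(names(agg))] <- agg
    }
    v
  }
  structure(list(breaks = (seq_len(n_bins) - 1L) * bin_bp + 1L,
                 ls5_freq = acc(ls5), hs5_freq = acc(hs5),
                 bin_size = bin_bp),
            class = "terminus_histogram")
}

#' Write pattern artifacts (matrix, histograms, spectra) as TSV
#'
#' @param pm A `pattern_matrix`.
#' @param th A `terminus_histogram` (optional).
#' @param ls A length spectrum from [length_spectrum()] (optional).
#' @param dir Output directory.
#' @return Invisibly, paths written.
#' @export
write_patterns <- function(pm, th = NULL, ls = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  long <- data.frame(ls5_bin = rep(seq_len(nrow(pm$bins)), ncol(pm$bins)),
                     hs5_bin = rep(seq_len(ncol(pm$bins)),
                                   each = nrow(pm$bins)),
                     fraction = as.numeric(pm$bins))
  p <- file.path(dir, "pattern_matrix.tsv")
  write.table(long[long$fraction > 0, ], p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(th)) {
    p <- file.path(dir, "terminus_histogram.tsv")
    write.table(data.frame(bin_start = th$breaks, ls5 = th$ls5_freq,
                           hs5 = th$hs5_freq),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(ls)) {
    p <- file.path(dir, "length_spectrum.tsv")
    write.table(data.frame(length_bin_start = ls$breaks, freq = ls$freq),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
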