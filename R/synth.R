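## Synthetic sequencing data with known ground truth.
##
## Emulates a heteroplasmic population of circular genomes: a dominant
## wild-type species plus deletant species at specified frequencies,
## optional plasmid-like spike-ins with known junctions, and uniform
## fragment sampling proportional to molecule abundance and length.

#' Specify a synthetic mtDNA population and sequencing run
#'
#' @param ref A [circular_reference()].
#' @param species data.frame with columns `ls5`, `hs5` (and optionally
#'   `wraps`) and `frequency`; one row per deletant species.  Frequencies
#'   must sum to < 1; the remainder is wild type.
#' @param spikeins Optional data.frame with columns `sequence` (a
#'   plasmid-like circular molecule carrying an internal junction) and
#'   `frequency`.
#' @param error_rate Per-base substitution probability.
#' @param read_length Read length (bp).
#' @param fragment_mean,fragment_sd Fragment size distribution (bp),
#'   truncated below at `read_length`.
#' @param depth Target mean coverage of the reference.
#' @param strict_junction_window In the strict test profile, no
#'   substitution errors are placed within this many bp of a deletion
#'   junction inside a read (isolates pipeline logic from error
#'   modelling); set to 0 for the realistic profile.
#' @param seed RNG seed.
#' @return A `population_spec` list.
#' @export
population_spec <- function(ref, species = NULL, spikeins = NULL,
                            error_rate = 0.002, read_length = 150L,
                            fragment_mean = 350, fragment_sd = 50,
                            depth = 2000, strict_junction_window = 5L,
                            seed = 1L) {
  if (is.null(species))
    species <- data.frame(ls5 = integer(), hs5 = integer(),
                          frequency = numeric())
  if (!"wraps" %in% names(species))
    species$wraps <- species$ls5 > species$hs5
  tot <- sum(species$frequency) +
    if (is.null(spikeins)) 0 else sum(spikeins$frequency)
  if (any(species$frequency < 0) || tot > 1)
    stop("species frequencies must be >= 0 and sum to <= 1")
  structure(list(ref = ref, species = species, spikeins = spikeins,
                 error_rate = error_rate,
                 read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 depth = depth,
                 strict_junction_window = as.integer(strict_junction_window),
                 seed = as.integer(seed)),
            class = "population_spec")
}

delete_from_reference <- function(ref, ls5, hs5, wraps) {
  L <- ref$length
  if (!wraps) {
    paste0(substr(ref$seq, 1L, ls5 - 1L), substr(ref$seq, hs5 + 1L, L))
  } else {
    substr(ref$seq, hs5 + 1L, ls5 - 1L)
  }
}

#' Build the molecule set of a population
#'
#' @param spec A [population_spec()].
#' @return data.frame with one row per molecular species: `id`, `type`,
#'   `sequence`, `length`, `weight`, `junction_at` (0-based molecule
#'   coordinate of the last base before the junction; `NA` for wild
#'   type), `ls5`, `hs5`.
#' @export
build_population <- function(spec) {
  ref <- spec$ref
  rows <- list()
  wt_w <- 1 - sum(spec$species$frequency) -
    if (is.null(spec$spikeins)) 0 else sum(spec$spikeins$frequency)
  rows[[1]] <- data.frame(id = "wt", type = "wildtype", sequence = ref$seq,
                          length = ref$length, weight = wt_w,
                          junction_at = NA_integer_,
                          ls5 = NA_integer_, hs5 = NA_integer_)
  for (i in seq_len(nrow(spec$species))) {
    s <- spec$species[i, ]
    sq <- delete_from_reference(ref, s$ls5, s$hs5, s$wraps)
    # junction sits after molecule base (ls5 - 1) for non-wrapping spans,
    # and at the sequence end for wrapping spans
    j <- if (!s$wraps) s$ls5 - 1L else nchar(sq)
    rows[[length(rows) + 1L]] <-
      data.frame(id = sprintf("del_%d_%d", s$ls5, s$hs5), type = "deletant",
                 sequence = sq, length = nchar(sq), weight = s$frequency,
                 junction_at = j, ls5 = s$ls5, hs5 = s$hs5)
  }
  if (!is.null(spec$spikeins)) {
    for (i in seq_len(nrow(spec$spikeins))) {
      s <- spec$spikeins[i, ]
      rows[[length(rows) + 1L]] <-
        data.frame(id = sprintf("spike_%d", i), type = "spikein",
                   sequence = s$sequence, length = nchar(s$sequence),
                   weight = s$frequency, junction_at = NA_integer_,
                   ls5 = NA_integer_, hs5 = NA_integer_)
    }
  }
  pop <- do.call(rbind, rows)
  if (abs(sum(pop$weight) - 1) > 1e-9) stop("population weights must sum to 1")
  pop
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

apply_errors <- function(seqs, rate, protect_at = NULL, window = 0L) {
  if (rate <= 0) return(seqs)
  n <- length(seqs)
  L <- nchar(seqs[1])
  k <- rbinom(n, L, rate)
  idx <- which(k > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(L, k[i])
    if (!is.null(protect_at) && !is.na(protect_at[i]) && window > 0L)
      pos <- pos[abs(pos - protect_at[i]) > window &
                 abs(pos - protect_at[i] - 1L) > window]
    if (!length(pos)) next
    ch <- strsplit(seqs[i], "")[[1L]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Generate paired-end reads from a population
#'
#' Fragments are drawn with probability proportional to species weight
#' times molecule length, with uniformly random start positions on the
#' circular molecule; paired reads are taken from the fragment ends
#' (mate 2 reverse-complemented).  Substitution errors are applied at
#' `error_rate`, sparing the junction neighbourhood in the strict
#' profile.  Deterministic per seed.
#'
#' @param spec A [population_spec()].
#' @param fq1,fq2 Output FASTQ paths (`.gz` supported).
#' @param population Optional pre-built population
#'   ([build_population()]).
#' @return Invisibly, a list with `truth` (data.frame of every
#'   junction-spanning read: `read_id`, `mate`, `ls5`, `hs5`,
#'   `junction_offset` -- bases of the read before the junction),
#'   `n_pairs`, `per_species` (pair counts), `resampled` (fragments
#'   redrawn because they exceeded the molecule length).
#' @export
generate_reads <- function(spec, fq1, fq2, population = NULL) {
  set.seed(spec$seed)
  pop <- if (is.null(population)) build_population(spec) else population
  ref_len <- spec$ref$length
  L_r <- spec$read_length
  n_pairs <- round(spec$depth * ref_len / (2 * L_r))
  alloc <- as.integer(stats::rmultinom(1, n_pairs,
                                       pop$weight * pop$length))
  truth <- list()
  out1 <- character(0); out2 <- character(0); ids <- character(0)
  resampled <- 0L
  for (m in seq_len(nrow(pop))) {
    nm <- alloc[m]
    if (nm == 0L) next
    mol <- pop$sequence[m]
    ml <- pop$length[m]
    mol2 <- paste0(mol, mol)
    if (ml < L_r) stop("molecule shorter than the read length")
    size <- pmax(L_r, round(rnorm(nm, spec$fragment_mean, spec$fragment_sd)))
    bad <- which(size > ml)
    for (attempt in 1:3) {        # redraw fragments longer than the molecule
      if (!length(bad)) break
      resampled <- resampled + length(bad)
      size[bad] <- pmax(L_r, round(rnorm(length(bad), spec$fragment_mean,
                                         spec$fragment_sd)))
      bad <- which(size > ml)
    }
    size <- pmin(size, ml)
    start <- sample.int(ml, nm, replace = TRUE)
    r1 <- substring(mol2, start, start + L_r - 1L)
    r2s <- start + size - L_r
    r2raw <- substring(mol2, r2s, r2s + L_r - 1L)
    id <- sprintf("%s_%d", pop$id[m], seq_len(nm))
    # junction bookkeeping (deletant molecules only)
    j1 <- rep(NA_integer_, nm); j2 <- rep(NA_integer_, nm)
    if (!is.na(pop$junction_at[m])) {
      j <- pop$junction_at[m]   # junction after this molecule base
      off1 <- (j - start + 1L) %% ml   # bases of read before junction
      hit1 <- off1 >= 1L & off1 <= L_r - 1L
      j1[hit1] <- off1[hit1]
      off2m <- (j - r2s + 1L) %% ml
      hit2 <- off2m >= 1L & off2m <= L_r - 1L
      # mate 2 is reverse-complemented: offset counts from the other end
      j2[hit2] <- L_r - off2m[hit2]
      for (w in which(hit1))
        truth[[length(truth) + 1L]] <-
          data.frame(read_id = id[w], mate = 1L, ls5 = pop$ls5[m],
                     hs5 = pop$hs5[m], junction_offset = j1[w])
      for (w in which(hit2))
        truth[[length(truth) + 1L]] <-
          data.frame(read_id = id[w], mate = 2L, ls5 = pop$ls5[m],
                     hs5 = pop$hs5[m], junction_offset = j2[w])
    }
    r2 <- revcomp_chr(r2raw)
    r1 <- apply_errors(r1, spec$error_rate, j1, spec$strict_junction_window)
    r2 <- apply_errors(r2, spec$error_rate, j2, spec$strict_junction_window)
    out1 <- c(out1, r1); out2 <- c(out2, r2); ids <- c(ids, id)
  }
  write_fastq(ids, out1, fq1)
  write_fastq(ids, out2, fq2)
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(read_id = character(), mate = integer(), ls5 = integer(),
               hs5 = integer(), junction_offset = integer())
  invisible(list(truth = truth_df, n_pairs = n_pairs,
                 per_species = setNames(alloc, pop$id),
                 resampled = resampled))
}

write_fastq <- function(ids, seqs, path, qual_char = "I") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (!length(ids)) return(invisible(path))
  qual <- vapply(nchar(seqs), function(n)
    strrep(qual_char, n), "")
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

#' Construct a control-sample catalog and depth profile
#'
#' Emulates a cultured-cell control: a sparse background of low-frequency
#' small deletions (frequencies at or below `max_frequency`, spans below
#' `max_span` bp -- the scale of short-read indel artifacts) over an
#' approximately uniform depth profile.  Returned as a ready-made
#' `deletion_catalog` for mappability factors and background
#' subtraction.
#'
#' @param ref A [circular_reference()].
#' @param n_background Number of background junction species.
#' @param depth Mean control depth.
#' @param read_length Mean read length recorded in the catalog.
#' @param max_frequency Upper bound on background species frequency.
#' @param max_span Upper bound on background span length (bp).
#' @param seed RNG seed.
#' @return A `deletion_catalog` (sample id `"control"`).
#' @export
make_control <- function(ref, n_background = 25L, depth = 1000,
                         read_length = 150, max_frequency = 1e-5,
                         max_span = 99L, seed = 99L) {
  set.seed(seed)
  L <- ref$length
  r_t <- round(depth * L / read_length)
  if (n_background > 0L) {
    ls5 <- sample.int(L - max_span - 1L, n_background)
    len <- sample.int(max_span, n_background, replace = TRUE)
    sp <- left_align(deletion_span(ls5, ls5 + len - 1L), ref)
    key <- !duplicated(paste(sp$ls5, sp$hs5))
    sp <- sp[key, , drop = FALSE]
    f <- runif(nrow(sp), max_frequency / 10, max_frequency)
    # expected supporting reads at this depth; keep at least one
    x <- pmax(1L, rpois_int(f * depth * (read_length - 1) / read_length))
    lenv <- span_length(sp, ref)
    calls <- data.frame(ls5 = sp$ls5, hs5 = sp$hs5, length = lenv,
                        x_i = x, wraps = sp$wraps,
                        possible_insertion = lenv > POSSIBLE_INSERTION_BP)
    calls <- calls[order(calls$ls5, calls$hs5), , drop = FALSE]
    rownames(calls) <- NULL
  } else {
    calls <- empty_calls()
  }
  dp <- pmax(1L, round(rnorm(L, depth, sqrt(depth))))
  new_catalog(calls, as.integer(dp), r_t, read_length, "control")
}

rpois_int <- function(lambda) as.integer(stats::rpois(length(lambda), lambda))
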