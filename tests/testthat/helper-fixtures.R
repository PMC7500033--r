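# Shared fixtures: the bundled reference is loaded once; small ad hoc
# references are built in code.

bundled_ref <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- default_reference()
    ref
  }
})

bundled_fmap <- local({
  fm <- NULL
  function() {
    if (is.null(fm)) fm <<- default_feature_map()
    fm
  }
})

# deterministic random circular reference with optional motif implants
tiny_ref <- function(n = 600L, seed = 4L, implants = list()) {
  withr::with_seed(seed, {
    b <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    for (im in implants) {
      s <- strsplit(im$motif, "")[[1L]]
      b[im$at:(im$at + length(s) - 1L)] <- s
    }
    circular_reference(paste(b, collapse = ""), name = sprintf("tiny%d", seed))
  })
}

# brute-force TMH oracle: maximal k such that some direct repeat of
# length k straddles the junction, computed by direct string comparison
brute_tmh <- function(span, ref, cap = 60L) {
  at <- function(p) substring(ref$seq, ((p - 1L) %% ref$length) + 1L,
                              ((p - 1L) %% ref$length) + 1L)
  r <- 0L
  while (r < cap && at(span$ls5 + r) == at(span$hs5 + 1L + r)) r <- r + 1L
  l <- 0L
  while (l < cap && at(span$ls5 - 1L - l) == at(span$hs5 - l)) l <- l + 1L
  r + l
}

# all ls5 values describing deletions equivalent to `span` (identical
# retained sequence), by exhaustive enumeration: retained bases are
# compared in absolute position order, which is phase-independent
equivalent_reps <- function(span, ref) {
  L <- ref$length
  len <- span_length(span, ref)
  chars <- strsplit(ref$seq, "")[[1L]]
  apply_del <- function(ls5) {
    gone <- ((seq(ls5, length.out = len) - 1L) %% L) + 1L
    paste(chars[-gone], collapse = "")
  }
  target <- apply_del(span$ls5)
  which(vapply(seq_len(L), apply_del, "") == target)
}

fastq_pair_from <- function(reads1, reads2, quals1, quals2, dir = tempdir()) {
  f1 <- tempfile("m1_", fileext = ".fastq", tmpdir = dir)
  f2 <- tempfile("m2_", fileext = ".fastq", tmpdir = dir)
  wr <- function(path, seqs, quals) {
    lines <- if (length(seqs))
      paste0("@r", seq_along(seqs), "\n", seqs, "\n+\n", quals)
    else character(0)
    writeLines(lines, path)
  }
  wr(f1, reads1, quals1)
  wr(f2, reads2, quals2)
  c(f1, f2)
}
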