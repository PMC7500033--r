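ref <- bundled_ref()

read_at <- function(start, len = 150L) {
  # contiguous read from the circular reference
  substr(paste0(ref$seq, ref$seq), start, start + len - 1L)
}

junction_read <- function(ls5, hs5, flank_left = 100L, len = 150L) {
  left <- substr(paste0(ref$seq, ref$seq),
                 ls5 - flank_left, ls5 - 1L)
  right <- substr(paste0(ref$seq, ref$seq), hs5 + 1L,
                  hs5 + (len - flank_left))
  paste0(left, right)
}

test_that("quality filtering drops pairs on mean Phred per mate", {
  q_of <- function(q, n = 60) strrep(intToUtf8(q + 33), n)
  seqs <- c(read_at(100, 60), read_at(400, 60), read_at(700, 60))
  paths <- fastq_pair_from(
    seqs, seqs,
    quals1 = c(q_of(25), q_of(19), q_of(35)),
    quals2 = c(q_of(30), q_of(35), q_of(20)))
  cat_ <- build_catalog(paths[1], paths[2], ref)
  # pair 2 dropped (mate 1 mean Q 19); pairs 1 and 3 kept
  expect_identical(cat_$r_t, 4L)
  # empty input yields an empty catalog with r_t = 0
  empty <- fastq_pair_from(character(), character(), character(), character())
  ecat <- build_catalog(empty[1], empty[2], ref)
  expect_identical(ecat$r_t, 0L)
  expect_identical(nrow(ecat$calls), 0L)
})

test_that("split alignment finds junctions, contiguity, and garbage", {
  sa <- align_split(junction_read(8471, 13447), ref)
  expect_identical(sa$type, "split")
  expect_identical(sa$gap_on_reference, 4977L)
  expect_null(align_split(paste(rep("ACGT", 38), collapse = ""), ref))
  expect_identical(align_split(read_at(100), ref)$type, "contiguous")
  # a read crossing the coordinate origin aligns contiguously on the
  # doubled reference
  expect_identical(align_split(read_at(16500), ref)$type, "contiguous")
})

test_that("junction calls give last-missing-base coordinates", {
  j <- call_junction(align_split(junction_read(8471, 13447), ref), ref)
  expect_identical(left_align(j, ref), deletion_span(8471, 13447))
  j2 <- call_junction(align_split(junction_read(10014, 12405), ref), ref)
  expect_identical(left_align(j2, ref), deletion_span(10014, 12405))
  # junction of a deletion wrapping position 1
  jw <- call_junction(align_split(junction_read(16571 + 16550, 16571 + 30,
                                                flank_left = 75L), ref), ref)
  jw <- left_align(jw, ref)
  expect_identical(span_length(jw, ref), 16571L - 16550L + 30L + 1L)
  expect_true(jw$wraps)
  expect_error(call_junction(align_split(read_at(100), ref), ref),
               "two-anchor")
})

test_that("left alignment returns the unique leftmost representation", {
  # single-base deletion inside the poly-C run: every in-run position is
  # equivalent; the canonical form is the run start
  run_start <- 303L
  while (substr(ref$seq, run_start - 1L, run_start - 1L) == "C")
    run_start <- run_start - 1L
  la <- left_align(deletion_span(306, 306), ref)
  reps <- equivalent_reps(list(ls5 = 306L, hs5 = 306L, wraps = FALSE), ref)
  expect_identical(la$ls5, min(reps))
  expect_identical(la$ls5, run_start)
  # all equivalent representations collapse to one canonical form
  for (p in reps)
    expect_identical(left_align(deletion_span(p, p), ref)$ls5, min(reps))
  # no flanking homology: fixpoint; and left_align is idempotent
  sp <- deletion_span(8471, 13447)
  la1 <- left_align(sp, ref)
  expect_identical(la1, sp)
  expect_identical(left_align(la1, ref), la1)
})

test_that("conflicting mates suppress a junction", {
  jr <- junction_read(8471, 13447)
  far <- read_at(2000)                # contiguous, away from the junction
  spanning <- read_at(8400)           # contiguous across 8470|8471
  q <- strrep("I", 150)
  p1 <- fastq_pair_from(jr, far, q, q)
  c1 <- build_catalog(p1[1], p1[2], ref)
  expect_identical(c1$calls$x_i, 1L)
  p2 <- fastq_pair_from(jr, spanning, q, q)
  c2 <- build_catalog(p2[1], p2[2], ref)
  expect_identical(nrow(c2$calls), 0L)
  # both mates supporting count two reads
  p3 <- fastq_pair_from(jr, junction_read(8471, 13447, flank_left = 60L),
                        q, q)
  c3 <- build_catalog(p3[1], p3[2], ref)
  expect_identical(c3$calls$x_i, 2L)
  expect_identical(c3$calls$ls5, 8471L)
})

test_that("round-trip: synthesized junction reads re-call their span", {
  withr::with_seed(21, {
    for (i in 1:12) {
      ls5 <- sample(500:15500, 1)
      len <- sample(c(2, 15, 120, 2500, 6000), 1)
      hs5 <- ls5 + len - 1L
      if (hs5 > 16571L) next
      fl <- sample(25:120, 1)
      rd <- junction_read(ls5, hs5, flank_left = fl)
      sa <- align_split(rd, ref)
      expect_false(is.null(sa))
      if (sa$type != "split") next  # tiny deletions may be absorbed
      got <- left_align(call_junction(sa, ref), ref)
      want <- left_align(deletion_span(ls5, hs5), ref)
      expect_identical(got, want)
    }
  })
})

test_that("depth accounting conserves aligned bases", {
  q <- strrep("I", 150)
  reads1 <- c(read_at(100), junction_read(8471, 13447))
  reads2 <- c(read_at(600), read_at(2000))
  p <- fastq_pair_from(reads1, reads2, rep(q, 2), rep(q, 2))
  cat_ <- build_catalog(p[1], p[2], ref)
  expect_identical(sum(cat_$depth), as.integer(round(cat_$r_t * cat_$L_r)))
  # split read contributes depth on both retained flanks (junction-side
  # microhomology bases are assigned to the left anchor)
  expect_identical(cat_$depth[8470], 1L)
  expect_identical(cat_$depth[13470], 1L)
  expect_identical(cat_$depth[9000], 0L)
})

test_that("deletion load is junction reads per mapped megabase", {
  cat_ <- structure(list(calls = data.frame(x_i = c(200L, 100L)),
                         r_t = 100000L, L_r = 100),
                    class = "deletion_catalog")
  expect_equal(deletion_load(cat_)$per_mbp, 30)
  expect_equal(deletion_load(cat_)$per_read, 0.003)
  cat0 <- structure(list(calls = data.frame(x_i = integer()),
                         r_t = 10L, L_r = 100), class = "deletion_catalog")
  expect_equal(deletion_load(cat0)$per_mbp, 0)
  cat_$r_t <- 0L
  expect_error(deletion_load(cat_), "undefined")
})

test_that("catalog construction is deterministic and round-trips via TSV", {
  species <- data.frame(ls5 = 8471, hs5 = 13447, frequency = 0.2)
  spec <- population_spec(ref, species, depth = 40, seed = 5)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "x1.fastq"); f2 <- file.path(d, "x2.fastq")
  generate_reads(spec, f1, f2)
  c1 <- build_catalog(f1, f2, ref, sample_id = "s")
  c2 <- build_catalog(f1, f2, ref, sample_id = "s")
  expect_identical(c1, c2)
  write_catalog(c1, file.path(d, "out"))
  c3 <- read_catalog(file.path(d, "out"))
  expect_identical(c3$calls$ls5, c1$calls$ls5)
  expect_identical(c3$calls$x_i, c1$calls$x_i)
  expect_identical(c3$r_t, c1$r_t)
  expect_identical(c3$depth, c1$depth)
})
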