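test_that("reads are assigned to the amplicon with the largest overlap", {
  amp <- data.frame(
    amplicon_id = c("a", "b", "c"),
    chrom = c("chr17", "chr17", "chr17"),
    start = c(90L, 200L, 400L), end = c(260L, 320L, 470L),
    stringsAsFactors = FALSE
  )
  reads <- data.frame(
    read_id = c("r1", "r2", "r3"),
    sample_id = "s", chrom = c("chr17", "chr17", "chr2"),
    pos = c(101L, 161L, 101L), mapq = 60L, flag = 0L,
    cigar = c("150M", "150M", "150M"), seq = "N", nm = 0L,
    stringsAsFactors = FALSE
  )
  reads <- tamseqbf:::.finish_reads(reads)
  out <- assign_to_amplicon(reads, amp)
  # r1 [100,250) is contained in a
  expect_identical(out$amplicon_id[1], "a")
  # r2 [160,310): 100 bp in a, 110 bp in b
  expect_identical(out$amplicon_id[2], "b")
  expect_identical(out$overlap_bp[2], 110L)
  # r3 sits on a chromosome with no amplicons
  expect_true(is.na(out$amplicon_id[3]))

  # exact tie: lower start wins, then lexicographic id
  amp_tie <- data.frame(amplicon_id = c("z", "y"), chrom = "chr17",
                        start = c(100L, 100L), end = c(200L, 200L),
                        stringsAsFactors = FALSE)
  r <- tamseqbf:::.finish_reads(data.frame(
    read_id = "t", sample_id = "s", chrom = "chr17", pos = 121L, mapq = 60L,
    flag = 0L, cigar = "50M", seq = "N", nm = 0L, stringsAsFactors = FALSE))
  expect_identical(assign_to_amplicon(r, amp_tie)$amplicon_id, "y")
})

test_that("filter boundaries are inclusive exactly as published", {
  amp <- toy_amplicons()
  specs <- data.frame(
    amplicon_id = c("amp60", "amp100", "amp100", "amp100", "amp100"),
    alignment_length = c(74, 75, 151, 151, 151),
    overlap = c(1.0, 0.75, 0.75, 0.90, 0.74),
    nm = c(0, 2, 2, 3, 0)
  )
  rs <- simulate_read_set(amp, specs)
  out <- passes_filters(rs$reads, amp)
  # 74 bp full-overlap read fails only the alignment-length rule
  expect_false(out$pass_filters[1])
  expect_identical(out$fail_reasons[1], "min_align_len")
  # 75 bp / 75% / NM 2 are all inclusive boundaries
  expect_true(out$pass_filters[2])
  expect_true(out$pass_filters[3])
  # NM 3 fails only the edit-distance rule
  expect_false(out$pass_filters[4])
  expect_identical(out$fail_reasons[4], "edit_distance")
  # 74% overlap fails the overlap rule
  expect_false(out$pass_filters[5])
  expect_identical(out$fail_reasons[5], "min_overlap")
  # generator's expectation record agrees with the filter stage
  expect_identical(out$pass_filters, rs$expectations$expected_pass)

  rs$reads$nm[2] <- NA
  expect_error(passes_filters(rs$reads, amp), "NM")
})

test_that("relaxing any threshold never shrinks the passing set", {
  amp <- toy_amplicons()
  set.seed(23)
  specs <- data.frame(
    amplicon_id = "amp100",
    alignment_length = sample(60:160, 40, replace = TRUE),
    overlap = round(runif(40, 0.5, 1), 2),
    nm = sample(0:5, 40, replace = TRUE)
  )
  specs$overlap <- pmin(specs$overlap, specs$alignment_length / 100)
  rs <- simulate_read_set(amp, specs)
  strict <- passes_filters(rs$reads, amp)$pass_filters
  for (relax in list(c(60, 0.75, 2), c(75, 0.5, 2), c(75, 0.75, 5))) {
    loose <- passes_filters(rs$reads, amp, min_align_len = relax[1],
                            min_overlap = relax[2], max_nm = relax[3])$pass_filters
    expect_true(all(loose[strict]))
  }
})

test_that("allele counting tallies the base aligned opposite each locus", {
  amp <- toy_amplicons()
  pos <- 1050L
  ref <- tamseqbf:::.ref_base(pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  specs <- data.frame(
    amplicon_id = "amp100", alignment_length = 100, overlap = 1.0,
    nm = c(rep(0, 6), rep(1, 2)),
    call_pos = pos, call_base = c(rep(ref, 6), rep(alt, 2))
  )
  rs <- simulate_read_set(amp, specs)
  loci <- data.frame(chrom = "chr17", pos = pos, ref = ref,
                     stringsAsFactors = FALSE)
  counts <- count_alleles(rs$reads, loci, amp)
  expect_identical(counts[[paste0("count_", ref)]], 6L)
  expect_identical(counts[[paste0("count_", alt)]], 2L)
  expect_identical(counts$depth, 8L)

  # a read whose aligned span ends before the locus contributes nothing
  short <- simulate_read_set(amp, data.frame(
    amplicon_id = "amp100", alignment_length = 80, overlap = 0.4, nm = 0))
  expect_lt(max(short$reads$align_end), pos)
  counts2 <- count_alleles(rbind(rs$reads, short$reads), loci, amp)
  expect_identical(counts2$depth, 8L)

  # a deletion spanning the locus is not counted
  del <- rs$reads[1, ]
  del$cigar <- "45M10D45M"  # deletion covers positions 1046..1055
  del$seq <- paste(rep("A", 90), collapse = "")
  del <- tamseqbf:::.finish_reads(del)
  expect_identical(count_alleles(del, loci, amp)$depth, 0L)

  expect_error(
    count_alleles(rs$reads, data.frame(chrom = "chr17", pos = 5L, ref = "A"),
                  amp),
    "outside")
})

test_that("SAM and TSV dialects of the same fixture give identical counts", {
  amp <- toy_amplicons()
  pos <- 1020L
  ref <- tamseqbf:::.ref_base(pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[2]
  specs <- data.frame(
    amplicon_id = "amp100", alignment_length = c(100, 90, 80, 74, 100),
    overlap = c(1, 0.8, 0.76, 0.74, 0.9),
    nm = c(0, 1, 2, 0, 3),
    call_pos = pos, call_base = c(ref, alt, ref, ref, ref)
  )
  rs <- simulate_read_set(amp, specs)
  sam <- tempfile(fileext = ".sam")
  tsv <- tempfile(fileext = ".tsv")
  write_sam(rs$reads, sam)
  write_reads_tsv(rs$reads, tsv)
  loci <- data.frame(chrom = "chr17", pos = pos, ref = ref,
                     stringsAsFactors = FALSE)
  from_sam <- filter_count(read_aligned_reads(sam), amp, loci)
  from_tsv <- filter_count(read_aligned_reads(tsv), amp, loci)
  expect_identical(from_sam[names(from_sam)], from_tsv[names(from_tsv)])
  lg <- attr(from_sam, "log")
  expect_identical(lg$reads_in, 5L)
  expect_identical(lg$passed, 3L)
})

test_that("unmapped and MAPQ-0 reads are dropped before filtering", {
  amp <- toy_amplicons()
  rs <- simulate_read_set(amp, data.frame(
    amplicon_id = "amp100", alignment_length = c(100, 100, 100),
    overlap = 1, nm = 0))
  rs$reads$flag[2] <- 4L
  rs$reads$mapq[3] <- 0L
  pos <- 1050L
  loci <- data.frame(chrom = "chr17", pos = pos,
                     ref = tamseqbf:::.ref_base(pos), stringsAsFactors = FALSE)
  out <- filter_count(rs$reads, amp, loci)
  expect_identical(attr(out, "log")$dropped_unmapped_or_mapq0, 2L)
  expect_identical(out$depth, 1L)
})

test_that("geometrically impossible read specs are rejected", {
  amp <- toy_amplicons()
  expect_error(
    simulate_read_set(amp, data.frame(amplicon_id = "amp100",
                                      alignment_length = 74, overlap = 0.80,
                                      nm = 0)),
    "impossible")
  expect_error(
    simulate_read_set(amp, data.frame(amplicon_id = "nope",
                                      alignment_length = 100, overlap = 0.8,
                                      nm = 0)),
    "unknown amplicon")
})
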