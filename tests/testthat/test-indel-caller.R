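test_that("insert-size filter uses open interval bounds", {
  contigs <- c(c1 = 10000L)
  mk <- function(q, tl) mk_pair(q, "c1", 1000, tl, rl = 10L)
  r <- mk_reads(mk("in300", 300), mk("at500", 500), mk("at50", 50),
                mk("at49", 49), mk("at499", 499), mk("at51", 51),
                contigs = contigs)
  kept <- filter_by_insert(r)
  expect_setequal(unique(kept$qname), c("in300", "at499", "at51"))
})

test_that("indel candidates need minimum read support", {
  contigs <- c(c1 = 1000L)
  refstr <- strrep("ACGT", 250)
  ref <- c(c1 = refstr)
  # 6 reads with the same 2 bp deletion at ref 501-502
  del_reads <- rbindlist(lapply(1:6, function(i)
    new_read(paste0("d", i), "c1", 481L,
             paste0(substr(refstr, 481, 500), substr(refstr, 503, 512)),
             cigar = "20M2D10M")))
  one <- new_read("solo", "c1", 431L,
                  paste0(substr(refstr, 431, 450), substr(refstr, 453, 462)),
                  cigar = "20M2D10M")
  r <- mk_reads(del_reads, one, contigs = contigs)
  cand <- discover_indel_candidates(r, ref, min_support = 2L)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$supporting_reads, 6L)
  expect_equal(cand$kind, "deletion")
  expect_equal(nchar(cand$sequence), 2L)
  # the singleton is below min_support
  expect_false(any(cand$start == 451L))
})

test_that("indels are reported at their leftmost equivalent position", {
  # reference with an A-run: deletion of one A anywhere in the run
  # normalizes to the run start
  refstr <- paste0(strrep("C", 10), strrep("A", 6), strrep("G", 10))
  # delete the A at position 14 (inside the run starting at 11)
  norm <- left_normalize_indel(refstr, 14L, "deletion", "A")
  expect_equal(norm$pos, 11L)
  expect_equal(norm$sequence, "A")
  # oracle: shifting left while the preceding base matches
  p <- 14L
  while (p > 1 && substr(refstr, p - 1, p - 1) == substr(refstr, p, p))
    p <- p - 1L
  expect_equal(norm$pos, p)

  # insertion of "A" after any base of the run anchors before the run
  normi <- left_normalize_indel(refstr, 14L, "insertion", "A")
  expect_equal(normi$pos, 10L)

  # deletion inside the G-run shifts to the run start; at the run start it
  # stays put
  expect_equal(left_normalize_indel(refstr, 20L, "deletion", "G")$pos, 17L)
  expect_equal(left_normalize_indel(refstr, 17L, "deletion", "G")$pos, 17L)
})

test_that("somatic test inspects the +/-5 base normal window inclusively", {
  contigs <- c(c1 = 1000L)
  refstr <- strrep("ACGT", 250)
  ref <- c(c1 = refstr)
  cand <- data.table(contig = "c1", start = 500L, end = 501L,
                     kind = "deletion",
                     sequence = substr(refstr, 500, 501),
                     supporting_reads = 5L)

  clean_normal <- mk_reads(rbindlist(lapply(1:10, function(i)
    new_read(paste0("n", i), "c1", 470L, substr(refstr, 470, 529),
             cigar = "60M"))), contigs = contigs)
  res <- indel_somatic_test(cand, clean_normal, ref)
  expect_true(res$somatic)
  expect_equal(res$normal_indel_evidence, 0L)

  # matching deletion in the normal: not somatic
  with_del <- mk_reads(rbindlist(lapply(1:5, function(i)
    new_read(paste0("m", i), "c1", 480L,
             paste0(substr(refstr, 480, 499), substr(refstr, 502, 521)),
             cigar = "20M2D20M"))), contigs = contigs)
  expect_false(indel_somatic_test(cand, with_del, ref)$somatic)

  # normal indel just outside the window (deletion at start-6) -> somatic
  # window is [495, 506]; a 1 bp deletion at 494 must not count
  outside <- mk_reads(
    rbindlist(lapply(1:5, function(i)
      new_read(paste0("o", i), "c1", 474L,
               paste0(substr(refstr, 474, 493), substr(refstr, 495, 514)),
               cigar = "20M1D20M"))),
    rbindlist(lapply(1:5, function(i)
      new_read(paste0("c", i), "c1", 470L, substr(refstr, 470, 529)))),
    contigs = contigs)
  res_out <- indel_somatic_test(cand, outside, ref)
  expect_true(res_out$somatic)

  # the same deletion one base right (at 495, on the boundary) does count
  boundary <- mk_reads(
    rbindlist(lapply(1:5, function(i)
      new_read(paste0("b", i), "c1", 475L,
               paste0(substr(refstr, 475, 494), substr(refstr, 496, 515)),
               cigar = "20M1D20M"))),
    contigs = contigs)
  expect_false(indel_somatic_test(cand, boundary, ref)$somatic)

  # no normal coverage: conservatively non-somatic
  empty_normal <- mk_reads(new_read("far", "c1", 900L, "AAAA"),
                           contigs = contigs)
  res_nc <- indel_somatic_test(cand, empty_normal, ref)
  expect_false(res_nc$somatic)
  expect_equal(res_nc$note, "no_normal_coverage")
})

test_that("the five validated coding indels round-trip with kind and length preserved", {
  recs <- coding_indel_records()
  expect_equal(nrow(recs), 5L)
  expect_equal(recs[gene == "CYP4A22", .(kind, nchar(sequence))],
               data.table(kind = "deletion", V2 = 1L))
  expect_equal(recs[gene == "KCNA10", .(kind, sequence)],
               data.table(kind = "insertion", sequence = "GAGCAAC"))
  expect_equal(recs[gene == "CCDC120", nchar(sequence)], 7L)

  p <- withr::local_tempfile(fileext = ".vcf")
  lens <- c(`1` = 250000000L, X = 160000000L)
  write_indel_vcf(recs[, .(contig, start, kind, sequence)], p,
                  reference = NULL, contig_lengths = lens)
  back <- parse_indel_vcf(p)
  expect_equal(nrow(back), 5L)
  expect_equal(back[order(contig, start), .(contig, start, kind, sequence)],
               recs[order(contig, start),
                    .(contig, start, kind, sequence)])
})

test_that("frameshift classification follows length mod 3", {
  gm <- validate_gene_models(data.table(
    gene = "G1", contig = "c1", strand = "+",
    exon_start = 101L, exon_end = 400L))
  expect_equal(classify_indel_consequence(gm, "c1", 200L, 200L, "T"),
               "frameshift")
  expect_equal(classify_indel_consequence(gm, "c1", 200L, 200L, "GAGCAAC"),
               "frameshift")
  expect_equal(classify_indel_consequence(gm, "c1", 200L, 202L, "GAG"),
               "inframe_indel")
  expect_equal(classify_indel_consequence(gm, "c1", 900L, 900L, "T"),
               "non_coding")
})
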