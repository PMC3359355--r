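sam_lines <- function(records, contigs = c(c1 = 10000L)) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs),
    records)
}

write_sam_file <- function(records, contigs = c(c1 = 10000L)) {
  p <- withr::local_tempfile(fileext = ".sam", .local_envir = parent.frame())
  writeLines(sam_lines(records, contigs), p)
  p
}

rec <- function(qname = "r1", flag = 0L, rname = "c1", pos = 100L,
                cigar = "100M", seq = strrep("A", 100),
                qual = strrep("?", nchar(seq))) {
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t0\t0\t%s\t%s",
          qname, flag, rname, pos, cigar, seq, qual)
}

test_that("read_sam accepts consistent CIGARs and rejects inconsistent ones", {
  p <- write_sam_file(c(
    rec("ok100", cigar = "100M"),
    rec("okins", cigar = "50M2I48M"),                  # consumes 100 query
    rec("baddel", cigar = "50M2D48M")))                # consumes 98 query
  expect_warning(reads <- read_sam(p), "baddel|line|mismatch")
  expect_equal(sort(reads$qname), c("ok100", "okins"))
  expect_equal(reads[qname == "okins", end - pos + 1L], 98L)  # ref span
})

test_that("read_sam requires a header", {
  p <- withr::local_tempfile(fileext = ".sam")
  writeLines(rec(), p)
  expect_error(read_sam(p), "header")
})

test_that("SAM read/write round trip is record-identical", {
  p <- write_sam_file(c(rec("a", pos = 10L), rec("b", pos = 20L, flag = 16L),
                        rec("d", pos = 30L, flag = 1024L)))
  r1 <- read_sam(p)
  p2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(r1, p2)
  r2 <- read_sam(p2)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_true(r2[qname == "d", is_duplicate])
})

test_that("flag_duplicates keeps one pair per coordinate key", {
  contigs <- c(c1 = 10000L)
  # two identical pairs -> exactly one flagged
  r <- mk_reads(mk_pair("p1", "c1", 100, 300), mk_pair("p2", "c1", 100, 300),
                contigs = contigs)
  r <- flag_duplicates(r)
  expect_equal(sum(r$is_duplicate), 2L)                 # one pair = two reads
  expect_equal(uniqueN(r[is_duplicate == TRUE, qname]), 1L)

  # pairs differing in mate position -> none flagged
  r2 <- mk_reads(mk_pair("p1", "c1", 100, 300), mk_pair("p2", "c1", 100, 310),
                 contigs = contigs)
  expect_equal(sum(flag_duplicates(r2)$is_duplicate), 0L)

  # k identical pairs -> k - 1 flagged (brute-force grouping)
  for (k in c(3L, 5L)) {
    rk <- mk_reads(rbindlist(lapply(seq_len(k), function(i)
      mk_pair(paste0("q", i), "c1", 500, 280))), contigs = contigs)
    expect_equal(sum(flag_duplicates(rk)$is_duplicate), 2L * (k - 1L))
  }
})

test_that("pileup counts strands and trims zero-quality bases", {
  contigs <- c(c1 = 1000L)
  ref <- c(c1 = strrep("A", 1000))
  r <- mk_reads(rbindlist(lapply(1:10, function(i)
    new_read(paste0("f", i), "c1", 96L, strrep("A", 10)))),
    contigs = contigs)
  pile <- build_pileup(r, ref, "c1", positions = 100L)
  col <- pileup_column(pile, 100L)
  expect_equal(col$depth_forward, 10L)
  expect_equal(col$depth_reverse, 0L)
  expect_true(all(col$forward$qual >= 1L))

  # one zero-quality base among 5 reads -> depth 4 at that position
  quals <- c("!", "?", "?", "?", "?")                  # "!" = Q0
  r2 <- mk_reads(rbindlist(lapply(1:5, function(i)
    new_read(paste0("z", i), "c1", 100L, "AAAAA",
             qual = paste0(substr(quals[i], 1, 1), strrep("?", 4))))),
    contigs = contigs)
  col2 <- pileup_column(build_pileup(r2, ref, "c1", positions = 100L), 100L)
  expect_equal(col2$depth_forward + col2$depth_reverse, 4L)
})

test_that("overlapping mates both contribute observations", {
  contigs <- c(c1 = 1000L)
  ref <- c(c1 = strrep("A", 1000))
  r <- mk_reads(mk_pair("p", "c1", 95, 15, rl = 10L,
                        seq1 = strrep("G", 10), seq2 = strrep("G", 10)),
                contigs = contigs)
  col <- pileup_column(build_pileup(r, ref, "c1", positions = 100L), 100L)
  expect_equal(col$depth_forward, 1L)
  expect_equal(col$depth_reverse, 1L)
})

test_that("deletions contribute no observation; insertions do not shift anchors", {
  contigs <- c(c1 = 1000L)
  ref <- c(c1 = strrep("A", 1000))
  # 4M2D4M starting at 100: covers 100-103 (query 1-4), skips 104-105,
  # covers 106-109 (query 5-8)
  r <- mk_reads(new_read("del", "c1", 100L, "GGGGCCCC", cigar = "4M2D4M"),
                new_read("ins", "c1", 200L, "TTTTGGTTTT", cigar = "4M2I4M"),
                contigs = contigs)
  pile <- build_pileup(r, ref, "c1", positions = c(100L, 104L, 106L,
                                                   200L, 203L, 204L))
  expect_equal(pileup_column(pile, 104L)$depth_forward, 0L)
  expect_equal(pileup_column(pile, 106L)$forward$base, "C")
  # insertion: query 5-6 are inserted; ref 204 gets query 7 ("T")
  expect_equal(pileup_column(pile, 203L)$forward$base, "T")
  expect_equal(pileup_column(pile, 204L)$forward$base, "T")
})

test_that("pileup depth equals brute-force interval counting on random reads", {
  set.seed(42)
  contigs <- c(c1 = 500L)
  ref <- c(c1 = paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                      collapse = ""))
  rows <- lapply(1:50, function(i) {
    pos <- sample(1:400, 1)
    rl <- sample(5:30, 1)
    new_read(paste0("r", i), "c1", pos,
             paste(sample(c("A", "C", "G", "T"), rl, replace = TRUE),
                   collapse = ""),
             strand = sample(c("+", "-"), 1))
  })
  r <- mk_reads(rbindlist(rows), contigs = contigs)
  r[, strand := ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")]
  positions <- sort(sample(1:450, 40))
  pile <- build_pileup(r, ref, "c1", positions = positions)
  d <- pileup_depths(pile)
  for (p in positions) {
    expected <- sum(r$pos <= p & r$end >= p)
    expect_equal(d[pos == p, depth_forward + depth_reverse], expected,
                 label = paste("pos", p))
  }
})

test_that("positions outside the contig are a range error", {
  contigs <- c(c1 = 100L)
  ref <- c(c1 = strrep("A", 100))
  r <- mk_reads(new_read("r", "c1", 1L, "AAAA"), contigs = contigs)
  expect_error(build_pileup(r, ref, "c1", positions = 200L), "range")
})
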