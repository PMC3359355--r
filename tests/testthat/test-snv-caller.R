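test_that("weighted alt fraction follows the quality-weight formula", {
  # all-alt column: fraction 1 regardless of qualities
  col <- mk_column(fwd_bases = rep("G", 10), fwd_quals = rep(30L, 10))
  expect_equal(weighted_alt_fraction(col, "G", "forward"), 1.0)

  # equal qualities: reduces to the unweighted fraction
  col2 <- mk_column(fwd_bases = c(rep("A", 5), rep("G", 5)),
                    fwd_quals = rep(25L, 10))
  expect_equal(weighted_alt_fraction(col2, "G", "forward"), 0.5)

  # hand computation: 1 alt at Q10 (w=0.9), 1 ref at Q30 (w=0.999)
  col3 <- mk_column(fwd_bases = c("G", "A"), fwd_quals = c(10L, 30L))
  expect_equal(weighted_alt_fraction(col3, "G", "forward"),
               0.9 / (0.9 + 0.999), tolerance = 1e-12)
  expect_equal(round(weighted_alt_fraction(col3, "G", "forward"), 4), 0.4739)

  # empty strand: undefined evidence, not zero
  expect_true(is.na(weighted_alt_fraction(col3, "G", "reverse")))
})

test_that("two-point KS distance is the absolute fraction difference", {
  expect_equal(ks_distance(0.5, "het"), 0.0)
  expect_equal(ks_distance(1.0, "hom_ref"), 1.0)
  expect_equal(ks_distance(0.4739, "het"), 0.0261, tolerance = 1e-9)
  expect_error(ks_distance(0.5, "triploid"), "genotype")
})

test_that("adding or upweighting alt observations never decreases the fraction", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(1:10, 1)
    bases <- sample(c("A", "G"), n, replace = TRUE)
    quals <- sample(c(2L, 10L, 20L, 30L), n, replace = TRUE)
    col <- mk_column(fwd_bases = bases, fwd_quals = quals)
    f0 <- weighted_alt_fraction(col, "G", "forward")
    # add an alt observation
    col_add <- mk_column(fwd_bases = c(bases, "G"),
                         fwd_quals = c(quals, sample(c(2L, 30L), 1)))
    expect_gte(weighted_alt_fraction(col_add, "G", "forward"), f0)
    # raise an alt base's quality
    gi <- which(bases == "G")
    if (length(gi)) {
      q2 <- quals; q2[gi[1]] <- 41L
      col_up <- mk_column(fwd_bases = bases, fwd_quals = q2)
      expect_gte(weighted_alt_fraction(col_up, "G", "forward"), f0)
    }
  }
})

test_that("standard calls require both strands to support the variant", {
  th <- caller_thresholds()
  # clean hom_alt on both strands at depth 20/20
  col <- mk_column(fwd_bases = rep("G", 20), fwd_quals = rep(30L, 20),
                   rev_bases = rep("G", 20), rev_quals = rep(30L, 20))
  call <- call_genotype(col, th, "standard")
  expect_equal(call$genotype, "hom_alt")
  expect_equal(call$tier, "high_quality")

  # forward het, reverse all-reference: no variant call (strand rule)
  col2 <- mk_column(fwd_bases = rep(c("A", "G"), 5), fwd_quals = rep(30L, 10),
                    rev_bases = rep("A", 10), rev_quals = rep(30L, 10))
  call2 <- call_genotype(col2, th, "standard")
  expect_false(isTRUE(call2$genotype %in% c("het", "hom_alt") &&
                        call2$tier != "no_call"))

  # clean het both strands
  col3 <- mk_column(fwd_bases = rep(c("A", "G"), 10), fwd_quals = rep(30L, 20),
                    rev_bases = rep(c("A", "G"), 10), rev_quals = rep(30L, 20))
  call3 <- call_genotype(col3, th, "standard")
  expect_equal(call3$genotype, "het")
  expect_equal(call3$tier, "high_quality")

  # empty column: no call
  call4 <- call_genotype(mk_column(), th, "standard")
  expect_equal(call4$tier, "no_call")
  expect_true(is.na(call4$genotype))
})

test_that("variant-consensus mode rescues pooled-fraction variants", {
  th <- caller_thresholds(lenient_max_distance = 0.2)
  # pooled fraction 0.35 with 2 alt observations per strand:
  # |0.35 - 0.5| = 0.15 <= 0.2 -> het at lenient tier
  col <- mk_column(fwd_bases = c(rep("A", 6), "G", "G"),
                   fwd_quals = rep(30L, 8),
                   rev_bases = c(rep("A", 7), "G", "G", "G"),
                   rev_quals = rep(30L, 10))
  # pooled alt fraction = 5/18 ~ 0.278; use exact 0.35: 7 alt of 20
  col <- mk_column(fwd_bases = c(rep("A", 6), rep("G", 3)),
                   fwd_quals = rep(30L, 9),
                   rev_bases = c(rep("A", 7), rep("G", 4)),
                   rev_quals = rep(30L, 11))
  call <- call_genotype(col, th, "variant_consensus")
  expect_equal(call$genotype, "het")
  expect_equal(call$tier, "lenient")

  # same column in standard mode fails the strict per-strand rule
  expect_equal(call_genotype(col, caller_thresholds(), "standard")$tier,
               "no_call")

  # fewer than min_alt_obs on one strand blocks the consensus call
  col2 <- mk_column(fwd_bases = c(rep("A", 5), rep("G", 4)),
                    fwd_quals = rep(30L, 9),
                    rev_bases = c(rep("A", 8), "G"),
                    rev_quals = rep(30L, 9))
  call2 <- call_genotype(col2, th, "variant_consensus")
  expect_false(identical(call2$tier, "lenient"))
})

test_that("somatic classification requires a high-quality reference normal", {
  th <- caller_thresholds()
  het <- mk_column(fwd_bases = rep(c("A", "G"), 10), fwd_quals = rep(30L, 20),
                   rev_bases = rep(c("A", "G"), 10), rev_quals = rep(30L, 20))
  ref_hq <- mk_column(fwd_bases = rep("A", 15), fwd_quals = rep(30L, 15),
                      rev_bases = rep("A", 15), rev_quals = rep(30L, 15))
  ref_lowdepth <- mk_column(fwd_bases = rep("A", 2), fwd_quals = rep(30L, 2),
                            rev_bases = rep("A", 2), rev_quals = rep(30L, 2))

  tumor <- call_genotype(het, th, "variant_consensus")
  expect_true(call_somatic(tumor, call_genotype(ref_hq, th))$somatic)

  som2 <- call_somatic(tumor, call_genotype(het, th))
  expect_false(som2$somatic)
  expect_equal(som2$filter_notes, "germline")

  som3 <- call_somatic(tumor, call_genotype(ref_lowdepth, th))
  expect_false(som3$somatic)
  expect_equal(som3$filter_notes, "ambiguous_normal")

  som4 <- call_somatic(call_genotype(ref_hq, th), call_genotype(ref_hq, th))
  expect_false(som4$somatic)
  expect_equal(som4$filter_notes, "tumor_no_call")

  other_locus <- call_genotype(
    mk_column(fwd_bases = rep("A", 10), fwd_quals = rep(30L, 10),
              rev_bases = rep("A", 10), rev_quals = rep(30L, 10),
              pos = 200L), th)
  expect_error(call_somatic(tumor, other_locus), "pairing")
})

test_that("dual-caller intersection and union behave as set algebra", {
  a <- data.table(contig = "c1", pos = c(1L, 2L, 3L), alt = "G")
  b <- data.table(contig = "c1", pos = c(2L, 3L, 4L), alt = "G")
  res <- dual_caller_intersection(a, b)
  expect_equal(res$intersection$pos, c(2L, 3L))
  expect_equal(res$union$pos, 1:4)
  expect_equal(dual_caller_intersection(a, a)$intersection$pos, a$pos)
  expect_equal(nrow(dual_caller_intersection(
    a, data.table(contig = "c1", pos = 9L, alt = "G"))$intersection), 0L)
})

test_that("scalar and vectorized genotype callers agree on random pileups", {
  set.seed(99)
  th <- caller_thresholds()
  for (mode in c("standard", "variant_consensus")) {
    for (rep in 1:200) {
      nf <- sample(0:10, 1); nr <- sample(0:10, 1)
      if (nf + nr == 0) next
      fb <- sample(c("A", "G"), nf, replace = TRUE)
      rb <- sample(c("A", "G"), nr, replace = TRUE)
      fq <- sample(c(2L, 20L, 30L), nf, replace = TRUE)
      rq <- sample(c(2L, 20L, 30L), nr, replace = TRUE)
      col <- mk_column(fwd_bases = fb, fwd_quals = fq,
                       rev_bases = rb, rev_quals = rq)
      sc <- call_genotype(col, th, mode)
      obs <- data.table(
        pos = 100L,
        strand = c(rep("+", nf), rep("-", nr)),
        base = c(fb, rb), qual = c(fq, rq))
      vec <- call_genotypes(mk_pileup(obs, 100L, "A"), th, mode)
      expect_equal(vec$genotype, sc$genotype, label = paste(mode, rep))
      expect_equal(vec$tier, sc$tier, label = paste(mode, rep))
      expect_equal(vec$f_fwd, sc$f_fwd, tolerance = 1e-12)
      expect_equal(vec$f_rev, sc$f_rev, tolerance = 1e-12)
    }
  }
})

test_that("standard calls match the brute-force minimizer on enumerated pileups", {
  # exhaustive over all strand/base/quality count patterns up to 6 obs
  th <- caller_thresholds()
  counts <- compositions_upto(8L, 6L)
  cats <- data.table(
    strand = rep(c("+", "-"), each = 4),
    base = rep(c("A", "A", "G", "G"), 2),
    qual = rep(c(2L, 30L), 4))
  for (i in seq_len(nrow(counts))) {
    k <- counts[i, ]
    if (sum(k) == 0) next
    idx <- rep(seq_len(8), k)
    fb <- cats$base[idx][cats$strand[idx] == "+"]
    fq <- cats$qual[idx][cats$strand[idx] == "+"]
    rb <- cats$base[idx][cats$strand[idx] == "-"]
    rq <- cats$qual[idx][cats$strand[idx] == "-"]
    col <- mk_column(fwd_bases = fb, fwd_quals = fq,
                     rev_bases = rb, rev_quals = rq)
    got <- call_genotype(col, th, "standard", alt = "G")
    want <- brute_genotype(fb, fq, rb, rq)
    expect_identical(
      list(got$genotype, got$tier),
      list(want$genotype, want$tier),
      label = paste(k, collapse = ","))
  }
})
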