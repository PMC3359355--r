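# independent 64-codon standard genetic code, written out explicitly
STANDARD_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

test_that("translation agrees with the standard code for all 64 codons", {
  for (codon in names(STANDARD_CODE))
    expect_equal(translate_codon(codon), unname(STANDARD_CODE[codon]),
                 label = codon)
  expect_error(translate_codon("ANG"), "invalid|ambiguous")
  expect_error(translate_codon("AC"), "invalid")
})

test_that("codon mapping anchors at the CDS start and handles strand", {
  refstr <- paste(rep(c("A", "C", "G", "T"), 75), collapse = "")
  ref <- c(c1 = refstr)
  gm <- validate_gene_models(data.table(
    gene = "plus", contig = "c1", strand = "+",
    exon_start = 101L, exon_end = 160L))
  m1 <- map_to_codon(gm, "plus", ref, 101L)
  expect_equal(m1[c("codon_index", "position_in_codon")],
               list(codon_index = 1L, position_in_codon = 1L))
  expect_equal(m1$ref_codon, substr(refstr, 101, 103))
  m2 <- map_to_codon(gm, "plus", ref, 104L)
  expect_equal(m2[c("codon_index", "position_in_codon")],
               list(codon_index = 2L, position_in_codon = 1L))
  expect_false(map_to_codon(gm, "plus", ref, 90L)$coding)

  # minus-strand toy: CDS 10..18; genomic position 17 is the second base
  # of the first codon after reverse complement
  gm2 <- validate_gene_models(data.table(
    gene = "minus", contig = "c2", strand = "-",
    exon_start = 10L, exon_end = 18L))
  ref2 <- c(c2 = "AAAAAAAAAGATCCCTAGAAAA")
  # CDS genomic 10..18 = "GATCCCTAG"; coding strand = revcomp = "CTAGGGATC"
  # genomic 17 = second base counting from the 3' exon end
  m3 <- map_to_codon(gm2, "minus", ref2, 17L)
  expect_equal(m3$codon_index, 1L)
  expect_equal(m3$position_in_codon, 2L)
  expect_equal(m3$ref_codon, "CTA")
})

test_that("multi-exon and strand-twin models give consistent consequences", {
  # gene on the minus strand and its reverse-complement twin on plus
  set.seed(5)
  cds <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
  up <- strrep("T", 20); down <- strrep("G", 20)
  plus_ref <- paste0(up, cds, down)
  minus_ref <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(plus_ref)))
  refs <- c(p = plus_ref, m = minus_ref)
  gmp <- validate_gene_models(data.table(gene = "gp", contig = "p",
                                         strand = "+", exon_start = 21L,
                                         exon_end = 50L))
  gmm <- validate_gene_models(data.table(gene = "gm", contig = "m",
                                         strand = "-", exon_start = 21L,
                                         exon_end = 50L))
  for (k in 0:29) {
    pos_p <- 21L + k
    pos_m <- 70L - 20L - k          # mirrored genomic position
    mp <- map_to_codon(gmp, "gp", refs, pos_p)
    mm <- map_to_codon(gmm, "gm", refs, pos_m)
    expect_equal(mp$codon_index, mm$codon_index)
    expect_equal(mp$position_in_codon, mm$position_in_codon)
    expect_equal(mp$ref_codon, mm$ref_codon)
  }
})

test_that("validated codon substitutions reproduce the recorded consequences", {
  recs <- validated_snv_records()
  expect_equal(nrow(recs), 7L)
  for (i in seq_len(nrow(recs))) {
    # the substituted position is where reference and mutated codons differ
    rc <- recs$ref_codon[i]; mc <- recs$mut_codon[i]
    diffs <- which(strsplit(rc, "")[[1]] != strsplit(mc, "")[[1]])
    expect_length(diffs, 1L)
    got <- mutate_codon(rc, diffs, substr(mc, diffs, diffs))
    expect_equal(got, mc)
    expect_equal(translate_codon(rc), recs$ref_aa[i])
    expect_equal(translate_codon(got), recs$mut_aa[i])
    expect_equal(classify_effect(rc, got), "nsSNP")
    expect_equal(recs$type[i], "nsSNP")
  }
})

test_that("effect classification distinguishes silent, missense and nonsense", {
  expect_equal(classify_effect("AGG", "AAG"), "nsSNP")     # R -> K
  expect_equal(classify_effect("CTG", "CTA"), "synonymous") # L -> L
  expect_equal(classify_effect("TGC", "TGA"), "nonsense")   # C -> stop
  expect_equal(classify_effect("TGA", "TGC"), "stop_lost")
  expect_warning(mutate_codon("AGC", 2L, "G"), "unchanged")
})

test_that("summary statistics count transitions, transversions and known sites", {
  calls <- data.table(contig = "c1", pos = 1:3, ref = c("A", "C", "A"),
                      alt = c("G", "T", "C"))
  s <- summary_stats(calls)
  expect_equal(s$n_transitions, 2L)
  expect_equal(s$n_transversions, 1L)
  expect_equal(s$titv_ratio, 2.0)
  expect_equal(s$known_fraction, 0)
  expect_equal(s$n_transitions + s$n_transversions, s$n_snvs)

  # 4 of 104 matched in the known set
  calls2 <- data.table(contig = "c1", pos = 1:104, ref = "A", alt = "G")
  known <- data.table(contig = "c1", pos = 1:4, ref = "A", alt = "G")
  expect_equal(summary_stats(calls2, known)$known_fraction, 4 / 104)

  # transversion-free set reports an undefined ratio
  s3 <- summary_stats(data.table(contig = "c1", pos = 1:2, ref = "A",
                                 alt = "G"))
  expect_true(is.na(s3$titv_ratio))
})

test_that("gene models with invalid CDS length are rejected with a warning", {
  gm <- data.table(gene = c("ok", "ok", "bad"), contig = "c1",
                   strand = "+",
                   exon_start = c(1L, 100L, 200L),
                   exon_end = c(30L, 129L, 203L))
  expect_warning(v <- validate_gene_models(gm), "bad")
  expect_setequal(unique(v$gene), "ok")
})

test_that("annotate_snvs maps somatic variants through toy gene models", {
  refstr <- paste(rep("ACGTTGCA", 50), collapse = "")
  ref <- c(c1 = refstr)
  gm <- validate_gene_models(data.table(
    gene = c("g1", "g1"), contig = "c1", strand = "+",
    exon_start = c(11L, 41L), exon_end = c(25L, 55L)))
  snvs <- data.table(contig = "c1", pos = c(12L, 43L, 300L),
                     ref = substr(refstr, c(12, 43, 300), c(12, 43, 300)),
                     alt = c("G", "A", "C"))
  ann <- annotate_snvs(snvs, gm, ref)
  expect_equal(ann$effect[3], "non_coding")
  expect_equal(ann$gene[1:2], c("g1", "g1"))
  # pos 43 is the 18th CDS base -> codon 6, position 3
  expect_equal(ann$codon_index[2], 6L)
  expect_equal(ann$position_in_codon[2], 3L)
  # mutated codon differs from reference at exactly one position
  for (i in 1:2) {
    d <- sum(strsplit(ann$ref_codon[i], "")[[1]] !=
               strsplit(ann$mut_codon[i], "")[[1]])
    expect_equal(d, 1L)
  }
})
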