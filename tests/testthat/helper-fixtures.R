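library(data.table)

# ---- aligned-read constructors (independent of the package's SAM writer) ---

.href_consume <- function(cigar) {
  m <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]", "", m))
  ops <- sub("\\d+", "", m)
  sum(lens[ops %in% c("M", "D", "N", "=", "X")])
}

new_read <- function(qname, rname, pos, seq, strand = "+", qual = NULL,
                     cigar = NULL, flag = NULL, rnext = "=", pnext = 0L,
                     tlen = 0L, mapq = 60L, dup = FALSE, paired = FALSE) {
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  if (is.null(qual)) qual <- strrep("?", nchar(seq))   # "?" = Q30
  if (is.null(flag)) {
    flag <- 0L
    if (strand == "-") flag <- bitwOr(flag, 16L)
    if (paired) flag <- bitwOr(flag, 1L + 2L + 32L * (strand == "+"))
    if (dup) flag <- bitwOr(flag, 1024L)
  }
  data.table(qname = qname, flag = as.integer(flag), rname = rname,
             pos = as.integer(pos), mapq = as.integer(mapq), cigar = cigar,
             rnext = rnext, pnext = as.integer(pnext),
             tlen = as.integer(tlen), seq = seq, qual = qual,
             strand = strand, mapped = TRUE, is_duplicate = dup,
             end = as.integer(pos + .href_consume(cigar) - 1L))
}

mk_reads <- function(..., contigs) {
  r <- rbindlist(list(...))
  setattr(r, "contigs", contigs)
  setattr(r, "class", c("aligned_reads", class(r)))
  r[]
}

# a proper FR pair: forward read at pos1, reverse mate ending at pos1+tlen-1
mk_pair <- function(qname, rname, pos1, tlen, rl = 10L,
                    seq1 = NULL, seq2 = NULL, dup = FALSE) {
  pos2 <- pos1 + tlen - rl
  if (is.null(seq1)) seq1 <- strrep("A", rl)
  if (is.null(seq2)) seq2 <- strrep("A", rl)
  rbind(
    new_read(qname, rname, pos1, seq1, "+",
             flag = bitwOr(99L, if (dup) 1024L else 0L),
             pnext = pos2, tlen = tlen),
    new_read(qname, rname, pos2, seq2, "-",
             flag = bitwOr(147L, if (dup) 1024L else 0L),
             pnext = pos1, tlen = -tlen))
}

# ---- pileup-column constructor for caller unit tests ------------------------

mk_column <- function(ref = "A", fwd_bases = character(), fwd_quals = integer(),
                      rev_bases = character(), rev_quals = integer(),
                      contig = "c1", pos = 100L) {
  fwd <- data.table(base = fwd_bases, qual = as.integer(fwd_quals))
  rev <- data.table(base = rev_bases, qual = as.integer(rev_quals))
  structure(list(contig = contig, pos = pos, ref_base = ref,
                 forward = fwd, reverse = rev,
                 depth_forward = nrow(fwd), depth_reverse = nrow(rev)),
            class = "pileup_column")
}

# build a pileup object directly from an observation table (unit tests)
mk_pileup <- function(obs, positions, ref_base, contig = "c1") {
  obs <- as.data.table(obs)
  names(ref_base) <- positions
  setattr(obs, "contig", contig)
  setattr(obs, "positions", as.integer(positions))
  setattr(obs, "ref_base", ref_base)
  setattr(obs, "class", c("pileup", class(obs)))
  obs[]
}

# ---- independent genotype oracle -------------------------------------------
# Direct arithmetic restatement of the calling rule, used to cross-check the
# caller: per strand the weighted alt fraction, the nearest of the three
# expected fractions (ties toward the smaller), then the combined rule.
brute_genotype <- function(fwd_bases, fwd_quals, rev_bases, rev_quals,
                           ref = "A", alt = "G",
                           strict = 0.15, min_depth = 4L) {
  side <- function(bases, quals) {
    if (!length(bases)) return(list(f = NA_real_, gt = NA_character_,
                                    d = NA_real_, depth = 0L))
    w <- 1 - 10^(-quals / 10)
    f <- sum(w[bases == alt]) / sum(w)
    best_gt <- NA_character_; best_d <- Inf
    for (g in c("hom_ref", "het", "hom_alt")) {
      e <- c(hom_ref = 0, het = 0.5, hom_alt = 1)[[g]]
      d <- abs(f - e)
      if (d < best_d) { best_d <- d; best_gt <- g }
    }
    list(f = f, gt = best_gt, d = best_d, depth = length(bases))
  }
  fw <- side(fwd_bases, fwd_quals); rv <- side(rev_bases, rev_quals)
  gt <- NA_character_; tier <- "no_call"
  if (fw$depth >= min_depth && rv$depth >= min_depth &&
      !is.na(fw$gt) && !is.na(rv$gt) && fw$gt == rv$gt &&
      fw$d <= strict && rv$d <= strict) {
    gt <- fw$gt; tier <- "high_quality"
  } else if (!is.na(fw$gt) && !is.na(rv$gt) &&
             fw$gt == "hom_ref" && rv$gt == "hom_ref") {
    gt <- "hom_ref"
  }
  list(genotype = gt, tier = tier)
}

# all k-tuples of non-negative counts summing to at most total
compositions_upto <- function(k, total) {
  if (k == 1L) return(matrix(0:total, ncol = 1))
  out <- vector("list", total + 1L)
  for (i in 0:total) {
    sub <- compositions_upto(k - 1L, total - i)
    out[[i + 1L]] <- cbind(rep.int(i, nrow(sub)), sub)
  }
  do.call(rbind, out)
}

# small simulation config for fast tests
tiny_config <- function(seed = 3L, ...) {
  defaults <- list(seed = seed, contig_lengths = c(60000, 40000),
                   n_somatic_snvs = 10L, n_somatic_indels = 3L,
                   n_germline_indels = 2L,
                   cnv_segments = data.frame(contig = character(),
                                             start = integer(),
                                             end = integer(),
                                             copy_number = integer()),
                   n_genes = 8L, depth_tumor = 40, depth_normal = 30)
  overrides <- list(...)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  do.call(simulation_config, defaults)
}
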