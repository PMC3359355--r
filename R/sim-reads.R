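#' Simulate coordinate-sorted paired-end alignments for one sample
#'
#' Draws fragments from the diploid genome described by a \code{sim_truth}
#' (germline SNPs baked into two haplotypes; germline indels carried by one
#' haplotype; somatic SNVs/indels patched into tumor fragments with
#' per-fragment probability equal to the configured VAF), emits both mates as
#' reference-forward sequences with per-base qualities from a two-component
#' mix (high quality around Q30-Q38, Phred 0 at \code{zero_quality_rate}),
#' adds i.i.d. substitution errors at \code{base_error_rate}, appends PCR
#' duplicate pairs sharing both mates' coordinates, and writes a
#' coordinate-sorted SAM with proper FLAG/TLEN bookkeeping. Tumor fragment
#' density is scaled by copy_number/2 inside CNV segments.
#'
#' Reads are emitted pre-aligned at their true coordinates; indel-carrying
#' reads encode the gap in their CIGAR (nM kI/kD mM). Reads whose leftmost
#' base would fall strictly inside a deleted interval are emitted as
#' reference-matching reads.
#'
#' @param truth a \code{sim_truth} from \code{\link{simulate_reference}}.
#' @param sample one of "normal", "tumor".
#' @param path output SAM path.
#' @param config optional override of \code{truth$config}.
#' @return Invisibly, a list with the path and the number of pairs written
#'   (including duplicates).
#' @export
simulate_read_pairs <- function(truth, sample = c("normal", "tumor"), path,
                                config = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  sample <- match.arg(sample)
  cfg <- if (is.null(config)) truth$config else config
  set.seed(.child_seed(cfg$seed, if (sample == "normal") 1L else 2L))

  rl <- cfg$read_length
  depth <- if (sample == "normal") cfg$depth_normal else cfg$depth_tumor
  lens <- cfg$contig_lengths
  is_tumor <- sample == "tumor"

  all_reads <- vector("list", length(lens))
  for (ci in seq_along(lens)) {
    ct <- names(lens)[ci]
    L <- lens[[ci]]
    haps <- .build_haplotypes(truth, ct)

    # fragment sampling intervals with CNV weighting (tumor only)
    iv <- data.table(start = 1L, end = L, w = 1)
    cnv <- truth$cnv_segments[contig == ct]
    if (is_tumor && nrow(cnv)) {
      bp <- sort(unique(c(1L, cnv$start, cnv$end + 1L, L + 1L)))
      iv <- data.table(start = bp[-length(bp)], end = bp[-1] - 1L)
      iv[, w := 1]
      for (k in seq_len(nrow(cnv)))
        iv[start >= cnv$start[k] & end <= cnv$end[k],
           w := cnv$copy_number[k] / 2]
    }
    iv[, len := end - start + 1L]
    n_base <- round(depth * L / (2 * rl))
    n_iv <- round(n_base * iv$w * iv$len / L)
    n_pairs <- sum(n_iv)
    if (n_pairs == 0L) next

    frag_iv <- rep.int(seq_len(nrow(iv)), n_iv)
    flen <- pmax(rl + 1L,
                 as.integer(round(rnorm(n_pairs, cfg$fragment_size_mean,
                                        cfg$fragment_size_sd))))
    fs <- iv$start[frag_iv] +
      as.integer(floor(runif(n_pairs) * pmax(iv$len[frag_iv] - flen + 1L, 1L)))
    fs <- pmax(1L, pmin(fs, L - flen + 1L))
    fe <- fs + flen - 1L
    fhap <- sample(1:2, n_pairs, replace = TRUE)

    pairs <- data.table(id = seq_len(n_pairs), fs = fs, fe = fe,
                        flen = flen, hap = fhap)

    # mates: left read forward [fs, fs+rl-1], right read reverse [fe-rl+1, fe]
    first_left <- runif(n_pairs) < 0.5
    reads <- rbind(
      pairs[, .(pair = id, hap, start = fs, end = fs + rl - 1L,
                strand = "+", tlen = flen,
                flag = ifelse(first_left, 99L, 163L), mate_pos = fe - rl + 1L)],
      pairs[, .(pair = id, hap, start = fe - rl + 1L, end = fe,
                strand = "-", tlen = -flen,
                flag = ifelse(first_left, 147L, 83L), mate_pos = fs)])

    hap1_str <- haps[[1L]]; hap2_str <- haps[[2L]]
    reads[, seq := stri_sub(hap1_str, start, end)]
    reads[hap == 2L, seq := stri_sub(hap2_str, start, end)]
    reads[, cigar := paste0(rl, "M")]

    # somatic SNVs: per-fragment carrier status at the configured VAF
    if (is_tumor) {
      sites <- truth$somatic_snvs[contig == ct]
      for (k in seq_len(nrow(sites))) {
        p <- sites$pos[k]
        carrier <- pairs[fs <= p & fe >= p][runif(.N) < sites$vaf[k], id]
        if (!length(carrier)) next
        hit <- reads[, which(pair %in% carrier & start <= p & end >= p)]
        if (!length(hit)) next
        reads$seq[hit] <- .patch_chars(reads$seq[hit], seq_along(hit),
                                       p - reads$start[hit] + 1L,
                                       rep(sites$alt[k], length(hit)))
      }
    }

    # indels: germline (haplotype-linked) and, for tumor, somatic fragments
    ind <- rbind(
      truth$germline_indels[contig == ct,
                            .(pos, kind, sequence, hap, vaf = NA_real_)],
      if (is_tumor) truth$somatic_indels[contig == ct,
                                         .(pos, kind, sequence,
                                           hap = NA_integer_, vaf)]
      else NULL)
    for (k in seq_len(nrow(ind))) {
      reads <- .apply_indel_to_reads(reads, pairs, truth$ref_strings[[ct]],
                                     ind[k], rl)
    }

    reads[, `:=`(rname = ct, pos = start,
                 qname = sprintf("%s_%s_%d", substr(sample, 1, 1), ct, pair))]
    all_reads[[ci]] <- reads[, .(qname, flag, rname, pos, cigar, mate_pos,
                                 tlen, seq, pair_key = paste0(ct, "_", pair))]
  }
  reads <- rbindlist(all_reads)
  if (!nrow(reads)) stop("no reads generated; check depths/contigs")

  # sequencing errors: i.i.d. substitutions at base_error_rate
  n <- nrow(reads)
  k_err <- rbinom(n, rl, cfg$base_error_rate)
  ei <- rep.int(which(k_err > 0L), k_err[k_err > 0L])
  if (length(ei)) {
    off <- sample.int(rl, length(ei), replace = TRUE)
    cur <- stri_sub(reads$seq[ei], off, off)
    sub <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG", N = "ACG")
    newb <- stri_sub(sub[cur], sample.int(3L, length(ei), replace = TRUE), length = 1L)
    reads[, seq := .patch_chars(seq, ei, off, newb)]
  }

  # per-base qualities from a pool of pre-drawn strings (two-component mix)
  pool <- .quality_pool(4096L, rl, cfg$zero_quality_rate)
  reads[, qual := pool[sample.int(length(pool), n, replace = TRUE)]]

  # PCR duplicates: extra copies of existing pairs (identical coordinates
  # and bases; flagging is downstream's job)
  n_pairs_tot <- n / 2L
  n_dup <- round(n_pairs_tot * cfg$duplicate_rate)
  if (n_dup > 0L) {
    src_keys <- sample(unique(reads$pair_key), min(n_dup, n_pairs_tot),
                       replace = FALSE)
    dup <- reads[pair_key %in% src_keys]
    dup[, qname := paste0(qname, "_dup")]
    reads <- rbind(reads, dup)
  }
  reads[, pair_key := NULL]

  setorder(reads, rname, pos, qname, flag)
  .write_sam_table(reads, path, lens)
  invisible(list(path = path, n_pairs = nrow(reads) / 2L))
}

# two haplotype strings for a contig: het SNPs on one haplotype, hom on both
.build_haplotypes <- function(truth, ct) {
  ref <- truth$ref_strings[[ct]]
  snps <- truth$germline_snps[contig == ct]
  h <- list(charToRaw(ref), charToRaw(ref))
  for (side in 1:2) {
    sel <- snps[genotype == "hom" | hap == side]
    if (nrow(sel)) h[[side]][sel$pos] <- charToRaw(stri_flatten(sel$alt))
  }
  list(rawToChar(h[[1]]), rawToChar(h[[2]]))
}

# rewrite reads overlapping one indel event: gapped CIGAR + shifted sequence
.apply_indel_to_reads <- function(reads, pairs, refstr, ev, rl) {
  p <- ev$pos; kind <- ev$kind; S <- ev$sequence
  len <- nchar(S)
  if (is.na(ev$vaf)) {             # germline: all fragments of carrier hap
    carrier_rows <- reads$hap == ev$hap
  } else {                         # somatic: Bernoulli(vaf) per fragment
    ids <- pairs[fs <= p + len & fe >= p - 1L, id]
    take <- ids[runif(length(ids)) < ev$vaf]
    carrier_rows <- reads$pair %in% take
  }
  if (kind == "deletion") {
    hit <- which(carrier_rows & reads$start < p & reads$end > p)
    if (!length(hit)) return(reads)
    a <- p - reads$start[hit]                    # matched bases before gap
    c_ <- rl - a                                 # matched bases after gap
    newseq <- paste0(stri_sub(refstr, reads$start[hit], p - 1L),
                     stri_sub(refstr, p + len, p + len + c_ - 1L))
    # haplotype SNPs inside the read prefix are lost here; the reference
    # suffices because indels are placed clear of other events
    reads$seq[hit] <- newseq
    reads$cigar[hit] <- sprintf("%dM%dD%dM", a, len, c_)
  } else {
    hit <- which(carrier_rows & reads$start <= p & reads$end > p)
    if (!length(hit)) return(reads)
    a <- p - reads$start[hit] + 1L
    ins <- pmin(len, rl - a)
    c_ <- rl - a - ins
    newseq <- paste0(stri_sub(refstr, reads$start[hit], p),
                     stri_sub(S, 1L, ins),
                     ifelse(c_ > 0L,
                            stri_sub(refstr, p + 1L, p + c_), ""))
    reads$seq[hit] <- newseq
    reads$cigar[hit] <- ifelse(c_ > 0L,
                               sprintf("%dM%dI%dM", a, ins, c_),
                               sprintf("%dM%dI", a, ins))
  }
  reads
}

.quality_pool <- function(n_strings, rl, zero_rate) {
  q <- matrix(sample(30:38, n_strings * rl, replace = TRUE),
              nrow = n_strings)
  if (zero_rate > 0)
    q[matrix(runif(n_strings * rl) < zero_rate, nrow = n_strings)] <- 0L
  apply(q, 1, function(row) intToUtf8(row + 33L))
}

.write_sam_table <- function(reads, path, contig_lengths) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)),
           "@PG\tID:somaticpair\tPN:somaticpair")
  writeLines(hdr, path)
  out <- reads[, .(qname, flag, rname, pos, mapq = 60L, cigar,
                   rnext = "=", pnext = mate_pos, tlen, seq, qual)]
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
         append = TRUE)
}

#' Simulate a full tumor/normal study
#'
#' Convenience wrapper: \code{\link{simulate_reference}} plus
#' \code{\link{simulate_read_pairs}} for both samples, writing all outputs
#' under one directory.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param dir output directory.
#' @return The \code{sim_truth}, with an attribute \code{paths} naming every
#'   written file.
#' @export
simulate_study <- function(config, dir) {
  truth <- simulate_reference(config)
  truth_paths <- write_sim_truth(truth, dir)
  normal <- file.path(dir, "normal.sam")
  tumor <- file.path(dir, "tumor.sam")
  simulate_read_pairs(truth, "normal", normal)
  simulate_read_pairs(truth, "tumor", tumor)
  attr(truth, "paths") <- c(truth_paths, normal = normal, tumor = tumor)
  truth
}
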