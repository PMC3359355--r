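#' Build per-locus, per-strand pileups
#'
#' Collects, for each requested reference position, every base observation
#' from mapped, non-duplicate reads, keeping the observation's strand and
#' Phred quality. Zero-quality bases are trimmed from the pileup at build
#' time, deletion-spanning reads contribute no observation at deleted
#' positions, and inserted bases (which consume no reference) are never
#' assigned to a position. Both mates of an overlapping pair are counted
#' independently.
#'
#' @param reads an \code{aligned_reads} table.
#' @param reference a \code{Biostrings::DNAStringSet} (or named character
#'   vector) of contig sequences.
#' @param contig contig name.
#' @param positions integer vector of 1-based positions, or \code{NULL} with
#'   \code{pos_range}.
#' @param pos_range optional length-2 integer range expanded to positions.
#' @return An object of class \code{pileup}: a \code{data.table} of
#'   observations (\code{pos}, \code{strand}, \code{base}, \code{qual}) with
#'   attributes \code{contig}, \code{positions} and \code{ref_base} (named by
#'   position).
#' @export
build_pileup <- function(reads, reference, contig, positions = NULL,
                         pos_range = NULL) {
  refstr <- .ref_string(reference, contig)
  L <- nchar(refstr)
  if (is.null(positions)) {
    if (is.null(pos_range)) stop("give positions or pos_range")
    pos_range <- as.integer(pos_range)
    positions <- seq.int(pos_range[1], pos_range[2])
  }
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) && (min(positions) < 1L || max(positions) > L))
    stop(sprintf("range error: positions outside contig %s [1, %d]",
                 contig, L), call. = FALSE)

  rr <- reads[rname == contig & mapped & !is_duplicate & seq != "*"]
  obs <- .gather_observations(rr, positions)
  obs <- obs[qual >= 1L]                       # zero-quality trimming
  ref_base <- stri_sub(refstr, positions, positions)
  names(ref_base) <- positions
  setorder(obs, pos, strand)
  setattr(obs, "contig", contig)
  setattr(obs, "positions", positions)
  setattr(obs, "ref_base", ref_base)
  setattr(obs, "class", c("pileup", class(obs)))
  obs[]
}

# observations (pos, strand, base, qual) for reads x positions
.gather_observations <- function(rr, positions) {
  empty <- data.table(pos = integer(), strand = character(),
                      base = character(), qual = integer())
  if (!nrow(rr) || !length(positions)) return(empty)
  simple <- stri_detect_regex(rr$cigar, "^\\d+M$")
  pieces <- list(empty)

  if (any(simple)) {
    rs <- rr[which(simple)]
    pdt <- data.table(p1 = positions, p2 = positions)
    rdt <- rs[, .(pos, end, seq, qual, strand)]
    setkey(rdt, pos, end)
    hits <- foverlaps(pdt, rdt, by.x = c("p1", "p2"),
                      by.y = c("pos", "end"), nomatch = NULL)
    if (nrow(hits)) {
      off <- hits$p1 - hits$pos + 1L
      pieces[[length(pieces) + 1L]] <- data.table(
        pos = hits$p1,
        strand = hits$strand,
        base = stri_sub(hits$seq, off, off),
        qual = .phred_decode_cat(stri_sub(hits$qual, off, off)))
    }
  }
  if (any(!simple)) {
    gp <- rr[which(!simple)]
    pset <- positions
    gobs <- vector("list", nrow(gp))
    for (i in seq_len(nrow(gp))) {
      map <- .cigar_ref_offsets(gp$cigar[i], gp$pos[i])
      if (!nrow(map)) next
      keep <- map[map$refpos %in% pset, , drop = FALSE]
      if (!nrow(keep)) next
      gobs[[i]] <- data.table(
        pos = keep$refpos, strand = gp$strand[i],
        base = stri_sub(gp$seq[i], keep$qoff, keep$qoff),
        qual = .phred_decode_cat(stri_sub(gp$qual[i], keep$qoff, keep$qoff)))
    }
    pieces[[length(pieces) + 1L]] <- rbindlist(gobs)
  }
  rbindlist(pieces)
}

# (refpos, query offset) pairs for the M/=/X segments of one CIGAR
.cigar_ref_offsets <- function(cigar, pos) {
  m <- stri_match_all_regex(cigar, "(\\d+)([MIDNSHP=X])")[[1]]
  lens <- as.integer(m[, 2]); ops <- m[, 3]
  refpos <- integer(0); qoff <- integer(0)
  rp <- pos; qp <- 1L
  for (i in seq_along(ops)) {
    op <- ops[i]; k <- lens[i]
    if (op %in% c("M", "=", "X")) {
      refpos <- c(refpos, rp:(rp + k - 1L))
      qoff <- c(qoff, qp:(qp + k - 1L))
      rp <- rp + k; qp <- qp + k
    } else if (op %in% c("D", "N")) {
      rp <- rp + k
    } else if (op %in% c("I", "S")) {
      qp <- qp + k
    }
  }
  data.frame(refpos = refpos, qoff = qoff)
}

.ref_string <- function(reference, contig) {
  if (inherits(reference, "DNAStringSet")) {
    if (!contig %in% names(reference))
      stop("contig not in reference: ", contig, call. = FALSE)
    as.character(reference[[contig]])
  } else if (is.character(reference)) {
    if (!contig %in% names(reference))
      stop("contig not in reference: ", contig, call. = FALSE)
    reference[[contig]]
  } else stop("unsupported reference type")
}

#' Extract one pileup column
#'
#' @param pileup a \code{pileup} object.
#' @param pos position (must be among the pileup's positions).
#' @return A list of class \code{pileup_column} with the contig, position,
#'   reference base, per-strand observation tables (\code{base},
#'   \code{qual}) and per-strand depths after zero-quality trimming.
#' @export
pileup_column <- function(pileup, pos) {
  positions <- attr(pileup, "positions")
  if (!pos %in% positions) stop("position not in pileup: ", pos)
  idx <- which(pileup$pos == pos)
  obs <- pileup[idx]
  fwd <- obs[strand == "+", .(base, qual)]
  rev <- obs[strand == "-", .(base, qual)]
  structure(list(contig = attr(pileup, "contig"), pos = pos,
                 ref_base = unname(attr(pileup, "ref_base")[as.character(pos)]),
                 forward = fwd, reverse = rev,
                 depth_forward = nrow(fwd), depth_reverse = nrow(rev)),
            class = "pileup_column")
}

#' Per-position depth summary of a pileup
#'
#' @param pileup a \code{pileup}.
#' @return \code{data.table} with \code{pos}, \code{depth_forward},
#'   \code{depth_reverse} for every requested position (zeros included).
#' @export
pileup_depths <- function(pileup) {
  positions <- attr(pileup, "positions")
  d <- dcast(pileup[, .N, by = .(pos, strand)], pos ~ strand,
             value.var = "N", fill = 0L)
  for (cn in c("+", "-")) if (!cn %in% names(d)) d[, (cn) := 0L]
  out <- data.table(pos = positions)
  out <- merge(out, d, by = "pos", all.x = TRUE)
  setnames(out, c("+", "-"), c("depth_forward", "depth_reverse"))
  out[is.na(depth_forward), depth_forward := 0L]
  out[is.na(depth_reverse), depth_reverse := 0L]
  out[]
}

#' Export a pileup as TSV
#'
#' One row per position: contig, pos, ref, forward bases/quals, reverse
#' bases/quals (qualities Phred+33 encoded).
#'
#' @param pileup a \code{pileup}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_pileup_tsv <- function(pileup, path) {
  positions <- attr(pileup, "positions")
  refb <- attr(pileup, "ref_base")
  enc <- function(q) stri_flatten(vapply(q, function(x) intToUtf8(x + 33L),
                                         character(1)))
  rows <- pileup[, .(fb = stri_flatten(base[strand == "+"]),
                     fq = enc(qual[strand == "+"]),
                     rb = stri_flatten(base[strand == "-"]),
                     rq = enc(qual[strand == "-"])), by = pos]
  out <- merge(data.table(pos = positions,
                          contig = attr(pileup, "contig"),
                          ref = unname(refb)),
               rows, by = "pos", all.x = TRUE)
  for (cn in c("fb", "fq", "rb", "rq"))
    out[is.na(get(cn)), (cn) := ""]
  fwrite(out[, .(contig, pos, ref, fb, fq, rb, rq)], path, sep = "\t")
  invisible(path)
}

#' Scan reads for candidate variant sites
#'
#' Streams mapped, non-duplicate reads against the reference and records
#' every mismatching base with quality >= 1; positions where at least
#' \code{min_alt_obs} observations support the same non-reference base are
#' returned as candidate sites for genotyping. This is a detection
#' pre-filter only: calls are made from full pileups at the candidate
#' positions.
#'
#' @param reads an \code{aligned_reads} table.
#' @param reference contig sequences (\code{DNAStringSet} or named character).
#' @param min_alt_obs minimum same-base mismatch observations.
#' @param chunk_size reads per processing chunk.
#' @return \code{data.table} with \code{contig}, \code{pos}, \code{n_obs}
#'   (observations supporting the best-supported non-reference base).
#' @export
scan_mismatch_sites <- function(reads, reference, min_alt_obs = 2L,
                                chunk_size = 250000L) {
  out <- list()
  for (ct in unique(reads$rname)) {
    refstr <- .ref_string(reference, ct)
    rr <- reads[rname == ct & mapped & !is_duplicate & seq != "*"]
    if (!nrow(rr)) next
    simple <- stri_detect_regex(rr$cigar, "^\\d+M$")
    rs <- rr[which(simple)]
    n <- nrow(rs)
    starts <- seq.int(1L, max(n, 1L), by = chunk_size)
    for (s0 in starts) {
      if (n == 0L) break
      i2 <- min(s0 + chunk_size - 1L, n)
      idx <- s0:i2
      lens <- nchar(rs$seq[idx])
      a <- charToRaw(stri_flatten(rs$seq[idx]))
      b <- charToRaw(stri_flatten(stri_sub(refstr, rs$pos[idx],
                                           rs$end[idx])))
      mm <- which(a != b)
      if (!length(mm)) next
      cum0 <- c(0L, cumsum(lens))
      ri <- findInterval(mm - 1L, cum0)
      off <- mm - cum0[ri]
      q <- charToRaw(stri_flatten(rs$qual[idx]))[mm]
      keep <- q > as.raw(33L)                  # quality >= 1
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.table(
        contig = ct,
        pos = rs$pos[idx][ri[keep]] + off[keep] - 1L,
        alt = rawToChar(a[mm[keep]], multiple = TRUE))
    }
    # gapped reads: use the generic per-read path on their M segments
    gp <- rr[which(!simple)]
    for (i in seq_len(nrow(gp))) {
      map <- .cigar_ref_offsets(gp$cigar[i], gp$pos[i])
      if (!nrow(map)) next
      bases <- stri_sub(gp$seq[i], map$qoff, map$qoff)
      refb <- stri_sub(refstr, map$refpos, map$refpos)
      quals <- .phred_decode_cat(stri_sub(gp$qual[i], map$qoff, map$qoff))
      mmi <- which(bases != refb & quals >= 1L)
      if (length(mmi))
        out[[length(out) + 1L]] <- data.table(contig = ct,
                                              pos = map$refpos[mmi],
                                              alt = bases[mmi])
    }
  }
  if (!length(out))
    return(data.table(contig = character(), pos = integer(),
                      alt = character(), n_obs = integer()))
  cand <- rbindlist(out)[, .(n_obs = .N), by = .(contig, pos, alt)]
  cand <- cand[n_obs >= min_alt_obs & alt %chin% c("A", "C", "G", "T")]
  cand[, .(n_obs = max(n_obs)), by = .(contig, pos)][
    , .(contig, pos, n_obs)][order(contig, pos)]
}
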