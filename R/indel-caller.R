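#' Filter read pairs by insert size
#'
#' Retains reads whose absolute insert size (TLEN, the outer fragment
#' length) lies strictly inside the open interval, removing unpaired reads
#' and reads with an unmapped mate. The default interval (50, 500) keeps
#' fragments consistent with a well-behaved short-insert library, so gapped
#' alignments cannot be mimicked by anomalous pairs.
#'
#' @param reads an \code{aligned_reads} table.
#' @param interval open interval bounds (lo, hi), exclusive.
#' @return The retained subset.
#' @export
filter_by_insert <- function(reads, interval = c(50, 500)) {
  lo <- interval[1]; hi <- interval[2]
  reads[mapped & bitwAnd(flag, 1L) > 0L & bitwAnd(flag, 8L) == 0L &
          tlen != 0L & abs(tlen) > lo & abs(tlen) < hi]
}

#' Left-normalize an indel against the reference
#'
#' Shifts an insertion/deletion to its leftmost equivalent placement in
#' repeat or homopolymer context, using the standard trim-and-extend
#' procedure on the anchor-base allele representation.
#'
#' @param refstr reference contig sequence (single character string).
#' @param pos 1-based first affected reference base (deletions) or anchor
#'   base after which the sequence is inserted (insertions).
#' @param kind "insertion" or "deletion".
#' @param sequence inserted or deleted bases.
#' @return A list with normalized \code{pos}, \code{kind}, \code{sequence}.
#' @export
left_normalize_indel <- function(refstr, pos, kind, sequence) {
  len <- nchar(sequence)
  if (len == 0L) stop("empty indel sequence", call. = FALSE)
  if (kind == "deletion") {
    # deletion of ref[pos .. pos+len-1]; shift left while the base before
    # the event equals the last deleted base
    while (pos > 1L &&
           stri_sub(refstr, pos - 1L, pos - 1L) ==
             stri_sub(refstr, pos + len - 1L, pos + len - 1L)) {
      pos <- pos - 1L
    }
    list(pos = pos, kind = kind,
         sequence = stri_sub(refstr, pos, pos + len - 1L))
  } else {
    s <- sequence
    while (pos > 1L && stri_sub(refstr, pos, pos) == stri_sub(s, len, len)) {
      s <- paste0(stri_sub(refstr, pos, pos), stri_sub(s, 1L, len - 1L))
      pos <- pos - 1L
    }
    list(pos = pos, kind = kind, sequence = s)
  }
}

#' Extract insertion/deletion alignment operations from reads
#'
#' Walks the CIGAR of every gapped read and reports one row per I/D
#' operation with its reference placement: deletions span
#' \code{[start, start+len-1]}; insertions anchor at the last reference
#' base before the inserted sequence (\code{start == end}).
#'
#' @param reads an \code{aligned_reads} table.
#' @param reference contig sequences (for deletion sequences).
#' @return \code{data.table}: contig, start, end, kind, sequence, qname,
#'   strand.
#' @export
gap_events <- function(reads, reference) {
  gp <- reads[mapped & !is_duplicate & seq != "*" &
                stri_detect_regex(cigar, "[ID]")]
  if (!nrow(gp))
    return(data.table(contig = character(), start = integer(),
                      end = integer(), kind = character(),
                      sequence = character(), qname = character(),
                      strand = character()))
  out <- vector("list", nrow(gp))
  refcache <- list()
  for (i in seq_len(nrow(gp))) {
    ct <- gp$rname[i]
    if (is.null(refcache[[ct]])) refcache[[ct]] <- .ref_string(reference, ct)
    m <- stri_match_all_regex(gp$cigar[i], "(\\d+)([MIDNSHP=X])")[[1]]
    lens <- as.integer(m[, 2]); ops <- m[, 3]
    rp <- gp$pos[i]; qp <- 1L
    evs <- list()
    for (k in seq_along(ops)) {
      op <- ops[k]; n <- lens[k]
      if (op %in% c("M", "=", "X")) { rp <- rp + n; qp <- qp + n }
      else if (op %in% c("D", "N")) {
        if (op == "D")
          evs[[length(evs) + 1L]] <- data.table(
            contig = ct, start = rp, end = rp + n - 1L, kind = "deletion",
            sequence = stri_sub(refcache[[ct]], rp, rp + n - 1L),
            qname = gp$qname[i], strand = gp$strand[i])
        rp <- rp + n
      } else if (op == "I") {
        evs[[length(evs) + 1L]] <- data.table(
          contig = ct, start = rp - 1L, end = rp - 1L, kind = "insertion",
          sequence = stri_sub(gp$seq[i], qp, qp + n - 1L),
          qname = gp$qname[i], strand = gp$strand[i])
        qp <- qp + n
      } else if (op == "S") qp <- qp + n
    }
    if (length(evs)) out[[i]] <- rbindlist(evs)
  }
  res <- rbindlist(out)
  if (!nrow(res))
    return(data.table(contig = character(), start = integer(),
                      end = integer(), kind = character(),
                      sequence = character(), qname = character(),
                      strand = character()))
  res
}

#' Discover small-indel candidates from gapped tumor alignments
#'
#' Collects insertion/deletion operations from mapped, non-duplicate reads
#' (after insert-size filtering by the caller), left-normalizes each event,
#' and reports one candidate per distinct (contig, start, kind, sequence)
#' with at least \code{min_support} supporting reads.
#'
#' @param reads insert-filtered \code{aligned_reads}.
#' @param reference contig sequences.
#' @param min_support minimum supporting reads (default 2).
#' @return \code{data.table} of class \code{indel_candidates}: contig,
#'   start, end, kind, sequence, supporting_reads.
#' @export
discover_indel_candidates <- function(reads, reference, min_support = 2L) {
  ev <- gap_events(reads, reference)
  if (!nrow(ev))
    return(data.table(contig = character(), start = integer(),
                      end = integer(), kind = character(),
                      sequence = character(), supporting_reads = integer()))
  refcache <- new.env()
  norm <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    ct <- ev$contig[i]
    if (is.null(refcache[[ct]]))
      assign(ct, .ref_string(reference, ct), envir = refcache)
    nn <- left_normalize_indel(get(ct, envir = refcache),
                               ev$start[i], ev$kind[i], ev$sequence[i])
    norm[[i]] <- data.table(contig = ct, start = nn$pos, kind = nn$kind,
                            sequence = nn$sequence)
  }
  nev <- rbindlist(norm)
  cand <- nev[, .(supporting_reads = .N), by = .(contig, start, kind, sequence)]
  cand <- cand[supporting_reads >= min_support]
  cand[, end := fifelse(kind == "deletion",
                        start + nchar(sequence) - 1L, start)]
  setcolorder(cand, c("contig", "start", "end", "kind", "sequence",
                      "supporting_reads"))
  cand[order(contig, start)]
}

#' Somatic test for indel candidates against the normal sample
#'
#' For each candidate, inspects the normal-sample window extending 5 bases
#' upstream of the indel start and 5 bases downstream of its end (inclusive
#' boundaries). The candidate is somatic only when no insertion/deletion
#' alignment operation in the normal reads intersects the window; windows
#' with no overlapping normal reads are conservatively non-somatic with
#' note \code{no_normal_coverage}.
#'
#' @param candidates an \code{indel_candidates} table.
#' @param normal_reads \code{aligned_reads} for the normal sample.
#' @param reference contig sequences.
#' @param window bases added on each side (default 5).
#' @return The candidates with \code{normal_window_start/end},
#'   \code{normal_reads_in_window}, \code{normal_indel_evidence},
#'   \code{somatic} and \code{note} columns.
#' @export
indel_somatic_test <- function(candidates, normal_reads, reference,
                               window = 5L) {
  cand <- copy(as.data.table(candidates))
  if (!nrow(cand)) {
    cand[, `:=`(normal_window_start = integer(),
                normal_window_end = integer(),
                normal_reads_in_window = integer(),
                normal_indel_evidence = integer(),
                somatic = logical(), note = character())]
    return(cand[])
  }
  cand[, `:=`(normal_window_start = start - as.integer(window),
              normal_window_end = end + as.integer(window))]
  nev <- gap_events(normal_reads, reference)
  nr <- normal_reads[mapped & !is_duplicate]
  cand[, normal_reads_in_window := {
    vapply(seq_len(.N), function(i)
      nr[rname == contig[i] & pos <= normal_window_end[i] &
           end >= normal_window_start[i], .N], integer(1))
  }]
  cand[, normal_indel_evidence := {
    vapply(seq_len(.N), function(i)
      nev[contig == cand$contig[i] & start <= cand$normal_window_end[i] &
            end >= cand$normal_window_start[i], .N], integer(1))
  }]
  cand[, somatic := normal_reads_in_window > 0L & normal_indel_evidence == 0L]
  cand[, note := fifelse(normal_reads_in_window == 0L, "no_normal_coverage",
                         fifelse(somatic, "", "normal_indel_evidence"))]
  cand[]
}

#' Two-step somatic indel calling
#'
#' The full strategy: (1) tumor reads are restricted to pairs whose insert
#' size lies strictly inside \code{interval}; candidate indels are
#' discovered from the remaining gapped alignments with left
#' normalization and a minimum read support; (2) each candidate is tested
#' against the normal sample in a +/- \code{window} base region and kept as
#' somatic only when the normal shows no indel operation there.
#'
#' @param tumor_reads,normal_reads \code{aligned_reads} tables.
#' @param reference contig sequences.
#' @param interval open insert-size interval for the tumor filter.
#' @param min_support minimum tumor reads supporting a candidate.
#' @param window normal-window margin in bases.
#' @return \code{data.table} of candidates with somatic classification.
#' @export
call_somatic_indels <- function(tumor_reads, normal_reads, reference,
                                interval = c(50, 500), min_support = 2L,
                                window = 5L) {
  if (!any(tumor_reads$is_duplicate)) tumor_reads <- flag_duplicates(tumor_reads)
  if (!any(normal_reads$is_duplicate)) normal_reads <- flag_duplicates(normal_reads)
  tf <- filter_by_insert(tumor_reads, interval)
  cand <- discover_indel_candidates(tf, reference, min_support)
  indel_somatic_test(cand, normal_reads, reference, window)
}
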