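#' Read a coordinate-sorted SAM file
#'
#' Parses the text SAM format into an \code{aligned_reads} table (one row per
#' record) with derived columns: \code{strand} from FLAG bit 0x10,
#' \code{mapped} from bit 0x4, \code{is_duplicate} from bit 0x400, and
#' \code{end}, the rightmost reference base consumed by the CIGAR. Records
#' whose CIGAR query consumption disagrees with the sequence length are
#' dropped with a warning naming the offending line numbers. Optional tag
#' columns are ignored.
#'
#' @param path SAM file path (must contain a header with \code{@SQ} lines).
#' @return A \code{data.table} of class \code{aligned_reads} with attribute
#'   \code{contigs}, a named integer vector of contig lengths.
#' @export
read_sam <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !startsWith(line, "@")) break
    hdr <- c(hdr, line)
  }
  close(con); on.exit(NULL)
  if (!length(hdr))
    stop("SAM format error: missing header in ", path, call. = FALSE)
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (!length(sq))
    stop("SAM format error: header has no @SQ lines in ", path, call. = FALSE)
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  contigs <- setNames(ln, sn)

  n_header <- length(hdr)
  reads <- tryCatch(
    fread(path, skip = n_header, header = FALSE, sep = "\t", quote = "",
          fill = TRUE, select = 1:11,
          col.names = c("qname", "flag", "rname", "pos", "mapq", "cigar",
                        "rnext", "pnext", "tlen", "seq", "qual"),
          colClasses = list(character = c(1, 3, 6, 7, 10, 11),
                            integer = c(2, 4, 5, 8, 9))),
    error = function(e) {
      if (grepl("skip=", conditionMessage(e)) || file.size(path) == 0)
        data.table(qname = character(), flag = integer(), rname = character(),
                   pos = integer(), mapq = integer(), cigar = character(),
                   rnext = character(), pnext = integer(), tlen = integer(),
                   seq = character(), qual = character())
      else stop(e)
    })
  if (nrow(reads)) {
    # validate CIGAR query consumption against sequence length; CIGARs are
    # highly repetitive so parse unique strings only
    uc <- unique(reads$cigar)
    consume <- .cigar_consume(uc)
    qcons <- consume$query[match(reads$cigar, uc)]
    bad <- which(!is.na(qcons) & qcons != nchar(reads$seq) & reads$seq != "*")
    if (length(bad)) {
      warning(sprintf(
        "rejected %d malformed SAM record(s) (CIGAR/sequence length mismatch) at line(s): %s",
        length(bad),
        paste(utils::head(bad + n_header, 20), collapse = ", ")),
        call. = FALSE)
      reads <- reads[-bad]
      qcons <- qcons[-bad]
    }
    rcons <- consume$ref[match(reads$cigar, uc)]
    reads[, `:=`(strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                 mapped = bitwAnd(flag, 4L) == 0L,
                 is_duplicate = bitwAnd(flag, 1024L) > 0L,
                 end = pos + ifelse(is.na(rcons), 0L, pmax(rcons - 1L, 0L)))]
  } else {
    reads[, `:=`(strand = character(), mapped = logical(),
                 is_duplicate = logical(), end = integer())]
  }
  setattr(reads, "contigs", contigs)
  setattr(reads, "class", c("aligned_reads", class(reads)))
  reads[]
}

# query- and reference-consumption of CIGAR strings ("*" -> NA)
.cigar_consume <- function(cigars) {
  q <- integer(length(cigars)); r <- integer(length(cigars))
  star <- cigars == "*"
  q[star] <- NA_integer_; r[star] <- NA_integer_
  if (any(!star)) {
    parts <- stri_match_all_regex(cigars[!star], "(\\d+)([MIDNSHP=X])")
    qr <- vapply(parts, function(m) {
      lens <- as.integer(m[, 2]); ops <- m[, 3]
      if (any(is.na(ops)) || !nrow(m)) return(c(NA_integer_, NA_integer_))
      c(sum(lens[ops %in% c("M", "I", "S", "=", "X")]),
        sum(lens[ops %in% c("M", "D", "N", "=", "X")]))
    }, integer(2))
    q[!star] <- qr[1, ]; r[!star] <- qr[2, ]
  }
  list(query = q, ref = r)
}

#' Write an aligned_reads table as SAM
#'
#' Inverse of \code{\link{read_sam}}; the duplicate flag column is folded
#' back into FLAG bit 0x400 so that a read/write round trip is
#' record-identical.
#'
#' @param reads an \code{aligned_reads} table.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_sam <- function(reads, path) {
  contigs <- attr(reads, "contigs")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)),
           "@PG\tID:somaticpair\tPN:somaticpair")
  writeLines(hdr, path)
  out <- reads[, .(qname,
                   flag = bitwOr(bitwAnd(flag, bitwNot(1024L)),
                                 ifelse(is_duplicate, 1024L, 0L)),
                   rname, pos, mapq, cigar, rnext, pnext, tlen, seq, qual)]
  if (nrow(out))
    fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
           append = TRUE)
  invisible(path)
}

#' Flag PCR duplicate read pairs by coordinate key
#'
#' A coordinate-level stand-in for external duplicate markers: read pairs
#' sharing both mates' (contig, position, strand) are considered PCR
#' duplicates and all but the first (in coordinate order of their leftmost
#' read, ties by name) are flagged. Flagged reads carry
#' \code{is_duplicate = TRUE} (and FLAG bit 0x400 when re-written) and are
#' excluded from pileups and clone coverage downstream. Reads without a
#' mapped mate are left untouched.
#'
#' @param reads an \code{aligned_reads} table (coordinate-sorted).
#' @return The table with \code{is_duplicate} set.
#' @export
flag_duplicates <- function(reads) {
  reads[, is_duplicate := FALSE]
  sel <- reads$mapped & bitwAnd(reads$flag, 1L) > 0L &
    bitwAnd(reads$flag, 8L) == 0L &
    (reads$rnext == "=" | reads$rnext == reads$rname)
  if (any(sel)) {
    p <- reads[sel, .(qname, rname, pos, strand)]
    setorder(p, qname, pos, strand)
    p[, m := rowid(qname)]
    ab <- merge(p[m == 1L, .(qname, rname, pos1 = pos, s1 = strand)],
                p[m == 2L, .(qname, pos2 = pos, s2 = strand)],
                by = "qname")
    if (nrow(ab)) {
      ab[, key := paste(rname, pos1, s1, pos2, s2, sep = ":")]
      setorder(ab, pos1, qname)
      dup_q <- ab[duplicated(key), qname]
      if (length(dup_q)) reads[qname %chin% dup_q, is_duplicate := TRUE]
    }
  }
  reads[]
}
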