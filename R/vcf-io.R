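# Minimal VCF 4.2 text writer. rows: contig,pos,id,ref,alt,qual,filter,info
# (+ optional gt column -> FORMAT/GT sample column).
.write_vcf <- function(rows, path, contig_lengths, sample_name = NULL,
                       extra_header = character()) {
  has_gt <- "gt" %in% names(rows) && !is.null(sample_name)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=somaticpair",
           sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                   as.integer(contig_lengths)),
           "##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description=\"Somatic event\">",
           "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Event type\">",
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
           extra_header)
  if (has_gt)
    hdr <- c(hdr,
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (has_gt) cols <- c(cols, "FORMAT", sample_name)
  hdr <- c(hdr, paste(cols, collapse = "\t"))
  writeLines(hdr, path)
  if (nrow(rows)) {
    body <- if (has_gt)
      sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s\t%s\tGT\t%s",
              rows$contig, rows$pos, rows$id, rows$ref, rows$alt,
              rows$qual, rows$filter, rows$info, rows$gt)
    else
      sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s\t%s",
              rows$contig, rows$pos, rows$id, rows$ref, rows$alt,
              rows$qual, rows$filter, rows$info)
    cat(body, file = path, sep = "\n", append = TRUE)
  }
  invisible(path)
}

#' Write somatic SNV calls as VCF
#'
#' INFO carries per-strand weighted fractions and distances plus the
#' SOMATIC flag; FILTER carries the call tier.
#'
#' @param calls table of tumor-variant calls (from
#'   \code{\link{call_somatic_snvs}}; columns contig, pos, ref, alt,
#'   f_fwd, f_rev, dist_fwd, dist_rev, tier, somatic).
#' @param path output path.
#' @param contig_lengths named integer vector.
#' @return Invisibly, the path.
#' @export
write_snv_vcf <- function(calls, path, contig_lengths) {
  calls <- as.data.table(calls)
  som <- if ("somatic" %in% names(calls)) calls$somatic
         else rep(FALSE, nrow(calls))
  rows <- calls[, .(
    contig, pos, id = ".", ref, alt, qual = ".",
    filter = tier,
    info = sprintf("%sFF=%.4f;FR=%.4f;DF=%.4f;DR=%.4f;GT_TUMOR=%s",
                   fifelse(som, "SOMATIC;", ""),
                   f_fwd, f_rev, dist_fwd, dist_rev, genotype))]
  extra <- c(
    "##INFO=<ID=FF,Number=1,Type=Float,Description=\"Forward-strand weighted alt fraction\">",
    "##INFO=<ID=FR,Number=1,Type=Float,Description=\"Reverse-strand weighted alt fraction\">",
    "##INFO=<ID=DF,Number=1,Type=Float,Description=\"Forward-strand distance to called genotype\">",
    "##INFO=<ID=DR,Number=1,Type=Float,Description=\"Reverse-strand distance to called genotype\">",
    "##INFO=<ID=GT_TUMOR,Number=1,Type=String,Description=\"Tumor combined genotype\">")
  .write_vcf(rows, path, contig_lengths, extra_header = extra)
}

#' Write indel calls as VCF (anchor-base convention)
#'
#' Deletions: POS is the base before the deleted run, REF anchor+deleted,
#' ALT anchor. Insertions: POS is the anchor base, REF anchor, ALT
#' anchor+inserted.
#'
#' @param indels table with contig, start, kind, sequence, somatic (and
#'   optionally supporting_reads).
#' @param path output path.
#' @param reference contig sequences (for the anchor base; "N" if absent).
#' @param contig_lengths named integer vector.
#' @return Invisibly, the path.
#' @export
write_indel_vcf <- function(indels, path, reference = NULL, contig_lengths) {
  indels <- as.data.table(indels)
  if (!nrow(indels)) {
    return(.write_vcf(
      data.table(contig = character(), pos = integer(), id = character(),
                 ref = character(), alt = character(), qual = character(),
                 filter = character(), info = character()),
      path, contig_lengths))
  }
  anchor_pos <- fifelse(indels$kind == "deletion", indels$start - 1L,
                        indels$start)
  anchor <- rep("N", nrow(indels))
  if (!is.null(reference)) {
    for (i in seq_len(nrow(indels)))
      anchor[i] <- stri_sub(.ref_string(reference, indels$contig[i]),
                            anchor_pos[i], anchor_pos[i])
  }
  som <- if ("somatic" %in% names(indels)) indels$somatic else
    rep(TRUE, nrow(indels))
  sup <- if ("supporting_reads" %in% names(indels))
    sprintf(";SUPPORT=%d", indels$supporting_reads) else ""
  rows <- data.table(
    contig = indels$contig, pos = anchor_pos, id = ".",
    ref = fifelse(indels$kind == "deletion",
                  paste0(anchor, indels$sequence), anchor),
    alt = fifelse(indels$kind == "deletion", anchor,
                  paste0(anchor, indels$sequence)),
    qual = ".", filter = "PASS",
    info = paste0(fifelse(som, "SOMATIC;", ""), "TYPE=",
                  indels$kind, sup))
  extra <- "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">"
  .write_vcf(rows, path, contig_lengths, extra_header = extra)
}

#' Parse indel records from a VCF into candidate representation
#'
#' Inverse of \code{\link{write_indel_vcf}}: decodes anchor-base REF/ALT
#' pairs back into (contig, start, end, kind, sequence).
#'
#' @param path VCF path.
#' @return \code{data.table}: contig, start, end, kind, sequence, somatic.
#' @export
parse_indel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.table(vcfR::getFIX(v, getINFO = TRUE))
  if (!nrow(fix))
    return(data.table(contig = character(), start = integer(),
                      end = integer(), kind = character(),
                      sequence = character(), somatic = logical()))
  out <- fix[, {
    pos <- as.integer(POS)
    del <- nchar(REF) > nchar(ALT)
    kind <- ifelse(del, "deletion", "insertion")
    seq <- ifelse(del, substring(REF, nchar(ALT) + 1L),
                  substring(ALT, nchar(REF) + 1L))
    start <- ifelse(del, pos + 1L, pos)
    end <- ifelse(del, start + nchar(seq) - 1L, start)
    .(contig = CHROM, start = start, end = end, kind = kind,
      sequence = seq, somatic = grepl("SOMATIC", INFO))
  }]
  out[]
}
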