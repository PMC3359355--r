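#' Read CDS gene models from a TSV file
#'
#' Expects columns gene, contig, strand, exon_start, exon_end (1-based
#' inclusive), one row per CDS exon. Models whose total CDS length is not
#' divisible by 3, or whose exons overlap, are rejected with a warning.
#'
#' @param path TSV path.
#' @return A \code{data.table} of class \code{gene_models}.
#' @export
read_gene_models <- function(path) {
  gm <- fread(path, sep = "\t",
              colClasses = list(character = c("gene", "contig", "strand"),
                                integer = c("exon_start", "exon_end")))
  need <- c("gene", "contig", "strand", "exon_start", "exon_end")
  if (!all(need %in% names(gm)))
    stop("gene model TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  validate_gene_models(gm)
}

#' Validate (and subset) gene models
#'
#' @param gm gene model table (see \code{\link{read_gene_models}}).
#' @return The validated table, class \code{gene_models}.
#' @export
validate_gene_models <- function(gm) {
  gm <- as.data.table(gm)
  bad <- gm[, .(len = sum(exon_end - exon_start + 1L),
                overlap = {
                  o <- order(exon_start)
                  s <- exon_start[o]; e <- exon_end[o]
                  length(s) > 1L && any(s[-1] <= e[-length(e)])
                }), by = gene]
  drop <- bad[len %% 3L != 0L | overlap == TRUE, gene]
  if (length(drop)) {
    warning("rejecting gene model(s) with CDS length not divisible by 3 or overlapping exons: ",
            paste(drop, collapse = ", "), call. = FALSE)
    gm <- gm[!gene %in% drop]
  }
  setattr(gm, "class", unique(c("gene_models", class(gm))))
  gm[]
}

# one gene's exons in transcription order
.gene_exons <- function(gm, g) {
  ex <- gm[gene == g]
  if (!nrow(ex)) stop("unknown gene: ", g, call. = FALSE)
  setorder(ex, exon_start)
  if (ex$strand[1] == "-") ex <- ex[rev(seq_len(.N))]
  ex
}

#' CDS nucleotide sequence of a gene model
#'
#' Exon sequences concatenated in transcription direction;
#' reverse-complemented for minus-strand models.
#'
#' @param gm a \code{gene_models} table.
#' @param gene_name gene identifier.
#' @param reference contig sequences.
#' @return Character string (coding strand, 5' to 3').
#' @export
cds_sequence <- function(gm, gene_name, reference) {
  ex <- .gene_exons(gm, gene_name)
  refstr <- .ref_string(reference, ex$contig[1])
  if (ex$strand[1] == "+") {
    stri_flatten(stri_sub(refstr, ex$exon_start, ex$exon_end))
  } else {
    stri_flatten(.revcomp(stri_sub(refstr, ex$exon_start, ex$exon_end)))
  }
}

#' Map a genomic position onto a codon of a gene model
#'
#' The codon index counts from the CDS start in transcription direction
#' (1-based, matching codon-position reporting in validation tables);
#' minus-strand models are handled by reverse complement.
#'
#' @param gm a \code{gene_models} table.
#' @param gene_name gene identifier.
#' @param reference contig sequences.
#' @param pos genomic position (1-based).
#' @return A list: \code{coding} flag; when coding, \code{codon_index},
#'   \code{position_in_codon} (1-3), \code{ref_codon}, and \code{cds_pos}.
#' @export
map_to_codon <- function(gm, gene_name, reference, pos) {
  ex <- .gene_exons(gm, gene_name)
  minus <- ex$strand[1] == "-"
  cds_pos <- 0L
  offset <- NA_integer_
  for (i in seq_len(nrow(ex))) {
    w <- ex$exon_end[i] - ex$exon_start[i] + 1L
    if (pos >= ex$exon_start[i] && pos <= ex$exon_end[i]) {
      offset <- cds_pos + if (minus) ex$exon_end[i] - pos + 1L
                          else pos - ex$exon_start[i] + 1L
      break
    }
    cds_pos <- cds_pos + w
  }
  if (is.na(offset)) return(list(coding = FALSE))
  cds <- cds_sequence(gm, gene_name, reference)
  ci <- ((offset - 1L) %/% 3L) + 1L
  pc <- ((offset - 1L) %% 3L) + 1L
  list(coding = TRUE, codon_index = ci, position_in_codon = pc,
       ref_codon = stri_sub(cds, 3L * (ci - 1L) + 1L, 3L * ci),
       cds_pos = offset)
}

#' Substitute one base of a codon
#'
#' @param codon reference codon (3 bases).
#' @param position_in_codon 1, 2 or 3.
#' @param alt alternate base on the coding strand.
#' @return The mutated codon. Substituting the base already present is a
#'   no-op and warns.
#' @export
mutate_codon <- function(codon, position_in_codon, alt) {
  if (!position_in_codon %in% 1:3) stop("position_in_codon must be 1-3",
                                        call. = FALSE)
  cur <- stri_sub(codon, position_in_codon, position_in_codon)
  if (identical(cur, alt)) {
    warning("alternate equals reference base; codon unchanged", call. = FALSE)
    return(codon)
  }
  stri_sub(codon, position_in_codon, position_in_codon) <- alt
  codon
}

#' Translate a codon under the standard genetic code
#'
#' @param codon 3 bases over A/C/G/T (case-insensitive).
#' @return Single-letter amino acid, or "*" for a stop codon.
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon))
    stop("invalid or ambiguous codon: ", codon, call. = FALSE)
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify the protein-level effect of a codon substitution
#'
#' @param ref_codon,mut_codon reference and mutated codons.
#' @return "synonymous", "nsSNP" (missense), "nonsense" (gain of stop) or
#'   "stop_lost".
#' @export
classify_effect <- function(ref_codon, mut_codon) {
  ra <- translate_codon(ref_codon)
  ma <- translate_codon(mut_codon)
  if (ra == ma) "synonymous"
  else if (ma == "*") "nonsense"
  else if (ra == "*") "stop_lost"
  else "nsSNP"
}

#' Coding consequence of an indel
#'
#' Frameshift when the inserted/deleted length is not a multiple of 3,
#' in-frame otherwise; non-coding when the event does not touch the CDS.
#'
#' @param gm a \code{gene_models} table.
#' @param contig,start,end,sequence indel description (deletion footprint
#'   \code{[start, end]}; insertion anchor \code{start == end}).
#' @return "frameshift", "inframe_indel" or "non_coding".
#' @export
classify_indel_consequence <- function(gm, contig, start, end, sequence) {
  ct <- contig; s0 <- start; e0 <- end
  hit <- as.data.table(gm)[contig == ct & exon_start <= e0 & exon_end >= s0]
  if (!nrow(hit)) return("non_coding")
  if (nchar(sequence) %% 3L != 0L) "frameshift" else "inframe_indel"
}

#' Annotate SNVs with codon-level consequences
#'
#' Maps each variant onto the gene models (first containing model wins),
#' computes the reference and mutated codons (alternate alleles are
#' complemented for minus-strand models), translates both, and classifies
#' the effect. Variants outside every CDS are labeled non-coding.
#'
#' @param snvs \code{data.table} with contig, pos, ref, alt.
#' @param gm a \code{gene_models} table.
#' @param reference contig sequences.
#' @return The input with gene, codon_index, position_in_codon, ref_codon,
#'   mut_codon, ref_aa, mut_aa, effect columns added.
#' @export
annotate_snvs <- function(snvs, gm, reference) {
  snvs <- copy(as.data.table(snvs))
  snvs[, `:=`(gene = NA_character_, codon_index = NA_integer_,
              position_in_codon = NA_integer_, ref_codon = NA_character_,
              mut_codon = NA_character_, ref_aa = NA_character_,
              mut_aa = NA_character_, effect = "non_coding")]
  if (!nrow(snvs) || !nrow(gm)) return(snvs[])
  spans <- gm[, .(contig = contig[1], strand = strand[1],
                  start = min(exon_start), end = max(exon_end)), by = gene]
  for (i in seq_len(nrow(snvs))) {
    cand <- spans[contig == snvs$contig[i] & start <= snvs$pos[i] &
                    end >= snvs$pos[i]]
    for (g in cand$gene) {
      mp <- map_to_codon(gm, g, reference, snvs$pos[i])
      if (!mp$coding) next
      strand <- cand[gene == g, strand]
      alt_coding <- if (strand == "-") .complement_base(snvs$alt[i])
                    else snvs$alt[i]
      mut <- mutate_codon(mp$ref_codon, mp$position_in_codon, alt_coding)
      set(snvs, i, c("gene", "codon_index", "position_in_codon",
                     "ref_codon", "mut_codon", "ref_aa", "mut_aa", "effect"),
          list(g, mp$codon_index, mp$position_in_codon, mp$ref_codon, mut,
               translate_codon(mp$ref_codon), translate_codon(mut),
               classify_effect(mp$ref_codon, mut)))
      break
    }
  }
  snvs[]
}

#' Transition/transversion and known-sites summary of an SNV call set
#'
#' Transitions are A<->G and C<->T; every other substitution is a
#' transversion. The known fraction is the share of calls matching a
#' known-sites set on (contig, pos, ref, alt).
#'
#' @param snvs \code{data.table} with contig, pos, ref, alt (biallelic
#'   SNVs).
#' @param known_sites optional \code{data.table} with contig, pos, ref,
#'   alt.
#' @return A list of class \code{variant_summary}: n_snvs, n_transitions,
#'   n_transversions, titv_ratio (NA when no transversions),
#'   known_fraction.
#' @export
summary_stats <- function(snvs, known_sites = NULL) {
  snvs <- as.data.table(snvs)
  n <- nrow(snvs)
  is_ti <- (snvs$ref == "A" & snvs$alt == "G") |
    (snvs$ref == "G" & snvs$alt == "A") |
    (snvs$ref == "C" & snvs$alt == "T") |
    (snvs$ref == "T" & snvs$alt == "C")
  ti <- sum(is_ti); tv <- n - ti
  kf <- if (is.null(known_sites) || !nrow(as.data.table(known_sites)) || n == 0L) {
    0
  } else {
    ks <- unique(as.data.table(known_sites)[, .(contig, pos, ref, alt)])
    nrow(merge(unique(snvs[, .(contig, pos, ref, alt)]), ks,
               by = c("contig", "pos", "ref", "alt"))) / n
  }
  structure(list(n_snvs = n, n_transitions = ti, n_transversions = tv,
                 titv_ratio = if (tv > 0L) ti / tv else NA_real_,
                 known_fraction = kf),
            class = "variant_summary")
}

#' @export
print.variant_summary <- function(x, ...) {
  cat(sprintf("variant_summary: %d SNVs; Ti %d / Tv %d (Ti/Tv %s); known fraction %.3f\n",
              x$n_snvs, x$n_transitions, x$n_transversions,
              ifelse(is.na(x$titv_ratio), "undefined",
                     sprintf("%.2f", x$titv_ratio)), x$known_fraction))
  invisible(x)
}

#' Read a known-sites VCF into a lookup table
#'
#' @param path VCF path (plain text or gzipped).
#' @return \code{data.table} with contig, pos, ref, alt (multiallelic ALTs
#'   exploded).
#' @export
read_known_sites <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.table(vcfR::getFIX(v))
  if (!nrow(fix))
    return(data.table(contig = character(), pos = integer(),
                      ref = character(), alt = character()))
  out <- fix[, .(contig = CHROM, pos = as.integer(POS), ref = REF,
                 alt = ALT)]
  out <- out[, .(alt = unlist(strsplit(alt, ",", fixed = TRUE))),
             by = .(contig, pos, ref)]
  out[]
}
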