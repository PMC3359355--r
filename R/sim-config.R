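#' Configuration for the synthetic tumor/normal study
#'
#' Defines the conditions under which the synthetic diploid genome and its
#' paired tumor/normal read sets are generated: contig sizes, germline SNP
#' density, spiked somatic SNVs/indels with a target variant-allele fraction,
#' copy-number segments, read geometry (paired-end 100 bp, fragments around
#' 300-350 bp), per-base error and quality model, and a PCR-duplicate rate.
#'
#' The defaults are the package's reference study conditions: a 5 Mb diploid
#' genome over three contigs, germline SNPs at 1e-3/bp with a transition bias
#' giving Ti/Tv near 2.1 and 87\% of sites marked as "known", 200 somatic SNVs
#' at VAF 0.5, 30 somatic and 20 germline indels of 1-7 bp, one copy-4 gain
#' and one copy-1 loss segment, 60X tumor / 30X normal coverage.
#'
#' @param seed integer seed; identical seed + config reproduce outputs
#'   byte-identically.
#' @param contig_lengths integer vector of contig lengths (bp), each >= 10 kb.
#' @param germline_snp_rate per-bp probability of a germline SNP.
#' @param het_fraction fraction of germline SNPs that are heterozygous.
#' @param transition_prob probability that a simulated alt allele is a
#'   transition (drives the germline Ti/Tv ratio; 0.68 gives about 2.1).
#' @param known_site_fraction fraction of germline SNPs written to the
#'   known-sites VCF (a stand-in for a dbSNP-style catalogue).
#' @param n_somatic_snvs number of spiked somatic SNVs.
#' @param somatic_vaf target somatic variant-allele fraction in (0, 1].
#' @param n_somatic_indels,n_germline_indels numbers of spiked indels.
#' @param indel_size_range integer pair, inclusive size range in bp.
#' @param cnv_segments data.frame with columns contig, start, end,
#'   copy_number (1-based inclusive coordinates; tumor copy number, integer
#'   >= 0; segments must not overlap).
#' @param n_genes number of toy CDS gene models generated on the genome.
#' @param read_length read length in bp.
#' @param fragment_size_mean,fragment_size_sd fragment (insert) size
#'   distribution in bp; mean must be >= read_length.
#' @param depth_normal,depth_tumor target fold read coverage per sample.
#' @param base_error_rate i.i.d. per-base substitution error rate.
#' @param zero_quality_rate fraction of bases assigned Phred quality 0.
#' @param duplicate_rate fraction of extra PCR-duplicate pairs.
#'
#' @return An object of class \code{simulation_config} (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              contig_lengths = c(3e6, 1.5e6, 5e5),
                              germline_snp_rate = 1e-3,
                              het_fraction = 2 / 3,
                              transition_prob = 0.68,
                              known_site_fraction = 0.87,
                              n_somatic_snvs = 200L,
                              somatic_vaf = 0.5,
                              n_somatic_indels = 30L,
                              n_germline_indels = 20L,
                              indel_size_range = c(1L, 7L),
                              cnv_segments = NULL,
                              n_genes = 60L,
                              read_length = 100L,
                              fragment_size_mean = 325,
                              fragment_size_sd = 40,
                              depth_normal = 30,
                              depth_tumor = 60,
                              base_error_rate = 0.001,
                              zero_quality_rate = 0.02,
                              duplicate_rate = 0.02) {
  contig_lengths <- as.integer(contig_lengths)
  if (any(contig_lengths < 10000L))
    stop("every contig must be at least 10 kb", call. = FALSE)
  if (is.null(names(contig_lengths)))
    names(contig_lengths) <- paste0("sim", seq_along(contig_lengths))

  if (is.null(cnv_segments)) {
    cnv_segments <- .default_cnv_segments(contig_lengths)
  }
  cnv_segments <- as.data.frame(cnv_segments)
  if (!nrow(cnv_segments)) {
    cnv_segments <- data.frame(contig = character(), start = integer(),
                               end = integer(), copy_number = integer())
  }
  if (nrow(cnv_segments)) {
    need <- c("contig", "start", "end", "copy_number")
    if (!all(need %in% names(cnv_segments)))
      stop("cnv_segments needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    if (any(cnv_segments$copy_number < 0) ||
        any(cnv_segments$copy_number != round(cnv_segments$copy_number)))
      stop("tumor copy_number must be a non-negative integer", call. = FALSE)
    bad <- !(cnv_segments$contig %in% names(contig_lengths))
    if (any(bad))
      stop("cnv_segments on unknown contig(s): ",
           paste(unique(cnv_segments$contig[bad]), collapse = ", "),
           call. = FALSE)
    for (ct in unique(cnv_segments$contig)) {
      s <- cnv_segments[cnv_segments$contig == ct, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (any(s$end < s$start) ||
          any(s$end > contig_lengths[[ct]]) || any(s$start < 1))
        stop("cnv_segments out of contig bounds on ", ct, call. = FALSE)
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
        stop("cnv_segments overlap on contig ", ct, call. = FALSE)
    }
  }

  for (nm in c("germline_snp_rate", "het_fraction", "transition_prob",
               "known_site_fraction", "base_error_rate",
               "zero_quality_rate", "duplicate_rate"))
    .stopifnot_scalar_number(get(nm), nm, 0, 1)
  .stopifnot_scalar_number(somatic_vaf, "somatic_vaf", 1e-9, 1)
  if (fragment_size_mean < read_length)
    stop("fragment_size_mean must be >= read_length", call. = FALSE)
  indel_size_range <- as.integer(indel_size_range)
  if (length(indel_size_range) != 2L || indel_size_range[1] < 1L ||
      indel_size_range[2] < indel_size_range[1])
    stop("indel_size_range must be an increasing positive integer pair",
         call. = FALSE)

  cfg <- list(seed = as.integer(seed),
              contig_lengths = contig_lengths,
              germline_snp_rate = germline_snp_rate,
              het_fraction = het_fraction,
              transition_prob = transition_prob,
              known_site_fraction = known_site_fraction,
              n_somatic_snvs = as.integer(n_somatic_snvs),
              somatic_vaf = somatic_vaf,
              n_somatic_indels = as.integer(n_somatic_indels),
              n_germline_indels = as.integer(n_germline_indels),
              indel_size_range = indel_size_range,
              cnv_segments = cnv_segments,
              n_genes = as.integer(n_genes),
              read_length = as.integer(read_length),
              fragment_size_mean = fragment_size_mean,
              fragment_size_sd = fragment_size_sd,
              depth_normal = depth_normal,
              depth_tumor = depth_tumor,
              base_error_rate = base_error_rate,
              zero_quality_rate = zero_quality_rate,
              duplicate_rate = duplicate_rate)
  class(cfg) <- "simulation_config"
  cfg
}

# default CNV layout: a copy-4 gain and a copy-1 loss on the second contig
# when it is large enough, otherwise none.
.default_cnv_segments <- function(contig_lengths) {
  if (length(contig_lengths) >= 2 && contig_lengths[2] >= 1.4e6) {
    ct <- names(contig_lengths)[2]
    data.frame(contig = c(ct, ct),
               start = c(500001L, 1000001L),
               end = c(700000L, 1200000L),
               copy_number = c(4L, 1L))
  } else {
    data.frame(contig = character(), start = integer(), end = integer(),
               copy_number = integer())
  }
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config\n")
  cat(sprintf("  genome: %d contig(s), %.2f Mb total\n",
              length(x$contig_lengths), sum(x$contig_lengths) / 1e6))
  cat(sprintf("  germline SNP rate %.2g/bp; somatic: %d SNVs @ VAF %.2f, %d indels (%d-%d bp)\n",
              x$germline_snp_rate, x$n_somatic_snvs, x$somatic_vaf,
              x$n_somatic_indels, x$indel_size_range[1], x$indel_size_range[2]))
  cat(sprintf("  coverage: tumor %gX / normal %gX; reads 2x%d bp, fragments %g+/-%g bp\n",
              x$depth_tumor, x$depth_normal, x$read_length,
              x$fragment_size_mean, x$fragment_size_sd))
  cat(sprintf("  CNV segments: %d; seed %d\n", nrow(x$cnv_segments), x$seed))
  invisible(x)
}
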