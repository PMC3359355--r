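#' Simulate a diploid reference genome with germline and somatic truth sets
#'
#' Generates random contigs (approximately uniform A/C/G/T), places germline
#' SNPs and indels, spikes somatic SNVs and indels, records copy-number
#' segments, and draws toy CDS gene models. All spiked indels are stored
#' left-normalized so truth positions are canonical. Somatic positions are
#' disjoint from germline positions, and events keep a minimal distance from
#' contig ends and from each other so that every truth record is unambiguous.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param dir optional output directory; when given, writes \code{ref.fa},
#'   \code{germline.vcf}, \code{somatic_truth.vcf}, \code{known_sites.vcf},
#'   \code{cnv_truth.bed} (0-based half-open) and \code{genes.tsv}.
#' @return An object of class \code{sim_truth}: the reference
#'   (\code{Biostrings::DNAStringSet}), truth tables (\code{data.table}s) for
#'   germline SNPs/indels, somatic SNVs/indels and CNV segments, toy gene
#'   models, and the config.
#' @export
simulate_reference <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(.child_seed(config$seed, 0L))
  margin <- 1000L
  lens <- config$contig_lengths
  contigs <- names(lens)

  refs <- lapply(lens, function(L)
    stri_flatten(sample(c("A", "C", "G", "T"), L, replace = TRUE)))

  # ---- germline SNPs -------------------------------------------------------
  germ <- rbindlist(lapply(contigs, function(ct) {
    L <- lens[[ct]]
    pos <- which(runif(L) < config$germline_snp_rate)
    pos <- pos[pos > margin & pos <= L - margin]
    if (!length(pos)) return(NULL)
    ref <- stri_sub(refs[[ct]], pos, pos)
    data.table(contig = ct, pos = pos, ref = ref,
               alt = .draw_alt(ref, config$transition_prob),
               genotype = ifelse(runif(length(pos)) < config$het_fraction,
                                 "het", "hom"),
               hap = sample(1:2, length(pos), replace = TRUE),
               known = runif(length(pos)) < config$known_site_fraction)
  }))
  if (is.null(germ) || !nrow(germ))
    germ <- data.table(contig = character(), pos = integer(),
                       ref = character(), alt = character(),
                       genotype = character(), hap = integer(),
                       known = logical())

  taken <- germ[, .(contig, pos)]

  # ---- indels (germline then somatic), left-normalized ---------------------
  place_indels <- function(n, contigs_w, somatic) {
    if (n <= 0L)
      return(data.table(contig = character(), pos = integer(),
                        kind = character(), sequence = character(),
                        end = integer(), hap = integer(), vaf = numeric()))
    out <- vector("list", n)
    got <- 0L; tries <- 0L
    while (got < n && tries < n * 200L) {
      tries <- tries + 1L
      ct <- sample(contigs, 1L, prob = lens / sum(lens))
      L <- lens[[ct]]
      size <- sample(seq(config$indel_size_range[1],
                         config$indel_size_range[2]), 1L)
      kind <- sample(c("insertion", "deletion"), 1L)
      p <- sample.int(L - 2L * margin, 1L) + margin
      seq <- if (kind == "deletion") stri_sub(refs[[ct]], p, p + size - 1L)
             else stri_flatten(sample(c("A", "C", "G", "T"), size,
                                      replace = TRUE))
      ev <- left_normalize_indel(refs[[ct]], p, kind, seq)
      end <- if (kind == "deletion") ev$pos + size - 1L else ev$pos
      # keep clear of other indels (normal-window rule spans +/-5) and margins
      if (ev$pos <= margin || end >= L - margin) next
      near <- .indel_env$placed[contig == ct &
                                  abs(pos - ev$pos) < 25L]
      if (nrow(near)) next
      got <- got + 1L
      row <- data.table(contig = ct, pos = ev$pos, kind = kind,
                        sequence = ev$sequence, end = end,
                        hap = sample(1:2, 1L),
                        vaf = if (somatic) config$somatic_vaf else NA_real_)
      out[[got]] <- row
      .indel_env$placed <- rbind(.indel_env$placed,
                                 row[, .(contig, pos)])
    }
    rbindlist(out[seq_len(got)])
  }
  .indel_env <- new.env()
  .indel_env$placed <- data.table(contig = character(), pos = integer())
  germ_indels <- place_indels(config$n_germline_indels, lens, somatic = FALSE)
  som_indels <- place_indels(config$n_somatic_indels, lens, somatic = TRUE)

  indel_footprint <- rbind(germ_indels[, .(contig, pos, end)],
                           som_indels[, .(contig, pos, end)])

  # ---- somatic SNVs: disjoint from germline sites and indel footprints -----
  som <- {
    n <- config$n_somatic_snvs
    out <- vector("list", n); got <- 0L; tries <- 0L
    while (got < n && tries < n * 200L) {
      tries <- tries + 1L
      ct <- sample(contigs, 1L, prob = lens / sum(lens))
      L <- lens[[ct]]
      p <- sample.int(L - 2L * margin, 1L) + margin
      if (nrow(taken[contig == ct & pos == p])) next
      if (nrow(indel_footprint[contig == ct & p >= pos - 10L &
                                 p <= end + 10L])) next
      got <- got + 1L
      ref <- stri_sub(refs[[ct]], p, p)
      out[[got]] <- data.table(contig = ct, pos = p, ref = ref,
                               alt = .draw_alt(ref, config$transition_prob),
                               vaf = config$somatic_vaf)
      taken <- rbind(taken, data.table(contig = ct, pos = p))
    }
    rbindlist(out[seq_len(got)])
  }
  if (!nrow(som))
    som <- data.table(contig = character(), pos = integer(),
                      ref = character(), alt = character(), vaf = numeric())

  genes <- .simulate_gene_models(refs, lens, config$n_genes, margin)

  truth <- structure(list(
    reference = Biostrings::DNAStringSet(
      setNames(unlist(refs), contigs)),
    ref_strings = refs,
    germline_snps = germ[order(contig, pos)],
    germline_indels = germ_indels[order(contig, pos)],
    somatic_snvs = som[order(contig, pos)],
    somatic_indels = som_indels[order(contig, pos)],
    cnv_segments = as.data.table(config$cnv_segments),
    gene_models = genes,
    config = config), class = "sim_truth")

  if (!is.null(dir)) write_sim_truth(truth, dir)
  truth
}

# alt allele with a configurable transition bias
.draw_alt <- function(ref, transition_prob) {
  ti <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"),
             C = c("A", "G"), T = c("A", "G"))
  is_ti <- runif(length(ref)) < transition_prob
  out <- character(length(ref))
  out[is_ti] <- ti[ref[is_ti]]
  if (any(!is_ti))
    out[!is_ti] <- vapply(ref[!is_ti], function(b) sample(tv[[b]], 1L),
                          character(1))
  out
}

# toy CDS models: 1-3 exons, total length a multiple of 3
.simulate_gene_models <- function(refs, lens, n_genes, margin) {
  if (n_genes <= 0L)
    return(data.table(gene = character(), contig = character(),
                      strand = character(), exon_start = integer(),
                      exon_end = integer()))
  out <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    ct <- sample(names(lens), 1L, prob = lens / sum(lens))
    L <- lens[[ct]]
    n_ex <- sample(1:3, 1L)
    ex_len <- 3L * sample(40:200, n_ex, replace = TRUE)
    gaps <- sample(100:1000, n_ex)
    span <- sum(ex_len) + sum(gaps[-1] * (n_ex > 1))
    start <- sample.int(max(L - 2L * margin - span, 1L), 1L) + margin
    starts <- integer(n_ex); ends <- integer(n_ex)
    cur <- start
    for (i in seq_len(n_ex)) {
      starts[i] <- cur
      ends[i] <- cur + ex_len[i] - 1L
      cur <- ends[i] + gaps[i] + 1L
    }
    out[[g]] <- data.table(gene = sprintf("G%03d", g), contig = ct,
                           strand = sample(c("+", "-"), 1L),
                           exon_start = starts, exon_end = ends)
  }
  rbindlist(out)
}

#' Write a sim_truth object to disk
#'
#' Writes the reference FASTA, truth VCFs (germline, somatic, known sites),
#' the CNV truth BED (0-based half-open) and the toy gene models TSV.
#'
#' @param truth a \code{sim_truth}.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named vector of the written paths.
#' @export
write_sim_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ref = file.path(dir, "ref.fa"),
             germline = file.path(dir, "germline.vcf"),
             somatic = file.path(dir, "somatic_truth.vcf"),
             known = file.path(dir, "known_sites.vcf"),
             cnv = file.path(dir, "cnv_truth.bed"),
             genes = file.path(dir, "genes.tsv"))
  Biostrings::writeXStringSet(truth$reference, paths[["ref"]], width = 80L)

  lens <- truth$config$contig_lengths
  gs <- copy(truth$germline_snps)
  gs[, `:=`(id = ".", qual = ".", filter = "PASS",
            info = paste0("TYPE=germline_snp"),
            gt = ifelse(genotype == "het", "0/1", "1/1"))]
  gi <- .indel_vcf_rows(truth$germline_indels, truth$ref_strings,
                        info = "TYPE=germline_indel")
  if (nrow(gi)) gi[, gt := "0/1"]
  germ_rows <- rbind(
    gs[, .(contig, pos, id, ref, alt, qual, filter, info, gt)],
    gi[, .(contig, pos, id, ref, alt, qual, filter, info, gt)])
  .write_vcf(germ_rows[order(contig, pos)], paths[["germline"]], lens,
             sample_name = "NORMAL")

  ss <- copy(truth$somatic_snvs)
  if (nrow(ss))
    ss[, `:=`(id = ".", qual = ".", filter = "PASS",
              info = sprintf("SOMATIC;TYPE=somatic_snv;VAF=%g", vaf),
              gt = "0/1")]
  si <- .indel_vcf_rows(truth$somatic_indels, truth$ref_strings,
                        info = "SOMATIC;TYPE=somatic_indel")
  if (nrow(si)) si[, gt := "0/1"]
  som_rows <- rbind(
    if (nrow(ss)) ss[, .(contig, pos, id, ref, alt, qual, filter, info, gt)]
    else NULL,
    if (nrow(si)) si[, .(contig, pos, id, ref, alt, qual, filter, info, gt)]
    else NULL)
  if (is.null(som_rows))
    som_rows <- data.table(contig = character(), pos = integer(),
                           id = character(), ref = character(),
                           alt = character(), qual = character(),
                           filter = character(), info = character(),
                           gt = character())
  .write_vcf(som_rows[order(contig, pos)], paths[["somatic"]], lens,
             sample_name = "TUMOR")

  kn <- truth$germline_snps[known == TRUE,
                            .(contig, pos, id = ".", ref, alt, qual = ".",
                              filter = "PASS", info = ".")]
  .write_vcf(kn, paths[["known"]], lens)

  cnv <- truth$cnv_segments
  bed <- if (nrow(cnv))
    sprintf("%s\t%d\t%d\tCN%d\t%d", cnv$contig, cnv$start - 1L, cnv$end,
            cnv$copy_number, cnv$copy_number)
  else character()
  writeLines(bed, paths[["cnv"]])

  fwrite(truth$gene_models, paths[["genes"]], sep = "\t")
  invisible(paths)
}

# anchor-base VCF encoding of indel truth rows
.indel_vcf_rows <- function(indels, refs, info) {
  if (!nrow(indels))
    return(data.table(contig = character(), pos = integer(),
                      id = character(), ref = character(),
                      alt = character(), qual = character(),
                      filter = character(), info = character()))
  rows <- copy(indels)
  rows[, anchor_pos := ifelse(kind == "deletion", pos - 1L, pos)]
  rows[, anchor := mapply(function(ct, p) stri_sub(refs[[ct]], p, p),
                          contig, anchor_pos)]
  rows[, `:=`(
    vref = ifelse(kind == "deletion", paste0(anchor, sequence), anchor),
    valt = ifelse(kind == "deletion", anchor, paste0(anchor, sequence)))]
  rows[, .(contig, pos = anchor_pos, id = ".", ref = vref, alt = valt,
           qual = ".", filter = "PASS", info = info)]
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth\n")
  cat(sprintf("  reference: %d contig(s), %.2f Mb\n",
              length(x$reference), sum(x$config$contig_lengths) / 1e6))
  cat(sprintf("  germline: %d SNPs, %d indels; somatic: %d SNVs, %d indels; CNV segments: %d\n",
              nrow(x$germline_snps), nrow(x$germline_indels),
              nrow(x$somatic_snvs), nrow(x$somatic_indels),
              nrow(x$cnv_segments)))
  invisible(x)
}
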