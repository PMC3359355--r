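#' Assemble a pipeline run configuration
#'
#' Either simulated inputs (a \code{\link{simulation_config}}) or paths to
#' existing reference/tumor/normal/gene-model/known-site files, plus the
#' caller, indel and copy-number parameters and the output directory.
#'
#' @param out_dir output directory.
#' @param simulate a \code{simulation_config}, or NULL to use the paths.
#' @param reference,tumor,normal,genes,known_sites input paths (ignored
#'   when \code{simulate} is given).
#' @param thresholds a \code{\link{caller_thresholds}}.
#' @param indel_interval open insert-size interval for the indel filter.
#' @param indel_min_support,indel_window indel caller parameters.
#' @param cnv_window_size,cnv_gain_thr,cnv_loss_thr,cnv_min_windows
#'   copy-number parameters.
#' @param presence_matrix path to a longitudinal codon matrix TSV (default:
#'   the packaged fixture).
#' @param seed integer seed for the simulation stage.
#' @return A \code{run_config} list.
#' @export
run_config <- function(out_dir,
                       simulate = simulation_config(),
                       reference = NULL, tumor = NULL, normal = NULL,
                       genes = NULL, known_sites = NULL,
                       thresholds = caller_thresholds(),
                       indel_interval = c(50, 500),
                       indel_min_support = 2L,
                       indel_window = 5L,
                       cnv_window_size = 2000L,
                       cnv_gain_thr = 0.3, cnv_loss_thr = -0.3,
                       cnv_min_windows = 3L,
                       presence_matrix = presence_matrix_path(),
                       seed = NULL) {
  if (is.null(simulate)) {
    for (p in c(reference, tumor, normal))
      if (is.null(p) || !file.exists(p))
        stop("config error: missing input file: ",
             if (is.null(p)) "(unset)" else p, call. = FALSE)
  } else {
    stopifnot(inherits(simulate, "simulation_config"))
    if (!is.null(seed)) simulate$seed <- as.integer(seed)
  }
  structure(list(out_dir = out_dir, simulate = simulate,
                 reference = reference, tumor = tumor, normal = normal,
                 genes = genes, known_sites = known_sites,
                 thresholds = thresholds,
                 indel_interval = indel_interval,
                 indel_min_support = as.integer(indel_min_support),
                 indel_window = as.integer(indel_window),
                 cnv_window_size = as.integer(cnv_window_size),
                 cnv_gain_thr = cnv_gain_thr, cnv_loss_thr = cnv_loss_thr,
                 cnv_min_windows = as.integer(cnv_min_windows),
                 presence_matrix = presence_matrix),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys mirror \code{\link{run_config}} arguments
#'   (nested \code{simulate} and \code{thresholds} maps are expanded).
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulate)) {
    if (!is.null(y$simulate$cnv_segments))
      y$simulate$cnv_segments <- rbindlist(lapply(y$simulate$cnv_segments,
                                                  as.data.table))
    do.call(simulation_config, y$simulate)
  } else NULL
  th <- if (!is.null(y$thresholds)) do.call(caller_thresholds, y$thresholds)
        else caller_thresholds()
  args <- y[setdiff(names(y), c("simulate", "thresholds"))]
  do.call(run_config, c(args, list(simulate = sim, thresholds = th)))
}

#' Run the full somatic pipeline
#'
#' simulate (optional) -> read/flag alignments -> somatic SNV calling ->
#' somatic indel calling -> clone-coverage copy number -> coding
#' annotation and summary statistics -> acquisition timeline -> genome
#' summary JSON + manifest. Re-running with the same config and seed
#' reproduces every output byte-identically.
#'
#' @param config a \code{\link{run_config}}.
#' @param quiet suppress stage messages.
#' @return A \code{genome_summary} list (invisibly written as JSON too).
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(f) file.path(config$out_dir, f)

  # ---- stage: inputs -------------------------------------------------------
  if (!is.null(config$simulate)) {
    say("[simulate] seed %d, %.2f Mb genome",
        config$simulate$seed, sum(config$simulate$contig_lengths) / 1e6)
    truth <- simulate_study(config$simulate, config$out_dir)
    paths <- attr(truth, "paths")
    ref <- truth$reference
    gm <- validate_gene_models(truth$gene_models)
    known <- truth$germline_snps[known == TRUE,
                                 .(contig, pos, ref, alt)]
    tumor_path <- paths[["tumor"]]; normal_path <- paths[["normal"]]
  } else {
    ref <- Biostrings::readDNAStringSet(config$reference)
    names(ref) <- sub("\\s.*", "", names(ref))
    gm <- if (!is.null(config$genes)) read_gene_models(config$genes)
          else data.table(gene = character(), contig = character(),
                          strand = character(), exon_start = integer(),
                          exon_end = integer())
    known <- if (!is.null(config$known_sites))
      read_known_sites(config$known_sites) else NULL
    tumor_path <- config$tumor; normal_path <- config$normal
    truth <- NULL
  }
  contig_lengths <- setNames(Biostrings::width(ref), names(ref))

  say("[read] tumor %s / normal %s", tumor_path, normal_path)
  tumor <- flag_duplicates(read_sam(tumor_path))
  normal <- flag_duplicates(read_sam(normal_path))
  say("[read] %d tumor / %d normal records (%d / %d flagged duplicate)",
      nrow(tumor), nrow(normal), sum(tumor$is_duplicate),
      sum(normal$is_duplicate))

  # ---- stage: somatic SNVs -------------------------------------------------
  norm_cand <- scan_mismatch_sites(normal, ref)
  snv <- call_somatic_snvs(tumor, normal, ref,
                           thresholds = config$thresholds,
                           extra_sites = norm_cand[, .(contig, pos)])
  say("[snv] %d candidate loci; %d tumor variants; %d somatic",
      nrow(snv$normal_calls), nrow(snv$all_tumor_variants),
      nrow(snv$somatic))
  write_snv_vcf(snv$all_tumor_variants, od("somatic_snvs.vcf"),
                contig_lengths)

  germline <- snv$normal_calls[!is.na(genotype) &
                                 genotype %chin% c("het", "hom_alt") &
                                 tier == "high_quality"]
  stats <- summary_stats(germline[, .(contig, pos, ref, alt)], known)
  say("[snv] germline: %d calls, Ti/Tv %.2f, known fraction %.3f",
      stats$n_snvs, stats$titv_ratio, stats$known_fraction)

  # ---- stage: somatic indels ----------------------------------------------
  indels <- call_somatic_indels(tumor, normal, ref,
                                interval = config$indel_interval,
                                min_support = config$indel_min_support,
                                window = config$indel_window)
  say("[indel] %d candidates, %d somatic", nrow(indels),
      sum(indels$somatic))
  write_indel_vcf(indels, od("somatic_indels.vcf"), ref, contig_lengths)

  # ---- stage: copy number --------------------------------------------------
  cnv <- call_cnv(tumor, normal, contig_lengths,
                  window_size = config$cnv_window_size,
                  gain_thr = config$cnv_gain_thr,
                  loss_thr = config$cnv_loss_thr,
                  min_windows = config$cnv_min_windows)
  say("[cnv] insert %.0f +/- %.0f; mode coverage %d; %d segments (%d gain, %d loss)",
      cnv$tumor_clones$insert_mean, cnv$tumor_clones$insert_sd,
      attr(cnv$tumor_track, "mode_coverage"), nrow(cnv$segments),
      sum(cnv$segments$call == "gain"), sum(cnv$segments$call == "loss"))
  fwrite(cnv$ratios[, .(contig, start = window_start - 1L,
                        end = window_end, log2_ratio)],
         od("cnv_log2.bedGraph"), sep = "\t", col.names = FALSE)
  fwrite(cnv$segments, od("cnv_segments.tsv"), sep = "\t")
  gene_cnv <- if (nrow(gm))
    genes_in_segments(cnv$segments, gm)
  else list(gained = character(), lost = character())

  # ---- stage: annotation ---------------------------------------------------
  ann <- annotate_snvs(snv$somatic[, .(contig, pos, ref, alt)], gm, ref)
  if (nrow(indels)) {
    indels[, consequence := vapply(seq_len(.N), function(i)
      classify_indel_consequence(gm, contig[i], start[i], end[i],
                                 sequence[i]), character(1))]
  }
  say("[annotate] %d somatic SNVs: %d coding (%d nsSNP, %d synonymous, %d nonsense)",
      nrow(ann), sum(ann$effect != "non_coding"),
      sum(ann$effect == "nsSNP"), sum(ann$effect == "synonymous"),
      sum(ann$effect == "nonsense"))
  fwrite(ann, od("somatic_snvs_annotated.tsv"), sep = "\t")

  # ---- stage: timeline -----------------------------------------------------
  timeline <- NULL
  if (!is.null(config$presence_matrix) &&
      file.exists(config$presence_matrix)) {
    pm <- load_presence_matrix(config$presence_matrix)
    timeline <- timeline_report(pm, od("timeline.json"))
    say("[timeline] %d sites: %d at diagnosis, %d acquired",
        pm$sites[, .N], length(timeline$present_at_diagnosis),
        length(timeline$acquired))
  }

  # ---- genome summary + manifest ------------------------------------------
  per_contig <- data.table(contig = names(contig_lengths))
  sc <- snv$somatic[, .(somatic_snvs = .N), by = contig]
  ic <- indels[somatic == TRUE, .(somatic_indels = .N), by = contig]
  gc_ <- cnv$segments[call == "gain", .(gain_segments = .N), by = contig]
  lc <- cnv$segments[call == "loss", .(loss_segments = .N), by = contig]
  for (x in list(sc, ic, gc_, lc))
    per_contig <- merge(per_contig, x, by = "contig", all.x = TRUE)
  for (cn in setdiff(names(per_contig), "contig"))
    per_contig[is.na(get(cn)), (cn) := 0L]

  summary <- list(
    per_contig = per_contig,
    n_somatic_snvs = nrow(snv$somatic),
    n_somatic_indels = sum(indels$somatic),
    germline_stats = unclass(stats),
    gained_genes = gene_cnv$gained,
    lost_genes = gene_cnv$lost,
    timeline = timeline)
  # cross-check assembled counts against the underlying call lists
  stopifnot(sum(per_contig$somatic_snvs) == nrow(snv$somatic),
            sum(per_contig$somatic_indels) == sum(indels$somatic))
  jsonlite::write_json(summary, od("genome_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null",
                       digits = NA)

  outputs <- sort(setdiff(list.files(config$out_dir, recursive = TRUE),
                          "manifest.json"))
  manifest <- data.table(file = outputs,
                         md5 = .md5(file.path(config$out_dir, outputs)),
                         bytes = file.size(file.path(config$out_dir,
                                                     outputs)))
  jsonlite::write_json(manifest, od("manifest.json"), pretty = TRUE,
                       digits = NA)
  say("[done] %d outputs in %s (%.1f s)", nrow(manifest), config$out_dir,
      as.numeric(difftime(Sys.time(), t0, units = "secs")))

  invisible(structure(c(summary,
                        list(manifest = manifest, snv = snv,
                             indels = indels, cnv = cnv,
                             annotated = ann, truth = truth)),
                      class = "genome_summary"))
}
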