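#' Extract clone (fragment) intervals from paired alignments
#'
#' A clone is the interval covered by a sequenced fragment: both mates plus
#' the unsequenced interlying region, from the leftmost to the rightmost
#' mapped base of the pair. Unmapped reads, reads with unmapped mates,
#' duplicates, and pairs whose insert size lies outside mean +/- 2 SD of
#' the estimated insert distribution are excluded.
#'
#' @param reads an \code{aligned_reads} table (coordinate-sorted, paired).
#' @param min_pairs refuse to estimate insert statistics below this many
#'   proper pairs (default 100).
#' @param n_sd exclusion width in standard deviations (default 2).
#' @return A list of class \code{clone_set}: \code{clones} (contig, start,
#'   end), \code{insert_mean}, \code{insert_sd}, \code{n_used},
#'   \code{n_excluded}.
#' @export
extract_clones <- function(reads, min_pairs = 100L, n_sd = 2) {
  rep_reads <- reads[mapped & !is_duplicate & bitwAnd(flag, 1L) > 0L &
                       bitwAnd(flag, 8L) == 0L & tlen > 0L &
                       (rnext == "=" | rnext == rname)]
  if (nrow(rep_reads) < min_pairs)
    stop(sprintf("too few proper pairs (%d < %d) to estimate insert statistics",
                 nrow(rep_reads), min_pairs), call. = FALSE)
  m <- mean(rep_reads$tlen); s <- stats::sd(rep_reads$tlen)
  keep <- rep_reads$tlen >= m - n_sd * s & rep_reads$tlen <= m + n_sd * s
  clones <- rep_reads[keep, .(contig = rname, start = pos,
                              end = pos + tlen - 1L)]
  structure(list(clones = clones, insert_mean = m, insert_sd = s,
                 n_used = nrow(clones), n_excluded = sum(!keep)),
            class = "clone_set")
}

#' Windowed, mode-normalized clone coverage
#'
#' Computes per-base clone depth by interval accumulation, averages it over
#' non-overlapping windows (default 2 kb; a final partial window is kept
#' when it spans at least half the window size), determines the genome-wide
#' mode of the integer per-base depth over covered bases (ties broken
#' toward the smaller depth), and normalizes window means by that mode so
#' tracks are invariant to global depth scaling.
#'
#' @param clone_set a \code{\link{extract_clones}} result, or a
#'   \code{data.table(contig, start, end)} of clone intervals.
#' @param contig_lengths named integer vector of contig lengths.
#' @param window_size window in bp (default 2000).
#' @return A \code{data.table} of class \code{coverage_track}: contig,
#'   window_start, window_end, mean_cov, norm; attribute
#'   \code{mode_coverage}.
#' @export
clone_coverage_track <- function(clone_set, contig_lengths,
                                 window_size = 2000L) {
  window_size <- as.integer(window_size)
  if (window_size <= 0L) stop("window_size must be positive", call. = FALSE)
  clones <- if (inherits(clone_set, "clone_set")) clone_set$clones
            else as.data.table(clone_set)
  depth_tab <- integer(0)       # pooled histogram of per-base depths
  tracks <- vector("list", length(contig_lengths))
  for (ci in seq_along(contig_lengths)) {
    ct <- names(contig_lengths)[ci]
    L <- contig_lengths[[ci]]
    cl <- clones[contig == ct]
    starts <- pmax(1L, pmin(cl$start, L))
    ends <- pmax(1L, pmin(cl$end, L))
    delta <- tabulate(starts, L)
    dec <- tabulate(ends[ends < L] + 1L, L)
    depth <- cumsum(delta - dec)
    tb <- tabulate(depth[depth > 0L])
    if (length(tb) > length(depth_tab)) {
      tb[seq_along(depth_tab)] <- tb[seq_along(depth_tab)] + depth_tab
      depth_tab <- tb
    } else if (length(tb)) {
      depth_tab[seq_along(tb)] <- depth_tab[seq_along(tb)] + tb
    }
    n_full <- L %/% window_size
    rem <- L - n_full * window_size
    keep_partial <- rem >= window_size / 2
    n_win <- n_full + as.integer(keep_partial)
    if (n_win == 0L) next
    ws <- (seq_len(n_win) - 1L) * window_size + 1L
    we <- pmin(ws + window_size - 1L, L)
    cs <- c(0, cumsum(as.numeric(depth)))
    means <- (cs[we + 1L] - cs[ws]) / (we - ws + 1L)
    tracks[[ci]] <- data.table(contig = ct, window_start = ws,
                               window_end = we, mean_cov = means)
  }
  track <- rbindlist(tracks)
  mode_cov <- if (length(depth_tab)) which.max(depth_tab) else 0L
  if (mode_cov <= 0L)
    stop("mode coverage is zero; genome not callable", call. = FALSE)
  track[, norm := mean_cov / mode_cov]
  setattr(track, "mode_coverage", as.integer(mode_cov))
  setattr(track, "window_size", window_size)
  setattr(track, "class", c("coverage_track", class(track)))
  track[]
}

#' Per-window log2 relative copy number
#'
#' \code{log2((tumor_norm + pseudocount) / (normal_norm + pseudocount))},
#' positive for tumor gains. Windows whose normal normalized coverage falls
#' below a callability floor are masked (NA).
#'
#' @param tumor_track,normal_track \code{coverage_track}s over the same
#'   tiling.
#' @param pseudocount stabilizer added to both normalized coverages.
#' @param min_normal_norm callability floor on the normal normalized
#'   coverage (default 0.1).
#' @return \code{data.table}: contig, window_start, window_end,
#'   tumor_norm, normal_norm, log2_ratio.
#' @export
log2_relative <- function(tumor_track, normal_track, pseudocount = 0.01,
                          min_normal_norm = 0.1) {
  if (nrow(tumor_track) != nrow(normal_track) ||
      !all(tumor_track$contig == normal_track$contig) ||
      !all(tumor_track$window_start == normal_track$window_start))
    stop("tiling mismatch between tumor and normal tracks", call. = FALSE)
  out <- tumor_track[, .(contig, window_start, window_end,
                         tumor_norm = norm)]
  out[, normal_norm := normal_track$norm]
  out[, log2_ratio := log2((tumor_norm + pseudocount) /
                             (normal_norm + pseudocount))]
  out[normal_norm < min_normal_norm, log2_ratio := NA_real_]
  out[]
}

#' Threshold run-length segmentation of log2 ratios
#'
#' Windows are labeled gain/loss/neutral by fixed thresholds; maximal runs
#' of at least \code{min_windows} consecutive gain or loss windows become
#' segments, shorter runs are folded into the surrounding neutral state.
#' Masked (NA) windows are treated as neutral.
#'
#' @param ratios output of \code{\link{log2_relative}}.
#' @param gain_thr,loss_thr log2 thresholds (defaults +0.3 / -0.3).
#' @param min_windows minimum consecutive windows (default 3).
#' @return \code{data.table} of class \code{cnv_segments}: contig, start,
#'   end, call, n_windows, mean_log2.
#' @export
segment_and_call <- function(ratios, gain_thr = 0.3, loss_thr = -0.3,
                             min_windows = 3L) {
  segs <- list()
  for (ct in unique(ratios$contig)) {
    r <- ratios[contig == ct]
    state <- rep("neutral", nrow(r))
    state[!is.na(r$log2_ratio) & r$log2_ratio >= gain_thr] <- "gain"
    state[!is.na(r$log2_ratio) & r$log2_ratio <= loss_thr] <- "loss"
    rl <- rle(state)
    rl$values[rl$values != "neutral" & rl$lengths < min_windows] <- "neutral"
    state <- inverse.rle(rl)
    rl <- rle(state)
    idx_end <- cumsum(rl$lengths)
    idx_start <- idx_end - rl$lengths + 1L
    segs[[ct]] <- data.table(
      contig = ct,
      start = r$window_start[idx_start],
      end = r$window_end[idx_end],
      call = rl$values,
      n_windows = rl$lengths,
      mean_log2 = vapply(seq_along(rl$values), function(k)
        mean(r$log2_ratio[idx_start[k]:idx_end[k]], na.rm = TRUE),
        numeric(1)))
  }
  out <- rbindlist(segs)
  setattr(out, "class", c("cnv_segments", class(out)))
  out[]
}

#' Intersect gene models with gain/loss segments
#'
#' A gene is reported gained (lost) when at least \code{min_overlap_frac}
#' of its genomic span overlaps gain (loss) segments.
#'
#' @param segments a \code{cnv_segments} table.
#' @param genes \code{data.frame} with gene, contig, and either start/end
#'   columns or exon_start/exon_end rows (the gene span is used).
#' @param min_overlap_frac minimum overlapping fraction of the gene length
#'   (default 0.5).
#' @return A list with \code{gained} and \code{lost} character vectors and
#'   the per-gene overlap table.
#' @export
genes_in_segments <- function(segments, genes, min_overlap_frac = 0.5) {
  genes <- as.data.table(genes)
  if (!"start" %in% names(genes) && "exon_start" %in% names(genes))
    genes <- genes[, .(start = min(exon_start), end = max(exon_end)),
                   by = .(gene, contig)]
  missing_ct <- setdiff(unique(genes$contig), unique(segments$contig))
  if (length(missing_ct))
    stop("contig name mismatch; gene contigs not in segments: ",
         paste(missing_ct, collapse = ", "), call. = FALSE)
  gr_genes <- GenomicRanges::GRanges(genes$contig,
                                     IRanges::IRanges(genes$start, genes$end))
  res <- data.table(gene = genes$gene, contig = genes$contig,
                    gain_frac = 0, loss_frac = 0)
  for (what in c("gain", "loss")) {
    seg <- segments[call == what]
    if (!nrow(seg)) next
    gr_seg <- GenomicRanges::reduce(GenomicRanges::GRanges(
      seg$contig, IRanges::IRanges(seg$start, seg$end)))
    ov <- GenomicRanges::findOverlaps(gr_genes, gr_seg)
    if (!length(ov)) next
    inter_w <- GenomicRanges::width(GenomicRanges::pintersect(
      gr_genes[S4Vectors::queryHits(ov)], gr_seg[S4Vectors::subjectHits(ov)]))
    agg <- data.table(q = S4Vectors::queryHits(ov), w = inter_w)[
      , .(w = sum(w)), by = q]
    frac <- agg$w / GenomicRanges::width(gr_genes)[agg$q]
    if (what == "gain") res$gain_frac[agg$q] <- frac
    else res$loss_frac[agg$q] <- frac
  }
  list(gained = res[gain_frac >= min_overlap_frac, gene],
       lost = res[loss_frac >= min_overlap_frac, gene],
       table = res[])
}

#' Paired tumor/normal copy-number calling
#'
#' Clone extraction for both samples, mode-normalized 2 kb coverage tracks,
#' per-window log2 tumor:normal ratios, and run-length segmentation.
#'
#' @param tumor_reads,normal_reads \code{aligned_reads} tables.
#' @param contig_lengths named integer vector.
#' @param window_size window in bp.
#' @param gain_thr,loss_thr,min_windows segmentation parameters.
#' @return A list of class \code{cnv_result}: clone sets, tracks, ratios,
#'   segments.
#' @export
call_cnv <- function(tumor_reads, normal_reads, contig_lengths,
                     window_size = 2000L, gain_thr = 0.3, loss_thr = -0.3,
                     min_windows = 3L) {
  if (!any(tumor_reads$is_duplicate)) tumor_reads <- flag_duplicates(tumor_reads)
  if (!any(normal_reads$is_duplicate)) normal_reads <- flag_duplicates(normal_reads)
  tc <- extract_clones(tumor_reads)
  nc <- extract_clones(normal_reads)
  tt <- clone_coverage_track(tc, contig_lengths, window_size)
  nt <- clone_coverage_track(nc, contig_lengths, window_size)
  ratios <- log2_relative(tt, nt)
  segments <- segment_and_call(ratios, gain_thr, loss_thr, min_windows)
  structure(list(tumor_clones = tc, normal_clones = nc,
                 tumor_track = tt, normal_track = nt,
                 ratios = ratios, segments = segments),
            class = "cnv_result")
}
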