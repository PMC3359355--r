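#' Caller thresholds
#'
#' Thresholds for the per-strand quality-weighted genotype caller. The
#' strict distance bound gates high-quality calls (both strands must agree
#' within it); the lenient bound gates the variant-consensus tier, which
#' rescues true variants whose per-strand allele fractions fluctuate, at the
#' price of requiring a minimum number of alternate observations on each
#' strand.
#'
#' @param strict_max_distance maximum per-strand distance for a
#'   high-quality call (default 0.15).
#' @param lenient_max_distance maximum pooled distance for a
#'   variant-consensus call (default 0.25); must be >= strict.
#' @param min_depth_per_strand minimum retained observations per strand for
#'   high-quality eligibility (default 4).
#' @param min_alt_obs_per_strand minimum alternate observations per strand
#'   in variant-consensus mode (default 2).
#' @return A \code{caller_thresholds} list.
#' @export
caller_thresholds <- function(strict_max_distance = 0.15,
                              lenient_max_distance = 0.25,
                              min_depth_per_strand = 4L,
                              min_alt_obs_per_strand = 2L) {
  .stopifnot_scalar_number(strict_max_distance, "strict_max_distance", 0, 1)
  .stopifnot_scalar_number(lenient_max_distance, "lenient_max_distance", 0, 1)
  if (strict_max_distance > lenient_max_distance)
    stop("strict_max_distance must be <= lenient_max_distance", call. = FALSE)
  structure(list(strict_max_distance = strict_max_distance,
                 lenient_max_distance = lenient_max_distance,
                 min_depth_per_strand = as.integer(min_depth_per_strand),
                 min_alt_obs_per_strand = as.integer(min_alt_obs_per_strand)),
            class = "caller_thresholds")
}

# expected alternate-allele fraction per diploid genotype
.gt_expected <- c(hom_ref = 0, het = 0.5, hom_alt = 1)

#' Quality-weighted alternate-allele fraction on one strand
#'
#' Each retained observation contributes weight \eqn{w = 1 - 10^{-Q/10}},
#' the probability that the base call is correct; the fraction is the
#' weighted share of observations equal to \code{alt}. Zero-quality bases
#' must already be trimmed (they carry weight 0 in any case).
#'
#' @param column a \code{pileup_column}.
#' @param alt alternate base.
#' @param strand "forward" or "reverse".
#' @return Fraction in [0, 1], or \code{NA_real_} when the strand has no
#'   retained observations (undefined evidence, distinct from fraction 0).
#' @export
weighted_alt_fraction <- function(column, alt, strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  obs <- column[[strand]]
  if (!nrow(obs)) return(NA_real_)
  w <- 1 - 10^(-obs$qual / 10)
  sum(w[obs$base == alt]) / sum(w)
}

#' Two-point Kolmogorov-Smirnov-style distance to a genotype
#'
#' For observations supported on the two points \{ref, alt\}, the KS
#' sup-distance between the sampled allele distribution and the expected
#' diploid genotype distribution reduces to the absolute difference between
#' the observed alternate fraction and the genotype's expected fraction
#' (0 for hom_ref, 0.5 for het, 1 for hom_alt).
#'
#' @param observed_fraction observed (weighted) alternate fraction in [0,1].
#' @param genotype one of "hom_ref", "het", "hom_alt".
#' @return Distance in [0, 1].
#' @export
ks_distance <- function(observed_fraction, genotype) {
  if (!genotype %in% names(.gt_expected)) stop("unknown genotype: ", genotype)
  abs(observed_fraction - .gt_expected[[genotype]])
}

#' Call a diploid genotype from one pileup column
#'
#' Standard mode: on each strand the genotype minimizing the two-point KS
#' distance to the weighted alternate fraction is chosen (ties resolved
#' toward the lower expected alternate fraction); the combined call is made,
#' at tier \code{high_quality}, only when both strands choose the same
#' genotype within \code{strict_max_distance} and both strands have at least
#' \code{min_depth_per_strand} retained observations. A variant genotype
#' therefore requires supporting evidence on both strands.
#'
#' Variant-consensus mode: a variant call is additionally made, at tier
#' \code{lenient}, when the pooled-strand weighted alternate fraction lies
#' within \code{lenient_max_distance} of a variant genotype and each strand
#' carries at least \code{min_alt_obs_per_strand} alternate observations;
#' calls that already satisfy the standard rule keep tier
#' \code{high_quality}.
#'
#' @param column a \code{pileup_column}.
#' @param thresholds a \code{\link{caller_thresholds}}.
#' @param mode "standard" or "variant_consensus".
#' @param alt alternate base; by default the non-reference base with the
#'   highest pooled weight (other non-reference bases at tri-allelic sites
#'   are noted but not evaluated).
#' @return A \code{genotype_call} list: position, ref/alt, per-strand
#'   fractions, best genotypes and distances, combined \code{genotype}
#'   ("hom_ref", "het", "hom_alt" or NA) and \code{tier}
#'   ("high_quality", "lenient", "no_call").
#' @export
call_genotype <- function(column, thresholds = caller_thresholds(),
                          mode = c("standard", "variant_consensus"),
                          alt = NULL) {
  mode <- match.arg(mode)
  ref <- column$ref_base
  all_obs <- rbind(cbind(column$forward, strand = "+"),
                   cbind(column$reverse, strand = "-"))
  if (is.null(alt)) {
    nonref <- all_obs[all_obs$base != ref & all_obs$base %in%
                        c("A", "C", "G", "T"), , drop = FALSE]
    if (nrow(nonref)) {
      w <- 1 - 10^(-nonref$qual / 10)
      alt <- names(which.max(tapply(w, nonref$base, sum)))
    } else alt <- NA_character_
  }

  if (is.na(alt)) {
    # no alternate allele observed: the alternate fraction is 0 wherever the
    # strand has evidence at all
    f_fwd <- if (column$depth_forward > 0L) 0 else NA_real_
    f_rev <- if (column$depth_reverse > 0L) 0 else NA_real_
  } else {
    f_fwd <- weighted_alt_fraction(column, alt, "forward")
    f_rev <- weighted_alt_fraction(column, alt, "reverse")
  }
  d_fwd <- if (is.na(f_fwd)) rep(NA_real_, 3) else abs(f_fwd - .gt_expected)
  d_rev <- if (is.na(f_rev)) rep(NA_real_, 3) else abs(f_rev - .gt_expected)
  gt_fwd <- if (is.na(f_fwd)) NA_character_
            else names(.gt_expected)[which.min(d_fwd)]
  gt_rev <- if (is.na(f_rev)) NA_character_
            else names(.gt_expected)[which.min(d_rev)]

  n_alt_fwd <- sum(column$forward$base == alt)
  n_alt_rev <- sum(column$reverse$base == alt)
  depth_ok <- column$depth_forward >= thresholds$min_depth_per_strand &&
    column$depth_reverse >= thresholds$min_depth_per_strand

  genotype <- NA_character_; tier <- "no_call"
  std_ok <- depth_ok && !is.na(gt_fwd) && !is.na(gt_rev) &&
    gt_fwd == gt_rev &&
    min(d_fwd) <= thresholds$strict_max_distance &&
    min(d_rev) <= thresholds$strict_max_distance
  if (std_ok) {
    genotype <- gt_fwd
    tier <- "high_quality"
  } else if (!is.na(gt_fwd) && !is.na(gt_rev) &&
             gt_fwd == "hom_ref" && gt_rev == "hom_ref") {
    genotype <- "hom_ref"   # low-confidence reference
    tier <- "no_call"
  }

  if (mode == "variant_consensus" && tier != "high_quality" && !is.na(alt)) {
    wf <- 1 - 10^(-column$forward$qual / 10)
    wr <- 1 - 10^(-column$reverse$qual / 10)
    tot <- sum(wf) + sum(wr)
    if (tot > 0) {
      f_pool <- (sum(wf[column$forward$base == alt]) +
                   sum(wr[column$reverse$base == alt])) / tot
      dv <- abs(f_pool - .gt_expected[c("het", "hom_alt")])
      best <- names(dv)[which.min(dv)]
      if (min(dv) <= thresholds$lenient_max_distance &&
          n_alt_fwd >= thresholds$min_alt_obs_per_strand &&
          n_alt_rev >= thresholds$min_alt_obs_per_strand) {
        genotype <- best
        tier <- "lenient"
      }
    }
  }
  # a variant genotype reached only one strand's support never survives:
  # enforced by construction (standard needs both strands; consensus needs
  # min_alt_obs on each strand)

  structure(list(contig = column$contig, pos = column$pos, ref = ref,
                 alt = alt, f_fwd = f_fwd, f_rev = f_rev,
                 gt_fwd = gt_fwd, gt_rev = gt_rev,
                 dist_fwd = if (all(is.na(d_fwd))) NA_real_ else min(d_fwd),
                 dist_rev = if (all(is.na(d_rev))) NA_real_ else min(d_rev),
                 n_alt_fwd = n_alt_fwd, n_alt_rev = n_alt_rev,
                 genotype = genotype, tier = tier, mode = mode),
            class = "genotype_call")
}

#' Vectorized genotype calling over a pileup
#'
#' Applies the same rules as \code{\link{call_genotype}} to every position
#' of a pileup at once; the scalar and vectorized paths are kept in exact
#' agreement (the scalar form is the reference implementation used by the
#' equivalence tests).
#'
#' @param pileup a \code{pileup}.
#' @param thresholds a \code{\link{caller_thresholds}}.
#' @param mode "standard" or "variant_consensus".
#' @return \code{data.table}, one row per position with at least one
#'   retained observation: ref/alt, per-strand fractions, distances, alt
#'   counts, depths, combined \code{genotype} and \code{tier}.
#' @export
call_genotypes <- function(pileup, thresholds = caller_thresholds(),
                           mode = c("standard", "variant_consensus")) {
  mode <- match.arg(mode)
  contig <- attr(pileup, "contig")
  refb <- attr(pileup, "ref_base")
  if (!nrow(pileup))
    return(data.table(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      f_fwd = numeric(), f_rev = numeric(),
                      dist_fwd = numeric(), dist_rev = numeric(),
                      n_alt_fwd = integer(), n_alt_rev = integer(),
                      depth_fwd = integer(), depth_rev = integer(),
                      genotype = character(), tier = character()))
  obs <- copy(pileup)
  obs[, ref := unname(refb[as.character(pos)])]
  obs[, w := 1 - 10^(-qual / 10)]

  # alt allele: highest pooled weight among non-reference ACGT bases
  altw <- obs[base != ref & base %chin% c("A", "C", "G", "T"),
              .(wsum = sum(w)), by = .(pos, base)]
  setorder(altw, pos, -wsum, base)
  alt_dt <- altw[, .SD[1], by = pos][, .(pos, alt = base)]
  obs <- merge(obs, alt_dt, by = "pos", all.x = TRUE)

  per <- obs[, .(tot_w = sum(w),
                 alt_w = sum(w[!is.na(alt) & base == alt]),
                 n_alt = sum(!is.na(alt) & base == alt),
                 depth = .N),
             by = .(pos, ref, alt, strand)]
  wide <- dcast(per, pos + ref + alt ~ strand,
                value.var = c("tot_w", "alt_w", "n_alt", "depth"),
                fill = 0)
  for (cn in c("tot_w_+", "alt_w_+", "n_alt_+", "depth_+",
               "tot_w_-", "alt_w_-", "n_alt_-", "depth_-"))
    if (!cn %in% names(wide)) wide[, (cn) := 0]
  setnames(wide,
           c("tot_w_+", "alt_w_+", "n_alt_+", "depth_+",
             "tot_w_-", "alt_w_-", "n_alt_-", "depth_-"),
           c("tw_f", "aw_f", "n_alt_fwd", "depth_fwd",
             "tw_r", "aw_r", "n_alt_rev", "depth_rev"))

  wide[, `:=`(f_fwd = ifelse(depth_fwd > 0, aw_f / tw_f, NA_real_),
              f_rev = ifelse(depth_rev > 0, aw_r / tw_r, NA_real_))]
  pick <- function(f) {
    d0 <- abs(f - 0); d5 <- abs(f - 0.5); d1 <- abs(f - 1)
    gt <- fifelse(d0 <= d5 & d0 <= d1, "hom_ref",
                  fifelse(d5 <= d1, "het", "hom_alt"))
    list(gt = gt, d = pmin(d0, d5, d1))
  }
  pf <- pick(wide$f_fwd); pr <- pick(wide$f_rev)
  wide[, `:=`(gt_fwd = pf$gt, dist_fwd = pf$d,
              gt_rev = pr$gt, dist_rev = pr$d)]

  th <- thresholds
  wide[, depth_ok := depth_fwd >= th$min_depth_per_strand &
         depth_rev >= th$min_depth_per_strand]
  wide[, std_ok := depth_ok & !is.na(gt_fwd) & !is.na(gt_rev) &
         gt_fwd == gt_rev & dist_fwd <= th$strict_max_distance &
         dist_rev <= th$strict_max_distance]
  wide[, `:=`(genotype = NA_character_, tier = "no_call")]
  wide[std_ok == TRUE, `:=`(genotype = gt_fwd, tier = "high_quality")]
  wide[std_ok == FALSE & !is.na(gt_fwd) & !is.na(gt_rev) &
         gt_fwd == "hom_ref" & gt_rev == "hom_ref",
       genotype := "hom_ref"]

  if (mode == "variant_consensus") {
    wide[, f_pool := fifelse(tw_f + tw_r > 0,
                             (aw_f + aw_r) / (tw_f + tw_r), NA_real_)]
    wide[, `:=`(dv_het = abs(f_pool - 0.5), dv_hom = abs(f_pool - 1))]
    wide[tier != "high_quality" & !is.na(alt) & !is.na(f_pool) &
           pmin(dv_het, dv_hom) <= th$lenient_max_distance &
           n_alt_fwd >= th$min_alt_obs_per_strand &
           n_alt_rev >= th$min_alt_obs_per_strand,
         `:=`(genotype = fifelse(dv_het <= dv_hom, "het", "hom_alt"),
              tier = "lenient")]
    wide[, c("f_pool", "dv_het", "dv_hom") := NULL]
  }
  wide[, c("tw_f", "aw_f", "tw_r", "aw_r", "depth_ok", "std_ok") := NULL]
  wide[, contig := contig]
  setcolorder(wide, c("contig", "pos", "ref", "alt"))
  wide[order(pos)]
}

#' Somatic classification of a tumor/normal call pair
#'
#' A locus is somatic when the tumor combined genotype is a variant (any
#' tier) while the matched normal shows a high-quality homozygous-reference
#' genotype. Non-somatic outcomes carry a note: \code{germline} (normal also
#' variant), \code{ambiguous_normal} (normal not confidently reference) or
#' \code{tumor_no_call}.
#'
#' @param tumor_call,normal_call \code{genotype_call}s at the same locus.
#' @return A list of class \code{somatic_snv}: both calls, \code{somatic}
#'   flag and \code{filter_notes}.
#' @export
call_somatic <- function(tumor_call, normal_call) {
  if (tumor_call$contig != normal_call$contig ||
      tumor_call$pos != normal_call$pos)
    stop("pairing error: calls are at different loci", call. = FALSE)
  if (!is.na(tumor_call$alt) && !is.na(normal_call$alt) &&
      tumor_call$alt != normal_call$alt &&
      normal_call$genotype %in% c("het", "hom_alt"))
    stop("pairing error: different alternate alleles", call. = FALSE)

  tumor_variant <- !is.na(tumor_call$genotype) &&
    tumor_call$genotype %in% c("het", "hom_alt") &&
    tumor_call$tier %in% c("high_quality", "lenient")
  normal_ref_hq <- !is.na(normal_call$genotype) &&
    normal_call$genotype == "hom_ref" && normal_call$tier == "high_quality"

  notes <- character()
  somatic <- FALSE
  if (!tumor_variant) {
    notes <- "tumor_no_call"
  } else if (normal_ref_hq) {
    somatic <- TRUE
  } else if (!is.na(normal_call$genotype) &&
             normal_call$genotype %in% c("het", "hom_alt")) {
    notes <- "germline"
  } else {
    notes <- "ambiguous_normal"
  }
  structure(list(tumor = tumor_call, normal = normal_call,
                 somatic = somatic, filter_notes = notes),
            class = "somatic_snv")
}

#' Intersect two variant call sets
#'
#' Emulates compiling calls made by two callers: loci present in both sets
#' (matched on contig, position and alternate allele) form the compiled set;
#' the union is retained as the lenient review set.
#'
#' @param calls_a,calls_b \code{data.table}s with columns contig, pos, alt.
#' @return A list with \code{intersection} and \code{union} tables.
#' @export
dual_caller_intersection <- function(calls_a, calls_b) {
  key <- c("contig", "pos", "alt")
  a <- unique(as.data.table(calls_a)[, ..key])
  b <- unique(as.data.table(calls_b)[, ..key])
  list(intersection = merge(a, b, by = key),
       union = funion(a, b)[order(contig, pos)])
}

#' Paired tumor/normal somatic SNV calling
#'
#' End-to-end somatic single-nucleotide calling: candidate sites are
#' detected from tumor mismatches, full per-strand pileups are built for
#' both samples at those sites, the tumor is genotyped in variant-consensus
#' mode (and in standard mode for the compiled dual-configuration set), the
#' normal in standard mode, and each tumor variant is classified somatic
#' when the normal is a high-quality homozygous reference.
#'
#' @param tumor_reads,normal_reads \code{aligned_reads} (duplicates are
#'   flagged here if none are marked yet).
#' @param reference contig sequences.
#' @param thresholds a \code{\link{caller_thresholds}}.
#' @param min_candidate_obs pre-filter: minimum same-base mismatch
#'   observations in the tumor.
#' @param extra_sites optional \code{data.table(contig, pos)} of additional
#'   loci to genotype (e.g. normal-derived candidates for germline calls).
#' @return A list of class \code{somatic_snv_calls}: \code{somatic} (table
#'   of somatic calls), \code{tumor_calls}, \code{normal_calls} (variant-
#'   consensus and standard tumor genotypes, standard normal genotypes at
#'   all candidate sites), \code{compiled} and \code{review} (intersection /
#'   union of the two tumor configurations).
#' @export
call_somatic_snvs <- function(tumor_reads, normal_reads, reference,
                              thresholds = caller_thresholds(),
                              min_candidate_obs = 2L,
                              extra_sites = NULL) {
  if (!any(tumor_reads$is_duplicate)) tumor_reads <- flag_duplicates(tumor_reads)
  if (!any(normal_reads$is_duplicate)) normal_reads <- flag_duplicates(normal_reads)

  cand <- scan_mismatch_sites(tumor_reads, reference,
                              min_alt_obs = min_candidate_obs)
  sites <- cand[, .(contig, pos)]
  if (!is.null(extra_sites))
    sites <- funion(sites, as.data.table(extra_sites)[, .(contig, pos)])
  setorder(sites, contig, pos)

  t_vc <- list(); t_std <- list(); n_std <- list()
  for (ct in unique(sites$contig)) {
    p <- sites[contig == ct, pos]
    tp <- build_pileup(tumor_reads, reference, ct, positions = p)
    np <- build_pileup(normal_reads, reference, ct, positions = p)
    t_vc[[ct]] <- call_genotypes(tp, thresholds, "variant_consensus")
    t_std[[ct]] <- call_genotypes(tp, thresholds, "standard")
    n_std[[ct]] <- call_genotypes(np, thresholds, "standard")
  }
  t_vc <- rbindlist(t_vc); t_std <- rbindlist(t_std); n_std <- rbindlist(n_std)

  variants <- function(x) x[!is.na(genotype) & genotype %chin%
                              c("het", "hom_alt") & tier %chin%
                              c("high_quality", "lenient")]
  comp <- dual_caller_intersection(variants(t_std), variants(t_vc))

  tv <- variants(t_vc)
  som <- merge(tv,
               n_std[, .(contig, pos, normal_genotype = genotype,
                         normal_tier = tier, normal_alt = alt,
                         normal_f_fwd = f_fwd, normal_f_rev = f_rev)],
               by = c("contig", "pos"), all.x = TRUE)
  som[, somatic := !is.na(normal_genotype) & normal_genotype == "hom_ref" &
        normal_tier == "high_quality"]
  som[, note := fifelse(somatic, "",
                fifelse(!is.na(normal_genotype) &
                          normal_genotype %chin% c("het", "hom_alt"),
                        "germline", "ambiguous_normal"))]

  structure(list(somatic = som[somatic == TRUE][order(contig, pos)],
                 all_tumor_variants = som[order(contig, pos)],
                 tumor_calls = t_vc, tumor_calls_standard = t_std,
                 normal_calls = n_std,
                 compiled = comp$intersection, review = comp$union,
                 thresholds = thresholds),
            class = "somatic_snv_calls")
}

#' @export
print.somatic_snv_calls <- function(x, ...) {
  cat("somatic_snv_calls\n")
  cat(sprintf("  candidate loci genotyped: %d\n", nrow(x$normal_calls)))
  cat(sprintf("  tumor variants (consensus): %d; compiled (both configurations): %d\n",
              nrow(x$all_tumor_variants), nrow(x$compiled)))
  cat(sprintf("  somatic: %d\n", nrow(x$somatic)))
  invisible(x)
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("genotype_call %s:%d %s>%s %s (%s)\n", x$contig, x$pos,
              x$ref, ifelse(is.na(x$alt), ".", x$alt),
              ifelse(is.na(x$genotype), "no_call", x$genotype), x$tier))
  cat(sprintf("  fwd f=%.3f gt=%s d=%.3f; rev f=%.3f gt=%s d=%.3f\n",
              x$f_fwd, x$gt_fwd, x$dist_fwd, x$f_rev, x$gt_rev, x$dist_rev))
  invisible(x)
}
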