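#' Load a longitudinal codon-presence matrix
#'
#' Reads a TSV with columns \code{sample_date} (m/d/yy), \code{site}, and
#' one column per gene holding the codon observed in that sample (or
#' \code{N/A}). A footer row with \code{sample_date == "reference"} gives
#' each site's reference codon; the mutant codon of a site is the unique
#' non-reference codon observed in its column. Any cell matching neither
#' the reference nor the mutant codon (nor N/A) is a validation error.
#'
#' @param path TSV path.
#' @return An object of class \code{presence_matrix}: \code{samples}
#'   (date, site), \code{sites} (gene, ref_codon, mut_codon), and
#'   \code{cells} (sample x gene observed codons, NA for N/A).
#' @export
load_presence_matrix <- function(path) {
  raw <- tryCatch(fread(path, sep = "\t", colClasses = "character"),
                  error = function(e) stop("format error reading ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  if (!nrow(raw) || !all(c("sample_date", "site") %in% names(raw)))
    stop("format error: need sample_date, site and gene columns in ", path,
         call. = FALSE)
  genes <- setdiff(names(raw), c("sample_date", "site"))
  if (!length(genes)) stop("format error: no gene columns", call. = FALSE)
  ref_row <- raw[sample_date == "reference"]
  if (nrow(ref_row) != 1L)
    stop("format error: expected exactly one 'reference' footer row",
         call. = FALSE)
  body <- raw[sample_date != "reference"]
  samples <- body[, .(date = as.Date(sample_date, format = "%m/%d/%y"),
                      site = site, label = paste(sample_date, site))]
  if (anyNA(samples$date))
    stop("format error: unparseable sample_date", call. = FALSE)

  cells <- as.matrix(body[, ..genes])
  cells[cells %in% c("N/A", "NA", "")] <- NA_character_
  rownames(cells) <- samples$label

  sites <- data.table(gene = genes,
                      ref_codon = unlist(ref_row[, ..genes]),
                      mut_codon = NA_character_)
  for (j in seq_along(genes)) {
    obs <- unique(stats::na.omit(cells[, j]))
    mut <- setdiff(obs, sites$ref_codon[j])
    if (length(mut) > 1L)
      stop(sprintf("validation error: column %s has multiple non-reference codons: %s",
                   genes[j], paste(mut, collapse = ", ")), call. = FALSE)
    if (length(mut)) sites$mut_codon[j] <- mut
    bad <- which(!is.na(cells[, j]) &
                   !cells[, j] %in% c(sites$ref_codon[j], mut))
    if (length(bad))
      stop(sprintf("validation error: cell [%s, %s] = '%s' matches neither reference nor mutant codon",
                   samples$label[bad[1]], genes[j], cells[bad[1], j]),
           call. = FALSE)
  }
  ord <- order(samples$date)
  structure(list(samples = samples[ord], cells = cells[ord, , drop = FALSE],
                 sites = sites), class = "presence_matrix")
}

#' Mutation presence in one sample at one site
#'
#' @param matrix a \code{presence_matrix}.
#' @param sample sample label ("date site" as loaded) or row index.
#' @param site gene name.
#' @return "mutant", "reference" or "unknown" (N/A cell).
#' @export
mutation_present <- function(matrix, sample, site) {
  stopifnot(inherits(matrix, "presence_matrix"))
  if (is.character(sample)) {
    idx <- which(matrix$samples$label == sample)
    if (!length(idx)) stop("unknown sample: ", sample, call. = FALSE)
  } else idx <- as.integer(sample)
  if (!site %in% matrix$sites$gene) stop("unknown site: ", site, call. = FALSE)
  obs <- matrix$cells[idx, site]
  st <- matrix$sites[gene == site]
  if (is.na(obs)) "unknown"
  else if (!is.na(st$mut_codon) && obs == st$mut_codon) "mutant"
  else "reference"
}

#' Classify mutations as present-at-diagnosis versus acquired
#'
#' Samples sharing a collection date are replicates: a mutation is present
#' at that date if any replicate shows the mutant codon; dates whose cells
#' are all N/A are skipped. A site is \code{present_at_diagnosis} when the
#' earliest evaluable date already shows the mutant codon;
#' \code{acquired} when the earliest evaluable date shows the reference
#' and a later date the mutant; \code{inconsistent} when a mutant
#' observation is followed by a reference-only date (reversion pattern);
#' \code{never_observed} when no mutant codon is ever seen.
#'
#' @param matrix a \code{presence_matrix}.
#' @return \code{data.table}: gene, status, first_positive (Date or NA).
#' @export
classify_acquisition <- function(matrix) {
  stopifnot(inherits(matrix, "presence_matrix"))
  dates <- sort(unique(matrix$samples$date))
  if (length(dates) < 2L)
    stop("need samples from at least two dates", call. = FALSE)
  out <- vector("list", nrow(matrix$sites))
  for (j in seq_len(nrow(matrix$sites))) {
    g <- matrix$sites$gene[j]
    state <- character(0); sdate <- as.Date(character(0))
    for (d in seq_along(dates)) {
      rows <- which(matrix$samples$date == dates[d])
      obs <- vapply(rows, function(r) mutation_present(matrix, r, g),
                    character(1))
      obs <- obs[obs != "unknown"]
      if (!length(obs)) next
      state <- c(state, if (any(obs == "mutant")) "mutant" else "reference")
      sdate <- c(sdate, dates[d])
    }
    status <- if (!length(state)) {
      warning("site ", g, " has no evaluable cells", call. = FALSE)
      "never_observed"
    } else if (!any(state == "mutant")) {
      "never_observed"
    } else {
      first_mut <- which(state == "mutant")[1]
      reverted <- any(state[seq_along(state) > first_mut] == "reference")
      if (reverted) "inconsistent"
      else if (state[1] == "mutant") "present_at_diagnosis"
      else "acquired"
    }
    first_pos <- if (any(state == "mutant"))
      sdate[which(state == "mutant")[1]] else as.Date(NA)
    out[[j]] <- data.table(gene = g, status = status,
                           first_positive = first_pos)
  }
  rbindlist(out)
}

#' Write an acquisition timeline report as JSON
#'
#' @param matrix a \code{presence_matrix}.
#' @param path output JSON path.
#' @return Invisibly, the report list.
#' @export
timeline_report <- function(matrix, path = NULL) {
  calls <- classify_acquisition(matrix)
  rep <- list(
    n_samples = nrow(matrix$samples),
    n_sites = nrow(matrix$sites),
    samples = matrix$samples[, .(date = format(date), site)],
    calls = calls[, .(gene, status, first_positive = ifelse(
      is.na(first_positive), NA_character_, format(first_positive)))],
    present_at_diagnosis = calls[status == "present_at_diagnosis", gene],
    acquired = calls[status == "acquired", gene])
  if (!is.null(path))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE,
                         null = "null", na = "null")
  invisible(rep)
}
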