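#' @import data.table
#' @importFrom stringi stri_sub stri_sub<- stri_flatten stri_detect_regex
#'   stri_match_all_regex stri_rand_strings stri_reverse
#' @importFrom stats rbinom rnorm runif setNames
#' @importFrom utils head tail
NULL

# Phred+33 encode/decode
.phred_encode <- function(q) {
  vapply(q, function(x) intToUtf8(x + 33L), character(1))
}

.phred_decode_cat <- function(qual_strings) {
  # decode a vector of quality strings into one integer vector (concatenated)
  if (!length(qual_strings)) return(integer(0))
  utf8ToInt(stri_flatten(qual_strings)) - 33L
}

# Patch single characters inside strings, handling repeated string indices
# (several edits to the same string are applied in successive rounds so no
# edit is lost to copy-on-write).
.patch_chars <- function(strings, idx, offset, newchar) {
  if (!length(idx)) return(strings)
  remaining <- seq_along(idx)
  while (length(remaining)) {
    first <- remaining[!duplicated(idx[remaining])]
    i <- idx[first]
    s <- strings[i]
    stri_sub(s, offset[first], offset[first]) <- newchar[first]
    strings[i] <- s
    remaining <- setdiff(remaining, first)
  }
  strings
}

# complement / reverse complement for plain character vectors
.comp_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
               a = "t", c = "g", g = "c", t = "a", n = "n")

.complement_base <- function(b) {
  out <- .comp_map[b]
  if (anyNA(out)) stop("cannot complement base(s): ",
                       paste(unique(b[is.na(out)]), collapse = ", "))
  unname(out)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

.stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

# deterministic child seeds (kept well under 2^31)
.child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1000L + as.integer(k)
}

.md5 <- function(paths) unname(tools::md5sum(paths))
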