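# IUPAC nucleotide code handling.
#
# Expansion sets follow the IUPAC standard. A pattern `N` is a true wildcard
# (matches A, C, G, T and N); every other pattern symbol matches only
# unambiguous bases, so an `N` in a *subject* sequence (e.g. an assembly gap)
# never satisfies a non-N pattern position.

.IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N")
)

# minimal IUPAC code covering a set of unambiguous bases
.IUPAC_COVER <- c(
  A = "A", C = "C", G = "G", T = "T",
  AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
  CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N"
)

.check_iupac <- function(pattern, what = "pattern") {
  sym <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(sym, names(.IUPAC_EXPAND))
  if (length(bad)) {
    stop(sprintf("invalid IUPAC symbol(s) in %s '%s': %s",
                 what, pattern, paste(unique(bad), collapse = ", ")))
  }
  sym
}

# Precompute per-position expansion sets for repeated matching.
iupac_compile <- function(pattern) {
  sym <- .check_iupac(pattern)
  lapply(sym, function(s) .IUPAC_EXPAND[[s]])
}

#' Match a degenerate IUPAC pattern against a nucleotide sequence
#'
#' Tests whether `seq` is an exact realization of the degenerate `pattern`,
#' position by position. Pattern symbols expand to their IUPAC sets (e.g.
#' `H` = A, C or T, as in the CGHH -10 element search). An `N` in `seq`
#' matches nothing except a pattern `N`, so assembly gaps are treated
#' conservatively.
#'
#' @param pattern character scalar over the IUPAC alphabet.
#' @param seq character scalar over A, C, G, T, N; must have the same
#'   length as `pattern`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' iupac_match("CGHH", "CGAT")  # TRUE: A and T both belong to H
#' iupac_match("CGHH", "CGGA")  # FALSE: G is not in H
#' @export
iupac_match <- function(pattern, seq) {
  seq <- toupper(seq)
  if (nchar(pattern) != nchar(seq)) {
    stop("pattern and sequence must have equal length")
  }
  comp <- iupac_compile(pattern)
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(chars, c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop(sprintf("sequence contains non-nucleotide character(s): %s",
                 paste(unique(bad), collapse = ", ")))
  }
  all(vapply(seq_along(chars), function(i) chars[i] %in% comp[[i]], logical(1)))
}

# Fast inner check used by the scanner: chars is a character vector,
# comp a compiled pattern, start the 1-based offset of the window.
.match_at <- function(chars, comp, start) {
  for (k in seq_along(comp)) {
    if (!(chars[start + k - 1L] %in% comp[[k]])) return(FALSE)
  }
  TRUE
}

# Sample one concrete realization of a degenerate pattern (used by the
# synthetic-promoter generator). N realizes to an unambiguous base.
.iupac_realize <- function(pattern) {
  comp <- iupac_compile(pattern)
  paste(vapply(comp, function(set) {
    set <- setdiff(set, "N")
    if (length(set) == 1L) set else sample(set, 1L)
  }, character(1)), collapse = "")
}

# Minimal covering code for a base set (consensus-string fallback).
.iupac_cover <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- .IUPAC_COVER[key]
  if (is.na(code)) "N" else unname(code)
}

.revcomp <- function(s) {
  vapply(s, function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }, character(1), USE.NAMES = FALSE)
}
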