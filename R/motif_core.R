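#' Bipartite sigma-I promoter motif specification
#'
#' Describes the two-element promoter architecture recognized by clostridial
#' sigma-I factors: a homopolymeric A-tract at the 3' end of the -35 element,
#' a variable spacer, and a short degenerate -10 core. The scanner extends
#' the -35 core to the *maximal* run of A containing it, so the default
#' `"AAA"` core together with maximal-run extension covers both the AAA triad
#' used for genome searches and the AAAA-tract consensus seen in curated
#' promoter alignments.
#'
#' @param minus35_core degenerate pattern for the -35 core (default `"AAA"`).
#'   Must be a homopolymeric A pattern for maximal-run extension to apply.
#' @param minus10_core degenerate pattern for the -10 core (default `"CGHH"`,
#'   where H is A, C or T).
#' @param spacer_min,spacer_max allowed spacer lengths in nt, measured from
#'   the 3' end of the maximal A-tract to the 5' start of the -10 core
#'   (defaults 12 and 15).
#' @param specificity_window nt immediately 5' of the A-tract retained as the
#'   "region of specificity" (default 6).
#' @param downstream_window nt retained 3' of the -10 core (default 6); the
#'   conserved AT dyad sits 3 nt after the -10 tetrad, inside this window.
#' @param atract_width A-tract column width used when promoters are stacked
#'   into alignment windows (default core length + 1, i.e. 4, matching the
#'   AAAA consensus tract).
#' @return an object of class `motif_spec`.
#' @examples
#' motif_spec()
#' motif_spec(minus10_core = "CGAA")  # sigma-I3-specific core
#' @export
motif_spec <- function(minus35_core = "AAA", minus10_core = "CGHH",
                       spacer_min = 12L, spacer_max = 15L,
                       specificity_window = 6L, downstream_window = 6L,
                       atract_width = nchar(minus35_core) + 1L) {
  stopifnot(nchar(minus35_core) >= 1, nchar(minus10_core) >= 1)
  .check_iupac(minus35_core, "minus35_core")
  .check_iupac(minus10_core, "minus10_core")
  if (!grepl("^A+$", minus35_core)) {
    stop("minus35_core must be a homopolymeric A pattern (A-tract core)")
  }
  spacer_min <- as.integer(spacer_min); spacer_max <- as.integer(spacer_max)
  if (!(spacer_min > 0 && spacer_min <= spacer_max)) {
    stop("need 0 < spacer_min <= spacer_max")
  }
  if (atract_width < nchar(minus35_core)) {
    stop("atract_width must be at least the -35 core length")
  }
  structure(list(
    minus35_core = toupper(minus35_core),
    minus10_core = toupper(minus10_core),
    spacer_min = spacer_min, spacer_max = spacer_max,
    specificity_window = as.integer(specificity_window),
    downstream_window = as.integer(downstream_window),
    atract_width = as.integer(atract_width)
  ), class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat("Bipartite promoter motif spec\n")
  cat(sprintf("  -35 core: %s (maximal A-tract extension, alignment width %d)\n",
              x$minus35_core, x$atract_width))
  cat(sprintf("  spacer:   %d-%d nt\n", x$spacer_min, x$spacer_max))
  cat(sprintf("  -10 core: %s\n", x$minus10_core))
  cat(sprintf("  windows:  specificity %d nt / downstream %d nt\n",
              x$specificity_window, x$downstream_window))
  invisible(x)
}

# Empty match table with the scanner's column contract.
.empty_matches <- function() {
  data.frame(
    atract_start = integer(0), atract_end = integer(0),
    spacer_len = integer(0), m10_start = integer(0), m10_end = integer(0),
    specificity_seq = character(0), atract_seq = character(0),
    minus10_seq = character(0), downstream_seq = character(0),
    upstream_seq = character(0), stringsAsFactors = FALSE
  )
}

#' Scan a sequence for bipartite A-tract/spacer/-10 promoter elements
#'
#' Finds every pair (maximal A-tract, -10 core) compatible with `spec`:
#' a run of A at least as long as the -35 core, followed after
#' `spacer_min`..`spacer_max` nt by a match to the -10 core pattern. The
#' A-tract is always reported as the maximal run, so a single biological site
#' on a long A-run yields one match per compatible -10 core rather than one
#' per AAA placement. Overlapping distinct element pairs are all reported.
#'
#' Coordinates are 1-based inclusive positions within `seq`. The
#' `specificity_seq` and `downstream_seq` context fields are truncated
#' silently at the sequence ends; `upstream_seq` is the contiguous window of
#' up to `specificity_window + atract_width` nt ending at the A-tract 3' end,
#' used for profile scoring.
#'
#' @param seq character scalar over A, C, G, T, N.
#' @param spec a [motif_spec()].
#' @return data.frame with one row per match, ordered left to right
#'   (by A-tract start, then -10 start).
#' @examples
#' scan_bipartite(paste0("TTAAA", strrep("G", 13), "CGAATT"), motif_spec())
#' @export
scan_bipartite <- function(seq, spec = motif_spec()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  core_len <- nchar(spec$minus35_core)
  m10_len <- nchar(spec$minus10_core)
  if (n < core_len + spec$spacer_min + m10_len) return(.empty_matches())

  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop(sprintf("sequence contains non-nucleotide character(s): %s",
                 paste(bad, collapse = ", ")))
  }

  # maximal A-runs of at least core length (greedy regex = maximal runs)
  runs <- gregexpr(sprintf("A{%d,}", core_len), seq)[[1]]
  if (runs[1] == -1L) return(.empty_matches())
  run_start <- as.integer(runs)
  run_len <- attr(runs, "match.length")
  run_end <- run_start + run_len - 1L

  comp10 <- iupac_compile(spec$minus10_core)
  u_width <- spec$specificity_window + spec$atract_width

  out <- vector("list", length(run_start) * (spec$spacer_max - spec$spacer_min + 1L))
  k <- 0L
  for (i in seq_along(run_start)) {
    a1 <- run_start[i]; a2 <- run_end[i]
    for (s in spec$spacer_min:spec$spacer_max) {
      j <- a2 + s + 1L
      if (j + m10_len - 1L > n) break
      if (.match_at(chars, comp10, j)) {
        k <- k + 1L
        spec_seq <- substr(seq, max(1L, a1 - spec$specificity_window), a1 - 1L)
        down_seq <- substr(seq, j + m10_len,
                           min(n, j + m10_len + spec$downstream_window - 1L))
        out[[k]] <- data.frame(
          atract_start = a1, atract_end = a2, spacer_len = s,
          m10_start = j, m10_end = j + m10_len - 1L,
          specificity_seq = spec_seq,
          atract_seq = substr(seq, a1, a2),
          minus10_seq = substr(seq, j, j + m10_len - 1L),
          downstream_seq = down_seq,
          upstream_seq = substr(seq, max(1L, a2 - u_width + 1L), a2),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (k == 0L) return(.empty_matches())
  res <- do.call(rbind, out[seq_len(k)])
  res[order(res$atract_start, res$m10_start), , drop = FALSE]
}

#' Scan a genome for bipartite promoter elements on one or both strands
#'
#' Applies [scan_bipartite()] to each contig and, for the minus strand, to
#' its reverse complement. Minus-strand matches are reported in genomic
#' (plus-strand) coordinates with `strand = "-"`; their sequence fields are
#' written in the promoter's reading orientation. Output is sorted by
#' contig, then by the leftmost genomic coordinate of the element pair.
#'
#' @param genome a `DNAStringSet` or named character vector of contigs.
#' @param spec a [motif_spec()].
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @return data.frame of matches with `contig` and `strand` columns plus the
#'   [scan_bipartite()] columns in genomic coordinates (1-based inclusive,
#'   `start <= end` regardless of strand).
#' @export
scan_genome <- function(genome, spec = motif_spec(), strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  seqs <- .genome_chars(genome)
  res <- list()
  for (ctg in names(seqs)) {
    sq <- seqs[[ctg]]
    L <- nchar(sq)
    if (strands %in% c("both", "+")) {
      m <- scan_bipartite(sq, spec)
      if (nrow(m)) {
        m <- cbind(contig = ctg, strand = "+", m, stringsAsFactors = FALSE)
        res[[length(res) + 1L]] <- m
      }
    }
    if (strands %in% c("both", "-")) {
      m <- scan_bipartite(.revcomp(sq), spec)
      if (nrow(m)) {
        # map local (revcomp) coordinates [a,b] to genomic [L-b+1, L-a+1]
        flip <- function(lo, hi) list(start = L - hi + 1L, end = L - lo + 1L)
        at <- flip(m$atract_start, m$atract_end)
        mt <- flip(m$m10_start, m$m10_end)
        m$atract_start <- at$start; m$atract_end <- at$end
        m$m10_start <- mt$start; m$m10_end <- mt$end
        m <- cbind(contig = ctg, strand = "-", m, stringsAsFactors = FALSE)
        res[[length(res) + 1L]] <- m
      }
    }
  }
  if (!length(res)) {
    return(cbind(contig = character(0), strand = character(0), .empty_matches()))
  }
  out <- do.call(rbind, res)
  gstart <- pmin(out$atract_start, out$m10_start)
  out <- out[order(out$contig, gstart, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expected background hit rate of the bipartite scanner
#'
#' Closed-form expectation, per position and per strand, of the number of
#' bipartite matches under an i.i.d. background with the given base
#' frequencies: the sum over allowed spacer lengths of the product of the
#' per-position pattern probabilities of both cores. With
#' `maximal_runs = FALSE` (the plain product) the value is an *upper bound*
#' on what [scan_genome()] reports, because the scanner collapses all
#' placements of the -35 core inside one maximal A-run into a single match.
#' `maximal_runs = TRUE` applies the exact correction for that semantics: the
#' A-run must end where the spacer begins, i.e. the following base is not A,
#' contributing a factor `1 - f(A)`.
#'
#' @param spec a [motif_spec()].
#' @param base_frequencies numeric, named A/C/G/T, summing to 1.
#' @param maximal_runs apply the maximal-run correction (default `FALSE`).
#' @return expected matches per position per strand.
#' @examples
#' background_hit_rate(motif_spec(), c(A = .25, C = .25, G = .25, T = .25))
#' @export
background_hit_rate <- function(spec, base_frequencies, maximal_runs = FALSE) {
  f <- base_frequencies[c("A", "C", "G", "T")]
  if (any(is.na(f))) stop("base_frequencies must be named A, C, G, T")
  if (any(f < 0)) stop("base frequencies must be non-negative")
  if (abs(sum(f) - 1) > 1e-6) stop("base frequencies must sum to 1")
  psym <- function(sym) sum(f[intersect(.IUPAC_EXPAND[[sym]], c("A", "C", "G", "T"))])
  ppat <- function(pat) prod(vapply(strsplit(pat, "")[[1]], psym, numeric(1)))
  nspacer <- spec$spacer_max - spec$spacer_min + 1L
  rate <- nspacer * ppat(spec$minus35_core) * ppat(spec$minus10_core)
  if (maximal_runs) rate <- rate * (1 - unname(f["A"]))
  unname(rate)
}
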