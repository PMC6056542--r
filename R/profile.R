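# Per-sigma promoter profiles: position frequencies, information content,
# consensus and log-odds scoring.
#
# Alignment model: curated promoters are stacked into two contiguous
# fixed-width windows anchored on the two element boundaries --
#   upstream block:  specificity_window + atract_width nt ending at the
#                    A-tract 3' end (right-aligned; spill of tracts longer
#                    than atract_width simply shifts context out on the left)
#   -10 block:       -10 core + downstream_window nt starting at the core
#                    5' start (left-aligned)
# The variable spacer is excluded from the columns and kept as a separate
# length distribution. Rows shorter than a window are padded with the gap
# symbol "-", which is ignored in counts. Because both windows are
# contiguous in the underlying DNA, any genomic candidate can be scored
# against the same columns without gaps.

.BASES <- c("A", "C", "G", "T")

#' Read curated promoter sets from a TSV fixture
#'
#' Expected columns: `sigma_label`, `gene_label`, `specificity_seq`,
#' `atract_seq`, `spacer_seq`, `minus10_seq` (the -10 core plus downstream
#' context, including the AT-dyad position), and optionally `utr5`.
#'
#' @param path TSV file.
#' @return validated data.frame of promoter records.
#' @export
read_promoter_sets <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_promoter_records(x)
}

#' @rdname read_promoter_sets
#' @param records data.frame of promoter records.
#' @export
validate_promoter_records <- function(records) {
  need <- c("sigma_label", "gene_label", "specificity_seq", "atract_seq",
            "spacer_seq", "minus10_seq")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("promoter records lack column(s): ",
                         paste(miss, collapse = ", "))
  for (col in c("specificity_seq", "atract_seq", "spacer_seq", "minus10_seq")) {
    records[[col]] <- toupper(records[[col]])
  }
  bad <- !grepl("^A{3,}$", records$atract_seq)
  if (any(bad)) stop("atract_seq must be all A and at least 3 nt (record ",
                     paste(records$gene_label[bad], collapse = ", "), ")")
  if (any(nchar(records$minus10_seq) < 4L)) {
    stop("minus10_seq must be at least 4 nt (the -10 tetrad)")
  }
  if (!"utr5" %in% names(records)) records$utr5 <- NA_integer_
  records
}

# right-align a string into width w, pad left with "-"; keep the last w chars
.pad_left <- function(s, w) {
  n <- nchar(s)
  if (n >= w) substr(s, n - w + 1L, n) else paste0(strrep("-", w - n), s)
}
# left-align into width w, pad right
.pad_right <- function(s, w) {
  n <- nchar(s)
  if (n >= w) substr(s, 1L, w) else paste0(s, strrep("-", w - n))
}

#' Stack promoter records into anchored alignment windows
#'
#' @param records promoter records (one sigma set).
#' @param spec a [motif_spec()] fixing the window widths.
#' @return character matrix, one row per record, with an `anchor` attribute
#'   giving the column index ranges of the upstream and -10 blocks.
#' @export
stack_promoters <- function(records, spec = motif_spec()) {
  records <- validate_promoter_records(records)
  if (!nrow(records)) stop("empty promoter set")
  U <- spec$specificity_window + spec$atract_width
  M <- nchar(spec$minus10_core) + spec$downstream_window
  up <- vapply(paste0(records$specificity_seq, records$atract_seq),
               .pad_left, character(1), w = U, USE.NAMES = FALSE)
  m10 <- vapply(records$minus10_seq, .pad_right, character(1), w = M,
                USE.NAMES = FALSE)
  rows <- paste0(up, m10)
  mat <- do.call(rbind, strsplit(rows, ""))
  rownames(mat) <- records$gene_label
  attr(mat, "anchor") <- list(upstream = seq_len(U), minus10 = U + seq_len(M),
                              U = U, M = M)
  mat
}

#' Fit a positional promoter profile for one sigma-I factor
#'
#' The central model object of the package: per-column base frequencies
#' (with pseudocounts) over the anchored promoter alignment, the per-column
#' information content relative to the background, the spacer length
#' distribution, and everything needed to score new candidates by log-odds.
#'
#' @param records data.frame of promoter records (see
#'   [read_promoter_sets()]); if several sigma labels are present,
#'   `sigma_label` selects one.
#' @param spec a [motif_spec()] fixing the alignment windows.
#' @param pseudocount added to every base count per column (default 0.5;
#'   curated sets are small, so zero counts are common).
#' @param background base frequency vector named A/C/G/T (default uniform).
#' @param sigma_label sigma factor label; defaults to the unique label in
#'   `records`.
#' @return an object of class `promoter_profile` with methods `print`,
#'   `summary`, `coef` (the frequency matrix), `predict` (log-odds scores),
#'   `plot` (information-content profile) and `simulate` (sample promoter
#'   records from the fitted columns).
#' @examples
#' recs <- read_promoter_sets(system.file("extdata",
#'   "ct_sigI_promoters.synthetic.tsv", package = "sigiscan"))
#' pf <- promoter_profile(recs, sigma_label = "sigI3")
#' pf
#' consensus_string(pf)
#' @export
promoter_profile <- function(records, spec = motif_spec(), pseudocount = 0.5,
                             background = NULL, sigma_label = NULL) {
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  records <- validate_promoter_records(records)
  if (!is.null(sigma_label)) {
    records <- records[records$sigma_label == sigma_label, , drop = FALSE]
    if (!nrow(records)) stop("no records with sigma_label '", sigma_label, "'")
  } else {
    sigma_label <- unique(records$sigma_label)
    if (length(sigma_label) != 1L) {
      stop("records contain several sigma labels; pass sigma_label=")
    }
  }
  if (is.null(background)) {
    background <- c(A = .25, C = .25, G = .25, T = .25)
  }
  background <- background[.BASES]
  if (any(is.na(background)) || abs(sum(background) - 1) > 1e-6) {
    stop("background must be named A/C/G/T and sum to 1")
  }

  mat <- stack_promoters(records, spec)
  anchor <- attr(mat, "anchor")
  W <- ncol(mat)
  counts <- vapply(seq_len(W), function(j) {
    col <- mat[, j]
    vapply(.BASES, function(b) sum(col == b), numeric(1))
  }, numeric(4))
  rownames(counts) <- .BASES
  n_eff <- colSums(counts)
  freq <- vapply(seq_len(W), function(j) {
    if (n_eff[j] == 0 && pseudocount == 0) return(unname(background))
    (counts[, j] + pseudocount) / (n_eff[j] + 4 * pseudocount)
  }, numeric(4))
  rownames(freq) <- .BASES

  ic <- vapply(seq_len(W), function(j) {
    f <- freq[, j]
    sum(ifelse(f > 0, f * log2(f / background), 0))
  }, numeric(1))

  spl <- nchar(records$spacer_seq)
  spacer_table <- table(factor(spl, levels = spec$spacer_min:spec$spacer_max))

  structure(list(
    freq = freq, counts = counts, n_eff = n_eff, ic = ic,
    n_records = nrow(records), pseudocount = pseudocount,
    background = background, spec = spec, anchor = anchor,
    spacer_table = spacer_table, sigma_label = sigma_label,
    gene_labels = records$gene_label
  ), class = "promoter_profile")
}

# region label of each profile column
.profile_regions <- function(object) {
  sp <- object$spec
  U <- object$anchor$U
  core <- nchar(sp$minus10_core)
  c(rep("specificity", sp$specificity_window),
    rep("atract", sp$atract_width),
    rep("minus10_core", core),
    rep("downstream", sp$downstream_window))
}

#' Consensus string of a promoter profile
#'
#' Per column: the base whose frequency reaches `threshold`; otherwise the
#' minimal IUPAC code covering all bases with frequency above 1/4; otherwise
#' `N`.
#'
#' @param profile a [promoter_profile()].
#' @param threshold majority threshold in (0.25, 1] (default 0.8).
#' @return character scalar (upstream block then -10 block).
#' @export
consensus_string <- function(profile, threshold = 0.8) {
  if (!(threshold > 0.25 && threshold <= 1)) stop("threshold must be in (0.25, 1]")
  f <- profile$freq
  paste(vapply(seq_len(ncol(f)), function(j) {
    col <- f[, j]
    if (max(col) >= threshold) return(names(which.max(col)))
    above <- names(col)[col > 0.25]
    if (!length(above)) "N" else .iupac_cover(above)
  }, character(1)), collapse = "")
}

#' Log-odds score of a candidate against a promoter profile
#'
#' Sums `log2(f(b, j) / background(b))` over the profile columns covered by
#' the candidate's two element windows (the contiguous upstream window
#' ending at the A-tract 3' end, right-aligned, and the -10 core plus
#' downstream context, left-aligned). Positions missing at a sequence edge,
#' gaps and N contribute 0.
#'
#' @param profile a [promoter_profile()].
#' @param upstream_seq contiguous sequence ending at the A-tract 3' end
#'   (up to `specificity_window + atract_width` nt).
#' @param minus10_seq contiguous sequence starting at the -10 core 5' start
#'   (core plus downstream context).
#' @return numeric score in bits.
#' @export
score_window <- function(profile, upstream_seq, minus10_seq) {
  U <- profile$anchor$U; M <- profile$anchor$M
  up <- vapply(toupper(upstream_seq), .pad_left, character(1), w = U,
               USE.NAMES = FALSE)
  m10 <- vapply(toupper(minus10_seq), .pad_right, character(1), w = M,
                USE.NAMES = FALSE)
  rows <- strsplit(paste0(up, m10), "")
  f <- profile$freq; bg <- profile$background
  vapply(rows, function(ch) {
    s <- 0
    for (j in seq_along(ch)) {
      b <- ch[j]
      if (b %in% .BASES) s <- s + log2(f[b, j] / bg[b])
    }
    s
  }, numeric(1))
}

# assemble scoring windows from heterogeneous candidate/record tables
.candidate_windows <- function(newdata) {
  if (is.null(dim(newdata))) stop("newdata must be a data.frame of candidates")
  if (all(c("specificity_seq", "atract_seq") %in% names(newdata)) &&
      !"upstream_seq" %in% names(newdata)) {
    up <- paste0(newdata$specificity_seq, newdata$atract_seq)
  } else if ("upstream_seq" %in% names(newdata)) {
    up <- newdata$upstream_seq
  } else {
    stop("candidates need upstream_seq or specificity_seq+atract_seq")
  }
  if ("downstream_seq" %in% names(newdata)) {
    m10 <- paste0(newdata$minus10_seq, newdata$downstream_seq)
  } else if ("minus10_seq" %in% names(newdata)) {
    m10 <- newdata$minus10_seq
  } else {
    stop("candidates need a minus10_seq column")
  }
  list(up = up, m10 = m10)
}

#' @export
predict.promoter_profile <- function(object, newdata, type = "score", ...) {
  type <- match.arg(type, "score")
  w <- .candidate_windows(newdata)
  score_window(object, w$up, w$m10)
}

#' @export
coef.promoter_profile <- function(object, ...) object$freq

#' @export
print.promoter_profile <- function(x, ...) {
  cat(sprintf("Promoter profile for %s (%d promoters, %d columns)\n",
              x$sigma_label, x$n_records, ncol(x$freq)))
  cat(sprintf("  consensus: %s | %s\n",
              substr(consensus_string(x), 1, x$anchor$U),
              substr(consensus_string(x), x$anchor$U + 1, ncol(x$freq))))
  cat(sprintf("  total information content: %.2f bits\n", sum(x$ic)))
  spl <- x$spacer_table
  if (sum(spl) > 0) {
    cat("  spacer lengths: ",
        paste(sprintf("%s nt x%d", names(spl)[spl > 0], spl[spl > 0]),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.promoter_profile <- function(object, ...) {
  cons <- strsplit(consensus_string(object), "")[[1]]
  out <- data.frame(
    column = seq_len(ncol(object$freq)),
    region = .profile_regions(object),
    consensus = cons,
    ic_bits = round(object$ic, 3),
    n_eff = object$n_eff,
    t(round(object$freq, 3))
  )
  rownames(out) <- NULL
  class(out) <- c("summary.promoter_profile", "data.frame")
  attr(out, "sigma_label") <- object$sigma_label
  out
}

#' @export
print.summary.promoter_profile <- function(x, ...) {
  cat("Column summary for", attr(x, "sigma_label"), "profile\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.promoter_profile <- function(x, ...) {
  regions <- .profile_regions(x)
  cols <- c(specificity = "#9467bd", atract = "#d62728",
            minus10_core = "#1f77b4", downstream = "grey60")
  cons <- strsplit(consensus_string(x), "")[[1]]
  bp <- graphics::barplot(x$ic, col = cols[regions], border = NA,
                          ylab = "information content (bits)",
                          ylim = c(0, 2.2),
                          main = sprintf("%s promoter profile", x$sigma_label),
                          ...)
  graphics::axis(1, at = bp, labels = cons, tick = FALSE, line = -0.5,
                 cex.axis = 0.7)
  graphics::legend("topleft", legend = names(cols), fill = cols, bty = "n",
                   cex = 0.8)
  invisible(bp)
}

#' Sample promoter records from a fitted profile
#'
#' Draws records column-independently from the profile's frequency columns;
#' spacer lengths are drawn from the fitted spacer distribution (uniform
#' over the allowed range if the profile has none) with uniform-background
#' spacer content. The sampled upstream window is decomposed at its maximal
#' trailing A-run into `specificity_seq` and `atract_seq`; draws whose
#' trailing run is shorter than the -35 core are rejected and redrawn, so
#' every sampled record is a valid promoter record.
#'
#' @param object a [promoter_profile()].
#' @param nsim number of records.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data.frame of promoter records.
#' @export
simulate.promoter_profile <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  U <- object$anchor$U; M <- object$anchor$M
  core_len <- nchar(object$spec$minus35_core)
  spl <- object$spacer_table
  spacer_lens <- as.integer(names(spl))
  spacer_probs <- if (sum(spl) > 0) as.numeric(spl) / sum(spl) else {
    rep(1 / length(spacer_lens), length(spacer_lens))
  }
  draw_block <- function(cols) {
    paste(vapply(cols, function(j) {
      sample(.BASES, 1L, prob = object$freq[, j])
    }, character(1)), collapse = "")
  }
  recs <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    for (tries in 1:1000) {
      up <- draw_block(seq_len(U))
      run <- regmatches(up, regexpr("A+$", up))
      if (length(run) && nchar(run) >= core_len) break
      if (tries == 1000) stop("could not sample a valid A-tract from profile")
    }
    tract <- regmatches(up, regexpr("A+$", up))
    spec_seq <- substr(up, 1L, U - nchar(tract))
    slen <- sample(spacer_lens, 1L, prob = spacer_probs)
    spacer <- paste(sample(.BASES, slen, replace = TRUE), collapse = "")
    m10 <- draw_block(U + seq_len(M))
    recs[[i]] <- data.frame(
      sigma_label = object$sigma_label,
      gene_label = sprintf("sim_%s_%04d", object$sigma_label, i),
      specificity_seq = spec_seq, atract_seq = tract, spacer_seq = spacer,
      minus10_seq = m10, utr5 = NA_integer_, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, recs)
}

#' @rdname simulate.promoter_profile
#' @param profile a [promoter_profile()].
#' @param n number of records to sample.
#' @export
sample_promoter_set <- function(profile, n, seed = NULL) {
  stopifnot(n >= 1)
  stats::simulate(profile, nsim = n, seed = seed)
}

#' Export a profile frequency matrix as plain text
#'
#' Position x A/C/G/T matrix, tab-separated, with region labels.
#'
#' @param profile a [promoter_profile()].
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  out <- data.frame(position = seq_len(ncol(profile$freq)),
                    region = .profile_regions(profile),
                    t(profile$freq), ic_bits = profile$ic)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
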