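# In-silico saturation transversion mutagenesis of a promoter window.
#
# Reconstructs the logic of the reporter-based mutant library: single
# transversions (A<->T, C<->G) across an assembled promoter window, with a
# hard "ablated" call when the mutant no longer contains the bipartite core
# elements at the wild-type anchors, and a graded log-odds effect otherwise.

.TRANSVERSION <- c(A = "T", T = "A", C = "G", G = "C")

#' Enumerate single-transversion mutants of a promoter window
#'
#' Applies the fixed transversion map (A to T, T to A, C to G, G to C) at
#' each selected position, one mutant per position, ordered by position.
#'
#' @param window promoter window over A, C, G, T.
#' @param positions integer positions to mutate (default: all).
#' @return data.frame with `position`, `wt_base`, `mut_base`, `window`.
#' @examples
#' enumerate_transversions("CA")  # GA (C->G), CT (A->T)
#' @export
enumerate_transversions <- function(window, positions = NULL) {
  window <- toupper(window)
  chars <- strsplit(window, "")[[1]]
  if (is.null(positions)) positions <- seq_along(chars)
  positions <- sort(as.integer(positions))
  if (length(positions) &&
      (min(positions) < 1L || max(positions) > length(chars))) {
    stop("positions outside the window")
  }
  if (any(!chars[positions] %in% names(.TRANSVERSION))) {
    stop("cannot mutate N or non-ACGT position(s): ",
         paste(positions[!chars[positions] %in% names(.TRANSVERSION)],
               collapse = ", "))
  }
  out <- data.frame(position = positions,
                    wt_base = chars[positions],
                    mut_base = unname(.TRANSVERSION[chars[positions]]),
                    stringsAsFactors = FALSE)
  out$window <- vapply(seq_len(nrow(out)), function(i) {
    ch <- chars
    ch[out$position[i]] <- out$mut_base[i]
    paste(ch, collapse = "")
  }, character(1))
  out
}

# anchors (A-tract 3' end, -10 start) of the unique wild-type match
.scan_anchor <- function(window, spec) {
  m <- scan_bipartite(window, spec)
  if (!nrow(m)) return(NULL)
  m[1L, , drop = FALSE]
}

# score a window at fixed anchors
.score_at_anchor <- function(window, anchor, profile) {
  U <- profile$anchor$U; M <- profile$anchor$M
  n <- nchar(window)
  up <- substr(window, max(1L, anchor$atract_end - U + 1L), anchor$atract_end)
  m10 <- substr(window, anchor$m10_start, min(n, anchor$m10_start + M - 1L))
  score_window(profile, up, m10)
}

# region label of a window position relative to the wild-type anchors;
# "specificity" covers every scored position 5' of the A-tract (the scored
# upstream window extends past specificity_window when the tract is shorter
# than the alignment tract width), "flank" only truly unscored positions
.position_region <- function(pos, anchor, spec, window_len) {
  u_width <- spec$specificity_window + spec$atract_width
  spec_lo <- min(anchor$atract_start - spec$specificity_window,
                 anchor$atract_end - u_width + 1L)
  down_hi <- anchor$m10_end + spec$downstream_window
  if (pos >= anchor$atract_start && pos <= anchor$atract_end) "atract"
  else if (pos >= spec_lo && pos < anchor$atract_start) "specificity"
  else if (pos > anchor$atract_end && pos < anchor$m10_start) "spacer"
  else if (pos >= anchor$m10_start && pos <= anchor$m10_end) "minus10_core"
  else if (pos > anchor$m10_end && pos <= down_hi) "downstream"
  else "flank"
}

#' Predict the effect of a single promoter mutation
#'
#' Re-scans the mutant window with `spec`: the core is intact when a
#' bipartite match survives at the wild-type anchors (same A-tract 3' end
#' and -10 core start -- 5'-extension of the A-tract, as in the
#' activity-increasing T-to-A mutant, keeps the anchors). A broken core is
#' called `ablated` (mirroring "not detected" reporter activity) regardless
#' of score. Otherwise the effect is the log-odds score difference at the
#' wild-type anchors, banded into `increased` / `reduced` / `neutral`.
#'
#' @param mutant_window,wt_window equal-length promoter windows.
#' @param profile a [promoter_profile()] for scoring.
#' @param spec the [motif_spec()] defining core integrity; for a
#'   sigma-I3-style analysis use `motif_spec(minus10_core = "CGAA")` so that
#'   any change of the conserved tetrad breaks the core.
#' @param neutral_band half-width of the neutral score band in bits
#'   (default 0.5).
#' @return one-row data.frame: `position`, `wt_base`, `mut_base`,
#'   `delta_score` (NA when ablated), `core_intact`, `predicted_class`,
#'   `region`.
#' @export
predict_effect <- function(mutant_window, wt_window, profile,
                           spec = motif_spec(), neutral_band = 0.5) {
  mutant_window <- toupper(mutant_window); wt_window <- toupper(wt_window)
  if (nchar(mutant_window) != nchar(wt_window)) {
    stop("mutant and wild-type windows must have equal length")
  }
  wt_anchor <- .scan_anchor(wt_window, spec)
  if (is.null(wt_anchor)) stop("wild-type window contains no bipartite match")
  diff_pos <- which(strsplit(mutant_window, "")[[1]] !=
                    strsplit(wt_window, "")[[1]])
  if (length(diff_pos) != 1L) {
    stop("windows must differ at exactly one position")
  }
  mm <- scan_bipartite(mutant_window, spec)
  core_intact <- nrow(mm) > 0 &&
    any(mm$atract_end == wt_anchor$atract_end &
        mm$m10_start == wt_anchor$m10_start)
  wt_base <- substr(wt_window, diff_pos, diff_pos)
  mut_base <- substr(mutant_window, diff_pos, diff_pos)
  region <- .position_region(diff_pos, wt_anchor, spec, nchar(wt_window))
  if (!core_intact) {
    cls <- "ablated"; delta <- NA_real_
  } else {
    delta <- .score_at_anchor(mutant_window, wt_anchor, profile) -
             .score_at_anchor(wt_window, wt_anchor, profile)
    cls <- if (delta > neutral_band) "increased"
           else if (delta < -neutral_band) "reduced"
           else "neutral"
  }
  data.frame(position = diff_pos, wt_base = wt_base, mut_base = mut_base,
             delta_score = delta, core_intact = core_intact,
             predicted_class = cls, region = region, stringsAsFactors = FALSE)
}

#' Saturation transversion report for a promoter window
#'
#' One [predict_effect()] row per position (or per selected position),
#' grouped by promoter region (specificity / A-tract / spacer / -10 core /
#' downstream / flank) relative to the wild-type match.
#'
#' @inheritParams predict_effect
#' @param wt_window the wild-type promoter window.
#' @param positions positions to mutate (default: all).
#' @return data.frame, one row per mutated position.
#' @export
mutagenesis_report <- function(wt_window, profile, spec = motif_spec(),
                               neutral_band = 0.5, positions = NULL) {
  muts <- enumerate_transversions(wt_window, positions)
  rows <- lapply(seq_len(nrow(muts)), function(i) {
    predict_effect(muts$window[i], wt_window, profile, spec, neutral_band)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
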