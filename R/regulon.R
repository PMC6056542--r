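# Regulon assignment: region-of-specificity rules, promoter prediction,
# classification with cross-talk detection, and cross-species transfer.

#' Declarative region-of-specificity rule for one sigma-I factor
#'
#' A candidate satisfies the rule when (a) the 3-nt `triad` matches within
#' `offset_min`..`offset_max` nt upstream of the A-tract 5' start (offset 0 =
#' immediately upstream, as for the sigma-I1 CTC triad; offset 2 = two nt
#' upstream, as for the sigma-I3 CCC triad), (b) the first four bases of the
#' -10 element match `minus10_tetrad`, and (c) if set, `downstream_dyad`
#' matches 3 nt after the tetrad (the conserved AT-dyad position).
#'
#' @param sigma_label sigma factor label.
#' @param triad degenerate pattern of length 3.
#' @param offset_min,offset_max allowed gap (nt) between the triad 3' end and
#'   the A-tract 5' start, inclusive.
#' @param minus10_tetrad degenerate pattern of length 4 (e.g. `"CGAA"`,
#'   or `"CGWA"` to also admit the CGTA tetrad of the sigI3 promoter).
#' @param downstream_dyad optional degenerate pattern of length 2.
#' @return object of class `specificity_rule`.
#' @export
specificity_rule <- function(sigma_label, triad, offset_min = 0L,
                             offset_max = offset_min,
                             minus10_tetrad = "CGHH",
                             downstream_dyad = NULL) {
  if (nchar(triad) != 3L) stop("triad must have length 3")
  .check_iupac(triad, "triad")
  if (nchar(minus10_tetrad) != 4L) stop("minus10_tetrad must have length 4")
  .check_iupac(minus10_tetrad, "minus10_tetrad")
  if (!is.null(downstream_dyad)) {
    if (nchar(downstream_dyad) != 2L) stop("downstream_dyad must have length 2")
    .check_iupac(downstream_dyad, "downstream_dyad")
  }
  offset_min <- as.integer(offset_min); offset_max <- as.integer(offset_max)
  if (offset_min < 0L || offset_max < offset_min) {
    stop("need 0 <= offset_min <= offset_max")
  }
  structure(list(sigma_label = sigma_label, triad = toupper(triad),
                 offset_min = offset_min, offset_max = offset_max,
                 minus10_tetrad = toupper(minus10_tetrad),
                 downstream_dyad = if (is.null(downstream_dyad)) NULL
                                   else toupper(downstream_dyad)),
            class = "specificity_rule")
}

#' @export
print.specificity_rule <- function(x, ...) {
  dy <- if (is.null(x$downstream_dyad)) "none" else x$downstream_dyad
  cat(sprintf("%s rule: triad %s at offset %d-%d | -10 tetrad %s | dyad %s\n",
              x$sigma_label, x$triad, x$offset_min, x$offset_max,
              x$minus10_tetrad, dy))
  invisible(x)
}

#' Default rule sets for the curated promoter collections
#'
#' `ct_specificity_rules()` returns rules for the five C. thermocellum
#' sigma-I factors of the curated collection. The sigma-I1 (CTC immediately
#' upstream of the A-tract, CGAA tetrad, AT dyad) and sigma-I3 (CCC up to two
#' nt upstream; CGWA tetrad and RT dyad so that the CGTA/GT variant of the
#' sigI3 promoter is admitted) rules encode the experimentally characterized
#' preferences; the sigma-I2/-I4/-I6 triads are synthetic placeholders
#' consistent with the synthetic curated sets shipped with the package.
#' `pc_sigI11_rule()` is the P. cellulosolvens sigma-I11 rule (CCC
#' immediately upstream of the A-tract, CGCA tetrad of the conserved CGCAT
#' pentad).
#'
#' @return a named list of [specificity_rule()] objects (or a single rule).
#' @export
ct_specificity_rules <- function() {
  rules <- list(
    specificity_rule("sigI1", "CTC", 0L, 0L, "CGAA", "AT"),
    specificity_rule("sigI2", "TGT", 0L, 0L, "CGAA", NULL),
    specificity_rule("sigI3", "CCC", 0L, 2L, "CGWA", "RT"),
    specificity_rule("sigI4", "GAG", 0L, 0L, "CGAA", NULL),
    specificity_rule("sigI6", "TAC", 0L, 0L, "CGAA", NULL)
  )
  stats::setNames(rules, vapply(rules, `[[`, character(1), "sigma_label"))
}

#' @rdname ct_specificity_rules
#' @export
pc_sigI11_rule <- function() {
  specificity_rule("sigI11", "CCC", 0L, 0L, "CGCA", NULL)
}

# rule check for one candidate row; returns matched offset or NA
.rule_offset <- function(spec_seq, rule) {
  L <- nchar(spec_seq)
  for (o in rule$offset_min:rule$offset_max) {
    lo <- L - o - 2L
    if (lo < 1L) next
    if (iupac_match(rule$triad, substr(spec_seq, lo, lo + 2L))) return(o)
  }
  NA_integer_
}

.rule_pass <- function(candidates, rule, count_based = FALSE, min_c = 3L) {
  m10full <- if ("downstream_seq" %in% names(candidates)) {
    paste0(candidates$minus10_seq, candidates$downstream_seq)
  } else candidates$minus10_seq
  n <- nrow(candidates)
  offs <- rep(NA_integer_, n)
  pass <- logical(n)
  for (i in seq_len(n)) {
    if (count_based) {
      sp <- candidates$specificity_seq[i]
      tail5 <- substr(sp, max(1L, nchar(sp) - 4L), nchar(sp))
      ok_triad <- sum(strsplit(tail5, "")[[1]] == "C") >= min_c
      if (ok_triad) offs[i] <- 0L
    } else {
      offs[i] <- .rule_offset(candidates$specificity_seq[i], rule)
      ok_triad <- !is.na(offs[i])
    }
    if (!ok_triad) next
    tet <- substr(m10full[i], 1L, 4L)
    if (nchar(tet) < 4L || !iupac_match(rule$minus10_tetrad, tet)) next
    if (!is.null(rule$downstream_dyad)) {
      dy <- substr(m10full[i], 8L, 9L)
      if (nchar(dy) < 2L || !iupac_match(rule$downstream_dyad, dy)) next
    }
    pass[i] <- TRUE
  }
  list(pass = pass, offset = ifelse(pass, offs, NA_integer_))
}

#' Filter promoter candidates by a region-of-specificity rule
#'
#' Keeps candidates satisfying the rule and records the matched triad offset
#' in a `matched_offset` column. With `count_based = TRUE` the triad
#' criterion is replaced by a cytosine-count criterion (at least `min_c` C in
#' the 5 nt immediately upstream of the A-tract); tetrad and dyad checks are
#' unchanged.
#'
#' @param candidates data.frame with `specificity_seq` and `minus10_seq`
#'   (plus `downstream_seq` when the -10 context is split).
#' @param rule a [specificity_rule()].
#' @param count_based use the cytosine-enrichment count rule instead of the
#'   positional triad.
#' @param min_c minimum C count for the count-based rule.
#' @return the kept rows of `candidates` with a `matched_offset` column.
#' @export
apply_specificity_rule <- function(candidates, rule, count_based = FALSE,
                                   min_c = 3L) {
  chk <- .rule_pass(candidates, rule, count_based = count_based, min_c = min_c)
  out <- candidates[chk$pass, , drop = FALSE]
  out$matched_offset <- chk$offset[chk$pass]
  rownames(out) <- NULL
  out
}

#' Predict promoter candidates genome-wide or from upstream regions
#'
#' `scope = "upstream_only"` scans each gene's upstream window on its sense
#' strand and assigns every match to that gene, with the 5'-UTR distance
#' measured from the -10 core 3' end to the first codon; matches shared by
#' overlapping windows are collapsed by genomic coordinates, keeping the
#' assignment with the smallest 5'-UTR. `scope = "whole_genome"` scans both
#' strands of the full genome and assigns each match to the nearest
#' downstream gene on the match strand with 5'-UTR at most `window` nt
#' (unassigned matches are kept with `NA`).
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param annotations data.frame from [read_annotations()].
#' @param spec a [motif_spec()].
#' @param window upstream window / maximum 5'-UTR in nt (default 600).
#' @param scope `"upstream_only"` or `"whole_genome"`.
#' @return data.frame of candidates: [scan_genome()] columns plus
#'   `assigned_gene` and `utr5`.
#' @export
predict_promoters <- function(genome, annotations, spec = motif_spec(),
                              window = 600L,
                              scope = c("upstream_only", "whole_genome")) {
  scope <- match.arg(scope)
  if (scope == "upstream_only") {
    out <- list()
    for (i in seq_len(nrow(annotations))) {
      gene <- annotations[i, ]
      region <- extract_upstream(genome, gene, window)
      if (!nzchar(region$seq)) next
      m <- scan_bipartite(region$seq, spec)
      if (!nrow(m)) next
      R <- nchar(region$seq)
      utr5 <- R - m$m10_end
      at <- .region_to_genomic(region, m$atract_start, m$atract_end)
      mt <- .region_to_genomic(region, m$m10_start, m$m10_end)
      m$atract_start <- at$start; m$atract_end <- at$end
      m$m10_start <- mt$start; m$m10_end <- mt$end
      m <- cbind(contig = region$contig, strand = gene$strand, m,
                 stringsAsFactors = FALSE)
      m$assigned_gene <- gene$locus_tag
      m$utr5 <- utr5
      out[[length(out) + 1L]] <- m
    }
    if (!length(out)) {
      empty <- cbind(contig = character(0), strand = character(0),
                     .empty_matches())
      empty$assigned_gene <- character(0); empty$utr5 <- integer(0)
      return(empty)
    }
    res <- do.call(rbind, out)
    # collapse duplicates from overlapping windows: one report per genomic
    # site, assigned to the gene with the smallest 5'-UTR
    key <- paste(res$contig, res$strand, res$atract_start, res$atract_end,
                 res$m10_start, sep = "|")
    res <- res[order(key, res$utr5), , drop = FALSE]
    res <- res[!duplicated(paste(res$contig, res$strand, res$atract_start,
                                 res$atract_end, res$m10_start, sep = "|")),
               , drop = FALSE]
  } else {
    res <- scan_genome(genome, spec, strands = "both")
    res$assigned_gene <- rep(NA_character_, nrow(res))
    res$utr5 <- rep(NA_integer_, nrow(res))
    for (i in seq_len(nrow(res))) {
      ctg <- res$contig[i]; std <- res$strand[i]
      g <- annotations[annotations$contig == ctg & annotations$strand == std, ,
                       drop = FALSE]
      if (!nrow(g)) next
      if (std == "+") {
        d <- g$start - res$m10_end[i] - 1L
      } else {
        d <- res$m10_start[i] - g$end - 1L
      }
      ok <- which(d >= 0L & d <= window)
      if (!length(ok)) next
      j <- ok[which.min(d[ok])]
      res$assigned_gene[i] <- g$locus_tag[j]
      res$utr5[i] <- d[j]
    }
  }
  gstart <- pmin(res$atract_start, res$m10_start)
  res <- res[order(res$contig, gstart, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify promoter candidates into sigma-I regulons
#'
#' For every candidate and every sigma label: the log-odds profile score is
#' reported, and the candidate is *assigned* to each label whose
#' [specificity_rule()] passes and whose score reaches `min_score`. Multiple
#' assignments are preserved -- cross-talk between sigma-I factors is a
#' biological observation, not an error -- and flagged in the `crosstalk`
#' column. Labels with a profile but no rule are scored but never assigned.
#'
#' @param candidates data.frame of candidates (from [scan_genome()] /
#'   [predict_promoters()] or promoter records).
#' @param profiles named list of [promoter_profile()] objects.
#' @param rules named list of [specificity_rule()] objects.
#' @param min_score assignment score threshold in bits (default 0: better
#'   than background).
#' @return `candidates` with per-label `score_*` columns, `passed_rules`,
#'   `assigned` (comma-separated), `n_assigned` and `crosstalk`.
#' @export
classify_regulon <- function(candidates, profiles, rules, min_score = 0) {
  if (!length(profiles)) stop("need at least one profile")
  labels <- names(profiles)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("profiles must be a named list keyed by sigma label")
  }
  n <- nrow(candidates)
  scores <- matrix(NA_real_, n, length(labels),
                   dimnames = list(NULL, labels))
  passed <- matrix(FALSE, n, length(labels), dimnames = list(NULL, labels))
  for (lab in labels) {
    scores[, lab] <- predict(profiles[[lab]], candidates)
    if (lab %in% names(rules)) {
      passed[, lab] <- .rule_pass(candidates, rules[[lab]])$pass
    }
  }
  assigned <- passed & (scores >= min_score)
  out <- candidates
  for (lab in labels) out[[paste0("score_", lab)]] <- scores[, lab]
  collapse <- function(m) {
    apply(m, 1L, function(r) paste(labels[r], collapse = ","))
  }
  out$passed_rules <- if (n) collapse(passed) else character(0)
  out$assigned <- if (n) collapse(assigned) else character(0)
  out$n_assigned <- if (n) rowSums(assigned) else integer(0)
  out$crosstalk <- out$n_assigned > 1L
  out
}

#' Candidate x sigma cross-talk matrix
#'
#' Tabulates [classify_regulon()] assignments as a logical matrix with one
#' row per candidate and one column per sigma label, plus the per-candidate
#' cross-talk degree (row sum).
#'
#' @param assignments output of [classify_regulon()].
#' @param sigma_labels column order; defaults to the labels seen in the
#'   `score_*` columns.
#' @return data.frame: `candidate`, one logical column per sigma label,
#'   `degree`.
#' @export
crosstalk_matrix <- function(assignments, sigma_labels = NULL) {
  if (is.null(sigma_labels)) {
    sigma_labels <- sub("^score_", "",
                        grep("^score_", names(assignments), value = TRUE))
  }
  id <- if ("assigned_gene" %in% names(assignments) &&
            any(!is.na(assignments$assigned_gene))) {
    ifelse(is.na(assignments$assigned_gene),
           sprintf("candidate_%d", seq_len(nrow(assignments))),
           assignments$assigned_gene)
  } else if ("gene_label" %in% names(assignments)) {
    assignments$gene_label
  } else {
    sprintf("candidate_%d", seq_len(nrow(assignments)))
  }
  sets <- if (nrow(assignments)) {
    strsplit(ifelse(is.na(assignments$assigned), "", assignments$assigned),
             ",")
  } else list()
  m <- vapply(sigma_labels, function(lab) {
    vapply(sets, function(s) lab %in% s, logical(1))
  }, logical(nrow(assignments)))
  m <- matrix(m, nrow = nrow(assignments), ncol = length(sigma_labels),
              dimnames = list(NULL, sigma_labels))
  out <- data.frame(candidate = id, m, degree = rowSums(m),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Transfer a sigma-I regulon model to another genome
#'
#' Composition of [predict_promoters()], [apply_specificity_rule()] and
#' [classify_regulon()] against a single source profile: the pipeline used
#' to find promoters in a target species that resemble the source sigma-I
#' factor's promoters (e.g. C. thermocellum sigma-I3-style promoters in the
#' P. cellulosolvens genome).
#'
#' @param profile source [promoter_profile()].
#' @param rule source [specificity_rule()].
#' @param genome,annotations target genome and annotation.
#' @param spec a [motif_spec()].
#' @param window maximum 5'-UTR in nt.
#' @param scope scan scope, see [predict_promoters()].
#' @param min_score assignment threshold in bits.
#' @return assignment table sorted by decreasing source-profile score.
#' @export
transfer_regulon <- function(profile, rule, genome, annotations,
                             spec = motif_spec(), window = 600L,
                             scope = "whole_genome", min_score = 0) {
  cand <- predict_promoters(genome, annotations, spec, window, scope)
  kept <- apply_specificity_rule(cand, rule)
  lab <- profile$sigma_label
  res <- classify_regulon(kept, stats::setNames(list(profile), lab),
                          stats::setNames(list(rule), lab), min_score)
  res[order(-res[[paste0("score_", lab)]]), , drop = FALSE]
}
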