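# Reporter-assay quantification: delta-FU with the not-detected rule, and
# relative promoter activity versus a wild-type control.

#' Induced-minus-uninduced fluorescence with the not-detected rule
#'
#' Computes `delta_fu = fu_induced - fu_uninduced` (fluorescence units at
#' OD600 = 1) and applies the not-detected (ND) rule: a measurement is ND
#' when delta-FU is negative or zero, or when its standard deviation across
#' replicates exceeds delta-FU. ND values are reported as `NA` with the
#' reason recorded; no arithmetic is ever performed on them downstream.
#'
#' @param fu_induced,fu_uninduced non-negative fluorescence units.
#' @param sd non-negative standard deviation of delta-FU across replicates.
#' @param strain_label optional labels carried through.
#' @return data.frame with `delta_fu` (NA when ND), `nd` and `nd_reason`
#'   (`"negative_or_zero"`, `"sd_exceeds"` or `"none"`).
#' @examples
#' delta_fu(100, 40, 10)   # delta-FU 60
#' delta_fu(100, 60, 50)   # ND: sd 50 exceeds delta-FU 40
#' @export
delta_fu <- function(fu_induced, fu_uninduced, sd, strain_label = NULL) {
  if (any(sd < 0)) stop("standard deviation must be non-negative")
  if (any(fu_induced < 0) || any(fu_uninduced < 0)) {
    stop("fluorescence units must be non-negative")
  }
  d <- fu_induced - fu_uninduced
  reason <- ifelse(d <= 0, "negative_or_zero",
                   ifelse(sd > d, "sd_exceeds", "none"))
  out <- data.frame(delta_fu = ifelse(reason == "none", d, NA_real_),
                    nd = reason != "none", nd_reason = reason,
                    stringsAsFactors = FALSE)
  if (!is.null(strain_label)) out <- cbind(strain_label = strain_label, out)
  out
}

#' Promoter activity relative to a wild-type control
#'
#' `100 * mutant / wildtype` delta-FU, with the wild type defined as 100%.
#' ND mutants propagate as ND. The ratio of per-condition mean delta-FU is
#' used (not the mean of per-replicate ratios).
#'
#' @param mutant result row(s) of [delta_fu()], or a numeric delta-FU vector
#'   (NA = ND).
#' @param wildtype a single non-ND, positive [delta_fu()] result (or
#'   numeric).
#' @return data.frame with `relative_activity` (percent; NA when ND) and
#'   `nd`.
#' @examples
#' relative_activity(delta_fu(356, 50, 12), delta_fu(250, 50, 10))  # 153%
#' @export
relative_activity <- function(mutant, wildtype) {
  mut <- if (is.data.frame(mutant)) mutant$delta_fu else as.numeric(mutant)
  wt <- if (is.data.frame(wildtype)) wildtype$delta_fu else as.numeric(wildtype)
  if (length(wt) != 1L) stop("wildtype must be a single measurement")
  if (is.na(wt) || wt <= 0) stop("wild-type delta-FU is ND or non-positive")
  data.frame(relative_activity = 100 * mut / wt, nd = is.na(mut))
}

#' Quantify a reporter measurement table
#'
#' Applies [delta_fu()] to a table of measurements (columns `strain_label`,
#' `fu_induced`, `fu_uninduced`, `sd`, optionally `n`) and, when a wild-type
#' strain label is given, adds the relative activity column.
#'
#' @param table data.frame of reporter measurements.
#' @param wildtype optional `strain_label` of the wild-type control.
#' @return the table with `delta_fu`, `nd`, `nd_reason` and (optionally)
#'   `relative_activity` columns.
#' @export
reporter_activity <- function(table, wildtype = NULL) {
  need <- c("strain_label", "fu_induced", "fu_uninduced", "sd")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("measurement table lacks column(s): ",
                         paste(miss, collapse = ", "))
  res <- delta_fu(table$fu_induced, table$fu_uninduced, table$sd)
  out <- cbind(table, res)
  if (!is.null(wildtype)) {
    i <- which(table$strain_label == wildtype)
    if (length(i) != 1L) stop("wild-type strain '", wildtype,
                              "' not found exactly once")
    wt <- res$delta_fu[i]
    if (is.na(wt) || wt <= 0) stop("wild-type delta-FU is ND or non-positive")
    out$relative_activity <- 100 * res$delta_fu / wt
  }
  out
}

#' @rdname reporter_activity
#' @param path TSV file of reporter measurements.
#' @export
read_reporter_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
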