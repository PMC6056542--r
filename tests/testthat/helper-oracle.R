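# Independent brute-force scanner used as the oracle for scan_bipartite.
# Deliberately built on a different route (character vector + rle run
# detection, own IUPAC table) than the package implementation.

.oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N")
)

oracle_scan <- function(seq, spacer_min = 12, spacer_max = 15,
                        core_len = 3, m10 = "CGHH") {
  chars <- strsplit(toupper(seq), "")[[1]]
  m10_sets <- lapply(strsplit(m10, "")[[1]], function(s) .oracle_iupac[[s]])
  r <- rle(chars == "A")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= core_len)
  out <- list()
  for (k in keep) {
    a1 <- starts[k]; a2 <- ends[k]
    for (s in spacer_min:spacer_max) {
      j <- a2 + s + 1L
      if (j + length(m10_sets) - 1L > length(chars)) next
      ok <- TRUE
      for (t in seq_along(m10_sets)) {
        if (!(chars[j + t - 1L] %in% m10_sets[[t]])) { ok <- FALSE; break }
      }
      if (ok) out[[length(out) + 1L]] <- c(a1, a2, s, j)
    }
  }
  if (!length(out)) {
    return(data.frame(atract_start = integer(0), atract_end = integer(0),
                      spacer_len = integer(0), m10_start = integer(0)))
  }
  m <- do.call(rbind, out)
  df <- data.frame(atract_start = m[, 1], atract_end = m[, 2],
                   spacer_len = m[, 3], m10_start = m[, 4])
  df[order(df$atract_start, df$m10_start), , drop = FALSE]
}

# key-set comparison between implementation and oracle
match_keys <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(paste(df$atract_start, df$atract_end, df$spacer_len, df$m10_start,
             sep = ":"))
}

rand_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1]]),
        collapse = "")
}
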