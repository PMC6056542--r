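# Seeded synthetic genomes with planted sigma-I promoters.
#
# The generator emulates the statistical structure the analysis assumes: an
# i.i.d. clostridial-like background (configurable GC), bipartite promoters
# planted at non-overlapping positions on sampled strands (region of
# specificity with a sigma-specific triad, all-A tract, rejection-screened
# spacer, realized -10 core, downstream context), and one downstream gene
# per plant at a sampled 5'-UTR distance. Plants are screened so that each
# contributes exactly one bipartite match at its intended coordinates;
# background matches elsewhere are left untouched, so recall is measured
# against truth coordinates rather than total counts.

#' Parametric promoter generator for one sigma-I factor
#'
#' @param sigma_label sigma label for truth rows.
#' @param triad 3-nt degenerate specificity triad.
#' @param offset gap (nt) between the triad 3' end and the A-tract start.
#' @param tetrad degenerate -10 core realized per plant (default `"CGAA"`).
#' @param dyad optional 2-nt pattern written 3 nt after the tetrad.
#' @param tract_lengths,tract_probs A-tract length distribution
#'   (default 3-5 nt centred on the 4-nt consensus tract).
#' @param forbid_triads triads that must not appear anywhere in the
#'   specificity window (used to build decoy promoters that cannot pass a
#'   given specificity rule).
#' @return object of class `sigma_generator`.
#' @export
sigma_generator <- function(sigma_label, triad, offset = 0L, tetrad = "CGAA",
                            dyad = NULL, tract_lengths = c(3L, 4L, 5L),
                            tract_probs = c(.25, .5, .25),
                            forbid_triads = character(0)) {
  .check_iupac(triad, "triad")
  .check_iupac(tetrad, "tetrad")
  if (!is.null(dyad)) .check_iupac(dyad, "dyad")
  stopifnot(nchar(triad) == 3L, offset >= 0L,
            length(tract_lengths) == length(tract_probs))
  structure(list(sigma_label = sigma_label, triad = toupper(triad),
                 offset = as.integer(offset), tetrad = toupper(tetrad),
                 dyad = if (is.null(dyad)) NULL else toupper(dyad),
                 tract_lengths = as.integer(tract_lengths),
                 tract_probs = tract_probs,
                 forbid_triads = toupper(forbid_triads)),
            class = "sigma_generator")
}

#' Sample promoter records from a parametric generator
#'
#' Draws full promoter records (specificity window with the generator's
#' triad written in, A-tract, screened spacer, realized -10 core plus
#' downstream context) from a [sigma_generator()], e.g. to fit a
#' [promoter_profile()] for a sigma factor defined only parametrically.
#'
#' @param object a [sigma_generator()].
#' @param nsim number of records.
#' @param seed optional integer seed.
#' @param spec a [motif_spec()].
#' @param gc GC fraction of the filler background.
#' @param spacer_probs spacer length probabilities (default uniform).
#' @param ... unused.
#' @return data.frame of promoter records.
#' @export
simulate.sigma_generator <- function(object, nsim = 1, seed = NULL,
                                     spec = motif_spec(), gc = 0.38,
                                     spacer_probs = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  nsp <- spec$spacer_max - spec$spacer_min + 1L
  if (is.null(spacer_probs)) spacer_probs <- rep(1 / nsp, nsp)
  bg <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  rows <- lapply(seq_len(nsim), function(i) {
    pl <- .generate_plant(object, spec, spacer_probs, bg)
    data.frame(sigma_label = object$sigma_label,
               gene_label = sprintf("gen_%s_%04d", object$sigma_label, i),
               specificity_seq = pl$spec_seq,
               atract_seq = strrep("A", pl$tract_len),
               spacer_seq = substr(pl$seq, pl$atract_end + 1L,
                                   pl$m10_start - 1L),
               minus10_seq = substr(pl$seq, pl$m10_start, nchar(pl$seq)),
               utr5 = NA_integer_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Synthetic genome specification
#'
#' Bundles everything [simulate_genome()] needs. The defaults are the
#' package's standard study conditions: a 38% GC clostridial-like
#' background, 5'-UTR distances uniform on 30-300 nt, and 300-nt synthetic
#' genes.
#'
#' @param genome_length contig length in nt.
#' @param gc GC fraction in (0, 1) (default 0.38).
#' @param per_sigma_plants named integer vector: plants per sigma label.
#' @param generators named list of [sigma_generator()] objects covering the
#'   labels in `per_sigma_plants`.
#' @param spacer_probs probabilities of spacer lengths
#'   `spec$spacer_min:spec$spacer_max` (default uniform).
#' @param utr5_range inclusive bounds of the sampled 5'-UTR distance.
#' @param gene_length synthetic gene length in nt.
#' @param n_decoys decoy genes without a planted promoter.
#' @param seed mandatory integer seed; identical specs give byte-identical
#'   outputs.
#' @param spec the [motif_spec()] used for plant screening.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(genome_length, gc = 0.38, per_sigma_plants,
                           generators, spacer_probs = NULL,
                           utr5_range = c(30L, 300L), gene_length = 300L,
                           n_decoys = 0L, seed, spec = motif_spec()) {
  if (missing(seed)) stop("seed is mandatory")
  if (!(gc > 0 && gc < 1)) stop("gc must be in (0, 1)")
  if (any(per_sigma_plants < 0)) stop("plant counts must be non-negative")
  miss <- setdiff(names(per_sigma_plants), names(generators))
  if (length(miss)) stop("no generator for sigma label(s): ",
                         paste(miss, collapse = ", "))
  nsp <- spec$spacer_max - spec$spacer_min + 1L
  if (is.null(spacer_probs)) spacer_probs <- rep(1 / nsp, nsp)
  if (length(spacer_probs) != nsp) stop("spacer_probs length mismatch")
  structure(list(genome_length = as.integer(genome_length), gc = gc,
                 per_sigma_plants = per_sigma_plants, generators = generators,
                 spacer_probs = spacer_probs,
                 utr5_range = as.integer(utr5_range),
                 gene_length = as.integer(gene_length),
                 n_decoys = as.integer(n_decoys),
                 seed = as.integer(seed), spec = spec),
            class = "synthetic_spec")
}

#' Generate an i.i.d. background genome
#'
#' Bases are drawn independently with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`.
#'
#' @param length contig length (>= 1).
#' @param gc GC fraction in (0, 1).
#' @param seed optional integer seed (reproducible draws).
#' @param contig_id contig name.
#' @return a single-contig `DNAStringSet`.
#' @export
make_background <- function(length, gc, seed = NULL, contig_id = "contig_1") {
  if (length < 1) stop("length must be >= 1")
  if (!(gc > 0 && gc < 1)) stop("gc must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sq <- paste(sample(names(p), length, replace = TRUE, prob = p),
              collapse = "")
  out <- Biostrings::DNAStringSet(sq)
  names(out) <- contig_id
  out
}

# sample one promoter plant; returns the plant string plus local element
# coordinates, rejection-screened so that the plant scans to exactly one
# bipartite match at the intended coordinates
.generate_plant <- function(gen, spec, spacer_probs, bg_probs) {
  w <- spec$specificity_window
  dw <- spec$downstream_window
  core_len <- nchar(spec$minus35_core)
  spacer_lens <- spec$spacer_min:spec$spacer_max
  for (try in 1:200) {
    tract_len <- sample(gen$tract_lengths, 1L, prob = gen$tract_probs)
    if (tract_len < core_len) next
    # specificity window: background filler with the triad written in
    repeat {
      sp <- sample(names(bg_probs), w, replace = TRUE, prob = bg_probs)
      tri <- strsplit(.iupac_realize(gen$triad), "")[[1]]
      lo <- w - gen$offset - 2L
      if (lo < 1L) stop("triad offset exceeds the specificity window")
      sp[lo:(lo + 2L)] <- tri
      if (sp[w] == "A") next  # would extend the A-tract 5'
      spstr <- paste(sp, collapse = "")
      if (length(gen$forbid_triads) &&
          any(vapply(gen$forbid_triads, grepl, logical(1), x = spstr,
                     fixed = TRUE))) next
      break
    }
    tract <- strrep("A", tract_len)
    slen <- sample(spacer_lens, 1L, prob = spacer_probs)
    repeat {
      spacer <- sample(names(bg_probs), slen, replace = TRUE, prob = bg_probs)
      if (spacer[1L] != "A") break  # keeps the tract 3' end exact
    }
    m10 <- .iupac_realize(gen$tetrad)
    down <- sample(names(bg_probs), dw, replace = TRUE, prob = bg_probs)
    if (!is.null(gen$dyad)) {
      dy <- strsplit(.iupac_realize(gen$dyad), "")[[1]]
      down[4:5] <- dy
    }
    plant <- paste0(spstr, tract, paste(spacer, collapse = ""), m10,
                    paste(down, collapse = ""))
    m <- scan_bipartite(plant, spec)
    ok <- nrow(m) == 1L && m$atract_start == w + 1L &&
      m$atract_end == w + tract_len &&
      m$m10_start == w + tract_len + slen + 1L
    if (ok) {
      return(list(seq = plant, tract_len = tract_len, spacer_len = slen,
                  spec_seq = spstr, m10_core = m10,
                  atract_start = w + 1L, atract_end = w + tract_len,
                  m10_start = w + tract_len + slen + 1L,
                  m10_end = w + tract_len + slen + nchar(m10)))
    }
  }
  stop("failed to generate a clean promoter plant after 200 attempts")
}

#' Plant promoters into a background genome
#'
#' Divides the (single-contig) genome into one slot per plant, writes a
#' generated promoter at a random position on a random strand inside each
#' slot, and records the exact truth coordinates of every element, the
#' sampled 5'-UTR distance and the downstream synthetic gene coordinates.
#' Slots guarantee that plants (and their genes) never overlap each other.
#'
#' @param genome background `DNAStringSet` (first contig is used).
#' @param sspec a [synthetic_spec()]; its `seed` is *not* applied here --
#'   use [simulate_genome()] for fully seeded generation.
#' @return list with `genome` (plants written in) and `truth` (data.frame).
#' @export
plant_promoters <- function(genome, sspec) {
  spec <- sspec$spec
  seqs <- .genome_chars(genome)
  ctg <- names(seqs)[1L]
  sq <- seqs[[ctg]]
  L <- nchar(sq)
  counts <- sspec$per_sigma_plants
  n <- sum(counts)
  if (n == 0L) {
    return(list(genome = genome, truth = .empty_truth()))
  }
  labels <- sample(rep(names(counts), counts))
  plant_max <- spec$specificity_window + max(vapply(sspec$generators, function(g)
    max(g$tract_lengths), integer(1))) + spec$spacer_max +
    nchar(spec$minus10_core) + spec$downstream_window
  required <- plant_max + max(sspec$utr5_range) + sspec$gene_length + 20L
  slot <- L %/% n
  if (slot < required) {
    stop(sprintf("genome too small for %d plants (need >= %d nt)",
                 n, n * required))
  }
  bg <- c(A = (1 - sspec$gc) / 2, C = sspec$gc / 2, G = sspec$gc / 2,
          T = (1 - sspec$gc) / 2)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gen <- sspec$generators[[labels[i]]]
    pl <- .generate_plant(gen, spec, sspec$spacer_probs, bg)
    plen <- nchar(pl$seq)
    utr5 <- sample(sspec$utr5_range[1]:sspec$utr5_range[2], 1L)
    strand <- sample(c("+", "-"), 1L)
    layout_len <- plen + utr5 + sspec$gene_length
    bin_start <- (i - 1L) * slot + 1L
    offset <- sample.int(slot - layout_len - 1L, 1L)
    if (strand == "+") {
      pstart <- bin_start + offset
      pend <- pstart + plen - 1L
      substr(sq, pstart, pend) <- pl$seq
      a1 <- pstart + pl$atract_start - 1L; a2 <- pstart + pl$atract_end - 1L
      m1 <- pstart + pl$m10_start - 1L; m2 <- pstart + pl$m10_end - 1L
      gene_start <- m2 + utr5 + 1L
      gene_end <- gene_start + sspec$gene_length - 1L
    } else {
      gene_start <- bin_start + offset
      gene_end <- gene_start + sspec$gene_length - 1L
      # -10 core 3' end (genomic low coordinate) sits utr5+1 above gene_end
      m_low <- gene_end + utr5 + 1L
      pstart <- m_low - (plen - pl$m10_end)
      pend <- pstart + plen - 1L
      substr(sq, pstart, pend) <- .revcomp(pl$seq)
      flip <- function(lo, hi) c(pstart + plen - hi, pstart + plen - lo)
      a <- flip(pl$atract_start, pl$atract_end)
      m <- flip(pl$m10_start, pl$m10_end)
      a1 <- a[1]; a2 <- a[2]; m1 <- m[1]; m2 <- m[2]
    }
    rows[[i]] <- data.frame(
      contig = ctg, strand = strand, sigma_label = labels[i],
      locus_tag = sprintf("SYN_%04d", i),
      plant_start = pstart, plant_end = pend,
      atract_start = a1, atract_end = a2,
      m10_start = m1, m10_end = m2,
      tract_len = pl$tract_len, spacer_len = pl$spacer_len,
      specificity_seq = pl$spec_seq, m10_core = pl$m10_core,
      utr5 = utr5, gene_start = gene_start, gene_end = gene_end,
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, rows)
  out <- Biostrings::DNAStringSet(sq)
  names(out) <- ctg
  list(genome = out, truth = truth)
}

.empty_truth <- function() {
  data.frame(contig = character(0), strand = character(0),
             sigma_label = character(0), locus_tag = character(0),
             plant_start = integer(0), plant_end = integer(0),
             atract_start = integer(0), atract_end = integer(0),
             m10_start = integer(0), m10_end = integer(0),
             tract_len = integer(0), spacer_len = integer(0),
             specificity_seq = character(0), m10_core = character(0),
             utr5 = integer(0), gene_start = integer(0),
             gene_end = integer(0), stringsAsFactors = FALSE)
}

#' Derive gene annotations from a planted-promoter truth table
#'
#' One synthetic gene per planted promoter, at the recorded coordinates
#' (`utr5` nt downstream of the -10 core 3' end on the promoter strand),
#' plus optional decoy genes placed away from all planted regions.
#'
#' @param truth truth table from [plant_promoters()].
#' @param genome the planted genome (needed to bound decoy placement and to
#'   validate coordinates).
#' @param n_decoys number of promoter-free decoy genes.
#' @param decoy_length decoy gene length in nt.
#' @return annotation data.frame as in [read_annotations()].
#' @export
make_annotations <- function(truth, genome, n_decoys = 0L,
                             decoy_length = 300L) {
  seqs <- .genome_chars(genome)
  L <- vapply(seqs, nchar, numeric(1))
  if (nrow(truth) && (any(truth$gene_start < 1L) ||
                      any(truth$gene_end > L[truth$contig]))) {
    stop("synthetic gene would run off the contig")
  }
  ann <- data.frame(
    contig = truth$contig, start = truth$gene_start, end = truth$gene_end,
    strand = truth$strand, locus_tag = truth$locus_tag,
    product = paste0("synthetic ", truth$sigma_label, " target"),
    stringsAsFactors = FALSE
  )
  if (n_decoys > 0L) {
    ctg <- names(seqs)[1L]
    occupied <- cbind(pmin(truth$plant_start, truth$gene_start),
                      pmax(truth$plant_end, truth$gene_end))
    placed <- 0L; tries <- 0L
    while (placed < n_decoys && tries < 10000L) {
      tries <- tries + 1L
      s <- sample.int(L[[ctg]] - decoy_length, 1L)
      e <- s + decoy_length - 1L
      if (nrow(truth) &&
          any(s <= occupied[, 2] & e >= occupied[, 1])) next
      placed <- placed + 1L
      ann <- rbind(ann, data.frame(
        contig = ctg, start = s, end = e,
        strand = sample(c("+", "-"), 1L),
        locus_tag = sprintf("DEC_%04d", placed),
        product = "synthetic decoy gene", stringsAsFactors = FALSE
      ))
      occupied <- rbind(occupied, c(s, e))
    }
    if (placed < n_decoys) stop("could not place all decoy genes")
  }
  rownames(ann) <- NULL
  ann
}

#' Simulate a full synthetic study: genome, truth table, annotations
#'
#' Seeds once from `sspec$seed`, then background generation, promoter
#' planting and annotation derivation; identical specs therefore give
#' byte-identical FASTA/GFF3/truth outputs.
#'
#' @param sspec a [synthetic_spec()].
#' @return list with `genome`, `truth`, `annotations`.
#' @export
simulate_genome <- function(sspec) {
  set.seed(sspec$seed)
  genome <- make_background(sspec$genome_length, sspec$gc)
  planted <- plant_promoters(genome, sspec)
  ann <- make_annotations(planted$truth, planted$genome,
                          n_decoys = sspec$n_decoys)
  list(genome = planted$genome, truth = planted$truth, annotations = ann)
}

#' Verify that a truth table re-slices to its generating elements
#'
#' Checks, for every truth row, that the genomic A-tract interval is all A
#' (with non-A flanks inside the contig), and that the -10 interval equals
#' the realized core (after strand correction).
#'
#' @param genome the planted genome.
#' @param truth the truth table.
#' @return logical vector, one entry per truth row.
#' @export
check_truth <- function(genome, truth) {
  seqs <- .genome_chars(genome)
  vapply(seq_len(nrow(truth)), function(i) {
    r <- truth[i, ]
    sq <- seqs[[r$contig]]
    at <- substr(sq, r$atract_start, r$atract_end)
    m10 <- substr(sq, r$m10_start, r$m10_end)
    if (r$strand == "-") { at <- .revcomp(at); m10 <- .revcomp(m10) }
    grepl("^A+$", at) && m10 == r$m10_core
  }, logical(1))
}

#' @rdname simulate_genome
#' @param truth truth table.
#' @param path output TSV.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname simulate_genome
#' @export
read_truth_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
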