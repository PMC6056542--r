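# Genome, annotation and result I/O.
#
# Coordinate conventions: everything inside the package is 1-based inclusive
# (the R/Bioconductor convention), so GFF3 coordinates are used as-is; BED
# output converts to 0-based half-open on the way out.

# normalize a genome argument to a named list of uppercase character strings
.genome_chars <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.list(toupper(as.character(genome)))
  } else if (is.character(genome)) {
    out <- as.list(toupper(genome))
  } else {
    stop("genome must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    stop("genome contigs must be named")
  }
  out
}

#' Read a genome from a FASTA file
#'
#' Wraps `Biostrings::readDNAStringSet()` with the normalization the
#' scanners expect: sequences are uppercased, contig ids are the first
#' whitespace-delimited word of each header, and IUPAC ambiguity codes other
#' than N are degraded to N (with a warning) so that draft genomes remain
#' scannable without ever matching a concrete pattern base.
#'
#' @param path FASTA file.
#' @return a `DNAStringSet` over the alphabet A, C, G, T, N.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("FASTA parse error in '", path, "': ",
                                         conditionMessage(e)))
  if (length(x) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  chr <- toupper(as.character(x))
  n_amb <- sum(vapply(chr, function(s) nchar(gsub("[ACGTN]", "", s)), numeric(1)))
  if (n_amb > 0) {
    warning(sprintf("%d ambiguity code(s) other than N converted to N", n_amb))
    chr <- vapply(chr, function(s) gsub("[^ACGTN]", "N", s), character(1))
  }
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- ids
  out
}

#' Write a genome to a FASTA file
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param path output file.
#' @param width line width (default 70).
#' @export
write_genome <- function(genome, path, width = 70L) {
  seqs <- .genome_chars(genome)
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read gene annotations from GFF3 or a minimal TSV
#'
#' GFF3 features of type `gene` or `CDS` are kept (all features if no such
#' types are present); the locus tag is taken from the `locus_tag` attribute,
#' falling back to `ID`. The TSV dialect expects columns `contig`, `start`,
#' `end`, `strand`, `locus_tag` and optionally `product`, with 1-based
#' inclusive coordinates. Strandless features are rejected: every promoter
#' operation here is orientation-dependent.
#'
#' @param path input file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @param genome optional genome; features on unknown contigs or outside the
#'   contig are rejected.
#' @return data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `locus_tag`, `product` (1-based inclusive).
#' @export
read_annotations <- function(path, dialect = c("gff3", "tsv"), genome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    df <- as.data.frame(gr)
    if ("type" %in% names(df) && any(df$type %in% c("gene", "CDS"))) {
      df <- df[df$type %in% c("gene", "CDS"), , drop = FALSE]
    }
    tag <- if ("locus_tag" %in% names(df)) df$locus_tag else NULL
    if (is.null(tag) || all(is.na(tag))) tag <- df$ID
    if (is.null(tag)) stop("GFF3 features carry neither locus_tag nor ID")
    ann <- data.frame(
      contig = as.character(df$seqnames),
      start = df$start, end = df$end,
      strand = as.character(df$strand),
      locus_tag = as.character(tag),
      product = if ("product" %in% names(df)) as.character(df$product) else NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("contig", "start", "end", "strand", "locus_tag")
    miss <- setdiff(need, names(ann))
    if (length(miss)) stop("TSV annotation lacks column(s): ",
                           paste(miss, collapse = ", "))
    if (!"product" %in% names(ann)) ann$product <- NA_character_
    ann <- ann[, c(need, "product")]
    ann$contig <- as.character(ann$contig)
    ann$strand <- as.character(ann$strand)
    ann$locus_tag <- as.character(ann$locus_tag)
  }
  if (any(!ann$strand %in% c("+", "-"))) {
    bad <- ann$locus_tag[!ann$strand %in% c("+", "-")]
    stop("strandless or invalid-strand feature(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  ann$start <- as.integer(ann$start); ann$end <- as.integer(ann$end)
  if (any(ann$start > ann$end) || any(ann$start < 1L)) {
    stop("invalid coordinates (need 1 <= start <= end)")
  }
  if (anyDuplicated(ann$locus_tag)) {
    stop("duplicate locus_tag(s): ",
         paste(unique(ann$locus_tag[duplicated(ann$locus_tag)]), collapse = ", "))
  }
  if (!is.null(genome)) {
    seqs <- .genome_chars(genome)
    unknown <- setdiff(unique(ann$contig), names(seqs))
    if (length(unknown)) stop("feature(s) on unknown contig(s): ",
                              paste(unknown, collapse = ", "))
    len <- vapply(seqs, nchar, numeric(1))[ann$contig]
    if (any(ann$end > len)) stop("feature(s) extend beyond contig end")
  }
  rownames(ann) <- NULL
  ann
}

#' Write gene annotations as GFF3
#'
#' Deterministic, input-ordered writer used by the synthetic-genome module.
#'
#' @param annotations data.frame as returned by [read_annotations()].
#' @param path output file.
#' @export
write_annotations_gff3 <- function(annotations, path) {
  prod <- ifelse(is.na(annotations$product), "",
                 paste0(";product=", annotations$product))
  lines <- sprintf("%s\tsigiscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s%s",
                   annotations$contig, annotations$start, annotations$end,
                   annotations$strand, annotations$locus_tag,
                   annotations$locus_tag, prod)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Extract the upstream region of a gene
#'
#' Returns the window immediately 5' of the gene in its reading orientation:
#' genomic `[start-window, start-1]` read forward for plus-strand genes,
#' `[end+1, end+window]` reverse-complemented for minus-strand genes. The
#' window is truncated silently at contig edges. The returned object carries
#' the genomic coordinates needed to back-map any match found in the region.
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param gene one-row data.frame (or list) with `contig`, `start`, `end`,
#'   `strand` (1-based inclusive).
#' @param window upstream window length in nt (default 600).
#' @return list of class `upstream_region` with `seq`, `gstart`, `gend`,
#'   `strand`, `contig`, `gene`, `window_requested`.
#' @export
extract_upstream <- function(genome, gene, window = 600L) {
  stopifnot(window >= 1)
  seqs <- .genome_chars(genome)
  ctg <- as.character(gene$contig)
  if (!ctg %in% names(seqs)) stop("gene contig '", ctg, "' absent from genome")
  L <- nchar(seqs[[ctg]])
  if (gene$start < 1L || gene$end > L) stop("gene lies outside its contig")
  if (gene$strand == "+") {
    gstart <- max(1L, gene$start - as.integer(window))
    gend <- gene$start - 1L
    sq <- if (gend >= gstart) substr(seqs[[ctg]], gstart, gend) else ""
  } else if (gene$strand == "-") {
    gstart <- gene$end + 1L
    gend <- min(L, gene$end + as.integer(window))
    sq <- if (gend >= gstart) .revcomp(substr(seqs[[ctg]], gstart, gend)) else ""
  } else {
    stop("gene strand must be '+' or '-'")
  }
  structure(list(seq = sq, gstart = gstart, gend = gend,
                 strand = gene$strand, contig = ctg,
                 gene = gene, window_requested = as.integer(window)),
            class = "upstream_region")
}

# Map a local interval [lo, hi] inside an upstream region back to genomic
# coordinates (1-based inclusive, start <= end on the plus strand).
.region_to_genomic <- function(region, lo, hi) {
  if (region$strand == "+") {
    list(start = region$gstart + lo - 1L, end = region$gstart + hi - 1L)
  } else {
    list(start = region$gend - hi + 1L, end = region$gend - lo + 1L)
  }
}

#' Write promoter candidates to TSV or BED
#'
#' The TSV format round-trips every candidate column through
#' [read_candidates()]. BED6 output is 0-based half-open over the full
#' element span (A-tract through -10 core); the name field encodes the
#' assigned sigma label(s) when present (`.` otherwise) together with the
#' assigned gene.
#'
#' @param candidates data.frame from [scan_genome()], [predict_promoters()]
#'   or [classify_regulon()].
#' @param path output file.
#' @param format `"tsv"` or `"bed"`.
#' @export
write_candidates <- function(candidates, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    need <- c("contig", "strand", "atract_start", "atract_end",
              "m10_start", "m10_end")
    miss <- setdiff(need, names(candidates))
    if (length(miss)) stop("BED output needs genomic coordinates; missing: ",
                           paste(miss, collapse = ", "))
    if (nrow(candidates)) {
      lo <- pmin(candidates$atract_start, candidates$m10_start)
      hi <- pmax(candidates$atract_end, candidates$m10_end)
      sig <- if ("assigned" %in% names(candidates)) {
        ifelse(is.na(candidates$assigned) | candidates$assigned == "",
               ".", gsub(",", "+", candidates$assigned))
      } else "."
      gene <- if ("assigned_gene" %in% names(candidates)) {
        ifelse(is.na(candidates$assigned_gene), ".", candidates$assigned_gene)
      } else "."
      lines <- sprintf("%s\t%d\t%d\t%s|%s\t0\t%s",
                       candidates$contig, lo - 1L, hi, sig, gene,
                       candidates$strand)
      writeLines(lines, path)
    } else {
      writeLines(character(0), path)
    }
  }
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = NA, na.strings = "NA")
}
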