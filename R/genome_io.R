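#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement DNAString matchPattern subseq
#' @importFrom BiocGenerics start end width
#' @importFrom methods is
#' @importFrom stats setNames
#' @importFrom utils head read.delim write.table
NULL

# Allowed genome alphabet after normalization.  Primers are held to a stricter
# {A,C,G,T} alphabet later; N is legal in a genome.
GENOME_ALPHABET <- c("A", "C", "G", "T", "N")

#' Normalize a nucleotide string to the genome alphabet
#'
#' Uppercases, maps U to T, and verifies every residue is one of A, C, G, T, N.
#'
#' @param x character scalar of residues.
#' @param what label used in error messages.
#' @return normalized character scalar.
#' @keywords internal
normalize_residues <- function(x, what = "sequence") {
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- gsub("[ACGTN]", "", x)
  if (nzchar(bad)) {
    stop(sprintf("%s contains disallowed residue(s) after normalization: %s",
                 what, paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")),
         call. = FALSE)
  }
  x
}

#' Construct a genome from named sequences
#'
#' Builds the genome container used throughout the package: a
#' [Biostrings::DNAStringSet] with unique contig names and residues normalized
#' to uppercase A/C/G/T/N (U is mapped to T).
#'
#' @param x named character vector of contig sequences, or a `DNAStringSet`.
#' @return a `DNAStringSet` with unique names.
#' @export
#' @examples
#' g <- as_genome(c(c1 = "acgtn"))
#' as.character(g[["c1"]])
as_genome <- function(x) {
  if (is(x, "DNAStringSet")) x <- setNames(as.character(x), names(x))
  if (!is.character(x)) stop("genome must be a named character vector or DNAStringSet")
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("every contig must be named")
  }
  if (anyDuplicated(names(x))) {
    dup <- unique(names(x)[duplicated(names(x))])
    stop(sprintf("duplicate contig id(s): %s", paste(dup, collapse = ", ")))
  }
  x <- vapply(seq_along(x), function(i) {
    normalize_residues(x[[i]], what = sprintf("contig '%s'", names(x)[i]))
  }, character(1), USE.NAMES = FALSE) |> setNames(names(x))
  DNAStringSet(x)
}

#' Read a multi-record FASTA file into a genome
#'
#' Wraps [Biostrings::readDNAStringSet()] and then applies the package's
#' normalization rules: residues uppercased, U mapped to T, only A/C/G/T/N
#' allowed, duplicate contig ids rejected.  FASTA descriptions are trimmed to
#' the first whitespace-delimited token.
#'
#' @param path path to a FASTA file.
#' @return a `DNAStringSet` genome.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  # read raw (BStringSet) so normalization (U -> T, case) happens under the
  # package's rules rather than Biostrings' DNA alphabet coercion
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) {
      stop(sprintf("malformed FASTA in %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) return(DNAStringSet())
  nm <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(nm))) {
    line <- which(!nzchar(nm))[1]
    stop(sprintf("malformed FASTA header (record %d) in %s", line, path))
  }
  as_genome(setNames(as.character(set), nm))
}

#' Write a genome to FASTA
#'
#' @param genome a `DNAStringSet` genome.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  writeXStringSet(as_genome(genome), path, width = width)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Standard Watson-Crick complement, reversed; N maps to N.  Character in,
#' character out: the workhorse for strand-aware extraction and primer
#' orientation.
#'
#' @param seq character scalar over A/C/G/T/N (case-insensitive, U allowed).
#' @return reverse-complemented character scalar (uppercase).
#' @export
#' @examples
#' reverse_complement("ATGC")  # "GCAT"
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- normalize_residues(seq, what = "sequence")
  if (!nzchar(seq)) return(seq)
  as.character(reverseComplement(DNAString(seq)))
}

#' Create a genomic interval
#'
#' Internal coordinates are 0-based half-open throughout the package;
#' GFF3 input (1-based inclusive) is converted at the boundary.
#'
#' @param contig_id contig name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @param strand "+" or "-".
#' @return a `genomic_interval` list.
#' @export
genomic_interval <- function(contig_id, start, end, strand = "+") {
  stopifnot(length(contig_id) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end) {
    stop("interval requires start <= end")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(
    list(contig_id = as.character(contig_id), start = start, end = end,
         strand = strand),
    class = "genomic_interval"
  )
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<interval %s:[%d,%d) %s width=%d>\n",
              x$contig_id, x$start, x$end, x$strand, x$end - x$start))
  invisible(x)
}

#' Extract a (possibly clipped) region from the genome
#'
#' Returns the plus-strand substring for `strand = "+"`, its reverse
#' complement for `strand = "-"`.  Intervals running past a contig boundary
#' are clipped, not rejected; the achieved interval is reported alongside the
#' sequence so callers can see how much was lost.
#'
#' @param genome a `DNAStringSet` genome.
#' @param interval a `genomic_interval` (start may be negative, end may exceed
#'   the contig: both are clipped).
#' @return list with `sequence`, `achieved` (the clipped `genomic_interval`),
#'   and `clipped` (logical).
#' @export
extract_region <- function(genome, interval) {
  stopifnot(inherits(interval, "genomic_interval"))
  if (!interval$contig_id %in% names(genome)) {
    stop(sprintf("unknown contig: %s", interval$contig_id))
  }
  len <- width(genome)[match(interval$contig_id, names(genome))]
  s <- max(0L, interval$start)
  e <- min(len, interval$end)
  if (s > e) { s <- min(s, len); e <- s }
  achieved <- genomic_interval(interval$contig_id, s, e, interval$strand)
  seq <- if (e > s) {
    as.character(subseq(genome[[interval$contig_id]], start = s + 1L, end = e))
  } else ""
  if (interval$strand == "-" && nzchar(seq)) seq <- reverse_complement(seq)
  list(sequence = seq, achieved = achieved,
       clipped = (s != interval$start || e != interval$end))
}

#' Construct a gene model
#'
#' @param gene_id gene identifier.
#' @param contig_id contig the gene lies on.
#' @param strand "+" or "-".
#' @param cds_segments list of `genomic_interval`s in transcript (5' to 3')
#'   order, all on `contig_id` with strand equal to `strand`.
#' @param translation_start 0-based genomic offset of the A of the start
#'   codon (on the plus-strand axis).
#' @param atg_ok logical; whether the codon at the annotated start reads ATG
#'   on the coding strand.  Models failing the check are kept, flagged.
#' @return a `gene_model` list.
#' @export
gene_model <- function(gene_id, contig_id, strand, cds_segments,
                       translation_start, atg_ok = NA) {
  stopifnot(strand %in% c("+", "-"), length(cds_segments) >= 1L)
  total <- sum(vapply(cds_segments, function(iv) iv$end - iv$start, integer(1)))
  if (total < 3L) stop(sprintf("gene %s: total CDS length < 3", gene_id))
  structure(
    list(gene_id = as.character(gene_id), contig_id = as.character(contig_id),
         strand = strand, cds_segments = cds_segments,
         translation_start = as.integer(translation_start), atg_ok = atg_ok),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s %s(%s) start=%d segments=%d atg_ok=%s>\n",
              x$gene_id, x$contig_id, x$strand, x$translation_start,
              length(x$cds_segments), x$atg_ok))
  invisible(x)
}

# Verify the start codon reads ATG on the coding strand.
check_atg <- function(genome, contig_id, strand, translation_start) {
  len <- width(genome)[match(contig_id, names(genome))]
  if (strand == "+") {
    if (translation_start + 3L > len) return(FALSE)
    iv <- genomic_interval(contig_id, translation_start, translation_start + 3L, "+")
  } else {
    if (translation_start - 2L < 0L) return(FALSE)
    iv <- genomic_interval(contig_id, translation_start - 2L, translation_start + 1L, "-")
  }
  identical(extract_region(genome, iv)$sequence, "ATG")
}

#' Read gene models from a GFF3 file
#'
#' Imports CDS features (via [rtracklayer::import()]), groups them by their
#' `Parent` (falling back to `gene_id`/`ID`), converts coordinates to the
#' package's 0-based half-open convention and derives the translation start
#' from the first CDS base in transcript orientation (the highest coordinate
#' for minus-strand genes).  Models whose annotated start codon does not read
#' ATG on the coding strand are returned flagged (`atg_ok = FALSE`), never
#' silently dropped.
#'
#' @param path GFF3 file path.
#' @param genome `DNAStringSet` genome the features must lie on.
#' @return named list of `gene_model`s.
#' @export
read_gene_models <- function(path, genome) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) return(list())
  meta <- S4Vectors::mcols(gr)
  parent <- if ("Parent" %in% names(meta)) {
    vapply(meta$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))
  for (alt in c("gene_id", "ID", "Name")) {
    if (all(!is.na(parent))) break
    if (alt %in% names(meta)) {
      v <- as.character(meta[[alt]])
      parent[is.na(parent)] <- v[is.na(parent)]
    }
  }
  if (any(is.na(parent))) {
    stop("CDS feature without a Parent/gene_id/ID attribute")
  }
  contig <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(contig), names(genome))
  if (length(unknown)) {
    stop(sprintf("CDS references unknown contig(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  clen <- setNames(width(genome), names(genome))
  if (any(start(gr) < 1L) || any(end(gr) > clen[contig])) {
    stop("CDS feature out of contig bounds")
  }
  models <- list()
  for (gid in unique(parent)) {
    idx <- which(parent == gid)
    g <- gr[idx]
    strand <- unique(as.character(BiocGenerics::strand(g)))
    if (length(strand) != 1L || !strand %in% c("+", "-")) {
      stop(sprintf("gene %s: CDS segments must share one of strand +/-", gid))
    }
    ctg <- unique(as.character(GenomicRanges::seqnames(g)))
    if (length(ctg) != 1L) stop(sprintf("gene %s: CDS on multiple contigs", gid))
    # to 0-based half-open, transcript order
    s0 <- start(g) - 1L; e0 <- end(g)
    ord <- if (strand == "+") order(s0) else order(-s0)
    s0 <- s0[ord]; e0 <- e0[ord]
    if (length(s0) > 1L) {
      gs <- sort(s0); ge <- e0[order(s0)]
      if (any(gs[-1] < ge[-length(ge)])) {
        stop(sprintf("gene %s: overlapping CDS segments", gid))
      }
    }
    segs <- Map(function(a, b) genomic_interval(ctg, a, b, strand), s0, e0)
    tstart <- if (strand == "+") s0[1] else e0[1] - 1L
    models[[gid]] <- gene_model(
      gid, ctg, strand, segs, tstart,
      atg_ok = check_atg(genome, ctg, strand, tstart)
    )
  }
  models
}
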