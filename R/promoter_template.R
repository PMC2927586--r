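# Promoter design templates: the 3000 bp upstream + 150 bp downstream region
# around a gene's translation start, always oriented promoter -> ATG -> coding.
# Translation starts come from annotation when a gene model exists, or from
# anchoring the 5' prefix of a CDS to the genome for unannotated candidates.

#' Locate a translation start by anchoring a CDS prefix to the genome
#'
#' Searches both strands of every contig for exact occurrences of the first
#' `min_anchor` bases of the CDS (which must begin with ATG).  A unique hit
#' yields the genomic position of the A of the ATG and the strand.  Absence
#' and ambiguity are distinct failures; on ambiguity the anchor is doubled
#' (up to the CDS length) and the search retried when `retry = TRUE`.
#'
#' @param cds_sequence coding sequence, 5' to 3', beginning with ATG.
#' @param genome a `DNAStringSet` genome.
#' @param min_anchor anchor length in bp (default 30).
#' @param retry double the anchor and retry on ambiguity.
#' @return list with `contig_id`, `position` (0-based offset of the A of ATG
#'   on the plus-strand axis), `strand`, and `anchor_used`.
#' @export
locate_translation_start <- function(cds_sequence, genome, min_anchor = 30L,
                                     retry = TRUE) {
  cds_sequence <- normalize_residues(cds_sequence, "CDS")
  if (nchar(cds_sequence) < min_anchor) {
    stop(sprintf("CDS shorter than min_anchor (%d < %d)",
                 nchar(cds_sequence), min_anchor))
  }
  if (substr(cds_sequence, 1, 3) != "ATG") stop("CDS must begin with ATG")
  anchor_len <- as.integer(min_anchor)
  repeat {
    anchor <- substr(cds_sequence, 1L, anchor_len)
    hits <- anchor_hits(anchor, genome)
    if (nrow(hits) == 1L) {
      return(list(contig_id = hits$contig_id, position = hits$position,
                  strand = hits$strand, anchor_used = anchor_len))
    }
    if (nrow(hits) == 0L) {
      stop(sprintf("CDS anchor (%d bp) not found in genome", anchor_len),
           call. = FALSE)
    }
    if (!retry || anchor_len >= nchar(cds_sequence)) {
      stop(sprintf("CDS anchor (%d bp) is ambiguous: %d genomic hits",
                   anchor_len, nrow(hits)), call. = FALSE)
    }
    anchor_len <- min(nchar(cds_sequence), anchor_len * 2L)
  }
}

# Exact anchor occurrences on both strands; position is the plus-axis offset
# of the ATG's A: match start on +, match end - 1 on -.
anchor_hits <- function(anchor, genome) {
  out <- list()
  rc <- reverse_complement(anchor)
  for (ctg in names(genome)) {
    subject <- genome[[ctg]]
    fwd <- matchPattern(anchor, subject)
    if (length(fwd)) {
      out[[length(out) + 1L]] <- data.frame(
        contig_id = ctg, position = start(fwd) - 1L, strand = "+",
        stringsAsFactors = FALSE)
    }
    rev <- matchPattern(rc, subject)
    if (length(rev)) {
      out[[length(out) + 1L]] <- data.frame(
        contig_id = ctg, position = end(rev) - 1L, strand = "-",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(contig_id = character(), position = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Build a promoter design template around a translation start
#'
#' Extracts `upstream` bp before and `downstream` bp from the translation
#' start (the downstream span includes the ATG itself), reverse-complementing
#' minus-strand genes so the template always reads promoter -> ATG -> coding.
#' Spans clipped at contig boundaries are recorded in
#' `upstream_achieved`/`downstream_achieved`; a short downstream span is
#' flagged, and a template too short upstream for any legal product
#' (`upstream_achieved` < 2150) is marked undesignable.
#'
#' @param genome a `DNAStringSet` genome.
#' @param gene a `gene_model`, or a list with `contig_id`, `position`,
#'   `strand` as returned by [locate_translation_start()].
#' @param upstream bp upstream of the ATG to extract (default 3000).
#' @param downstream bp from the A of the ATG onward to extract (default 150).
#' @param gene_id identifier for located (annotation-free) starts.
#' @return a `promoter_template` object: `gene_id`, `sequence`, `atg_offset`,
#'   `source_interval`, `upstream_achieved`, `downstream_achieved`, `flags`.
#' @export
build_template <- function(genome, gene, upstream = 3000L, downstream = 150L,
                           gene_id = NULL) {
  if (inherits(gene, "gene_model")) {
    contig_id <- gene$contig_id
    position <- gene$translation_start
    strand <- gene$strand
    gene_id <- gene$gene_id
    atg_ok <- isTRUE(gene$atg_ok) || is.na(gene$atg_ok)
  } else {
    contig_id <- gene$contig_id
    position <- gene$position
    strand <- gene$strand
    if (is.null(gene_id)) gene_id <- gene$gene_id %||% "unnamed"
    atg_ok <- TRUE
  }
  if (!contig_id %in% names(genome)) {
    stop(sprintf("unknown contig: %s", contig_id))
  }
  clen <- width(genome)[match(contig_id, names(genome))]
  if (strand == "+") {
    if (position > clen - 3L) stop("translation start within 3 bp of contig end")
    iv <- genomic_interval(contig_id, position - upstream,
                           position + downstream, "+")
  } else {
    if (position < 2L) stop("translation start within 3 bp of contig end")
    # mirror interval: downstream runs toward lower coordinates
    iv <- genomic_interval(contig_id, position - downstream + 1L,
                           position + upstream + 1L, "-")
  }
  ext <- extract_region(genome, iv)
  if (strand == "+") {
    upstream_achieved <- position - ext$achieved$start
    downstream_achieved <- ext$achieved$end - position
  } else {
    upstream_achieved <- ext$achieved$end - position - 1L
    downstream_achieved <- position - ext$achieved$start + 1L
  }
  flags <- character(0)
  if (downstream_achieved < downstream) flags <- c(flags, "short_downstream")
  if (upstream_achieved < upstream) flags <- c(flags, "short_upstream")
  if (upstream_achieved < 2150L) flags <- c(flags, "undesignable")
  if (!atg_ok) flags <- c(flags, "no_atg")
  tpl <- structure(
    list(gene_id = gene_id, sequence = ext$sequence,
         atg_offset = as.integer(upstream_achieved),
         source_interval = ext$achieved,
         upstream_achieved = as.integer(upstream_achieved),
         downstream_achieved = as.integer(downstream_achieved),
         flags = flags),
    class = "promoter_template"
  )
  stopifnot(nchar(tpl$sequence) == tpl$upstream_achieved + tpl$downstream_achieved)
  tpl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.promoter_template <- function(x, ...) {
  cat(sprintf("<promoter_template %s len=%d atg_offset=%d up=%d down=%d%s>\n",
              x$gene_id, nchar(x$sequence), x$atg_offset,
              x$upstream_achieved, x$downstream_achieved,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}
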