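# Construct-funnel tracking and Plant Ontology (PO) expression analytics.
#
# Constructs move through an ordered funnel from primer design to
# GFP-positive transgenic lines; per-stage attrition gives the pipeline's
# success rates.  GFP observations on transgenic lines are annotated with PO
# codes at four screening stages; per-code promoter counts, consistency
# categories across lines, and code/gene/tissue queries summarize them.

#' Ordered funnel stages
#' @export
FUNNEL_STAGES <- c("primer_designed", "entry_clone", "sequence_confirmed",
                   "expression_clone", "agro_clone", "dipped",
                   "transgenic_positive", "in_soil", "gfp_positive")

#' GFP screening stages
#' @export
SCREENING_STAGES <- c("plate_day10", "rosette", "pre_flowering", "flowering")

#' Round half-up
#'
#' Base R rounds half to even; funnel percentages use the conventional
#' half-up rule (74.75 -> 74.8).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Validate pipeline records
#'
#' Records are one row per gene with a logical column per funnel stage.
#' Stage statuses must be monotone: a stage can be reached only if all
#' prior stages were reached.
#'
#' @param df data.frame with `gene_id` and logical columns named after
#'   [FUNNEL_STAGES].
#' @return validated data.frame of class `pipeline_records`.
#' @export
as_pipeline_records <- function(df) {
  stopifnot(is.data.frame(df), "gene_id" %in% names(df))
  missing <- setdiff(FUNNEL_STAGES, names(df))
  if (length(missing)) {
    stop(sprintf("missing stage column(s): %s", paste(missing, collapse = ", ")))
  }
  for (s in FUNNEL_STAGES) df[[s]] <- as.logical(df[[s]])
  m <- as.matrix(df[, FUNNEL_STAGES])
  if (anyNA(m)) stop("stage statuses must be TRUE/FALSE, not NA")
  later <- m[, -1, drop = FALSE] & !m[, -ncol(m), drop = FALSE]
  if (any(later)) {
    bad <- df$gene_id[which(rowSums(later) > 0)]
    stop(sprintf("non-monotone stage statuses for gene(s): %s",
                 paste(head(bad, 5), collapse = ", ")))
  }
  class(df) <- c("pipeline_records", "data.frame")
  df
}

#' Per-stage reached counts
#'
#' @param records a `pipeline_records` data.frame or a named numeric vector
#'   of per-stage counts.
#' @return named integer vector over [FUNNEL_STAGES] (counts are
#'   non-increasing along the funnel).
#' @export
stage_counts <- function(records) {
  if (is.numeric(records)) {
    missing <- setdiff(names(records), FUNNEL_STAGES)
    if (length(missing)) {
      stop(sprintf("unknown stage(s): %s", paste(missing, collapse = ", ")))
    }
    return(records)
  }
  records <- as_pipeline_records(as.data.frame(records))
  colSums(as.matrix(records[, FUNNEL_STAGES]))
}

#' Stage-to-stage success rate
#'
#' 100 x (number reaching `stage_to`) / (number reaching `stage_from`),
#' rounded half-up to one decimal.
#'
#' @param records `pipeline_records` or named per-stage counts.
#' @param stage_from,stage_to funnel stage names.
#' @return percentage (one decimal).
#' @export
#' @examples
#' counts <- c(primer_designed = 627, entry_clone = 469)
#' success_rate(counts, "primer_designed", "entry_clone")  # 74.8
success_rate <- function(records, stage_from, stage_to) {
  counts <- stage_counts(records)
  for (s in c(stage_from, stage_to)) {
    if (!s %in% names(counts)) stop(sprintf("unknown stage: %s", s))
  }
  denom <- counts[[stage_from]]
  if (denom == 0) stop(sprintf("no record reached stage '%s'", stage_from))
  round_half_up(100 * counts[[stage_to]] / denom, 1L)
}

#' Read/write pipeline records as delimited text
#'
#' @param path file path.
#' @return `pipeline_records` data.frame.
#' @export
read_pipeline_records <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE)
  as_pipeline_records(df)
}

#' @rdname read_pipeline_records
#' @param records a `pipeline_records` data.frame.
#' @export
write_pipeline_records <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

PO_CODE_PATTERN <- "^PO:[0-9]{7}$"

#' Validate PO annotations
#'
#' One row per (image, PO code): `image_id`, `line_id`, `gene_id`, `stage`
#' (one of [SCREENING_STAGES]) and `po_code` (`PO:nnnnnnn`).  Invalid codes,
#' codes absent from the vocabulary, and unknown stages are errors at load
#' time.
#'
#' @param df annotation data.frame.
#' @param vocabulary named character vector, PO code -> name; defaults to
#'   the packaged vocabulary (see [po_vocabulary()]).
#' @return validated data.frame of class `po_annotations`.
#' @export
as_po_annotations <- function(df, vocabulary = po_vocabulary()) {
  need <- c("image_id", "line_id", "gene_id", "stage", "po_code")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  bad <- !grepl(PO_CODE_PATTERN, df$po_code)
  if (any(bad)) {
    stop(sprintf("invalid PO code(s): %s",
                 paste(unique(df$po_code[bad]), collapse = ", ")))
  }
  unknown <- setdiff(df$po_code, names(vocabulary))
  if (length(unknown)) {
    stop(sprintf("PO code(s) not in vocabulary: %s",
                 paste(unknown, collapse = ", ")))
  }
  badstage <- setdiff(unique(df$stage), SCREENING_STAGES)
  if (length(badstage)) {
    stop(sprintf("unknown screening stage(s): %s",
                 paste(badstage, collapse = ", ")))
  }
  class(df) <- c("po_annotations", "data.frame")
  attr(df, "vocabulary") <- vocabulary
  df
}

# Per-line expression pattern: the union of the line's PO codes over all
# screening stages, as a sorted character vector.
line_patterns <- function(lines, annotations) {
  pat <- split(annotations$po_code, annotations$line_id)
  lapply(setNames(lines$line_id, lines$line_id), function(id) {
    sort(unique(pat[[id]] %||% character(0)))
  })
}

#' Classify GFP expression consistency across one gene's transgenic lines
#'
#' A line's pattern is the union of its PO codes over all screening stages;
#' a line expresses iff its pattern is non-empty.  Two lines agree when
#' their patterns are equal non-empty sets (or share at least one code in
#' the relaxed mode).  Categories: `consistent_multi` (two or more
#' expressing lines, all agreeing), `single_line_expressing` (the gene's
#' only line expresses), `single_expressing_of_many` (several lines, exactly
#' one expresses), `inconsistent` (two or more expressing lines with
#' disagreeing patterns), `no_expression` (no line expresses).
#' `independent_dip_consistent` is TRUE for consistent_multi genes whose
#' agreeing lines come from at least two distinct floral-dip events.
#'
#' @param lines data.frame of one gene's lines: `line_id`, `gene_id`,
#'   `dip_event` (and optionally `survived_to_soil`).
#' @param annotations `po_annotations` rows for those lines.
#' @param relaxed use non-empty pattern intersection instead of exact set
#'   equality for agreement.
#' @return list with `category`, `independent_dip_consistent`,
#'   `n_lines`, `n_expressing`, `patterns`.
#' @export
classify_consistency <- function(lines, annotations, relaxed = FALSE) {
  stopifnot(nrow(lines) >= 1L)
  if (length(unique(lines$gene_id)) != 1L) {
    stop("classify_consistency takes the lines of a single gene")
  }
  patterns <- line_patterns(lines, annotations)
  expressing <- vapply(patterns, function(p) length(p) > 0L, logical(1))
  expr_pat <- patterns[expressing]
  agree <- function(a, b) {
    if (relaxed) length(intersect(a, b)) > 0L else identical(a, b)
  }
  all_agree <- length(expr_pat) >= 2L &&
    all(vapply(expr_pat[-1], agree, logical(1), b = expr_pat[[1]]))
  category <- if (sum(expressing) == 0L) {
    "no_expression"
  } else if (nrow(lines) == 1L) {
    "single_line_expressing"
  } else if (sum(expressing) == 1L) {
    "single_expressing_of_many"
  } else if (all_agree) {
    "consistent_multi"
  } else {
    "inconsistent"
  }
  idc <- FALSE
  if (category == "consistent_multi") {
    dips <- unique(lines$dip_event[expressing[match(lines$line_id,
                                                    names(patterns))]])
    idc <- length(dips) >= 2L
  }
  list(category = category, independent_dip_consistent = idc,
       n_lines = nrow(lines), n_expressing = sum(expressing),
       patterns = patterns)
}

#' Classify consistency for every gene in a line table
#'
#' @param lines data.frame of lines (`line_id`, `gene_id`, `dip_event`).
#' @param annotations `po_annotations`.
#' @param relaxed see [classify_consistency()].
#' @return data.frame, one row per gene: `gene_id`, `category`,
#'   `independent_dip_consistent`, `n_lines`, `n_expressing`.
#' @export
classify_all_consistency <- function(lines, annotations, relaxed = FALSE) {
  res <- lapply(split(lines, lines$gene_id), function(gl) {
    cl <- classify_consistency(gl, annotations[annotations$line_id %in%
                                                 gl$line_id, , drop = FALSE],
                               relaxed = relaxed)
    data.frame(gene_id = gl$gene_id[1], category = cl$category,
               independent_dip_consistent = cl$independent_dip_consistent,
               n_lines = cl$n_lines, n_expressing = cl$n_expressing,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarize PO annotations into promoters-per-code counts
#'
#' Counts the distinct genes annotated with each code (a gene annotated on
#' many images still counts once), the number of distinct codes, and the
#' most frequent code (ties broken by lexicographically smallest code).
#' Order-invariant and idempotent.
#'
#' @param annotations `po_annotations` (or any data.frame with `gene_id`
#'   and `po_code`).
#' @param vocabulary named character vector PO code -> name.
#' @return `po_summary` data.frame (`po_code`, `po_name`, `n_promoters`),
#'   sorted by descending count then code, with attributes
#'   `n_distinct_codes` and `most_frequent` (list: `po_code`, `n_promoters`).
#' @export
summarize_po <- function(annotations, vocabulary = po_vocabulary()) {
  if (!nrow(annotations)) {
    out <- data.frame(po_code = character(), po_name = character(),
                      n_promoters = integer(), stringsAsFactors = FALSE)
    attr(out, "n_distinct_codes") <- 0L
    attr(out, "most_frequent") <- NULL
    class(out) <- c("po_summary", "data.frame")
    return(out)
  }
  pairs <- unique(annotations[, c("gene_id", "po_code")])
  tab <- table(pairs$po_code)
  out <- data.frame(po_code = names(tab),
                    po_name = unname(vocabulary[names(tab)]),
                    n_promoters = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_promoters, out$po_code), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_distinct_codes") <- nrow(out)
  top <- out[out$n_promoters == max(out$n_promoters), , drop = FALSE]
  top <- top[order(top$po_code), , drop = FALSE]
  attr(out, "most_frequent") <- list(po_code = top$po_code[1],
                                     n_promoters = top$n_promoters[1])
  class(out) <- c("po_summary", "data.frame")
  out
}

#' @export
print.po_summary <- function(x, ...) {
  cat(sprintf("<po_summary: %d distinct code(s)", attr(x, "n_distinct_codes")))
  mf <- attr(x, "most_frequent")
  if (!is.null(mf)) {
    cat(sprintf("; most frequent %s (%d promoters)", mf$po_code,
                mf$n_promoters))
  }
  cat(">\n")
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more row(s)\n", nrow(x) - 10))
  invisible(x)
}

#' Assemble an annotation store
#'
#' Desk-scale stand-in for the project LIMS: line and annotation tables plus
#' the PO vocabulary, queryable by code, gene or tissue-name substring and
#' round-trippable through delimited text.
#'
#' @param lines data.frame of transgenic lines (`line_id`, `gene_id`,
#'   `dip_event`, optionally `survived_to_soil`).
#' @param annotations `po_annotations`.
#' @param vocabulary named character vector PO code -> name.
#' @return a `po_store` list.
#' @export
po_store <- function(lines, annotations, vocabulary = po_vocabulary()) {
  annotations <- as_po_annotations(as.data.frame(annotations), vocabulary)
  structure(list(lines = lines, annotations = annotations,
                 vocabulary = vocabulary),
            class = "po_store")
}

#' Query a PO store or summary
#'
#' Exactly one of `po_code`, `gene_id`, `tissue` must be given.  Codes and
#' gene ids match exactly; `tissue` is a case-insensitive substring match
#' against PO names.  Store queries return annotation rows ordered by
#' `(gene_id, image_id)`; summary queries return summary rows.
#'
#' @param x a `po_store` or `po_summary`.
#' @param po_code exact PO code.
#' @param gene_id exact gene id (stores only).
#' @param tissue tissue-name substring.
#' @return matching rows (possibly empty).
#' @export
po_query <- function(x, po_code = NULL, gene_id = NULL, tissue = NULL) {
  keys <- c(!is.null(po_code), !is.null(gene_id), !is.null(tissue))
  if (sum(keys) != 1L) {
    stop("give exactly one of po_code, gene_id, tissue")
  }
  UseMethod("po_query")
}

#' @export
po_query.po_store <- function(x, po_code = NULL, gene_id = NULL,
                              tissue = NULL) {
  ann <- as.data.frame(x$annotations)
  hit <- if (!is.null(po_code)) {
    ann$po_code == po_code
  } else if (!is.null(gene_id)) {
    ann$gene_id == gene_id
  } else {
    codes <- names(x$vocabulary)[grepl(tissue, x$vocabulary,
                                       ignore.case = TRUE, fixed = FALSE)]
    ann$po_code %in% codes
  }
  out <- ann[hit, , drop = FALSE]
  out <- out[order(out$gene_id, out$image_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
po_query.po_summary <- function(x, po_code = NULL, gene_id = NULL,
                                tissue = NULL) {
  if (!is.null(gene_id)) stop("unknown query key for a summary: gene_id")
  df <- as.data.frame(x)
  hit <- if (!is.null(po_code)) {
    df$po_code == po_code
  } else {
    grepl(tissue, df$po_name, ignore.case = TRUE)
  }
  out <- df[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write/read a PO store as delimited text
#'
#' The store is persisted as a directory of TSV tables (`lines.tsv`,
#' `annotations.tsv`, `vocabulary.tsv`).
#'
#' @param store a `po_store`.
#' @param dir directory path (created if needed).
#' @return `dir` (write) or a `po_store` (read).
#' @export
write_po_store <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(store$lines, file.path(dir, "lines.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(store$annotations),
              file.path(dir, "annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(po_code = names(store$vocabulary),
                         po_name = unname(store$vocabulary)),
              file.path(dir, "vocabulary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_po_store
#' @export
read_po_store <- function(dir) {
  voc <- read.delim(file.path(dir, "vocabulary.tsv"), sep = "\t",
                    colClasses = "character")
  vocabulary <- setNames(voc$po_name, voc$po_code)
  lines <- read.delim(file.path(dir, "lines.tsv"), sep = "\t")
  annotations <- read.delim(file.path(dir, "annotations.tsv"), sep = "\t",
                            colClasses = "character")
  po_store(lines, annotations, vocabulary)
}
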