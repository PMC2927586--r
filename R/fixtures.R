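# Packaged reference data: the construct funnel stage counts, the
# promoters-per-PO-code expression summary, and the aggregate screening
# outcomes of the source screen.  These are inputs (printed tables), carried
# as plain-text fixtures; the outcome aggregates are metadata that the
# package consistency-checks but does not recompute.

PO_SUMMARY_MD5 <- "d1d9d6be5327148cc70f7011b199e7f0"

pkg_extdata <- function(name) {
  path <- system.file("extdata", name, package = "promoterforge")
  if (!nzchar(path)) stop(sprintf("packaged fixture not found: %s", name))
  path
}

#' Load the packaged funnel stage counts
#'
#' Per-stage gene counts of the reference promoter-reporter screen: 627
#' designed, 469 entry clones, 442 expression clones, 353 Agrobacterium
#' clones (= dipped), 266 transgenic-positive, 150 GFP-positive.
#'
#' @return named numeric vector over [FUNNEL_STAGES].
#' @export
load_funnel_fixture <- function() {
  df <- read.delim(pkg_extdata("reference_funnel.tsv"), sep = "\t")
  counts <- setNames(as.numeric(df$n_genes), df$stage)
  counts[FUNNEL_STAGES]
}

#' Load the packaged per-PO-code promoter counts
#'
#' The reference screen's expression summary: 81 distinct PO codes with the
#' number of distinct promoters annotated with each.  The file checksum is
#' verified so silent fixture corruption is an error, not a wrong number.
#'
#' @return a `po_summary` data.frame (see [summarize_po()]).
#' @export
load_po_summary_fixture <- function() {
  path <- pkg_extdata("po_expression_summary.tsv")
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, PO_SUMMARY_MD5)) {
    stop(sprintf("PO summary fixture checksum mismatch (%s)", md5))
  }
  df <- read.delim(path, sep = "\t", colClasses = c("character", "character",
                                                    "integer"))
  bad <- !grepl(PO_CODE_PATTERN, df$po_code)
  if (any(bad)) stop("invalid PO code in fixture")
  if (anyDuplicated(df$po_code)) stop("duplicate PO code in fixture")
  if (any(df$n_promoters < 1L)) stop("fixture count below 1")
  df <- df[order(-df$n_promoters, df$po_code), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_distinct_codes") <- nrow(df)
  top <- df[df$n_promoters == max(df$n_promoters), , drop = FALSE]
  top <- top[order(top$po_code), , drop = FALSE]
  attr(df, "most_frequent") <- list(po_code = top$po_code[1],
                                    n_promoters = top$n_promoters[1])
  class(df) <- c("po_summary", "data.frame")
  df
}

#' Packaged PO vocabulary (code -> tissue name)
#'
#' @return named character vector.
#' @export
po_vocabulary <- function() {
  df <- as.data.frame(load_po_summary_fixture())
  setNames(df$po_name, df$po_code)
}

#' Load the packaged aggregate screening outcomes
#'
#' Laboratory outcome aggregates of the reference screen (line, image and
#' annotation totals, the consistency-category split, independent-dip
#' confirmations).  They depend on wet-lab events and unpublished line-level
#' data, so they are carried as metadata and consistency-checked, never
#' recomputed.
#'
#' @return named numeric vector of outcome aggregates.
#' @export
load_reference_outcomes <- function() {
  df <- read.delim(pkg_extdata("reference_outcomes.tsv"), sep = "\t")
  setNames(as.numeric(df$value), df$key)
}
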