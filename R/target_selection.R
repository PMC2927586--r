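# Candidate selection from microarray detection calls.
#
# Genes are classified from per-array present/marginal/absent (P/M/A) calls:
# "no expression" = present in none of the arrays, "low expression" = present
# in fewer than 5% of arrays (strict inequality), everything else "expressed".
# Candidates are the no/low genes minus those with independent MPSS transcript
# evidence.

EXPRESSION_LABELS <- c("no_expression", "low_expression", "expressed")

#' Read an expression-call matrix from delimited text
#'
#' Dialect: first column gene id, header row of array ids, cells P/M/A
#' (case-insensitive).  Missing cells are not allowed implicitly: empty or NA
#' entries are imputed as A (absent) and counted, with a warning.
#'
#' @param path delimited text file (tab by default).
#' @param sep field separator.
#' @return a character matrix with gene ids as rownames, array ids as
#'   colnames, entries in {"P","M","A"}.
#' @export
read_call_matrix <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, header = TRUE, row.names = 1,
                   check.names = FALSE, colClasses = "character")
  m <- as.matrix(df)
  as_call_matrix(m)
}

#' Validate/normalize a call matrix
#'
#' @param m character matrix of calls, rownames = gene ids, colnames = array
#'   ids.
#' @return normalized call matrix.
#' @export
as_call_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("call matrix needs gene ids as rownames and array ids as colnames")
  }
  m[] <- toupper(trimws(m))
  miss <- is.na(m) | m == ""
  if (any(miss)) {
    warning(sprintf("%d missing call(s) imputed as A (absent)", sum(miss)))
    m[miss] <- "A"
  }
  bad <- !m %in% c("P", "M", "A")
  if (any(bad)) {
    stop(sprintf("invalid call value(s): %s",
                 paste(unique(m[bad]), collapse = ", ")))
  }
  m
}

#' Classify genes as no/low/expressed from P/M/A calls
#'
#' Present fraction is the number of P calls divided by the number of arrays;
#' marginal and absent calls both count as non-expressed.  A gene is
#' `no_expression` when its present fraction is exactly zero,
#' `low_expression` when the fraction is strictly below `threshold`, and
#' `expressed` otherwise (a gene exactly at the threshold is expressed).
#'
#' @param calls a call matrix (see [as_call_matrix()]).
#' @param threshold present-fraction cutoff separating low expression from
#'   expressed; default 0.05.
#' @return data.frame with columns `gene_id`, `n_present`, `n_arrays`,
#'   `present_fraction`, `label`.
#' @export
#' @examples
#' m <- matrix("A", 2, 20, dimnames = list(c("g1", "g2"), paste0("a", 1:20)))
#' m["g2", 1:3] <- "P"
#' classify_expression(m)
classify_expression <- function(calls, threshold = 0.05) {
  if (ncol(calls) == 0L) stop("call matrix has zero arrays")
  calls <- as_call_matrix(calls)
  n_arrays <- ncol(calls)
  n_present <- rowSums(calls == "P")
  frac <- n_present / n_arrays
  label <- ifelse(frac == 0, "no_expression",
                  ifelse(frac < threshold, "low_expression", "expressed"))
  data.frame(
    gene_id = rownames(calls),
    n_present = as.integer(n_present),
    n_arrays = n_arrays,
    present_fraction = frac,
    label = factor(label, levels = EXPRESSION_LABELS),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Apply the MPSS exclusion to classified genes
#'
#' Candidates are the genes labelled no/low expression whose ids are absent
#' from the MPSS-expressed list (independent sequencing-based transcript
#' evidence).  Exclusions are reported alongside the candidates; MPSS ids not
#' present among the classified genes are ignored with a warning.
#'
#' @param classes output of [classify_expression()].
#' @param mpss_expressed character vector of gene ids with MPSS expression
#'   evidence.
#' @return list with `candidates` (data.frame subset of `classes`) and
#'   `excluded` (data.frame with `gene_id` and `reason`).
#' @export
apply_mpss_exclusion <- function(classes, mpss_expressed = character()) {
  stopifnot(is.data.frame(classes), "label" %in% names(classes))
  mpss_expressed <- unique(as.character(mpss_expressed))
  unknown <- setdiff(mpss_expressed, classes$gene_id)
  if (length(unknown)) {
    warning(sprintf("%d MPSS id(s) not in the classified set (ignored)",
                    length(unknown)))
  }
  nolow <- classes[classes$label %in% c("no_expression", "low_expression"), ,
                   drop = FALSE]
  hit <- nolow$gene_id %in% mpss_expressed
  excluded <- data.frame(
    gene_id = nolow$gene_id[hit],
    reason = if (any(hit)) "mpss_expressed" else character(0),
    stringsAsFactors = FALSE
  )
  list(candidates = nolow[!hit, , drop = FALSE], excluded = excluded)
}

#' Read a plain-text gene-id list (one id per line)
#'
#' @param path file path; blank lines and `#` comments ignored.
#' @return character vector of ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}
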