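# Genome-wide primer specificity screening.
#
# A primer "hits" a genomic locus when an ungapped alignment over the full
# primer length, on either strand, reaches at least 80% identity.  A pair is
# acceptable when each primer has at most 3 such loci (the intended locus
# counts: every primer hits itself).  brute_force_matches is the exact
# sliding-window oracle; seeded_matches is the k-mer seeded fast path that is
# provably complete under the pigeonhole condition and must agree with the
# oracle there.

# Integer codes per contig/strand for fast vectorized comparison.
.seq_codes <- function(x) utf8ToInt(x)

# All windows of `plen` on one contig (plus-strand axis) whose identity to
# `codes` (primer as integer codes) is >= min_identity.  Returns 0-based
# starts and identities.
scan_codes <- function(contig_codes, codes, min_identity) {
  plen <- length(codes)
  L <- length(contig_codes)
  n_win <- L - plen + 1L
  if (n_win < 1L) {
    return(data.frame(start = integer(), identity = numeric()))
  }
  matches <- integer(n_win)
  for (k in seq_len(plen)) {
    matches <- matches + (contig_codes[k:(k + n_win - 1L)] == codes[k])
  }
  identity <- matches / plen
  hit <- identity >= min_identity
  data.frame(start = which(hit) - 1L, identity = identity[hit])
}

# Merge overlapping same-strand windows into loci anchored at the
# best-identity offset (ties -> leftmost).
merge_windows <- function(df, plen) {
  if (!nrow(df)) return(df)
  df <- df[order(df$start), , drop = FALSE]
  # windows overlap when the next start falls before the group's running
  # maximum end; chain overlaps left to right
  group <- integer(nrow(df))
  g <- 1L; max_end <- df$start[1] + plen
  group[1] <- g
  for (i in seq_len(nrow(df))[-1]) {
    if (df$start[i] < max_end) {
      group[i] <- g
      max_end <- max(max_end, df$start[i] + plen)
    } else {
      g <- g + 1L
      group[i] <- g
      max_end <- df$start[i] + plen
    }
  }
  out <- do.call(rbind, lapply(split(df, group), function(grp) {
    best <- which(grp$identity == max(grp$identity))[1]
    grp[best, , drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}

match_locus_frame <- function(contig_id, start, strand, identity, primer_role) {
  data.frame(contig_id = contig_id, start = start, strand = strand,
             identity = identity, primer_role = primer_role,
             stringsAsFactors = FALSE)
}

empty_locus_frame <- function() {
  match_locus_frame(character(), integer(), character(), numeric(),
                    character())
}

#' Brute-force genomic matches of a primer (oracle)
#'
#' Slides the primer and its reverse complement over every window of every
#' contig, scoring ungapped identity = matches / primer length, and reports
#' every window at or above `min_identity`.  Overlapping windows on the same
#' strand are merged into one locus anchored at the best-identity offset
#' (ties broken leftmost).  Exact by construction; the reference the seeded
#' fast path is tested against.
#'
#' @param primer primer sequence (length >= 10, A/C/G/T).
#' @param genome a `DNAStringSet` genome.
#' @param min_identity identity threshold (default 0.80).
#' @param primer_role label recorded on the loci ("left"/"right").
#' @return data.frame of match loci: `contig_id`, `start` (0-based),
#'   `strand`, `identity`, `primer_role`.
#' @export
brute_force_matches <- function(primer, genome, min_identity = 0.80,
                                primer_role = "left") {
  primer <- toupper(primer)
  if (nchar(primer) < 10L) stop("primer length must be >= 10")
  if (grepl("[^ACGT]", primer)) stop("primer must contain only A/C/G/T")
  plen <- nchar(primer)
  fwd <- .seq_codes(primer)
  rev <- .seq_codes(reverse_complement(primer))
  out <- list()
  for (ctg in names(genome)) {
    contig_codes <- .seq_codes(as.character(genome[[ctg]]))
    for (strand in c("+", "-")) {
      codes <- if (strand == "+") fwd else rev
      hits <- merge_windows(scan_codes(contig_codes, codes, min_identity), plen)
      if (nrow(hits)) {
        out[[length(out) + 1L]] <- match_locus_frame(
          ctg, hits$start, strand, hits$identity, primer_role)
      }
    }
  }
  if (!length(out)) return(empty_locus_frame())
  res <- do.call(rbind, out)
  res[order(res$contig_id, res$start, res$strand), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Seeded genomic matches of a primer (fast path)
#'
#' Partitions the primer into `budget + 1` disjoint exact seeds (budget =
#' `floor((1 - min_identity) * length)` substitutions) and verifies every
#' seeded window by direct ungapped comparison.  By the pigeonhole principle
#' any window within the substitution budget contains at least one exact
#' seed, so the locus set equals [brute_force_matches()] whenever
#' `(budget + 1) * seed_length <= primer length`.  When that condition fails
#' the function falls back to the brute-force scan with a warning.
#'
#' @inheritParams brute_force_matches
#' @param seed_length exact-seed length in bp (default 11).
#' @return data.frame of match loci (same shape as [brute_force_matches()]).
#' @export
seeded_matches <- function(primer, genome, min_identity = 0.80,
                           seed_length = 11L, primer_role = "left") {
  primer <- toupper(primer)
  if (nchar(primer) < 10L) stop("primer length must be >= 10")
  if (grepl("[^ACGT]", primer)) stop("primer must contain only A/C/G/T")
  plen <- nchar(primer)
  budget <- floor((1 - min_identity) * plen)
  if ((budget + 1L) * seed_length > plen) {
    warning(sprintf(
      "pigeonhole condition violated ((%d+1)*%d > %d); falling back to brute force",
      budget, seed_length, plen))
    return(brute_force_matches(primer, genome, min_identity, primer_role))
  }
  seed_offsets <- (0:budget) * seed_length  # 0-based within primer
  out <- list()
  for (ctg in names(genome)) {
    subject <- genome[[ctg]]
    contig_codes <- .seq_codes(as.character(subject))
    L <- length(contig_codes)
    for (strand in c("+", "-")) {
      oriented <- if (strand == "+") primer else reverse_complement(primer)
      # seed offsets within the oriented primer: reverse complementation
      # mirrors positions, but seeding the oriented sequence directly with
      # the same partition is equally complete
      codes <- .seq_codes(oriented)
      cand <- integer(0)
      for (off in seed_offsets) {
        seed <- substr(oriented, off + 1L, off + seed_length)
        m <- matchPattern(seed, subject)
        if (length(m)) cand <- c(cand, start(m) - 1L - off)
      }
      cand <- sort(unique(cand))
      cand <- cand[cand >= 0L & cand + plen <= L]
      if (!length(cand)) next
      ident <- vapply(cand, function(s) {
        mean(contig_codes[(s + 1L):(s + plen)] == codes)
      }, numeric(1))
      keep <- ident >= min_identity
      if (!any(keep)) next
      hits <- merge_windows(
        data.frame(start = cand[keep], identity = ident[keep]), plen)
      out[[length(out) + 1L]] <- match_locus_frame(
        ctg, hits$start, strand, hits$identity, primer_role)
    }
  }
  if (!length(out)) return(empty_locus_frame())
  res <- do.call(rbind, out)
  res[order(res$contig_id, res$start, res$strand), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Screening parameters for primer specificity
#'
#' @param max_hits maximum genomic loci allowed per primer (default 3; the
#'   intended locus counts, since a primer always hits itself).
#' @param min_identity ungapped identity threshold (default 0.80).
#' @param mode "per_primer" (default: each primer <= max_hits loci) or
#'   "amplicon" (stricter: <= max_hits convergent left/right co-placements
#'   within `max_amplicon` bp).
#' @param max_amplicon largest left-to-right span counted as a potential
#'   amplicon in "amplicon" mode.
#' @param matcher "seeded" (default) or "brute_force".
#' @return a `screen_params` list.
#' @export
screen_params <- function(max_hits = 3L, min_identity = 0.80,
                          mode = c("per_primer", "amplicon"),
                          max_amplicon = 5000L,
                          matcher = c("seeded", "brute_force")) {
  list(max_hits = as.integer(max_hits), min_identity = min_identity,
       mode = match.arg(mode), max_amplicon = as.integer(max_amplicon),
       matcher = match.arg(matcher))
}

run_matcher <- function(primer, genome, params, primer_role) {
  if (params$matcher == "brute_force") {
    return(brute_force_matches(primer, genome, params$min_identity,
                               primer_role))
  }
  plen <- nchar(primer)
  budget <- floor((1 - params$min_identity) * plen)
  seed_length <- max(1L, plen %/% (budget + 1L))
  seeded_matches(primer, genome, params$min_identity, seed_length,
                 primer_role)
}

# Count potential amplicons: convergent (+ left, - right) or (- right
# upstream ... ) co-placements on one contig within max_amplicon bp.
count_amplicons <- function(left_hits, right_hits, max_amplicon) {
  n <- 0L
  for (ctg in intersect(unique(left_hits$contig_id),
                        unique(right_hits$contig_id))) {
    l <- left_hits[left_hits$contig_id == ctg, ]
    r <- right_hits[right_hits$contig_id == ctg, ]
    for (i in seq_len(nrow(l))) for (j in seq_len(nrow(r))) {
      if (l$strand[i] == "+" && r$strand[j] == "-" &&
          r$start[j] >= l$start[i] &&
          r$start[j] - l$start[i] <= max_amplicon) n <- n + 1L
      if (l$strand[i] == "-" && r$strand[j] == "+" &&
          l$start[i] >= r$start[j] &&
          l$start[i] - r$start[j] <= max_amplicon) n <- n + 1L
    }
  }
  n
}

#' Evaluate a primer pair's genomic specificity
#'
#' Runs the matcher for each primer of the pair and applies the acceptance
#' rule: in the default "per_primer" mode the pair passes iff each primer
#' has at most `max_hits` (default 3) genomic loci at `min_identity`
#' (default 80%); the boundary is inclusive.  In the stricter "amplicon"
#' mode the pair passes iff at most `max_hits` convergent co-placements
#' could form a product.
#'
#' @param pair a `primer_pair` with concrete sequences.
#' @param genome a `DNAStringSet` genome.
#' @param params a [screen_params()] list.
#' @return a `specificity_report`: `left_hits`, `right_hits` (locus
#'   data.frames), `pass`, `max_hits`, `min_identity`, `mode`.
#' @export
evaluate_pair <- function(pair, genome, params = screen_params()) {
  stopifnot(inherits(pair, "primer_pair"))
  left_hits <- run_matcher(pair$left$sequence, genome, params, "left")
  right_hits <- run_matcher(pair$right$sequence, genome, params, "right")
  pass <- if (params$mode == "per_primer") {
    nrow(left_hits) <= params$max_hits && nrow(right_hits) <= params$max_hits
  } else {
    count_amplicons(left_hits, right_hits, params$max_amplicon) <=
      params$max_hits
  }
  structure(
    list(left_hits = left_hits, right_hits = right_hits, pass = pass,
         max_hits = params$max_hits, min_identity = params$min_identity,
         mode = params$mode),
    class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat(sprintf("<specificity_report %s: left %d, right %d loci (max %d @ >=%.0f%% identity, %s)>\n",
              if (x$pass) "PASS" else "FAIL",
              nrow(x$left_hits), nrow(x$right_hits), x$max_hits,
              100 * x$min_identity, x$mode))
  invisible(x)
}

#' Build a specificity evaluator closure for [design_for_gene()]
#'
#' @param genome a `DNAStringSet` genome.
#' @param params a [screen_params()] list.
#' @return `function(pair) -> specificity_report`.
#' @export
specificity_screen <- function(genome, params = screen_params()) {
  force(genome); force(params)
  function(pair) evaluate_pair(pair, genome, params)
}

#' Write match loci as a BED file
#'
#' 0-based half-open intervals with the identity in the score column
#' (scaled to 0-1000) and the strand column set.
#'
#' @param hits locus data.frame from a matcher.
#' @param primer_length length of the primer (defines interval width).
#' @param path output path.
#' @param name feature name prefix.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, primer_length, path, name = "hit") {
  bed <- data.frame(
    chrom = hits$contig_id,
    chromStart = hits$start,
    chromEnd = hits$start + primer_length,
    name = paste0(name, "_", hits$primer_role, "_", seq_len(nrow(hits))),
    score = as.integer(round(1000 * hits$identity)),
    strand = hits$strand
  )
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
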