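# Primer pair enumeration and scoring on a promoter template.
#
# Placement rules on a full template (ATG at offset 3000): product size
# 2150-2650 bp containing the 50 bp target window starting at the ATG, left
# primer 5' end at least 2000 bp upstream of the ATG, right primer 3' end
# between 50 and 150 bp downstream of the translation start.  Thermodynamics
# use the unified nearest-neighbor table with an Owczarzy-style monovalent
# salt correction.

# Unified nearest-neighbor parameters (dH kcal/mol, dS cal/mol/K) for the ten
# distinct DNA/DNA stacks; complementary stacks share values.
NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
# Duplex initiation per terminal base pair.
NN_INIT_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
NN_INIT_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)
NN_SYM_DS <- -1.4  # self-complementary duplex entropy correction
GAS_CONSTANT <- 1.987  # cal/(mol K)

#' Solution conditions for melting-temperature calculation
#'
#' @param mono_mM total monovalent cation concentration in mM (default 50).
#' @param oligo_nM total oligo strand concentration in nM (default 50; the
#'   annealing concentration is `oligo_nM/4` for non-self-complementary
#'   oligos, `oligo_nM/2` for self-complementary ones).
#' @return list of conditions.
#' @export
tm_conditions <- function(mono_mM = 50, oligo_nM = 50) {
  stopifnot(mono_mM > 0, oligo_nM > 0)
  list(mono_mM = mono_mM, oligo_nM = oligo_nM)
}

#' GC fraction of a primer sequence
#'
#' @param seq character scalar over A/C/G/T (no N allowed in primers).
#' @return fraction of G+C residues.
#' @export
#' @examples
#' gc_fraction("ATGC")  # 0.5
gc_fraction <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty sequence")
  if (grepl("[^ACGT]", seq)) stop("primer sequence must contain only A/C/G/T")
  ch <- strsplit(seq, "")[[1]]
  sum(ch %in% c("G", "C")) / length(ch)
}

#' Nearest-neighbor melting temperature of a primer
#'
#' Sums unified nearest-neighbor stack enthalpies/entropies with terminal
#' initiation terms (and the symmetry correction for self-complementary
#' oligos), converts to a 1 M Na+ melting temperature at the annealing
#' strand concentration, then applies the Owczarzy-style monovalent
#' reciprocal-temperature correction
#' `1/Tm(mono) = 1/Tm(1M) + (4.29 fGC - 3.95)e-5 ln(m) + 9.40e-6 ln(m)^2`.
#' Deterministic for fixed conditions; `Tm(s) == Tm(reverse_complement(s))`
#' because both describe the same duplex.
#'
#' @param seq primer sequence, 8-36 nt over A/C/G/T.
#' @param conditions a [tm_conditions()] list.
#' @return melting temperature in degrees Celsius.
#' @export
#' @examples
#' compute_tm("AGCTTGCATGCCTGCAGGTCGAC")
compute_tm <- function(seq, conditions = tm_conditions()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 8L || n > 36L) stop("primer length must be between 8 and 36 nt")
  if (grepl("[^ACGT]", seq)) stop("primer sequence must contain only A/C/G/T")
  ch <- strsplit(seq, "")[[1]]
  stacks <- paste0(ch[-n], ch[-1])
  dh <- sum(NN_DH[stacks]) + NN_INIT_DH[ch[1]] + NN_INIT_DH[ch[n]]
  ds <- sum(NN_DS[stacks]) + NN_INIT_DS[ch[1]] + NN_INIT_DS[ch[n]]
  selfcomp <- identical(seq, reverse_complement(seq))
  if (selfcomp) ds <- ds + NN_SYM_DS
  k <- conditions$oligo_nM * 1e-9 / (if (selfcomp) 2 else 4)
  tm_1m <- dh * 1000 / (ds + GAS_CONSTANT * log(k))  # Kelvin
  mono <- conditions$mono_mM / 1000
  fgc <- gc_fraction(seq)
  inv <- 1 / tm_1m + (4.29 * fgc - 3.95) * 1e-5 * log(mono) +
    9.40e-6 * log(mono)^2
  unname(1 / inv - 273.15)
}

#' Self-complementarity scores of a primer
#'
#' Scores all ungapped antiparallel self-alignments of the oligo with the
#' convention match = +1, mismatch = 0.  `self_any` is the maximum number of
#' complementary pairs over all offsets; `self_end` is the maximum over
#' alignments in which the oligo's 3'-terminal base is paired (a subset, so
#' `self_end <= self_any` always).
#'
#' @param seq primer sequence over A/C/G/T.
#' @return list with `self_any` and `self_end` (integer scores).
#' @export
#' @examples
#' self_complementarity("GAATTC")  # palindrome: self_any 6
self_complementarity <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop("primer sequence must contain only A/C/G/T")
  s <- strsplit(seq, "")[[1]]
  t <- strsplit(reverse_complement(seq), "")[[1]]
  n <- length(s)
  self_any <- 0L
  self_end <- 0L
  for (off in seq.int(-(n - 1L), n - 1L)) {
    i <- max(0L, off):min(n - 1L, n - 1L + off)
    score <- sum(s[i + 1L] == t[i - off + 1L])
    if (score > self_any) self_any <- score
    if (off >= 0L && score > self_end) self_end <- score
  }
  list(self_any = as.integer(self_any), self_end = as.integer(self_end))
}

#' Primer design parameters
#'
#' Defaults reproduce the pipeline's published settings: product size range
#' 2150-2650 bp, a 50 bp target window starting at the ATG (template offset
#' 3000 on a full template), primer lengths 18/20/27 (min/opt/max), melting
#' temperatures 57/60/63 C, GC fraction 0.20-0.80.  Penalty weights only
#' affect ranking, never the hard constraints.
#'
#' @param product_min,product_max product size bounds in bp.
#' @param target_length length of the target window (bp) starting at the ATG.
#' @param primer_len_min,primer_len_opt,primer_len_max primer lengths (nt).
#' @param tm_min,tm_opt,tm_max melting-temperature bounds (C).
#' @param gc_min,gc_max GC-fraction bounds.
#' @param max_self_any,max_self_end self-complementarity score caps.  Under
#'   the match=+1/mismatch=0 counting convention a random primer's scores sit
#'   near overlap/4, so the caps (14/12) trim the dimer-prone upper tail
#'   rather than mimicking mismatch-penalized scales.
#' @param max_homopolymer longest allowed single-base run in a primer.
#' @param candidates_per_gene length of the ranked pair list.
#' @param candidates_per_side per-orientation shortlist depth used before
#'   pairing (ranking detail, not a hard constraint).
#' @param min_upstream_distance minimum bp from the left primer 5' end to the
#'   ATG.
#' @param min_downstream_offset,max_downstream_offset bounds (bp) on the
#'   right primer 3' end position downstream of the translation start,
#'   counted from the A of the ATG inclusive.
#' @param weight_tm,weight_len,weight_tm_diff penalty weights per degree C of
#'   Tm deviation, per nt of length deviation, and per degree C of mate Tm
#'   difference.
#' @param enforce_frame require the downstream offset to be a multiple of 3
#'   (in-frame reporter fusion); off by default.
#' @param conditions [tm_conditions()] for Tm calculation.
#' @return a `design_params` list.
#' @export
design_params <- function(product_min = 2150L, product_max = 2650L,
                          target_length = 50L,
                          primer_len_min = 18L, primer_len_opt = 20L,
                          primer_len_max = 27L,
                          tm_min = 57, tm_opt = 60, tm_max = 63,
                          gc_min = 0.20, gc_max = 0.80,
                          max_self_any = 14L, max_self_end = 12L,
                          max_homopolymer = 5L,
                          candidates_per_gene = 20L,
                          candidates_per_side = 250L,
                          min_upstream_distance = 2000L,
                          min_downstream_offset = 50L,
                          max_downstream_offset = 150L,
                          weight_tm = 1.0, weight_len = 1.0,
                          weight_tm_diff = 1.0,
                          enforce_frame = FALSE,
                          conditions = tm_conditions()) {
  stopifnot(product_min <= product_max,
            primer_len_min <= primer_len_opt,
            primer_len_opt <= primer_len_max,
            tm_min <= tm_opt, tm_opt <= tm_max,
            gc_min <= gc_max,
            min_downstream_offset <= max_downstream_offset)
  structure(as.list(environment()), class = "design_params")
}

# Vectorized per-window quantities along a template: Tm (non-self-complement
# approximation, refined later for the shortlist), GC, N content, homopolymer
# runs.  Offsets are 0-based.
template_profile <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  stacks <- paste0(ch[-n], ch[-1])
  dh <- unname(NN_DH[stacks]); dh[is.na(dh)] <- 0
  ds <- unname(NN_DS[stacks]); ds[is.na(ds)] <- 0
  run6 <- if (n >= 6L) {
    same <- ch[-1] == ch[-n]
    runs <- logical(n - 5L)
    acc <- rep(TRUE, n - 5L)
    for (k in 0:4) acc <- acc & same[seq_len(n - 5L) + k]
    acc
  } else logical(0)
  list(
    ch = ch, n = n,
    cum_dh = c(0, cumsum(dh)), cum_ds = c(0, cumsum(ds)),
    cum_gc = c(0L, cumsum(ch %in% c("G", "C"))),
    cum_n = c(0L, cumsum(ch == "N")),
    cum_run6 = c(0L, cumsum(c(run6, integer(min(5L, n)))))
  )
}

# Window thermodynamics from a profile: starts/lens are parallel vectors,
# 0-based starts.  Returns a data.frame of window stats.
window_stats <- function(prof, starts, lens, conditions) {
  ends <- starts + lens  # exclusive
  dh <- prof$cum_dh[ends] - prof$cum_dh[starts + 1L] +
    NN_INIT_DH[prof$ch[starts + 1L]] + NN_INIT_DH[prof$ch[ends]]
  ds <- prof$cum_ds[ends] - prof$cum_ds[starts + 1L] +
    NN_INIT_DS[prof$ch[starts + 1L]] + NN_INIT_DS[prof$ch[ends]]
  gc <- (prof$cum_gc[ends + 1L] - prof$cum_gc[starts + 1L]) / lens
  has_n <- (prof$cum_n[ends + 1L] - prof$cum_n[starts + 1L]) > 0L
  # a run of >= 6 identical bases lies inside the window iff a run6 start
  # falls at offsets [start, end - 6]
  hp_hi <- pmax(starts, ends - 6L + 1L)
  has_run <- (prof$cum_run6[pmin(hp_hi, length(prof$cum_run6) - 1L) + 1L] -
                prof$cum_run6[pmin(starts, length(prof$cum_run6) - 1L) + 1L]) > 0L
  k <- conditions$oligo_nM * 1e-9 / 4
  tm_1m <- dh * 1000 / (ds + GAS_CONSTANT * log(k))
  mono <- conditions$mono_mM / 1000
  inv <- 1 / tm_1m + (4.29 * gc - 3.95) * 1e-5 * log(mono) +
    9.40e-6 * log(mono)^2
  data.frame(start = starts, len = lens, tm = unname(1 / inv - 273.15),
             gc = gc, has_n = has_n, has_run = has_run)
}

# Filter and rank one orientation's candidates over an explicit
# (start, len) window grid.
enumerate_side <- function(tpl, prof, grid, params, orientation) {
  grid <- grid[grid$start >= 0L & grid$start + grid$len <= prof$n, ,
               drop = FALSE]
  if (!nrow(grid)) return(NULL)
  st <- window_stats(prof, grid$start, grid$len, params$conditions)
  keep <- !st$has_n & !st$has_run &
    st$tm >= params$tm_min & st$tm <= params$tm_max &
    st$gc >= params$gc_min & st$gc <= params$gc_max
  st <- st[keep, , drop = FALSE]
  if (!nrow(st)) return(NULL)
  st$penalty <- params$weight_tm * abs(st$tm - params$tm_opt) +
    params$weight_len * abs(st$len - params$primer_len_opt)
  st <- st[order(st$penalty, st$start, st$len), , drop = FALSE]
  st <- head(st, params$candidates_per_side)
  # exact scores for the shortlist
  st$sequence <- vapply(seq_len(nrow(st)), function(i) {
    w <- substr(tpl$sequence, st$start[i] + 1L, st$start[i] + st$len[i])
    if (orientation == "right") reverse_complement(w) else w
  }, character(1))
  st$tm <- vapply(st$sequence, compute_tm, numeric(1),
                  conditions = params$conditions, USE.NAMES = FALSE)
  sc <- lapply(st$sequence, self_complementarity)
  st$self_any <- vapply(sc, `[[`, integer(1), "self_any")
  st$self_end <- vapply(sc, `[[`, integer(1), "self_end")
  st <- st[st$self_any <= params$max_self_any &
             st$self_end <= params$max_self_end &
             st$tm >= params$tm_min & st$tm <= params$tm_max, , drop = FALSE]
  if (!nrow(st)) return(NULL)
  st$penalty <- params$weight_tm * abs(st$tm - params$tm_opt) +
    params$weight_len * abs(st$len - params$primer_len_opt)
  st$orientation <- orientation
  st
}

primer_candidate <- function(row) {
  list(sequence = row$sequence, template_start = as.integer(row$start),
       length = as.integer(row$len), orientation = row$orientation,
       tm = row$tm, gc = row$gc,
       self_any = as.integer(row$self_any),
       self_end = as.integer(row$self_end),
       penalty = row$penalty)
}

#' Enumerate ranked primer pairs on a promoter template
#'
#' Enumerates left and right primer windows consistent with the placement
#' rules, filters on length, Tm, GC, N content, homopolymer runs and
#' self-complementarity caps, then pairs them under the product-size and
#' target-coverage constraints.  Pairs are ranked by ascending
#' `pair_penalty` (Tm deviations + length deviations + mate Tm difference)
#' with deterministic tie-breaking by `(left_start, right_end, left_len,
#' right_len)`.
#'
#' @param template a `promoter_template`.
#' @param params a [design_params()] list.
#' @return object of class `primer_pair_list`: a list of `primer_pair`s with
#'   attribute `reason` set when empty ("template_too_short",
#'   "no_candidates", "no_feasible_pair").
#' @export
enumerate_pairs <- function(template, params = design_params()) {
  stopifnot(inherits(template, "promoter_template"))
  empty <- function(reason) {
    structure(list(), class = "primer_pair_list", gene_id = template$gene_id,
              reason = reason)
  }
  A <- template$atg_offset
  L <- nchar(template$sequence)
  D <- template$downstream_achieved
  if ("undesignable" %in% template$flags || L < params$product_min ||
      A < params$min_upstream_distance) {
    return(empty("template_too_short"))
  }
  prof <- template_profile(template$sequence)
  lens <- params$primer_len_min:params$primer_len_max
  # right 3' ends (0-based): downstream_offset = end - A + 1 in [min, max]
  dmax <- min(params$max_downstream_offset, D)
  ends <- (A + params$min_downstream_offset - 1L):(A + dmax - 1L)
  ends <- ends[ends < L]
  if (params$enforce_frame) ends <- ends[(ends - A + 1L) %% 3L == 0L]
  if (!length(ends)) return(empty("no_candidates"))
  # left 5' starts: upstream_distance = A - start >= min_upstream_distance and
  # product feasibility against the extreme right ends
  smin <- max(0L, A + params$min_downstream_offset - params$product_max)
  smax <- min(A - params$min_upstream_distance,
              max(ends) - params$product_min + 1L)
  if (smax < smin) return(empty("no_candidates"))
  left_grid <- expand.grid(start = smin:smax, len = lens)
  lefts <- enumerate_side(template, prof, left_grid, params, "left")
  right_grid <- expand.grid(end = ends, len = lens)
  right_grid <- data.frame(start = right_grid$end - right_grid$len + 1L,
                           len = right_grid$len)
  rights <- enumerate_side(template, prof, right_grid, params, "right")
  if (is.null(lefts) || is.null(rights)) return(empty("no_candidates"))
  li <- rep(seq_len(nrow(lefts)), times = nrow(rights))
  ri <- rep(seq_len(nrow(rights)), each = nrow(lefts))
  right_end <- rights$start[ri] + rights$len[ri] - 1L
  product <- right_end - lefts$start[li] + 1L
  ok <- product >= params$product_min & product <= params$product_max
  if (!any(ok)) return(empty("no_feasible_pair"))
  li <- li[ok]; ri <- ri[ok]; product <- product[ok]
  right_end <- right_end[ok]
  penalty <- lefts$penalty[li] + rights$penalty[ri] +
    params$weight_tm_diff * abs(lefts$tm[li] - rights$tm[ri])
  ord <- order(penalty, lefts$start[li], right_end, lefts$len[li],
               rights$len[ri])
  ord <- head(ord, params$candidates_per_gene)
  pairs <- lapply(ord, function(j) {
    l <- lefts[li[j], ]; r <- rights[ri[j], ]
    structure(
      list(gene_id = template$gene_id,
           left = primer_candidate(l), right = primer_candidate(r),
           product_length = as.integer(product[j]),
           upstream_distance = as.integer(A - l$start),
           downstream_offset = as.integer(right_end[j] - A + 1L),
           pair_penalty = penalty[j],
           specificity = NULL, status = "candidate"),
      class = "primer_pair")
  })
  structure(pairs, class = "primer_pair_list", gene_id = template$gene_id,
            reason = NULL)
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf(
    "<primer_pair %s %s product=%dbp up=%d down=%d penalty=%.2f\n  L %s (tm=%.1f)\n  R %s (tm=%.1f)>\n",
    x$gene_id, x$status, x$product_length, x$upstream_distance,
    x$downstream_offset, x$pair_penalty,
    x$left$sequence, x$left$tm, x$right$sequence, x$right$tm))
  invisible(x)
}

#' @export
print.primer_pair_list <- function(x, ...) {
  cat(sprintf("<%d ranked primer pair(s) for %s%s>\n", length(x),
              attr(x, "gene_id"),
              if (!is.null(attr(x, "reason")))
                paste0("; reason: ", attr(x, "reason")) else ""))
  invisible(x)
}

#' Design the accepted primer pair for one gene
#'
#' Walks the ranked pair list, invoking the specificity evaluator on each
#' pair, and returns the first pair that passes (status "accepted").  If the
#' list is exhausted, a `design_failure` record is returned carrying the
#' per-pair rejection reasons; failure is a value, not an error.
#'
#' @param template a `promoter_template`.
#' @param params a [design_params()] list.
#' @param screen specificity evaluator: `function(pair) -> specificity
#'   report` with a logical `pass` element (see [evaluate_pair()]), or NULL
#'   to accept the top-ranked pair unscreened.
#' @return an accepted `primer_pair`, or a `design_failure` record.
#' @export
design_for_gene <- function(template, params = design_params(), screen = NULL) {
  ranked <- enumerate_pairs(template, params)
  if (!length(ranked)) {
    return(structure(
      list(gene_id = template$gene_id,
           reason = attr(ranked, "reason") %||% "no_candidates",
           rejections = list()),
      class = "design_failure"))
  }
  rejections <- list()
  for (i in seq_along(ranked)) {
    pair <- ranked[[i]]
    if (is.null(screen)) {
      pair$status <- "accepted"
      return(pair)
    }
    report <- screen(pair)
    if (isTRUE(report$pass)) {
      pair$status <- "accepted"
      pair$specificity <- report
      return(pair)
    }
    pair$status <- "rejected_specificity"
    rejections[[length(rejections) + 1L]] <- list(
      rank = i,
      left = pair$left$sequence, right = pair$right$sequence,
      left_hits = length(report$left_hits),
      right_hits = length(report$right_hits))
  }
  structure(
    list(gene_id = template$gene_id, reason = "all_candidates_rejected",
         rejections = rejections),
    class = "design_failure")
}

#' @export
print.design_failure <- function(x, ...) {
  cat(sprintf("<design_failure %s: %s (%d rejection(s))>\n",
              x$gene_id, x$reason, length(x$rejections)))
  invisible(x)
}
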