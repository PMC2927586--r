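# Seeded synthetic data: genomes with planted genes and planted primer
# off-target copies, expression-call matrices with exact planted present
# counts, and funnel/line/annotation tables emulating the construct
# pipeline.  Backgrounds are i.i.d. nucleotides at a specified GC fraction
# (no repeat structure beyond what is explicitly planted), so hit-count and
# recovery ground truth is provable.  All generators are seed-deterministic.

#' Specification of a synthetic genome with planted genes
#'
#' @param seed RNG seed.
#' @param n_contigs number of background contigs.
#' @param contig_length length of each contig (bp).
#' @param gc background GC fraction.
#' @param genes data.frame with `gene_id`, `contig` (index or name),
#'   `offset` (0-based position of the A of the planted ATG), `strand`,
#'   `cds_length`.
#' @param planted_offtargets list of off-target plantings, each a list with
#'   `source` = c(contig, start, length) naming a window of the finished
#'   genome (or `sequence` giving the window directly), `n_copies`, and
#'   `identity` (per-copy ungapped identity; substitutions only, drawn
#'   without replacement, first/last base protected).
#' @param protect_upstream bp upstream of each planted ATG kept free of
#'   other plantings (room for the promoter template).
#' @return a `synthetic_genome_spec` list.
#' @export
synthetic_genome_spec <- function(seed, n_contigs = 1L, contig_length = 20000L,
                                  gc = 0.5, genes = NULL,
                                  planted_offtargets = list(),
                                  protect_upstream = 3050L) {
  stopifnot(gc >= 0, gc <= 1, contig_length > 0)
  structure(
    list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
         contig_length = as.integer(contig_length), gc = gc,
         genes = genes, planted_offtargets = planted_offtargets,
         protect_upstream = as.integer(protect_upstream)),
    class = "synthetic_genome_spec")
}

random_bases <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Overlap bookkeeping for planted features.
overlaps_any <- function(iv, occupied) {
  any(vapply(occupied, function(o) {
    o$contig == iv$contig && iv$start < o$end && o$start < iv$end
  }, logical(1)))
}

#' Generate a synthetic genome with planted genes and off-target copies
#'
#' Builds i.i.d. background contigs, writes each gene's CDS (ATG + random
#' coding bases) at its stated offset (reverse-complemented for minus-strand
#' genes so the ATG's A sits at `offset` on the plus axis), then plants the
#' requested off-target copies with exactly the substitution count implied
#' by their identity.  Planted features may not overlap one another or the
#' protected upstream span of any gene; an infeasible placement is an error.
#'
#' @param spec a [synthetic_genome_spec()].
#' @return list with `genome` (`DNAStringSet`), `models` (list of
#'   `gene_model`s), and `truth` (list of data.frames: `genes` with planted
#'   coordinates and CDS, `offtargets` with per-copy positions, strands and
#'   identities).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  set.seed(spec$seed)
  contig_names <- sprintf("ctg%02d", seq_len(spec$n_contigs))
  contigs <- lapply(seq_len(spec$n_contigs), function(i) {
    strsplit(random_bases(spec$contig_length, spec$gc), "")[[1]]
  })
  names(contigs) <- contig_names
  occupied <- list()
  genes <- spec$genes
  truth_genes <- NULL
  models <- list()
  if (!is.null(genes) && nrow(genes)) {
    if (is.numeric(genes$contig)) genes$contig <- contig_names[genes$contig]
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      len <- g$cds_length
      cds <- paste0("ATG", random_bases(len - 3L, spec$gc))
      if (g$strand == "+") {
        s <- g$offset; e <- g$offset + len
        protect <- list(contig = g$contig,
                        start = g$offset - spec$protect_upstream, end = e)
        planted <- strsplit(cds, "")[[1]]
      } else {
        s <- g$offset - len + 1L; e <- g$offset + 1L
        protect <- list(contig = g$contig, start = s,
                        end = g$offset + spec$protect_upstream + 1L)
        planted <- strsplit(reverse_complement(cds), "")[[1]]
      }
      if (s < 0L || e > spec$contig_length) {
        stop(sprintf("gene %s does not fit its contig", g$gene_id))
      }
      iv <- list(contig = g$contig, start = s, end = e)
      if (overlaps_any(iv, occupied)) {
        stop(sprintf("gene %s overlaps a previously planted feature",
                     g$gene_id))
      }
      contigs[[g$contig]][(s + 1L):e] <- planted
      occupied[[length(occupied) + 1L]] <- protect
      truth_genes <- rbind(truth_genes, data.frame(
        gene_id = g$gene_id, contig_id = g$contig, offset = g$offset,
        strand = g$strand, cds_length = len, cds = cds,
        stringsAsFactors = FALSE))
      models[[g$gene_id]] <- gene_model(
        g$gene_id, g$contig, g$strand,
        list(genomic_interval(g$contig, s, e, g$strand)),
        translation_start = g$offset, atg_ok = TRUE)
    }
  }
  truth_off <- NULL
  for (ot in spec$planted_offtargets) {
    if (!is.null(ot$sequence)) {
      src <- toupper(ot$sequence)
    } else {
      ctg <- ot$source[[1]]
      if (is.numeric(ctg) || grepl("^[0-9]+$", ctg)) {
        ctg <- contig_names[as.integer(ctg)]
      }
      s0 <- as.integer(ot$source[[2]]); l0 <- as.integer(ot$source[[3]])
      src <- paste(contigs[[ctg]][(s0 + 1L):(s0 + l0)], collapse = "")
    }
    len <- nchar(src)
    n_sub <- round((1 - ot$identity) * len)
    if (n_sub > max(0L, len - 2L)) {
      stop("identity too low for end-protected substitution planting")
    }
    for (copy in seq_len(ot$n_copies)) {
      ch <- strsplit(src, "")[[1]]
      if (n_sub > 0L) {
        pos <- sample(2:(len - 1L), n_sub)
        for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      }
      strand <- sample(c("+", "-"), 1)
      seq_out <- if (strand == "+") ch else
        strsplit(reverse_complement(paste(ch, collapse = "")), "")[[1]]
      placed <- FALSE
      for (try in 1:200) {
        ctg_to <- sample(contig_names, 1)
        s <- sample.int(spec$contig_length - len + 1L, 1) - 1L
        iv <- list(contig = ctg_to, start = s, end = s + len)
        if (!overlaps_any(iv, occupied)) {
          contigs[[ctg_to]][(s + 1L):(s + len)] <- seq_out
          occupied[[length(occupied) + 1L]] <- iv
          truth_off <- rbind(truth_off, data.frame(
            copy = copy, contig_id = ctg_to, start = s, strand = strand,
            length = len, identity = 1 - n_sub / len,
            stringsAsFactors = FALSE))
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place off-target copy without overlap")
    }
  }
  genome <- as_genome(vapply(contigs, paste, character(1), collapse = ""))
  list(genome = genome, models = models,
       truth = list(genes = truth_genes, offtargets = truth_off))
}

#' Generate an expression-call matrix with exact planted present counts
#'
#' Each gene's number of P calls is drawn from `present_count_sampler`
#' (defaulting to a mixture of zeros, near-threshold low counts and clearly
#' expressed counts) and planted exactly, so classification recovers the
#' truth labels with certainty.  Remaining cells are A with a sprinkling of
#' M calls (marginal counts as non-expressed).
#'
#' @param n_genes number of genes.
#' @param n_arrays number of arrays (default 1381).
#' @param seed RNG seed.
#' @param present_count_sampler function(n, n_arrays) -> integer P counts.
#' @param marginal_rate fraction of non-P cells set to M.
#' @param threshold classification threshold (for the truth labels).
#' @return list with `calls` (character matrix) and `truth`
#'   (data.frame: `gene_id`, `n_present`, `label`).
#' @export
generate_call_matrix <- function(n_genes, n_arrays = 1381L, seed = 1L,
                                 present_count_sampler = NULL,
                                 marginal_rate = 0.02, threshold = 0.05) {
  set.seed(seed)
  if (is.null(present_count_sampler)) {
    present_count_sampler <- function(n, n_arrays) {
      lim <- ceiling(threshold * n_arrays)
      grp <- sample(1:3, n, replace = TRUE, prob = c(0.35, 0.35, 0.30))
      counts <- integer(n)
      counts[grp == 2] <- sample(seq_len(max(1L, lim - 1L)),
                                 sum(grp == 2), replace = TRUE)
      counts[grp == 3] <- sample(lim:n_arrays, sum(grp == 3), replace = TRUE)
      counts
    }
  }
  n_present <- present_count_sampler(n_genes, n_arrays)
  stopifnot(all(n_present >= 0L), all(n_present <= n_arrays))
  gene_ids <- sprintf("SYNG%04d", seq_len(n_genes))
  calls <- matrix("A", n_genes, n_arrays,
                  dimnames = list(gene_ids, sprintf("array%04d",
                                                    seq_len(n_arrays))))
  for (i in seq_len(n_genes)) {
    if (n_present[i] > 0L) {
      calls[i, sample.int(n_arrays, n_present[i])] <- "P"
    }
    rest <- which(calls[i, ] == "A")
    nm <- rbinom(1, length(rest), marginal_rate)
    if (nm > 0L) calls[i, sample(rest, nm)] <- "M"
  }
  frac <- n_present / n_arrays
  label <- ifelse(frac == 0, "no_expression",
                  ifelse(frac < threshold, "low_expression", "expressed"))
  list(calls = calls,
       truth = data.frame(gene_id = gene_ids, n_present = n_present,
                          label = factor(label, levels = EXPRESSION_LABELS),
                          stringsAsFactors = FALSE))
}

#' Specification of a synthetic construct funnel
#'
#' Default per-transition success probabilities reproduce the reference
#' screen's realized rates; lines per construct come from up to 3 floral
#' dips x 3 seedlings (capped at 9).
#'
#' @param seed RNG seed.
#' @param n_genes number of constructs entering the funnel.
#' @param stage_probs named per-transition success probabilities (names are
#'   [FUNNEL_STAGES] minus the first).
#' @param n_dips independent transformations per construct.
#' @param seedlings_per_dip seedlings transferred per selection plate.
#' @param line_success_prob per-seedling probability of yielding a positive
#'   line (defaults to the reference screen's 1885 lines over 266 x 9
#'   opportunities).
#' @param survival_prob per-line probability of surviving transfer to soil
#'   (reference: 1457 of 1885).
#' @param line_expression_prob per surviving line probability of GFP
#'   expression (reference: 761 of 1457; beyond the one guaranteed line of a
#'   GFP-positive gene).
#' @param inconsistent_rate probability an expressing line shows a pattern
#'   other than its gene's true pattern.
#' @param pattern_dictionary list of PO-code character vectors to draw
#'   gene-level expression patterns from; defaults to patterns over the
#'   packaged vocabulary.
#' @return a `synthetic_funnel_spec` list.
#' @export
synthetic_funnel_spec <- function(seed, n_genes = 627L,
                                  stage_probs = c(
                                    entry_clone = 469 / 627,
                                    sequence_confirmed = 1,
                                    expression_clone = 442 / 469,
                                    agro_clone = 353 / 442,
                                    dipped = 1,
                                    transgenic_positive = 266 / 353,
                                    in_soil = 239 / 266,
                                    gfp_positive = 150 / 239),
                                  n_dips = 3L, seedlings_per_dip = 3L,
                                  line_success_prob = 1885 / (266 * 9),
                                  survival_prob = 1457 / 1885,
                                  line_expression_prob = 761 / 1457,
                                  inconsistent_rate = 0.03,
                                  pattern_dictionary = NULL) {
  stopifnot(all(stage_probs >= 0), all(stage_probs <= 1),
            identical(sort(names(stage_probs)), sort(FUNNEL_STAGES[-1])))
  if (is.null(pattern_dictionary)) {
    codes <- sort(names(po_vocabulary()))
    singles <- as.list(codes[1:12])
    doubles <- list(codes[c(1, 13)], codes[c(2, 14)], codes[c(3, 15)])
    pattern_dictionary <- c(singles, doubles)
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         stage_probs = stage_probs, n_dips = as.integer(n_dips),
         seedlings_per_dip = as.integer(seedlings_per_dip),
         line_success_prob = line_success_prob,
         survival_prob = survival_prob,
         line_expression_prob = line_expression_prob,
         inconsistent_rate = inconsistent_rate,
         pattern_dictionary = pattern_dictionary),
    class = "synthetic_funnel_spec")
}

#' Generate synthetic funnel records, transgenic lines and PO annotations
#'
#' Stage statuses follow a seeded Bernoulli chain (monotone by
#' construction).  Genes reaching `transgenic_positive` receive up to
#' `n_dips * seedlings_per_dip` lines (capped at 9); GFP-positive genes get
#' at least one expressing line, whose PO patterns come from the gene's
#' dictionary pattern with occasional inconsistent lines.  Expressing lines
#' are annotated at one or two screening stages, one image per stage, one
#' row per PO code.
#'
#' @param spec a [synthetic_funnel_spec()].
#' @return list with `records` (`pipeline_records`), `lines` (data.frame:
#'   `line_id`, `gene_id`, `dip_event`, `survived_to_soil`), and
#'   `annotations` (`po_annotations`).
#' @export
generate_funnel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_funnel_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  gene_ids <- sprintf("SYNG%04d", seq_len(n))
  status <- matrix(FALSE, n, length(FUNNEL_STAGES),
                   dimnames = list(gene_ids, FUNNEL_STAGES))
  status[, "primer_designed"] <- TRUE
  for (k in seq_along(FUNNEL_STAGES)[-1]) {
    stage <- FUNNEL_STAGES[k]
    prev <- status[, FUNNEL_STAGES[k - 1L]]
    status[, stage] <- prev & (runif(n) < spec$stage_probs[[stage]])
  }
  records <- as_pipeline_records(
    data.frame(gene_id = gene_ids, status, stringsAsFactors = FALSE))
  vocab <- po_vocabulary()
  lines <- NULL; ann <- NULL
  true_pattern <- sample(spec$pattern_dictionary, n, replace = TRUE)
  max_lines <- min(9L, spec$n_dips * spec$seedlings_per_dip)
  for (i in which(status[, "transgenic_positive"])) {
    gid <- gene_ids[i]
    n_lines <- max(1L, rbinom(1, max_lines, spec$line_success_prob))
    dip <- ((seq_len(n_lines) - 1L) %% spec$n_dips) + 1L
    survived <- runif(n_lines) < spec$survival_prob
    if (status[i, "in_soil"] && !any(survived)) survived[1] <- TRUE
    if (!status[i, "in_soil"]) survived[] <- FALSE
    expressing <- logical(n_lines)
    if (status[i, "gfp_positive"]) {
      alive <- which(survived)
      expressing[alive] <- runif(length(alive)) < spec$line_expression_prob
      if (!any(expressing)) expressing[alive[1]] <- TRUE
    }
    line_ids <- sprintf("%s_L%02d", gid, seq_len(n_lines))
    lines <- rbind(lines, data.frame(
      line_id = line_ids, gene_id = gid, dip_event = dip,
      survived_to_soil = survived, stringsAsFactors = FALSE))
    for (j in which(expressing)) {
      pattern <- if (runif(1) < spec$inconsistent_rate) {
        sample(spec$pattern_dictionary, 1)[[1]]
      } else true_pattern[[i]]
      stages <- sample(SCREENING_STAGES, sample(1:2, 1))
      for (st in stages) {
        img <- sprintf("%s_%s_img", line_ids[j], st)
        ann <- rbind(ann, data.frame(
          image_id = img, line_id = line_ids[j], gene_id = gid,
          stage = st, po_code = pattern, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(lines)) {
    lines <- data.frame(line_id = character(), gene_id = character(),
                        dip_event = integer(), survived_to_soil = logical(),
                        stringsAsFactors = FALSE)
  }
  if (is.null(ann)) {
    ann <- data.frame(image_id = character(), line_id = character(),
                      gene_id = character(), stage = character(),
                      po_code = character(), stringsAsFactors = FALSE)
  }
  list(records = records, lines = lines,
       annotations = as_po_annotations(ann, vocab))
}
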