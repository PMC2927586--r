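# Shared builders for synthetic test inputs.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One planted plus-strand gene on a 20 kb contig with a full 3150 bp template.
planted_gene <- function(seed = 1, strand = "+", offset = NULL) {
  if (is.null(offset)) offset <- if (strand == "+") 5000L else 15000L
  spec <- synthetic_genome_spec(
    seed = seed, n_contigs = 1L, contig_length = 20000L,
    genes = data.frame(gene_id = "g1", contig = 1, offset = offset,
                       strand = strand, cds_length = 300L))
  gen <- generate_genome(spec)
  gen$template <- build_template(gen$genome, gen$models[["g1"]])
  gen
}

# A primer_pair skeleton with given sequences (for screen-only tests).
fake_pair <- function(left_seq, right_seq, gene_id = "gX") {
  structure(
    list(gene_id = gene_id,
         left = list(sequence = left_seq, template_start = 0L,
                     length = nchar(left_seq), orientation = "left"),
         right = list(sequence = right_seq, template_start = 0L,
                      length = nchar(right_seq), orientation = "right"),
         product_length = NA_integer_, upstream_distance = NA_integer_,
         downstream_offset = NA_integer_, pair_penalty = NA_real_,
         specificity = NULL, status = "candidate"),
    class = "primer_pair")
}

# Substitute k bases at deterministic interior positions.
substitute_bases <- function(seq, k, seed = 99) {
  set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(2:(length(ch) - 1L), k)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# Minimal line/annotation tables for consistency-category tests.
make_lines <- function(gene_id, n, dips = NULL) {
  data.frame(line_id = sprintf("%s_L%d", gene_id, seq_len(n)),
             gene_id = gene_id,
             dip_event = dips %||% rep(1L, n),
             survived_to_soil = TRUE, stringsAsFactors = FALSE)
}

make_ann <- function(lines, patterns) {
  rows <- NULL
  for (i in seq_len(nrow(lines))) {
    for (code in patterns[[i]]) {
      rows <- rbind(rows, data.frame(
        image_id = paste0(lines$line_id[i], "_img"),
        line_id = lines$line_id[i], gene_id = lines$gene_id[i],
        stage = "rosette", po_code = code, stringsAsFactors = FALSE))
    }
  }
  if (is.null(rows)) {
    rows <- data.frame(image_id = character(), line_id = character(),
                       gene_id = character(), stage = character(),
                       po_code = character(), stringsAsFactors = FALSE)
  }
  rows
}

`%||%` <- function(a, b) if (is.null(a)) b else a
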