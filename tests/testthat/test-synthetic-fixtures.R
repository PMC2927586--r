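test_that("genome generation is seed-deterministic to the byte", {
  spec <- synthetic_genome_spec(
    seed = 19, n_contigs = 2, contig_length = 5000,
    genes = data.frame(gene_id = "g1", contig = 1, offset = 3500,
                       strand = "+", cds_length = 120))
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g1$genome, f1)
  write_genome_fasta(g2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted genes and off-target copies are exactly recoverable", {
  gen <- planted_gene(seed = 20)
  expect_equal(gen$template$atg_offset, 3000L)
  expect_equal(substr(as.character(gen$genome[["ctg01"]]), 5001, 5003), "ATG")

  # off-target copies carry exactly the requested substitution count
  spec <- synthetic_genome_spec(
    seed = 20, n_contigs = 1, contig_length = 20000,
    genes = data.frame(gene_id = "g1", contig = 1, offset = 5000,
                       strand = "+", cds_length = 300),
    planted_offtargets = list(list(source = list("ctg01", 2500, 20),
                                   n_copies = 3, identity = 0.85)))
  gen2 <- generate_genome(spec)
  truth <- gen2$truth$offtargets
  expect_equal(nrow(truth), 3L)
  expect_equal(unique(truth$identity), 0.85)
  src <- substr(as.character(gen2$genome[["ctg01"]]), 2501, 2520)
  for (i in seq_len(nrow(truth))) {
    planted <- substr(as.character(gen2$genome[[truth$contig_id[i]]]),
                      truth$start[i] + 1L, truth$start[i] + 20L)
    if (truth$strand[i] == "-") planted <- reverse_complement(planted)
    mism <- sum(strsplit(planted, "")[[1]] != strsplit(src, "")[[1]])
    expect_equal(mism, 3L)  # round(0.15 * 20)
  }
  # the scanner sees source + 3 copies at >= 80% identity
  hits <- brute_force_matches(src, gen2$genome)
  expect_equal(nrow(hits), 4L)
})

test_that("planted off-target copies defeat the specificity screen", {
  gen <- planted_gene(seed = 5)
  top <- enumerate_pairs(gen$template)[[1]]
  src_start <- gen$template$source_interval$start + top$left$template_start
  spec <- synthetic_genome_spec(
    seed = 5, n_contigs = 1, contig_length = 20000,
    genes = data.frame(gene_id = "g1", contig = 1, offset = 5000,
                       strand = "+", cds_length = 300),
    planted_offtargets = list(list(
      source = list("ctg01", src_start, top$left$length),
      n_copies = 4, identity = 0.85)))
  gen2 <- generate_genome(spec)
  # same seed: background identical, so the top-ranked pair is unchanged
  tpl2 <- build_template(gen2$genome, gen2$models[["g1"]])
  expect_identical(tpl2$sequence, gen$template$sequence)
  rep <- evaluate_pair(top, gen2$genome)
  expect_equal(nrow(rep$left_hits), 5L)  # self + 4 planted copies
  expect_false(rep$pass)
  # the design iterates to a different, specific pair
  acc <- design_for_gene(tpl2, screen = specificity_screen(gen2$genome))
  expect_s3_class(acc, "primer_pair")
  expect_true(acc$specificity$pass)
})

test_that("call-matrix truth labels are recovered exactly at the boundary", {
  cm <- generate_call_matrix(
    6, n_arrays = 1381, seed = 23,
    present_count_sampler = function(n, na) c(0L, 69L, 70L, 1L, 1380L, 13L))
  cl <- classify_expression(cm$calls)
  expect_equal(as.character(cl$label), as.character(cm$truth$label))
  expect_equal(as.character(cl$label[cl$gene_id == "SYNG0002"]),
               "low_expression")
  expect_equal(as.character(cl$label[cl$gene_id == "SYNG0003"]),
               "expressed")
})

test_that("funnel realizations track the reference screen's expectations", {
  spec <- synthetic_funnel_spec(
    seed = 29, n_genes = 627,
    stage_probs = c(entry_clone = 469 / 627, sequence_confirmed = 1,
                    expression_clone = 442 / 469, agro_clone = 353 / 442,
                    dipped = 1, transgenic_positive = 266 / 353,
                    in_soil = 1, gfp_positive = 150 / 266))
  fun <- generate_funnel(spec)
  counts <- stage_counts(fun$records)
  expected <- c(469, 442, 353, 266, 150)
  realized <- counts[c("entry_clone", "expression_clone", "agro_clone",
                       "transgenic_positive", "gfp_positive")]
  # within 3 binomial standard deviations of the expectation
  upstream <- c(627, 469, 442, 353, 266)
  p <- expected / upstream
  sd3 <- 3 * sqrt(upstream * p * (1 - p))
  expect_true(all(abs(realized - expected) <= sd3))

  # lines per construct are capped at 9 (3 dips x 3 seedlings)
  per_gene <- table(fun$lines$gene_id)
  expect_lte(max(per_gene), 9L)
  expect_true(all(fun$lines$dip_event %in% 1:3))

  # all-ones chain pushes every gene to gfp_positive
  all1 <- synthetic_funnel_spec(
    seed = 31, n_genes = 40,
    stage_probs = setNames(rep(1, length(FUNNEL_STAGES) - 1),
                           FUNNEL_STAGES[-1]))
  fun1 <- generate_funnel(all1)
  expect_equal(unname(stage_counts(fun1$records)[["gfp_positive"]]), 40)
})

test_that("the packaged expression summary matches its printed source", {
  ps <- load_po_summary_fixture()
  expect_equal(attr(ps, "n_distinct_codes"), 81L)
  expect_equal(ps$n_promoters[ps$po_code == "PO:0005660"], 35L)  # hydathode
  expect_equal(ps$n_promoters[ps$po_code == "PO:0009005"], 37L)  # root
  expect_equal(ps$n_promoters[ps$po_code == "PO:0009073"], 1L)   # stigma
  expect_equal(ps$po_name[ps$po_code == "PO:0009073"], "stigma")
})
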