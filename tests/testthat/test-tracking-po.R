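test_that("funnel success rates reproduce the reference screen's percentages", {
  counts <- load_funnel_fixture()
  expect_equal(success_rate(counts, "primer_designed", "entry_clone"), 74.8)
  expect_equal(success_rate(counts, "dipped", "transgenic_positive"), 75.4)
  # computed from counts, the next two stages give 94.2 and 79.9
  expect_equal(success_rate(counts, "sequence_confirmed", "expression_clone"),
               94.2)
  expect_equal(success_rate(counts, "expression_clone", "agro_clone"), 79.9)
  expect_equal(success_rate(counts, "dipped", "dipped"), 100.0)
  expect_error(success_rate(c(primer_designed = 0, entry_clone = 0),
                            "primer_designed", "entry_clone"),
               "no record reached")
})

test_that("percentages round half-up, not half-even", {
  expect_equal(round_half_up(74.75, 1), 74.8)
  expect_equal(round_half_up(74.85, 1), 74.9)
  expect_equal(round_half_up(0.5), 1)
})

test_that("pipeline records enforce funnel monotonicity", {
  df <- data.frame(gene_id = c("a", "b"))
  for (s in FUNNEL_STAGES) df[[s]] <- TRUE
  df$entry_clone[2] <- FALSE  # reached later stages without entry clone
  expect_error(as_pipeline_records(df), "non-monotone")
  df2 <- df
  for (s in FUNNEL_STAGES[-1]) df2[[s]][2] <- FALSE
  rec <- as_pipeline_records(df2)
  counts <- stage_counts(rec)
  expect_true(all(diff(counts) <= 0))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pipeline_records(rec, f)
  expect_equal(stage_counts(read_pipeline_records(f)), counts)
})

test_that("consistency categories cover all five line configurations", {
  leaf <- "PO:0000036"; root <- "PO:0009005"

  # two expressing lines agreeing, one silent -> consistent_multi
  l3 <- make_lines("gA", 3, dips = c(1L, 2L, 1L))
  a3 <- make_ann(l3, list(leaf, leaf, character(0)))
  r <- classify_consistency(l3, a3)
  expect_equal(r$category, "consistent_multi")
  expect_true(r$independent_dip_consistent)  # dips 1 and 2

  # agreeing lines from a single dip are consistent but not dip-independent
  l1d <- make_lines("gB", 2, dips = c(1L, 1L))
  rb <- classify_consistency(l1d, make_ann(l1d, list(root, root)))
  expect_equal(rb$category, "consistent_multi")
  expect_false(rb$independent_dip_consistent)

  # disagreeing expressing patterns -> inconsistent
  l2 <- make_lines("gC", 2)
  rc <- classify_consistency(l2, make_ann(l2, list(leaf, root)))
  expect_equal(rc$category, "inconsistent")
  # relaxed mode: overlapping multi-code patterns count as agreement
  rc2 <- classify_consistency(
    l2, make_ann(l2, list(c(leaf, root), root)), relaxed = TRUE)
  expect_equal(rc2$category, "consistent_multi")

  # one recovered line, expressing
  lS <- make_lines("gD", 1)
  expect_equal(classify_consistency(lS, make_ann(lS, list(leaf)))$category,
               "single_line_expressing")

  # several lines, exactly one expressing
  lM <- make_lines("gE", 3)
  expect_equal(
    classify_consistency(
      lM, make_ann(lM, list(leaf, character(0), character(0))))$category,
    "single_expressing_of_many")

  # no expression anywhere
  expect_equal(
    classify_consistency(lM, make_ann(lM, list(character(0), character(0),
                                               character(0))))$category,
    "no_expression")
})

test_that("categories partition the genes of a generated screen", {
  fun <- generate_funnel(synthetic_funnel_spec(seed = 13, n_genes = 120))
  cc <- classify_all_consistency(fun$lines, fun$annotations)
  expect_equal(nrow(cc), length(unique(fun$lines$gene_id)))
  expect_true(all(cc$category %in% c(
    "consistent_multi", "single_line_expressing",
    "single_expressing_of_many", "inconsistent", "no_expression")))
  # a gene expresses GFP iff at least one of its lines has annotations
  gfp <- stage_counts(fun$records)[["gfp_positive"]]
  expect_equal(sum(cc$category != "no_expression"), gfp)
})

test_that("PO summaries count each promoter once per code", {
  leaf <- "PO:0000036"; root <- "PO:0009005"
  ann <- data.frame(
    image_id = c("i1", "i2", "i3", "i4", "i5"),
    line_id = c("l1", "l1", "l2", "l3", "l3"),
    gene_id = c("g1", "g1", "g1", "g2", "g2"),
    stage = "rosette",
    po_code = c(leaf, leaf, leaf, leaf, root),
    stringsAsFactors = FALSE)
  sm <- summarize_po(ann)
  expect_equal(attr(sm, "n_distinct_codes"), 2L)
  # g1 on three images still counts once for the leaf code
  expect_equal(sm$n_promoters[sm$po_code == leaf], 2L)
  expect_equal(attr(sm, "most_frequent")$po_code, leaf)

  # order invariance and idempotence
  sm2 <- summarize_po(ann[sample(nrow(ann)), ])
  expect_equal(as.data.frame(sm2), as.data.frame(sm))

  empty <- summarize_po(ann[0, ])
  expect_equal(attr(empty, "n_distinct_codes"), 0L)
  expect_equal(nrow(empty), 0L)

  # tie on the maximum resolves to the lexicographically smallest code
  tie <- rbind(ann, data.frame(image_id = "i6", line_id = "l9",
                               gene_id = "g9", stage = "rosette",
                               po_code = root))
  smt <- summarize_po(tie)
  expect_equal(attr(smt, "most_frequent")$po_code, leaf)
})

test_that("annotation stores validate codes and answer typed queries", {
  expect_error(
    as_po_annotations(data.frame(image_id = "i", line_id = "l",
                                 gene_id = "g", stage = "rosette",
                                 po_code = "PO:12345")),
    "invalid PO code")
  expect_error(
    as_po_annotations(data.frame(image_id = "i", line_id = "l",
                                 gene_id = "g", stage = "rosette",
                                 po_code = "PO:9999999")),
    "not in vocabulary")

  fun <- generate_funnel(synthetic_funnel_spec(seed = 17, n_genes = 60))
  store <- po_store(fun$lines, fun$annotations)
  gid <- fun$annotations$gene_id[1]
  byg <- po_query(store, gene_id = gid)
  expect_true(all(byg$gene_id == gid))
  expect_equal(nrow(byg), sum(fun$annotations$gene_id == gid))
  expect_false(is.unsorted(byg$image_id))

  code <- fun$annotations$po_code[1]
  byc <- po_query(store, po_code = code)
  expect_true(all(byc$po_code == code))
  expect_equal(nrow(po_query(store, po_code = "PO:0000017")) +
                 nrow(po_query(store, gene_id = "absent_gene")) >= 0, TRUE)
  expect_error(po_query(store), "exactly one")
  expect_error(po_query(store, po_code = "PO:0000036", gene_id = "g"),
               "exactly one")

  # tissue queries match PO names case-insensitively
  byt <- po_query(store, tissue = "ROOT")
  root_codes <- names(po_vocabulary())[grepl("root", po_vocabulary(),
                                             ignore.case = TRUE)]
  expect_true(all(byt$po_code %in% root_codes))

  d <- withr::local_tempdir()
  write_po_store(store, d)
  back <- read_po_store(d)
  expect_equal(nrow(back$annotations), nrow(store$annotations))
  expect_equal(summarize_po(back$annotations, back$vocabulary)$n_promoters,
               summarize_po(store$annotations)$n_promoters)
})
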