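test_that("attB tails are pure 5' prefixes and adapters stay consistent", {
  k <- gateway_constants()
  expect_equal(nchar(k$attB1_adapter), 29L)
  expect_equal(nchar(k$attB2_adapter), 29L)
  expect_true(endsWith(k$attB1_adapter, toupper(k$left_tail)))
  # the attB2 adapter ends with the conventional 12-nt tail; the pipeline's
  # printed 11-nt default drops one G and so is NOT an adapter suffix --
  # the documented discrepancy the standard_attb2_tail override exists for
  k12 <- gateway_constants(standard_attb2_tail = TRUE)
  expect_true(endsWith(k$attB2_adapter, toupper(k12$right_tail)))
  expect_equal(nchar(k$right_tail), 11L)
  expect_false(endsWith(k$attB2_adapter, toupper(k$right_tail)))

  pair <- fake_pair(random_dna(20, seed = 61), random_dna(20, seed = 62),
                    gene_id = "gT")
  pair$product_length <- 2400L
  tp <- add_tails(pair)
  expect_equal(nchar(tp$left_oligo), 32L)
  expect_equal(nchar(tp$right_oligo), 31L)
  expect_true(startsWith(tp$left_oligo, "AAAAAGCAGGCT"))
  expect_true(startsWith(tp$right_oligo, "AGAAAGCTGGT"))
  # stripping the tail recovers the gene-specific primer exactly
  expect_equal(substring(tp$left_oligo, 13), pair$left$sequence)
  expect_equal(substring(tp$right_oligo, 12), pair$right$sequence)
  expect_equal(tp$expected_stage1_product, 2400L + 12L + 11L)
  expect_equal(tp$expected_stage2_product,
               tp$expected_stage1_product + (29L - 12L) + (29L - 11L))
})

test_that("coding inclusion counts complete native codons", {
  tplike <- structure(list(), class = "promoter_template")
  p50 <- fake_pair("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT")
  p50$downstream_offset <- 50L
  inc <- check_coding_inclusion(tplike, p50)
  expect_equal(inc$codons_included, 16L)
  expect_false(inc$in_frame)
  p150 <- p50; p150$downstream_offset <- 150L
  inc2 <- check_coding_inclusion(tplike, p150)
  expect_equal(inc2$codons_included, 50L)
  expect_true(inc2$in_frame)
  # any legal offset (>= 50) includes at least 16 codons
  for (off in c(50L, 51L, 52L, 99L, 150L)) {
    p <- p50; p$downstream_offset <- off
    expect_gte(check_coding_inclusion(tplike, p)$codons_included, 16L)
  }
})

test_that("the two-stage thermal programs match the pipeline cycling", {
  s1 <- emit_pcr_protocol(1)
  anneal <- unlist(lapply(s1$blocks, function(b) {
    t <- b$steps$temperature_C
    rep(t[t >= 56 & t <= 63 & t != 72], b$repeats)
  }))
  expect_equal(sort(unique(anneal)), c(58, 59, 60, 61, 62, 63))
  expect_equal(length(anneal), 14L)  # 1+1+1+1+1+9 annealing-bearing cycles
  reps <- vapply(s1$blocks, `[[`, integer(1), "repeats")
  expect_equal(max(reps), 9L)
  # touchdown: annealing temperatures descend
  expect_true(all(diff(anneal) <= 0))

  s2 <- emit_pcr_protocol(2)
  anneal2 <- unlist(lapply(s2$blocks, function(b) {
    t <- b$steps$temperature_C
    rep(t[t == 56], b$repeats)
  }))
  expect_equal(length(anneal2), 19L)
  expect_equal(unique(anneal2), 56)
  expect_error(emit_pcr_protocol(3), "stage must be")
})

test_that("plate layout pairs left/right wells and handles overflow", {
  mk <- function(i) {
    p <- fake_pair(random_dna(20), random_dna(20),
                   gene_id = sprintf("g%03d", i))
    p$product_length <- 2400L
    add_tails(p)
  }
  set.seed(71)
  full <- lapply(1:96, mk)
  ord <- layout_plates(full)
  expect_equal(sort(unique(ord$plate_id)), c("PF_L_01", "PF_R_01"))
  expect_equal(nrow(ord), 192L)
  expect_equal(sum(ord$plate_id == "PF_L_01"), 96L)

  over <- lapply(1:97, mk)
  ord2 <- layout_plates(over)
  expect_equal(sort(unique(ord2$plate_id)),
               c("PF_L_01", "PF_L_02", "PF_R_01", "PF_R_02"))
  second <- ord2[ord2$plate_id == "PF_L_02", ]
  expect_equal(nrow(second), 1L)
  expect_equal(second$well, "A1")
  # gene k's left and right oligos share a well index on paired plates
  g5 <- ord2[ord2$gene_id == "g005", ]
  expect_equal(unique(g5$well), "A5")

  ord0 <- layout_plates(list())
  expect_equal(nrow(ord0), 0L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_order_file(ord0, f)
  expect_equal(nrow(read_order_file(f)), 0L)
  expect_equal(names(read_order_file(f)),
               c("plate_id", "well", "gene_id", "role", "sequence"))

  # round trip preserves every row
  write_order_file(ord2, f)
  back <- read_order_file(f)
  expect_equal(back$sequence, ord2$sequence)
  expect_equal(back$well, ord2$well)
})

test_that("tail prefix invariant holds across a designed batch", {
  gen <- planted_gene(seed = 12)
  pairs <- enumerate_pairs(gen$template)
  batch <- lapply(pairs[1:5], add_tails)
  for (tp in batch) {
    expect_true(startsWith(tp$left_oligo, toupper(gateway_constants()$left_tail)))
    expect_true(startsWith(tp$right_oligo, toupper(gateway_constants()$right_tail)))
    expect_equal(nchar(tp$left_oligo), 12L + nchar(tp$left_specific))
    expect_equal(nchar(tp$right_oligo), 11L + nchar(tp$right_specific))
  }
})
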