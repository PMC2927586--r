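test_that("gc_fraction counts G+C over clean primer sequences only", {
  expect_equal(gc_fraction("GGCC"), 1.0)
  expect_equal(gc_fraction("ATGC"), 0.5)
  expect_equal(gc_fraction("AAAA"), 0.0)
  expect_error(gc_fraction(""), "empty")
  expect_error(gc_fraction("ACGN"), "only A/C/G/T")
})

test_that("nearest-neighbor Tm matches the independent thermodynamic oracle", {
  # frozen from an independent nearest-neighbor summation over the unified
  # table (50 mM monovalent, 50 nM total strand, Owczarzy monovalent
  # correction); self-complementary cases exercise the symmetry term
  expect_equal(compute_tm("ACGTACGTACGTACGTACGT"), 52.18023, tolerance = 1e-6)
  expect_equal(compute_tm("AGCTTGCATGCCTGCAGGTCGAC"), 62.82061,
               tolerance = 1e-6)
  expect_equal(compute_tm("TTTTTTTTTTAAAAAAAAAA"), 29.63263, tolerance = 1e-6)
  expect_equal(compute_tm("GCGCGCGCGCGCGCGCGC"), 78.21342, tolerance = 1e-6)
  expect_error(compute_tm("ACGTACG"), "between 8 and 36")
  expect_error(compute_tm(strrep("ACGT", 10)), "between 8 and 36")
  expect_error(compute_tm("ACGTACGN"), "only A/C/G/T")
})

test_that("Tm is duplex-symmetric and increases with A/T -> G/C swaps", {
  set.seed(31)
  for (i in 1:25) {
    s <- random_dna(sample(10:30, 1))
    expect_equal(compute_tm(s), compute_tm(reverse_complement(s)),
                 tolerance = 1e-12)
  }
  for (i in 1:50) {
    n <- sample(12:30, 1)
    s <- random_dna(n)
    ch <- strsplit(s, "")[[1]]
    at <- which(ch %in% c("A", "T"))
    at <- at[at > 1 & at < n]
    if (!length(at)) next
    ch[sample(at, 1)] <- sample(c("G", "C"), 1)
    expect_gte(compute_tm(paste(ch, collapse = "")), compute_tm(s))
  }
})

test_that("self-complementarity scores follow the counting convention", {
  expect_equal(self_complementarity("GAATTC")$self_any, 6L)  # palindrome
  expect_equal(self_complementarity("AAAA")$self_any, 0L)
  set.seed(33)
  for (i in 1:30) {
    sc <- self_complementarity(random_dna(sample(8:27, 1)))
    expect_lte(sc$self_end, sc$self_any)
  }
})

test_that("enumerated pairs respect every placement constraint", {
  gen <- planted_gene(seed = 8)
  pairs <- enumerate_pairs(gen$template)
  expect_s3_class(pairs, "primer_pair_list")
  expect_gt(length(pairs), 0L)
  for (p in pairs) {
    expect_gte(p$upstream_distance, 2000L)
    expect_gte(p$downstream_offset, 50L)
    expect_lte(p$downstream_offset, 150L)
    expect_gte(p$product_length, 2150L)
    expect_lte(p$product_length, 2650L)
    # feasible left 5' positions on a full template lie in [400, 1000]
    expect_gte(p$left$template_start, 400L)
    expect_lte(p$left$template_start, 1000L)
    # product interval contains the 50 bp target window at the ATG
    expect_lte(p$left$template_start, 3000L)
    right_end <- p$right$template_start + p$right$length - 1L
    expect_gte(right_end, 3049L)
    # oligo identities: left is the template substring, right its
    # reverse complement
    expect_equal(p$left$sequence,
                 substr(gen$template$sequence, p$left$template_start + 1L,
                        p$left$template_start + p$left$length))
    expect_equal(p$right$sequence,
                 reverse_complement(
                   substr(gen$template$sequence, p$right$template_start + 1L,
                          right_end + 1L)))
    expect_equal(p$left$tm, compute_tm(p$left$sequence), tolerance = 1e-9)
    expect_false(grepl("(.)\\1{5}", p$left$sequence))
    expect_false(grepl("(.)\\1{5}", p$right$sequence))
  }
  # ranked by ascending penalty
  pen <- vapply(pairs, `[[`, numeric(1), "pair_penalty")
  expect_true(all(diff(pen) >= 0))
})

test_that("enumeration is deterministic and fails cleanly on short templates", {
  gen <- planted_gene(seed = 9)
  p1 <- enumerate_pairs(gen$template)
  p2 <- enumerate_pairs(gen$template)
  expect_identical(p1, p2)

  spec <- synthetic_genome_spec(
    seed = 4, contig_length = 6000L, protect_upstream = 900L,
    genes = data.frame(gene_id = "gc", contig = 1, offset = 1000L,
                       strand = "+", cds_length = 300L))
  gen2 <- generate_genome(spec)
  tpl2 <- build_template(gen2$genome, gen2$models[["gc"]])
  empty <- enumerate_pairs(tpl2)
  expect_length(empty, 0L)
  expect_equal(attr(empty, "reason"), "template_too_short")
})

test_that("design_for_gene walks the ranked list until the screen passes", {
  gen <- planted_gene(seed = 10)
  calls <- 0L

  pass_all <- function(pair) { calls <<- calls + 1L; list(pass = TRUE) }
  acc <- design_for_gene(gen$template, screen = pass_all)
  expect_s3_class(acc, "primer_pair")
  expect_equal(acc$status, "accepted")
  expect_equal(calls, 1L)

  calls <- 0L
  fail_first <- function(pair) {
    calls <<- calls + 1L
    list(pass = calls > 1L,
         left_hits = data.frame(), right_hits = data.frame())
  }
  acc2 <- design_for_gene(gen$template, screen = fail_first)
  expect_equal(acc2$status, "accepted")
  expect_equal(calls, 2L)
  # the second-ranked pair was returned
  ranked <- enumerate_pairs(gen$template)
  expect_equal(acc2$left$sequence, ranked[[2]]$left$sequence)

  fail_all <- function(pair) {
    list(pass = FALSE, left_hits = data.frame(), right_hits = data.frame())
  }
  fl <- design_for_gene(gen$template, screen = fail_all)
  expect_s3_class(fl, "design_failure")
  expect_equal(fl$reason, "all_candidates_rejected")
  expect_equal(length(fl$rejections), length(ranked))
})
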