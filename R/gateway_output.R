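# Gateway attB tail assembly, coding-inclusion bookkeeping, two-stage PCR
# program metadata and 96-well plate order files.
#
# Stage-1 primers carry partial attB tails 5' of the gene-specific sequence;
# stage 2 re-amplifies with two universal 29-nt adapter primers to complete
# the attB1/attB2 sites.  The recombination site contributes an 8-amino-acid
# linker to the reporter fusion.

#' Gateway tail and adapter constants
#'
#' The default downstream (attB2) tail is the 11-nt sequence used by the
#' original pipeline; the attB2 adapter itself ends in the conventional
#' 12-nt AGAAAGCTGGGT, and `standard_attb2_tail = TRUE` switches the tail to
#' that 12-nt form.  Tails are stored lowercase and compared
#' case-insensitively; order files emit uppercase.
#'
#' @param standard_attb2_tail use the conventional 12-nt attB2 tail
#'   (agaaagctgggt) instead of the pipeline's printed 11-nt tail.
#' @return a `gateway_constants` list: `left_tail`, `right_tail`,
#'   `attB1_adapter`, `attB2_adapter`, `linker_aa`.
#' @export
gateway_constants <- function(standard_attb2_tail = FALSE) {
  structure(
    list(
      left_tail = "aaaaagcaggct",
      right_tail = if (standard_attb2_tail) "agaaagctgggt" else "agaaagctggt",
      attB1_adapter = "GGGGACAAGTTTGTACAAAAAAGCAGGCT",
      attB2_adapter = "GGGGACCACTTTGTACAAGAAAGCTGGGT",
      linker_aa = 8L
    ),
    class = "gateway_constants")
}

#' Append Gateway attB tails to an accepted primer pair
#'
#' Pure 5' concatenation: the gene-specific portions are unchanged and
#' recoverable by stripping the tail prefix.  Product bookkeeping:
#' stage 1 amplifies template with the tailed primers; stage 2 extends each
#' end to the full 29-nt adapter.
#'
#' @param pair an accepted `primer_pair`.
#' @param constants a [gateway_constants()] list.
#' @return a `tailed_primer_pair`: `gene_id`, `left_oligo`, `right_oligo`
#'   (uppercase), gene-specific halves, expected stage-1/stage-2 product
#'   sizes in bp.
#' @export
add_tails <- function(pair, constants = gateway_constants()) {
  stopifnot(inherits(pair, "primer_pair"))
  lt <- toupper(constants$left_tail)
  rt <- toupper(constants$right_tail)
  left_oligo <- paste0(lt, pair$left$sequence)
  right_oligo <- paste0(rt, pair$right$sequence)
  stage1 <- pair$product_length + nchar(lt) + nchar(rt)
  stage2 <- stage1 + (nchar(constants$attB1_adapter) - nchar(lt)) +
    (nchar(constants$attB2_adapter) - nchar(rt))
  structure(
    list(gene_id = pair$gene_id,
         left_oligo = left_oligo, right_oligo = right_oligo,
         left_specific = pair$left$sequence,
         right_specific = pair$right$sequence,
         left_tail = lt, right_tail = rt,
         attB1_adapter = constants$attB1_adapter,
         attB2_adapter = constants$attB2_adapter,
         expected_stage1_product = as.integer(stage1),
         expected_stage2_product = as.integer(stage2)),
    class = "tailed_primer_pair")
}

#' @export
print.tailed_primer_pair <- function(x, ...) {
  cat(sprintf("<tailed_primer_pair %s\n  L %s\n  R %s\n  stage1 %d bp, stage2 %d bp>\n",
              x$gene_id, x$left_oligo, x$right_oligo,
              x$expected_stage1_product, x$expected_stage2_product))
  invisible(x)
}

#' Coding-sequence inclusion of an accepted design
#'
#' The right primer sits 50-150 bp downstream of the translation start, so
#' the cloned fragment carries the first `floor(downstream_offset / 3)`
#' native codons; the fusion is in frame with the downstream reporter when
#' the offset is a multiple of 3.
#'
#' @param template the `promoter_template` the pair was designed on.
#' @param pair an accepted `primer_pair`.
#' @return list with `codons_included` and `in_frame`.
#' @export
check_coding_inclusion <- function(template, pair) {
  stopifnot(inherits(pair, "primer_pair"))
  off <- pair$downstream_offset
  list(codons_included = off %/% 3L, in_frame = (off %% 3L == 0L))
}

#' Two-stage PCR thermal programs
#'
#' Stage 1 is a touchdown program: after the initial denaturation, six
#' annealing temperatures descend 63 to 58 C one degree per cycle, with the
#' final 58 C block repeated 9 times (14 annealing-bearing cycles in all).
#' Stage 2 re-amplifies with the universal adapters for 19 cycles at 56 C.
#' Durations are in seconds; the final 4 C hold has duration NA.
#'
#' @param stage 1 or 2.
#' @return a `pcr_program`: list of blocks, each `list(repeats, steps)` with
#'   steps as data.frames of `temperature_C` and `duration_s`.
#' @export
emit_pcr_protocol <- function(stage) {
  if (!stage %in% c(1L, 2L)) stop("stage must be 1 or 2")
  step <- function(t, d) data.frame(temperature_C = t, duration_s = d)
  block <- function(repeats, ...) list(repeats = as.integer(repeats),
                                       steps = do.call(rbind, list(...)))
  blocks <- if (stage == 1L) {
    c(list(block(1, step(98, 30))),
      lapply(c(63, 62, 61, 60, 59), function(ta) {
        block(1, step(98, 10), step(ta, 30), step(72, 120))
      }),
      list(block(9, step(98, 10), step(58, 30), step(72, 120)),
           block(1, step(72, 600)),
           block(1, step(4, NA))))
  } else {
    list(block(1, step(98, 30)),
         block(19, step(98, 10), step(56, 30), step(72, 120)),
         block(1, step(72, 600)),
         block(1, step(4, NA)))
  }
  structure(list(stage = as.integer(stage), blocks = blocks),
            class = "pcr_program")
}

#' @export
print.pcr_program <- function(x, ...) {
  cat(sprintf("<pcr_program stage %d>\n", x$stage))
  for (b in x$blocks) {
    steps <- paste(sprintf("%gC %ss", b$steps$temperature_C,
                           ifelse(is.na(b$steps$duration_s), "hold",
                                  b$steps$duration_s)),
                   collapse = ", ")
    cat(sprintf("  %dx: %s\n", b$repeats, steps))
  }
  invisible(x)
}

well_ids <- function() {
  paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
}

#' Lay out tailed primer pairs on paired 96-well order plates
#'
#' Row-major fill (A1..A12, B1..): the left oligo of gene k and the right
#' oligo of gene k occupy the same well index on paired left/right plates;
#' overflow opens a new plate pair.
#'
#' @param batch list of `tailed_primer_pair`s.
#' @param plate_prefix prefix for plate ids.
#' @return data.frame with `plate_id`, `well`, `gene_id`, `role`,
#'   `sequence` (uppercase), one row per oligo.
#' @export
layout_plates <- function(batch, plate_prefix = "PF") {
  if (!length(batch)) {
    return(data.frame(plate_id = character(), well = character(),
                      gene_id = character(), role = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  wells <- well_ids()
  idx <- seq_along(batch) - 1L
  plate_no <- idx %/% 96L + 1L
  well <- wells[idx %% 96L + 1L]
  rows <- lapply(seq_along(batch), function(i) {
    tp <- batch[[i]]
    data.frame(
      plate_id = sprintf("%s_%s_%02d", plate_prefix, c("L", "R"), plate_no[i]),
      well = well[i],
      gene_id = tp$gene_id,
      role = c("left", "right"),
      sequence = toupper(c(tp$left_oligo, tp$right_oligo)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$plate_id, match(out$well, wells)), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Write a plate order file
#'
#' Tab-delimited with header `plate_id, well, gene_id, role, sequence`; an
#' empty batch produces a header-only file.
#'
#' @param order data.frame from [layout_plates()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_order_file <- function(order, path) {
  write.table(order, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plate order file
#'
#' @param path order file written by [write_order_file()].
#' @return data.frame with the order columns.
#' @export
read_order_file <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, colClasses = "character")
}
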