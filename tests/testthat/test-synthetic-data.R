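# Generator: consensus architecture, planted genomes, transcript pools,
# and seeded read simulation with ground truth.

test_that("consensus carries the 85/253/269 donor architecture", {
  expect_equal(fix_r85[["end"]] - fix_r85[["start"]] + 1L, 85L)
  expect_equal(fix_r253[["end"]] - fix_r253[["start"]] + 1L, 253L)
  expect_equal(fix_r269[["end"]] - fix_r269[["start"]] + 1L, 269L)
  # contiguous, in order, spanning 607 nt
  expect_equal(fix_r253[["start"]], fix_r85[["end"]] + 1L)
  expect_equal(fix_r269[["start"]], fix_r253[["end"]] + 1L)
  expect_equal(fix_r269[["end"]] - fix_r85[["start"]] + 1L, 607L)
})

test_that("consensus is deterministic and annotation-consistent", {
  a <- build_consensus(seed = 42L)
  expect_identical(a$sequence, fix_cons$sequence)
  expect_identical(a$regions, fix_cons$regions)
  # total element length equals the sum of the emitted region intervals
  expect_equal(nchar(a$sequence), sum(a$regions$end - a$regions$start + 1L))
  # full element: LTR5 starts at 1, LTR3 ends at the element end, and the
  # two LTR copies are identical sequence
  expect_equal(a$regions$start[a$regions$label == "LTR5"], 1L)
  expect_equal(a$regions$end[a$regions$label == "LTR3"], nchar(a$sequence))
  expect_identical(region_seq <- substr(a$sequence, 1, 450),
                   substr(a$sequence, nchar(a$sequence) - 449,
                          nchar(a$sequence)))
})

test_that("consensus builder validates parameters and drops empty regions", {
  expect_error(consensus_params(ltr = -1L), ">= 0")
  wheat <- build_consensus(
    seed = 1L, params = consensus_params(region85 = 135L, region253 = 0L,
                                         region269 = 188L))
  expect_false("REGION253" %in% wheat$regions$label)
  jx <- element_junction(wheat)
  expect_equal(jx$donor - jx$acceptor + 1L, 323L)
})

test_that("planted genomes reproduce the consensus at annotated intervals", {
  g0 <- plant_elements(5000L, fix_cons, n_full = 0L, n_fragmented = 0L,
                       seed = 1L)
  expect_equal(nchar(g0$sequence), 5000L)
  expect_equal(nrow(g0$insertions), 0L)

  g <- plant_elements(30000L, fix_cons, n_full = 3L, n_fragmented = 2L,
                      seed = 5L, divergence = 0)
  expect_equal(nrow(g$insertions), 5L)
  expect_equal(nchar(g$sequence), 30000L)
  full <- g$insertions[g$insertions$type == "full_element", ]
  expect_true(all(full$end - full$start + 1L == nchar(fix_cons$sequence)))
  for (i in seq_len(nrow(g$insertions))) {
    ins <- g$insertions[i, ]
    extracted <- substr(g$sequence, ins$start, ins$end)
    if (ins$strand == "-") extracted <- revcomp(extracted)
    expect_identical(extracted, substr(fix_cons$sequence, ins$cons_start,
                                       ins$cons_end))
  }
  expect_error(plant_elements(1000L, fix_cons, n_full = 3L,
                              n_fragmented = 0L),
               "too small")
})

test_that("transcripts are segment concatenations with declared strands", {
  lin <- make_transcripts(fix_cons, list(
    isoform_spec("r85", "LINEAR", list(unname(fix_r85)))))
  expect_identical(lin$sequence,
                   substr(fix_cons$sequence, fix_r85[["start"]],
                          fix_r85[["end"]]))
  # default set: the full-retention circle is sense-only, the short
  # variants come from both strands
  circ607 <- fix_tx[fix_tx$length == 607, ]
  expect_identical(circ607$strand, "+")
  for (len in c(277L, 286L, 296L)) {
    expect_setequal(fix_tx$strand[fix_tx$length == len & fix_tx$kind ==
                                    "CIRCULAR"], c("+", "-"))
  }
  # circ354 = seq(REGION85) + seq(REGION269), up to rotation
  c354 <- fix_tx$seq_plus[fix_tx$id == "circ354_plus"]
  ref <- paste0(substr(fix_cons$sequence, fix_r85[["start"]], fix_r85[["end"]]),
                substr(fix_cons$sequence, fix_r269[["start"]],
                       fix_r269[["end"]]))
  expect_identical(c354, ref)
  for (k in c(1L, 17L, 200L)) {
    expect_identical(canonical_rotation(rotate_circle(c354, k)),
                     canonical_rotation(c354))
  }
  expect_error(make_transcripts(fix_cons, list(
    isoform_spec("bad", "LINEAR", list(c(1L, nchar(fix_cons$sequence) + 1L))))),
    "outside")
})

test_that("wrap-point crossing matches brute-force enumeration", {
  # circular template of 354 nt, 100-nt reads: exactly 99 of the 354
  # start positions cross the junction point
  crossing <- vapply(1:354, crosses_wrap, TRUE, frag_len = 100L,
                     circ_len = 354L)
  expect_equal(sum(crossing), 99L)
  # brute force: a placement crosses when it spans the boundary of the
  # doubled string
  brute <- vapply(1:354, function(s) s + 99L > 354L, TRUE)
  expect_identical(crossing, brute)
})

test_that("read simulation is deterministic, conserved, and wrap-correct", {
  suppressWarnings({
    a <- simulate_reads(fix_tx, n_pairs = 60L, seed = 11L)
    b <- simulate_reads(fix_tx, n_pairs = 60L, seed = 11L)
  })
  expect_identical(a$r1, b$r1)
  expect_identical(a$r2, b$r2)
  expect_identical(a$truth, b$truth)
  # byte-identical FASTQ for identical seeds
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(a$r1, a$q1, f1)
  write_fastq(b$r1, b$q1, f2)
  expect_identical(readLines(f1), readLines(f2))
  # conservation
  expect_equal(length(a$r1), 60L)
  expect_equal(nrow(a$truth), 60L)
  expect_false(anyDuplicated(a$truth$read_id) > 0)
  # wrap correctness: at err 0 every fragment is a substring of the
  # doubled template (template frame)
  for (i in seq_len(60L)) {
    tpl <- fix_tx[fix_tx$id == a$truth$template_id[i], ]
    doubled <- if (tpl$kind == "CIRCULAR") strrep(tpl$seq_plus, 2)
               else tpl$seq_plus
    frag <- substr(doubled, a$truth$start[i],
                   a$truth$start[i] + a$truth$insert[i] - 1L)
    if (tpl$strand == "-") frag <- revcomp(frag)
    expect_identical(a$r1[[i]], substr(frag, 1, 125))
    expect_identical(a$r2[[i]], revcomp(substr(frag, nchar(frag) - 124,
                                               nchar(frag))))
  }
})

test_that("strand flip of a template reverse-complements its fragments", {
  circ <- fix_tx[fix_tx$id == "circ354_plus", ]
  plus <- list(isoform_spec("t", "CIRCULAR",
                            list(unname(fix_r85), unname(fix_r269)), "+"))
  minus <- list(isoform_spec("t", "CIRCULAR",
                             list(unname(fix_r85), unname(fix_r269)), "-"))
  sp <- simulate_reads(make_transcripts(fix_cons, plus), 20L, seed = 3L)
  sm <- simulate_reads(make_transcripts(fix_cons, minus), 20L, seed = 3L)
  # same seed -> same placements; paired-end chemistry is strand
  # symmetric, so the flipped run swaps the two reads of each pair
  expect_identical(unname(sp$r1), unname(sm$r2))
  expect_identical(unname(sp$r2), unname(sm$r1))
})

test_that("simulation guards its domain", {
  expect_error(simulate_reads(fix_tx, 10L, err_rate = 1), "err_rate")
  expect_error(simulate_reads(fix_tx, 10L, read_len = 0L), "read_len")
  expect_warning(
    simulate_reads(fix_tx, 10L, read_len = 125L, seed = 1L),
    "skipping")
  # abundance 0 -> no reads from that template
  tx0 <- fix_tx
  tx0$abundance[tx0$id != "RNA-269"] <- 0
  s <- simulate_reads(tx0, 40L, seed = 2L)
  expect_true(all(s$truth$template_id == "RNA-269"))
})

test_that("library-count simulation reflects enrichment factors", {
  ab <- stats::setNames(rep(1, 50), sprintf("f%02d", 1:50))
  cts <- simulate_library_counts(ab, n_input = 2e5, n_rip = 2e5,
                                 enrichment = c(f01 = 4), seed = 1L)
  est <- relative_enrichment(cts$rip_count[1], attr(cts, "n_rip"),
                             cts$input_count[1], attr(cts, "n_input"))
  expect_gt(est, 3); expect_lt(est, 5)
})
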