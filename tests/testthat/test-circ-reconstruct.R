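# Junction clustering, isoform reconstruction, divergent PCR, the
# genomic-origin test, and sequence design utilities.

test_that("junction calls cluster by coordinates and support", {
  calls <- data.frame(
    consensus_id = "c",
    acceptor = c(100L, 100L, 100L, 100L, 300L),
    donor = c(900L, 900L, 900L, 900L, 700L),
    strand = "+",
    read_id = sprintf("r%d", 1:5), stringsAsFactors = FALSE)
  cl <- cluster_junctions(calls)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$support, c(4L, 1L))
  expect_equal(cl$acceptor[1], 100L); expect_equal(cl$donor[1], 900L)
  # tolerance merges near calls; single-linkage on the two-call instance
  near <- data.frame(consensus_id = "c", acceptor = c(100L, 101L),
                     donor = c(900L, 899L), strand = "+",
                     read_id = c("a", "b"), stringsAsFactors = FALSE)
  expect_equal(nrow(cluster_junctions(near, tolerance = 2L)), 1L)
  expect_equal(nrow(cluster_junctions(near, tolerance = 0L)), 2L)
  # empty input
  expect_equal(nrow(cluster_junctions(calls[0, ])), 0L)
  # different strands never merge
  two <- data.frame(consensus_id = "c", acceptor = 100L, donor = 900L,
                    strand = c("+", "-"), read_id = c("a", "b"),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(cluster_junctions(two)), 2L)
})

test_that("retention patterns give the expected isoform lengths", {
  skip253 <- list(c(fix_r253[["start"]], fix_r253[["end"]]))
  iso354 <- reconstruct_isoforms(fix_jx, fix_cons, list(skip253))[[1]]
  expect_equal(iso354$length, 354L)
  expect_equal(length(iso354$segments), 2L)

  iso607 <- reconstruct_isoforms(fix_jx, fix_cons)[[1]]
  expect_equal(iso607$length, 607L)

  k8 <- list(c(fix_jx$acceptor + 8L, fix_r253[["end"]]))
  expect_equal(reconstruct_isoforms(fix_jx, fix_cons, list(k8))[[1]]$length,
               277L)
  k27 <- list(c(fix_jx$acceptor + 27L, fix_r253[["end"]]))
  expect_equal(reconstruct_isoforms(fix_jx, fix_cons, list(k27))[[1]]$length,
               296L)
  # segments start at the acceptor and end at the donor
  expect_equal(iso354$segments[[1]][1], fix_jx$acceptor)
  expect_equal(iso354$segments[[2]][2], fix_jx$donor)
  # retention interval outside the junction span errors
  expect_error(reconstruct_isoforms(fix_jx, fix_cons,
                                    list(list(c(1L, 50L)))), "outside")
  # skipping the acceptor base itself is invalid
  expect_error(reconstruct_isoforms(
    fix_jx, fix_cons, list(list(c(fix_jx$acceptor, fix_jx$acceptor + 10L)))),
    "retained")
})

test_that("the wheat-style 188+135 architecture reconstructs to 323 nt", {
  wheat <- build_consensus(
    seed = 3L, params = consensus_params(region85 = 135L, region253 = 0L,
                                         region269 = 188L))
  iso <- reconstruct_isoforms(element_junction(wheat), wheat)[[1]]
  expect_equal(iso$length, 323L)
})

test_that("circle sequences respect canonical rotation and strand", {
  skip253 <- list(c(fix_r253[["start"]], fix_r253[["end"]]))
  iso <- reconstruct_isoforms(fix_jx, fix_cons, list(skip253))[[1]]
  ref <- paste0(substr(fix_cons$sequence, fix_r85[["start"]], fix_r85[["end"]]),
                substr(fix_cons$sequence, fix_r269[["start"]],
                       fix_r269[["end"]]))
  expect_identical(circular_sequence(iso), ref)
  expect_identical(canonical_rotation(rotate_circle(ref, 17)),
                   canonical_rotation(ref))
  # minus strand: reverse complement of the plus circle, re-canonicalized
  jx_m <- junction(fix_cons$id, fix_jx$acceptor, fix_jx$donor, "-")
  iso_m <- reconstruct_isoforms(jx_m, fix_cons, list(skip253))[[1]]
  expect_identical(canonical_rotation(circular_sequence(iso_m)),
                   canonical_rotation(revcomp(ref)))
})

test_that("divergent PCR discriminates circles from linear templates", {
  skip253 <- list(c(fix_r253[["start"]], fix_r253[["end"]]))
  circ <- circular_sequence(
    reconstruct_isoforms(fix_jx, fix_cons, list(skip253))[[1]])
  L <- nchar(circ)
  # divergent pair: forward near the 3' end, reverse near the 5' end
  fwd <- substr(circ, 301, 315)
  rev_site <- substr(circ, 26, 40)
  rev <- revcomp(rev_site)
  amp <- divergent_pcr(circ, fwd, rev, circular = TRUE)
  expect_false(is.null(amp))
  # derived product length: from position 301 across the junction to 40
  expect_equal(nchar(amp), (L - 301 + 1) + 40)
  # the amplicon spans the back-splice junction
  boundary <- paste0(substr(circ, L - 9, L), substr(circ, 1, 10))
  expect_true(grepl(boundary, amp, fixed = TRUE))
  # the same primers give nothing on the linearized sequence
  expect_null(divergent_pcr(circ, fwd, rev, circular = FALSE))
  # absent primer -> no product; malformed primers error
  expect_null(divergent_pcr(circ, strrep("A", 15), rev, circular = TRUE))
  expect_error(divergent_pcr(circ, "ACGTACGTACGTACX", rev), "non-ACGT")
  expect_error(divergent_pcr(circ, "ACGTACGTAC", rev), ">= 15")
})

test_that("every simulated circle supports divergent PCR, its linear form none", {
  circles <- fix_tx[fix_tx$kind == "CIRCULAR", ]
  for (i in seq_len(nrow(circles))) {
    circ <- circles$seq_plus[i]
    L <- nchar(circ)
    fwd <- substr(circ, L - 44, L - 30)
    rev <- revcomp(substr(circ, 16, 30))
    expect_false(is.null(divergent_pcr(circ, fwd, rev, circular = TRUE)),
                 info = circles$id[i])
    expect_null(divergent_pcr(circ, fwd, rev, circular = FALSE))
  }
})

test_that("genomic reads never cover the fusion point unless it is planted", {
  genome <- plant_elements(20000L, fix_cons, n_full = 2L, n_fragmented = 1L,
                           seed = 8L, divergence = 0.02)
  dna <- simulate_dna_reads(genome, 250L, read_len = 100L, seed = 8L)
  rep0 <- genomic_origin_test(fix_jx, fix_cons, dna$reads)
  expect_equal(rep0$n_junction_covering, 0L)
  expect_identical(rep0$verdict, "NO_GENOMIC_COPY")
  expect_equal(rep0$n_reads_checked, 250L)
  expect_equal(nchar(rep0$assumed_junction_sequence), 354L)

  # plant the fused junction sequence itself: covering counts must match
  # the brute-force count from read placements
  fused <- rep0$assumed_junction_sequence
  g2 <- plant_elements(6000L, fix_cons, n_full = 0L, n_fragmented = 0L,
                       seed = 9L, divergence = 0,
                       extra_sequences = c(fused_copy = fused))
  ins <- g2$insertions[g2$insertions$type == "fused_copy", ]
  dna2 <- simulate_dna_reads(g2, 400L, read_len = 100L, seed = 10L)
  rep1 <- genomic_origin_test(fix_jx, fix_cons, dna2$reads,
                              min_overhang = 10L)
  fusion_pos <- if (ins$strand == "+") ins$start + 177L - 1L
                else ins$end - 177L + 1L
  brute <- if (ins$strand == "+") {
    sum(dna2$truth$start <= fusion_pos - 9L &
          dna2$truth$end >= fusion_pos + 10L)
  } else {
    sum(dna2$truth$start <= fusion_pos - 10L &
          dna2$truth$end >= fusion_pos + 9L)
  }
  expect_equal(rep1$n_junction_covering, brute)
  expect_gt(rep1$n_junction_covering, 1L)
  expect_identical(rep1$verdict, "GENOMIC_COPY_SUSPECTED")
  # max_residual is monotone: a single residual read flips no verdict
  expect_identical(
    genomic_origin_test(fix_jx, fix_cons, dna2$reads,
                        max_residual = rep1$n_junction_covering)$verdict,
    "NO_GENOMIC_COPY")
  expect_error(genomic_origin_test(fix_jx, fix_cons, dna$reads, flank = 5L),
               "min_overhang")
  expect_error(genomic_origin_test(fix_jx, fix_cons, dna$reads,
                                   flank = 5000L), "exceeds")
})

test_that("junction-spanning target design follows the architecture", {
  expect_equal(nchar(design_junction_target(fix_jx, fix_cons)), 289L)
  expect_equal(nchar(design_junction_target(fix_jx, fix_cons,
                                            upstream_len = 0L)), 85L)
  expect_equal(nchar(design_junction_target(fix_jx, fix_cons,
                                            upstream_len = 100L)), 185L)
  tgt <- design_junction_target(fix_jx, fix_cons)
  expect_identical(substr(tgt, 205, 289),
                   substr(fix_cons$sequence, fix_r85[["start"]],
                          fix_r85[["end"]]))
  expect_error(design_junction_target(fix_jx, fix_cons, upstream_len = -1L),
               ">= 0")
})

test_that("restriction-site insertion edits right-to-left", {
  set.seed(12)
  tpl <- random_frag(1659)
  edited <- insert_restriction_sites(tpl, list(
    list(position = 400L, site = "GGATCC"),
    list(position = 1200L, site = "GAATTC")))
  expect_equal(nchar(edited), 1671L)
  expect_identical(substr(edited, 401, 406), "GGATCC")
  expect_identical(substr(edited, 1207, 1212), "GAATTC")
  # empty insertion list leaves the template unchanged
  expect_identical(insert_restriction_sites(tpl, list()), tpl)
  # a site at position 0 becomes the prefix
  pre <- insert_restriction_sites(tpl, list(list(position = 0L,
                                                 site = "GGATCC")))
  expect_equal(nchar(pre), 1665L)
  expect_identical(substr(pre, 1, 6), "GGATCC")
  expect_error(insert_restriction_sites(tpl, list(
    list(position = 10L, site = "GGATCC"),
    list(position = 10L, site = "GAATTC"))), "conflict")
})
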