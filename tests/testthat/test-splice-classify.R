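# Read taxonomy and back-splice junction extraction.

mk_hits <- function(rs, re, cs, ce, strand = "+", cons_id = "CRM1like") {
  data.frame(read_id = "x", read_start = rs, read_end = re,
             consensus_id = cons_id, c_start = cs, c_end = ce,
             strand = strand, score = re - rs + 1, identity = 1,
             evalue = 1e-10, rescued = FALSE, stringsAsFactors = FALSE)
}
mk_chain <- function(hits) {
  structure(list(hits = hits, consensus_id = hits$consensus_id[1],
                 strand = hits$strand[1], score = sum(hits$score),
                 primary = TRUE), class = "SegmentChain")
}

test_that("segment geometry drives the taxonomy", {
  # no chain -> UNALIGNED
  expect_identical(classify_fragment(NULL, fix_cons, read_id = "u")$category,
                   "UNALIGNED")
  # one internal segment -> NONSPLICED
  one <- mk_chain(mk_hits(1, 50, 2001, 2050))
  expect_identical(classify_fragment(one, fix_cons)$category, "NONSPLICED")
  # downstream site then upstream site on the read -> BACK_SPLICED with
  # donor = first segment's end, acceptor = second segment's start
  back <- mk_chain(rbind(mk_hits(1, 50, 2851, 2900),
                         mk_hits(51, 100, 1701, 1750)))
  cb <- classify_fragment(back, fix_cons)
  expect_identical(cb$category, "BACK_SPLICED")
  canon <- canonicalize_junction(1701, 2900, fix_cons)
  expect_equal(cb$acceptor, canon[["acceptor"]])
  expect_equal(cb$donor, canon[["donor"]])
  expect_lt(cb$acceptor, cb$donor)
  # collinear segments skipping a gap -> NORMAL_SPLICED
  norm <- mk_chain(rbind(mk_hits(1, 50, 1701, 1750),
                         mk_hits(51, 100, 2001, 2050)))
  cn <- classify_fragment(norm, fix_cons)
  expect_identical(cn$category, "NORMAL_SPLICED")
  expect_equal(cn$donor, 1750); expect_equal(cn$acceptor, 2001)
  # two backward adjacencies -> AMBIGUOUS
  amb <- mk_chain(rbind(mk_hits(1, 40, 2851, 2890),
                        mk_hits(41, 80, 1701, 1740),
                        mk_hits(81, 120, 901, 940)))
  expect_identical(classify_fragment(amb, fix_cons)$category, "AMBIGUOUS")
  # one backward adjacency among collinear ones is still a back splice
  multi <- mk_chain(rbind(mk_hits(1, 40, 2861, 2900),
                          mk_hits(41, 80, 1701, 1740),
                          mk_hits(81, 120, 2001, 2040)))
  expect_identical(classify_fragment(multi, fix_cons)$category,
                   "BACK_SPLICED")
})

test_that("LTR overlap takes precedence and partitions hold", {
  # 30 nt inside LTR5 -> LTR even though a second segment exists
  ltr <- mk_chain(rbind(mk_hits(1, 40, 421, 460),
                        mk_hits(41, 90, 2001, 2050)))
  expect_identical(classify_fragment(ltr, fix_cons)$category, "LTR")
  # overlap below the threshold stays NONSPLICED
  sub <- mk_chain(mk_hits(1, 60, 441, 500))  # 10 nt in LTR5
  expect_identical(classify_fragment(sub, fix_cons)$category, "NONSPLICED")
  # chain spanning two consensus ids -> AMBIGUOUS
  mixed <- mk_chain(rbind(mk_hits(1, 50, 2001, 2050),
                          mk_hits(51, 100, 101, 150, cons_id = "other")))
  expect_identical(classify_fragment(mixed, fix_cons)$category, "AMBIGUOUS")
})

test_that("junction microhomology canonicalizes to the leftmost placement", {
  # build a consensus with a 3-nt repeat shared by the two junction flanks:
  # bases before the acceptor equal bases ending at the donor
  set.seed(9)
  base <- random_frag(1000)
  acc0 <- 201L; don0 <- 800L
  s <- base
  substr(s, acc0 - 3, acc0 - 1) <- "TAG"
  substr(s, don0 - 2, don0) <- "TAG"
  # ensure no accidental extension beyond the constructed repeat
  substr(s, acc0 - 4, acc0 - 4) <- "A"; substr(s, don0 - 3, don0 - 3) <- "C"
  cons <- structure(list(id = "c", sequence = s,
                         regions = fix_cons$regions[0, ]),
                    class = "RepeatConsensus")
  shifts <- 0:3
  canon <- lapply(shifts, function(k)
    canonicalize_junction(acc0 - k, don0 - k, cons))
  for (k in seq_along(canon)) expect_identical(canon[[k]], canon[[1]])
  expect_equal(canon[[1]][["acceptor"]], acc0 - 3L)
  expect_equal(canon[[1]][["donor"]], don0 - 3L)
})

test_that("call_junctions emits one canonical call per back-spliced read", {
  expect_equal(nrow(call_junctions(
    data.frame(read_id = "a", category = "NONSPLICED",
               consensus_id = "c", acceptor = NA, donor = NA, strand = "+"),
    fix_cons)), 0L)
  cls <- data.frame(read_id = c("a", "b"),
                    category = c("BACK_SPLICED", "NONSPLICED"),
                    consensus_id = "CRM1like",
                    acceptor = c(fix_jx$acceptor, NA),
                    donor = c(fix_jx$donor, NA),
                    strand = "+", stringsAsFactors = FALSE)
  calls <- call_junctions(cls, fix_cons)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$acceptor, fix_canon[["acceptor"]])
  expect_equal(calls$donor, fix_canon[["donor"]])
})

test_that("classification is strand-invariant on simulated fragments", {
  sim <- simulate_reads(fix_tx[fix_tx$kind == "CIRCULAR", ], 40L,
                        seed = 21L, insert_mean = 150, insert_sd = 15)
  mg <- merge_pairs(sim$r1, sim$r2, q1 = sim$q1, q2 = sim$q2)
  frags <- mg$fragments$sequence
  cls_fwd <- classify_fragments(
    data.frame(id = mg$fragments$id, sequence = frags), fix_idx, fix_cons)
  cls_rev <- classify_fragments(
    data.frame(id = mg$fragments$id, sequence = revcomp(frags)), fix_idx,
    fix_cons)
  expect_identical(cls_fwd$category, cls_rev$category)
  expect_identical(cls_fwd$acceptor, cls_rev$acceptor)
  expect_identical(cls_fwd$donor, cls_rev$donor)
  # strand labels flip where defined
  def <- !is.na(cls_fwd$strand) & !is.na(cls_rev$strand)
  expect_true(all(cls_fwd$strand[def] != cls_rev$strand[def]))
})

test_that("every fragment gets exactly one category", {
  suppressWarnings(
    sim <- simulate_reads(fix_tx, 80L, seed = 31L, insert_mean = 150,
                          insert_sd = 15))
  mg <- merge_pairs(sim$r1, sim$r2, q1 = sim$q1, q2 = sim$q2)
  cls <- classify_fragments(mg$fragments, fix_idx, fix_cons)
  expect_equal(nrow(cls), nrow(mg$fragments))
  expect_true(all(cls$category %in% retrocirc:::CATEGORIES))
  expect_equal(sum(table(cls$category)), nrow(mg$fragments))
  # junction present iff spliced
  spliced <- cls$category %in% c("NORMAL_SPLICED", "BACK_SPLICED")
  expect_true(all(!is.na(cls$acceptor[spliced])))
  expect_true(all(is.na(cls$acceptor[!spliced])))
})

test_that("simulated circles round-trip to their true junction", {
  sim <- simulate_reads(fix_tx[fix_tx$kind == "CIRCULAR", ], 150L,
                        seed = 41L, insert_mean = 150, insert_sd = 15)
  mg <- merge_pairs(sim$r1, sim$r2, q1 = sim$q1, q2 = sim$q2)
  cls <- classify_fragments(mg$fragments, fix_idx, fix_cons)
  m <- merge(cls, sim$truth, by = "read_id")
  el <- eligible_crossing(m)
  expect_gt(sum(el), 20)
  sub <- m[el, ]
  expect_true(all(sub$category == "BACK_SPLICED"))
  expect_true(all(sub$acceptor == fix_canon[["acceptor"]]))
  expect_true(all(sub$donor == fix_canon[["donor"]]))
  # reads wholly inside one consensus-contiguous stretch are nonspliced
  lin <- simulate_reads(fix_tx[fix_tx$id == "RNA-269", ], 40L, seed = 43L,
                        insert_mean = 150, insert_sd = 15)
  mg2 <- merge_pairs(lin$r1, lin$r2, q1 = lin$q1, q2 = lin$q2)
  cls2 <- classify_fragments(mg2$fragments, fix_idx, fix_cons)
  expect_true(all(cls2$category == "NONSPLICED"))
})
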