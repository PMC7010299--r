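# Shared fixtures, built once per test run. All synthetic, all seeded.

fix_cons <- build_consensus(seed = 42L)
fix_r85 <- consensus_region(fix_cons, "REGION85")
fix_r253 <- consensus_region(fix_cons, "REGION253")
fix_r269 <- consensus_region(fix_cons, "REGION269")
fix_jx <- element_junction(fix_cons)
fix_canon <- canonicalize_junction(fix_jx$acceptor, fix_jx$donor, fix_cons)
fix_tx <- make_transcripts(fix_cons)
fix_idx <- consensus_index(fix_cons)

# a ~2 kb single-copy consensus (no duplicated LTRs), used wherever
# alignment placements must be unambiguous
cons2kb <- build_consensus(
  seed = 7L,
  params = consensus_params(ltr = 0L, gag = 500L, pr = 200L, rt = 400L,
                            rnh = 150L, int = 138L, spacer = 0L),
  id = "cons2kb")

# acceptor-side retained length per default circular template (the k of
# the 277-296 variants; 85 for the full acceptor-side region)
default_k <- c(circ354_plus = 85L, circ354_minus = 85L, circ607_plus = 85L,
               circ277_plus = 8L, circ277_minus = 8L,
               circ286_plus = 17L, circ286_minus = 17L,
               circ296_plus = 27L, circ296_minus = 27L)

# microhomology run of a junction fusing ...cons[d] | cons[a]...: hl = how
# far the fusion point can shift left, hr = how far right, without changing
# the fused sequence
homology_shifts <- function(consensus, acceptor, donor) {
  s <- consensus$sequence
  base <- function(i) substr(s, i, i)
  hl <- 0L
  while (acceptor - hl - 1L >= 1 && base(acceptor - hl - 1L) ==
         base(donor - hl)) hl <- hl + 1L
  hr <- 0L
  while (donor + hr + 1L <= nchar(s) && base(donor + hr + 1L) ==
         base(acceptor + hr)) hr <- hr + 1L
  c(hl = hl, hr = hr)
}

fix_h <- homology_shifts(fix_cons, fix_jx$acceptor, fix_jx$donor)

# a junction-crossing read is structurally identifiable when each arm
# offers >= min_word anchorable nt beyond the junction's microhomology run
# (homology bases are claimed by the other arm's alignment), and the
# acceptor side reaches min_word nt beyond any retained piece shorter than
# min_word
eligible_crossing <- function(truth, min_word = 11L, h = fix_h) {
  k <- default_k[truth$template_id]
  need_acc <- ifelse(k >= min_word, min_word, k + min_word) + h[["hr"]]
  truth$crosses_junction & !is.na(k) &
    truth$donor_arm >= min_word + h[["hl"]] &
    truth$acceptor_arm >= need_acc
}

random_frag <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                 collapse = "")
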