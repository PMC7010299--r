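# Read taxonomy: every merged fragment is assigned exactly one category.
# Reads touching an LTR take the LTR class (precedence keeps the taxonomy a
# partition); single-segment reads inside the element body are nonspliced;
# two-site reads are spliced, and the order of the two sites on the read
# distinguishes a normal (collinear, gap-skipping) splice from a back
# splice, where the downstream 3' site is fused to an upstream 5' site.

CATEGORIES <- c("LTR", "NONSPLICED", "NORMAL_SPLICED", "BACK_SPLICED",
                "UNALIGNED", "AMBIGUOUS")

#' Canonicalize back-splice junction coordinates
#'
#' Junction-flank microhomology makes the exact breakpoint ambiguous: if
#' the base before the acceptor equals the donor base, the junction can be
#' shifted one step left without changing the circle sequence. Coordinates
#' are shifted to the leftmost equivalent placement so every equivalent
#' call maps to one cluster key.
#'
#' @param acceptor,donor 1-based consensus coordinates (acceptor < donor).
#' @param consensus a `RepeatConsensus` (or character sequence).
#' @return integer `c(acceptor, donor)` after leftmost shifting.
#' @export
canonicalize_junction <- function(acceptor, donor, consensus) {
  s <- if (inherits(consensus, "RepeatConsensus")) consensus$sequence
       else consensus
  while (acceptor > 1 &&
         substr(s, acceptor - 1, acceptor - 1) == substr(s, donor, donor)) {
    acceptor <- acceptor - 1L
    donor <- donor - 1L
  }
  c(acceptor = as.integer(acceptor), donor = as.integer(donor))
}

# adjacency relation between consecutive (normalized) segments; consensus
# gaps up to `jitter` are alignment noise, not splices
adjacency_kind <- function(a, b, jitter) {
  if (b$c_start < a$c_start) return("backward")
  cg <- b$c_start - a$c_end - 1L
  if (cg > jitter) return("forward") else return("contiguous")
}

#' Classify one fragment from its primary segment chain
#'
#' Categories: no chain is UNALIGNED; any segment overlapping an LTR region
#' by `>= min_ltr_overlap` nt makes the read LTR (precedence); a single
#' internal segment is NONSPLICED; collinear segments skipping an internal
#' gap are NORMAL_SPLICED; a downstream-then-upstream segment order on the
#' read is BACK_SPLICED, with donor = first segment's consensus end and
#' acceptor = second segment's consensus start, canonicalized leftmost.
#' Chains with more than one backward adjacency, or with inconsistent
#' geometry, are AMBIGUOUS. Chains with several segments but exactly one
#' backward adjacency and otherwise collinear geometry are BACK_SPLICED
#' (a read can traverse both the back-splice and a forward splice of the
#' same circle).
#'
#' For minus-strand chains the geometry is evaluated on the reverse
#' complement frame, so classification is strand-invariant and junction
#' coordinates always refer to the plus consensus frame.
#'
#' When the two arms of a back-splice leave a short unaligned insert on the
#' read (a partially retained acceptor-side piece shorter than the seed
#' word), the insert is matched exactly against the consensus; a unique
#' upstream placement relocates the acceptor to it.
#'
#' @param chain a `SegmentChain` or NULL.
#' @param consensus the `RepeatConsensus` the chain is on.
#' @param fragment the fragment sequence (enables insert refinement;
#'   optional).
#' @param min_ltr_overlap minimum LTR overlap in nt for the LTR class.
#' @param jitter consensus-gap tolerance treated as contiguity noise.
#' @param read_id id recorded when `chain` is NULL.
#' @return one-row data frame: `read_id`, `category`, `consensus_id`,
#'   `acceptor`, `donor`, `strand`.
#' @export
classify_fragment <- function(chain, consensus, fragment = NULL,
                              min_ltr_overlap = 20L, jitter = 10L,
                              read_id = NA_character_) {
  row <- function(category, consensus_id = NA_character_,
                  acceptor = NA_integer_, donor = NA_integer_,
                  strand = NA_character_, id = read_id) {
    data.frame(read_id = id, category = category,
               consensus_id = consensus_id, acceptor = acceptor,
               donor = donor, strand = strand, stringsAsFactors = FALSE)
  }
  if (is.null(chain)) return(row("UNALIGNED"))
  hits <- chain$hits
  id <- hits$read_id[1]
  if (length(unique(hits$consensus_id)) > 1)
    return(row("AMBIGUOUS", id = id))
  # LTR precedence
  ltr <- consensus$regions[consensus$regions$label %in% c("LTR5", "LTR3"), ]
  if (nrow(ltr) > 0) {
    for (i in seq_len(nrow(hits))) {
      ov <- pmin(hits$c_end[i], ltr$end) - pmax(hits$c_start[i], ltr$start) + 1L
      if (any(ov >= min_ltr_overlap))
        return(row("LTR", chain$consensus_id, strand = chain$strand, id = id))
    }
  }
  # normalize geometry onto the plus frame
  nh <- hits
  nfrag <- fragment
  if (chain$strand == "-" && !is.null(fragment)) nfrag <- revcomp(fragment)
  if (chain$strand == "-") {
    m <- if (!is.null(fragment)) nchar(fragment) else max(hits$read_end)
    rs <- m - nh$read_end + 1L
    re <- m - nh$read_start + 1L
    nh$read_start <- rs; nh$read_end <- re
  }
  nh <- nh[order(nh$read_start, nh$read_end), , drop = FALSE]
  n <- nrow(nh)
  if (n == 1)
    return(row("NONSPLICED", chain$consensus_id, strand = chain$strand,
               id = id))
  kinds <- character(n - 1)
  for (i in seq_len(n - 1))
    kinds[i] <- adjacency_kind(nh[i, ], nh[i + 1, ], jitter)
  nb <- sum(kinds == "backward")
  nf <- sum(kinds == "forward")
  if (nb == 0 && nf == 0)
    return(row("NONSPLICED", chain$consensus_id, strand = chain$strand,
               id = id))
  if (nb == 0) {
    i <- which(kinds == "forward")[1]
    return(row("NORMAL_SPLICED", chain$consensus_id,
               acceptor = nh$c_start[i + 1], donor = nh$c_end[i],
               strand = chain$strand, id = id))
  }
  if (nb > 1)
    return(row("AMBIGUOUS", id = id))
  i <- which(kinds == "backward")
  a_seg <- nh[i, ]; b_seg <- nh[i + 1, ]
  if (!is.null(nfrag)) {
    rf <- refine_backsplice(nfrag, a_seg, b_seg, consensus$sequence)
    donor <- rf[["donor"]]; acceptor <- rf[["acceptor"]]
  } else {
    donor <- a_seg$c_end
    acceptor <- b_seg$c_start
    o <- a_seg$read_end - b_seg$read_start + 1L
    if (o > 0) donor <- donor - o  # overlap bases belong to the acceptor side
  }
  if (acceptor >= donor) return(row("AMBIGUOUS", id = id))
  cd <- canonicalize_junction(acceptor, donor, consensus)
  row("BACK_SPLICED", chain$consensus_id, acceptor = cd[["acceptor"]],
      donor = cd[["donor"]], strand = chain$strand, id = id)
}

# Anchored split refinement of a back-splice breakpoint. The two segments
# anchor ungapped mappings of the spanning read interval: left-anchored
# from the donor arm's start, right-anchored from the acceptor arm's end.
# The split maximizing total matches places the breakpoint; on a
# microhomology plateau the leftmost split is taken, matching leftmost
# junction canonicalization. A retained acceptor-side piece too short to
# anchor shows up as a run of right-arm mismatches just after the split;
# if it matches the consensus at a unique upstream position, the acceptor
# relocates there. Assumes substitution-only arms (no indels), which holds
# for anchor-trimmed hits on the default error model.
refine_backsplice <- function(nfrag, a_seg, b_seg, cons_seq,
                              anchor_run = 6L, min_insert = 8L) {
  A <- a_seg$read_start; B <- b_seg$read_end
  L <- nchar(cons_seq)
  fc <- chars(substr(nfrag, A, B))
  n <- length(fc)
  cc <- chars(cons_seq)
  lpos <- a_seg$c_start + (seq_len(n) - 1L)
  rpos <- b_seg$c_end - (n - seq_len(n))
  fl <- lpos >= 1 & lpos <= L & fc == cc[pmin(pmax(lpos, 1L), L)]
  fr <- rpos >= 1 & rpos <= L & fc == cc[pmin(pmax(rpos, 1L), L)]
  CL <- cumsum(fl)
  CR <- rev(cumsum(rev(fr)))
  tot <- CL[1:(n - 1)] + CR[2:n]
  valid <- lpos[1:(n - 1)] <= L & rpos[2:n] >= 1
  tot[!valid] <- -Inf
  if (all(!is.finite(tot))) {
    return(c(donor = a_seg$c_end, acceptor = b_seg$c_start))
  }
  s <- which.max(tot)  # leftmost maximum
  best <- list(score = tot[s], donor = lpos[s], acceptor = rpos[s + 1L])
  base_score <- best$score
  # alternative interpretation: left arm | short retained insert matching
  # the consensus at a unique upstream position | right-anchored arm.
  # Total explained matches decide between the two.
  anchored <- which(vapply(seq_len(max(0L, n - anchor_run + 1L)),
                           function(j) all(fr[j:(j + anchor_run - 1L)]),
                           TRUE))
  run_starts <- if (length(anchored))
    anchored[c(TRUE, diff(anchored) > 1L)] else integer(0)
  # chance matches just before a run can shift its apparent start, so the
  # right-arm anchor j0 is also scanned a few positions past each start
  tried <- character(0)
  cand_best <- NULL
  for (rs0 in run_starts) {
    for (j0 in rs0:min(rs0 + anchor_run, n)) {
      if (j0 <= min_insert + 1L || !fr[j0]) next
      for (s2 in seq(j0 - 1L - min_insert, max(1L, j0 - 1L - 40L))) {
        key <- paste(s2, j0)
        if (key %in% tried) next
        tried <- c(tried, key)
        g <- j0 - 1L - s2
        # cheap upper bound before the expensive placement search; a
        # spurious placement next to a sequencing error can inflate the
        # score by at most +1 (the tolerated substitution), so the insert
        # interpretation must beat the plain split by at least 2
        if (CL[s2] + g + CR[j0] <= base_score + 1L) next
        insert <- substr(nfrag, A + s2, A + s2 + g - 1L)
        # the insert must have a single best placement (allowing one
        # substitution, with a one-mismatch margin over the runner-up) in
        # the whole consensus, upstream of the anchored arm
        pl <- best_unique_placement(insert, cons_seq, max_mismatch = 1L)
        if (is.null(pl) || pl$pos + g - 1L >= rpos[j0]) next
        sc <- CL[s2] + (g - pl$mism) + CR[j0]
        if (sc <= base_score + 1L) next
        # among tied insert interpretations the rightmost donor (maximal
        # donor arm) wins, then the leftmost acceptor
        if (is.null(cand_best) || sc > cand_best$score ||
            (sc == cand_best$score &&
             (lpos[s2] > cand_best$donor ||
              (lpos[s2] == cand_best$donor &&
               pl$pos < cand_best$acceptor)))) {
          cand_best <- list(score = sc, donor = lpos[s2],
                            acceptor = pl$pos)
        }
      }
    }
  }
  if (!is.null(cand_best) && cand_best$score > best$score)
    best <- cand_best
  c(donor = best$donor, acceptor = best$acceptor)
}

exact_occurrences <- function(pattern, subject) {
  if (nchar(pattern) == 0) return(integer(0))
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

# unique best placement of a short pattern: at most `max_mismatch`
# substitutions, and strictly fewer mismatches than any other candidate
best_unique_placement <- function(pattern, subject, max_mismatch = 1L) {
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject),
                                max.mismatch = max_mismatch)
  pos <- BiocGenerics::start(m)
  if (length(pos) == 0) return(NULL)
  if (length(pos) == 1) {
    mm <- sum(chars(pattern) !=
                chars(substr(subject, pos, pos + nchar(pattern) - 1L)))
    return(list(pos = pos, mism = mm))
  }
  pc <- chars(pattern)
  mm <- vapply(pos, function(p)
    sum(pc != chars(substr(subject, p, p + nchar(pattern) - 1L))), 1)
  ord <- order(mm)
  if (mm[ord[2]] - mm[ord[1]] < 1) return(NULL)
  list(pos = pos[ord[1]], mism = mm[ord[1]])
}

#' Classify a set of fragments end to end
#'
#' Runs align -> rescue -> chain -> classify for each fragment and returns
#' the full classification table (one row per fragment).
#'
#' @param fragments data frame with `id` and `sequence` columns (e.g. from
#'   [merge_pairs()]), or a named character vector.
#' @param index a `ConsensusIndex` or consensus set.
#' @param consensus the `RepeatConsensus` used for region labels and
#'   canonicalization (defaults to the single entry of `index`).
#' @param min_word,evalue_max,min_identity,max_read_gap,max_read_overlap,min_ltr_overlap
#'   stage thresholds (see the stage functions).
#' @param params scoring parameters.
#' @return data frame of classifications plus a `hits` attribute (all
#'   retained hits, for quantification).
#' @export
classify_fragments <- function(fragments, index, consensus = NULL,
                               min_word = 11L, evalue_max = 1e-5,
                               min_identity = 0.85, max_read_gap = 10L,
                               max_read_overlap = 10L, min_ltr_overlap = 20L,
                               params = align_params()) {
  if (!inherits(index, "ConsensusIndex"))
    index <- consensus_index(index, word = min_word)
  if (is.null(consensus)) {
    if (length(index$entries) != 1)
      stop("supply `consensus` when the index holds several elements",
           call. = FALSE)
    consensus <- index$entries[[1]]$consensus
  }
  if (is.character(fragments)) {
    fragments <- data.frame(
      id = names(fragments) %||% sprintf("frag_%06d", seq_along(fragments)),
      sequence = unname(fragments), stringsAsFactors = FALSE)
  }
  rows <- vector("list", nrow(fragments))
  all_hits <- vector("list", nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    fr <- fragments$sequence[i]
    id <- fragments$id[i]
    if (nchar(fr) < min_word) {
      rows[[i]] <- classify_fragment(NULL, consensus, read_id = id)
      next
    }
    hits <- align_fragment(fr, index, min_word = min_word,
                           evalue_max = evalue_max,
                           min_identity = min_identity, read_id = id,
                           params = params)
    hits <- rescue_anchors(fr, hits, index, min_word = min_word,
                           min_identity = min_identity, params = params)
    all_hits[[i]] <- hits
    if (nrow(hits) == 0) {
      rows[[i]] <- classify_fragment(NULL, consensus, read_id = id)
      next
    }
    chains <- chain_segments(hits, max_read_gap = max_read_gap,
                             max_read_overlap = max_read_overlap)
    primary <- chains[[which(vapply(chains, `[[`, TRUE, "primary"))]]
    cons_i <- consensus
    if (primary$consensus_id != consensus$id) {
      j <- match(primary$consensus_id,
                 vapply(index$entries, `[[`, "", "id"))
      cons_i <- index$entries[[j]]$consensus
    }
    rows[[i]] <- classify_fragment(primary, cons_i, fragment = fr,
                                   min_ltr_overlap = min_ltr_overlap,
                                   jitter = max_read_gap, read_id = id)
  }
  out <- do.call(rbind, rows)
  attr(out, "hits") <- do.call(rbind, all_hits)
  out
}

#' Emit one canonicalized junction call per back-spliced read
#'
#' @param classifications data frame from [classify_fragments()] (or rows
#'   built by [classify_fragment()]).
#' @param consensus a `RepeatConsensus` for canonicalization.
#' @return data frame of per-read junction calls: `consensus_id`,
#'   `acceptor`, `donor`, `strand`, `read_id`.
#' @export
call_junctions <- function(classifications, consensus) {
  bs <- classifications[classifications$category == "BACK_SPLICED", ,
                        drop = FALSE]
  if (nrow(bs) == 0) {
    return(data.frame(consensus_id = character(0), acceptor = integer(0),
                      donor = integer(0), strand = character(0),
                      read_id = character(0), stringsAsFactors = FALSE))
  }
  canon <- t(vapply(seq_len(nrow(bs)), function(i)
    canonicalize_junction(bs$acceptor[i], bs$donor[i], consensus),
    integer(2)))
  data.frame(consensus_id = bs$consensus_id, acceptor = canon[, 1],
             donor = canon[, 2], strand = bs$strand, read_id = bs$read_id,
             stringsAsFactors = FALSE)
}

#' Write classifications as TSV
#' @param classifications classification data frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_classifications <- function(classifications, path) {
  utils::write.table(classifications, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
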