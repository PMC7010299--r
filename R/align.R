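# Seed-and-extend local alignment of fragments against the repeat consensus
# set. The strategy mirrors a BLASTN-style search at desk scale: exact
# word seeds locate candidate subject windows, an affine-gap Smith-Waterman
# kernel extends within each window, and the best local alignment is
# accepted if it passes a Karlin-Altschul e-value and an identity floor;
# the query interval it explains is then masked and the flanks re-searched
# so one chimeric fragment yields several non-overlapping hits.

#' Alignment scoring parameters
#'
#' BLASTN-like defaults: match +1, mismatch -2, and affine gaps costing
#' `gap_open + L * gap_ext` for a gap of length L. The Karlin-Altschul
#' lambda is solved from the substitution scores under a uniform base
#' composition; K defaults to 0.62, the tabulated ungapped BLASTN value
#' for +1/-2 scoring.
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_ext positive gap costs.
#' @param K Karlin-Altschul K.
#' @return list of scoring parameters with `lambda` precomputed.
#' @export
align_params <- function(match = 1L, mismatch = -2L, gap_open = 5L,
                         gap_ext = 2L, K = 0.62) {
  lambda <- stats::uniroot(
    function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1,
    c(1e-6, 10), tol = 1e-12)$root
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_ext = gap_ext, K = K, lambda = lambda)
}

# Local alignments over-extend through partially matching sequence (any
# flank scoring > 0 on balance is absorbed), which corrupts back-splice
# breakpoints. Ends are therefore trimmed back to exact anchors: the
# alignment must start and end with `trim_k` consecutive match columns.
# Returns the retained column range, or NULL when no such anchor exists.
anchor_trim_range <- function(match_col, trim_k) {
  r <- rle(match_col == 1)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  good <- which(r$values & r$lengths >= trim_k)
  if (length(good) == 0) return(NULL)
  c(starts[good[1]], ends[good[length(good)]])
}

# score of a column subrange (diagonal columns score match/mismatch, gap
# runs cost open + ext per base)
score_cols <- function(qpos, spos, match_col, range, params) {
  idx <- range[1]:range[2]
  q <- qpos[idx]; s <- spos[idx]; mc <- match_col[idx]
  diag <- q > 0 & s > 0
  sc <- sum(mc[diag]) * params$match +
    sum(diag & mc == 0) * params$mismatch
  gap <- !diag
  if (any(gap)) {
    runs <- rle(gap)
    n_runs <- sum(runs$values)
    sc <- sc - n_runs * params$gap_open - sum(gap) * params$gap_ext
  }
  sc
}

# apply anchor trimming to a kernel alignment result; NULL when nothing
# anchored remains
trim_alignment <- function(al, trim_k, params) {
  rg <- anchor_trim_range(al$match_col, trim_k)
  if (is.null(rg)) return(NULL)
  idx <- rg[1]:rg[2]
  q <- al$qpos[idx]; s <- al$spos[idx]; mc <- al$match_col[idx]
  list(score = score_cols(al$qpos, al$spos, al$match_col, rg, params),
       q_start = min(q[q > 0]), q_end = max(q[q > 0]),
       s_start = min(s[s > 0]), s_end = max(s[s > 0]),
       n_match = sum(mc), n_col = length(idx),
       qpos = q, spos = s, match_col = mc)
}

#' Karlin-Altschul expectation value for a local alignment score
#'
#' @param score alignment score.
#' @param m query (fragment) length.
#' @param n database length (total consensus length).
#' @param params from [align_params()].
#' @return numeric e-value.
#' @export
evalue_score <- function(score, m, n, params = align_params()) {
  params$K * m * n * exp(-params$lambda * score)
}

#' Precompute a word index over a consensus set
#'
#' @param consensus_set a `RepeatConsensus` or list of them.
#' @param word seed word size.
#' @return a `ConsensusIndex` used by [align_fragment()].
#' @export
consensus_index <- function(consensus_set, word = 11L) {
  if (inherits(consensus_set, "RepeatConsensus"))
    consensus_set <- list(consensus_set)
  if (length(consensus_set) == 0)
    stop("empty consensus set (configuration error)", call. = FALSE)
  entries <- lapply(consensus_set, function(cons) {
    s <- cons$sequence
    L <- nchar(s)
    if (L < word) stop("consensus shorter than word size", call. = FALSE)
    words <- substring(s, 1:(L - word + 1L), word:L)
    list(id = cons$id, seq = s, len = L,
         index = split(seq_len(L - word + 1L), words),
         consensus = cons)
  })
  ids <- vapply(entries, `[[`, character(1), "id")
  # fragment-to-family ties are broken by lexicographic consensus id
  entries <- entries[order(ids)]
  structure(list(entries = entries, word = word,
                 total_len = sum(vapply(entries, `[[`, 1L, "len"))),
            class = "ConsensusIndex")
}

# best seeded local alignment of fragment interval [qs, qe] over all
# consensus entries and both strands; returns NULL when no seed fires or
# nothing scores > 0. Deterministic tie-break: highest score, then "+"
# before "-", then consensus id, then smallest subject start, then smallest
# read start.
seeded_best <- function(fragment, qs, qe, index, params) {
  w <- index$word
  ns <- qe - qs + 1L
  if (ns < w) return(NULL)
  sub <- substr(fragment, qs, qe)
  pad <- 20L
  cands <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") sub else revcomp(sub)
    qwords <- substring(q, 1:(ns - w + 1L), w:ns)
    for (e in index$entries) {
      hits <- e$index[qwords]
      spos <- sort(unique(unlist(hits, use.names = FALSE)))
      if (length(spos) == 0) next
      # group seed positions into windows no wider than needed for a full
      # query extension
      brk <- c(0L, which(diff(spos) > ns + 2L * pad), length(spos))
      for (g in seq_len(length(brk) - 1L)) {
        gpos <- spos[(brk[g] + 1L):brk[g + 1L]]
        ws <- max(1L, min(gpos) - ns - pad)
        we <- min(e$len, max(gpos) + w + ns + pad)
        al <- .sw_align_cpp(q, substr(e$seq, ws, we), params$match,
                            params$mismatch, params$gap_open, params$gap_ext)
        if (al$score <= 0) next
        cands[[length(cands) + 1L]] <- list(
          al = al, score = al$score, consensus_id = e$id, ws = ws,
          strand = strand, qs = qs, ns = ns)
      }
    }
  }
  if (length(cands) == 0) return(NULL)
  # selection is on the raw (untrimmed) score, like an exhaustive scan
  ord <- order(-vapply(cands, `[[`, 1, "score"),
               vapply(cands, `[[`, "", "strand"),
               vapply(cands, `[[`, "", "consensus_id"),
               vapply(cands, function(x) as.numeric(x$ws + x$al$s_start), 1),
               vapply(cands, function(x) as.numeric(x$qs), 1))
  cands[[ord[1]]]
}

# map a (possibly trimmed) kernel alignment of the strand-local query back
# to fragment and consensus frames
map_candidate <- function(cand, tal) {
  if (cand$strand == "+") {
    rs <- cand$qs + tal$q_start - 1L; re <- cand$qs + tal$q_end - 1L
  } else {
    rs <- cand$qs + (cand$ns - tal$q_end + 1L) - 1L
    re <- cand$qs + (cand$ns - tal$q_start + 1L) - 1L
  }
  list(read_start = rs, read_end = re, consensus_id = cand$consensus_id,
       c_start = cand$ws + tal$s_start - 1L,
       c_end = cand$ws + tal$s_end - 1L, strand = cand$strand,
       score = tal$score, n_match = tal$n_match, n_col = tal$n_col)
}

#' Align one fragment against the consensus set
#'
#' Reports every non-redundant local alignment passing the e-value and
#' identity thresholds, on either strand, sorted by read position. The
#' query intervals of accepted hits never overlap: after accepting the
#' best alignment of an interval the flanking sub-intervals are searched
#' recursively (equivalent to masking).
#'
#' @param fragment fragment sequence (character scalar).
#' @param index a `ConsensusIndex` (or consensus set, indexed on the fly).
#' @param min_word seed word size when indexing on the fly; also the
#'   smallest query interval worth searching.
#' @param evalue_max maximum e-value (the "1e-5" BLAST setting).
#' @param min_identity minimum identity (matches / alignment columns).
#' @param trim_k alignments are trimmed back so that they start and end
#'   with `trim_k` consecutive match columns; this stops local alignments
#'   from over-extending through partially matching junction flanks, which
#'   would corrupt back-splice breakpoints.
#' @param read_id id recorded in the output.
#' @param params scoring parameters.
#' @return data frame of `SegmentHit` rows: `read_id`, `read_start`,
#'   `read_end`, `consensus_id`, `c_start`, `c_end`, `strand`, `score`,
#'   `identity`, `evalue`, `rescued` (all coordinates 1-based inclusive,
#'   read intervals on the fragment as given).
#' @export
align_fragment <- function(fragment, index, min_word = 11L,
                           evalue_max = 1e-5, min_identity = 0.85,
                           trim_k = 6L, read_id = "read",
                           params = align_params()) {
  if (!inherits(index, "ConsensusIndex"))
    index <- consensus_index(index, word = min_word)
  m <- nchar(fragment)
  if (m < min_word)
    stop("fragment shorter than min_word", call. = FALSE)
  assert_dna(fragment, "fragment")
  hits <- list()
  recurse <- function(qs, qe) {
    if (qe - qs + 1L < index$word) return(invisible())
    cand <- seeded_best(fragment, qs, qe, index, params)
    if (is.null(cand)) return(invisible())
    tal <- trim_alignment(cand$al, trim_k, params)
    if (is.null(tal)) return(invisible())
    best <- map_candidate(cand, tal)
    ev <- evalue_score(best$score, m, index$total_len, params)
    ident <- best$n_match / best$n_col
    # accept-the-best-or-stop, mirrored exactly by the exhaustive oracle
    if (ev > evalue_max || ident < min_identity) return(invisible())
    best$evalue <- ev
    best$identity <- ident
    hits[[length(hits) + 1L]] <<- best
    recurse(qs, best$read_start - 1L)
    recurse(best$read_end + 1L, qe)
    invisible()
  }
  recurse(1L, m)
  hits_df(hits, read_id)
}

hits_df <- function(hits, read_id) {
  if (length(hits) == 0) {
    return(data.frame(read_id = character(0), read_start = integer(0),
                      read_end = integer(0), consensus_id = character(0),
                      c_start = integer(0), c_end = integer(0),
                      strand = character(0), score = integer(0),
                      identity = numeric(0), evalue = numeric(0),
                      rescued = logical(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    read_id = read_id,
    read_start = vapply(hits, `[[`, 1, "read_start"),
    read_end = vapply(hits, `[[`, 1, "read_end"),
    consensus_id = vapply(hits, `[[`, "", "consensus_id"),
    c_start = vapply(hits, `[[`, 1, "c_start"),
    c_end = vapply(hits, `[[`, 1, "c_end"),
    strand = vapply(hits, `[[`, "", "strand"),
    score = vapply(hits, `[[`, 1, "score"),
    identity = vapply(hits, `[[`, 1, "identity"),
    evalue = vapply(hits, function(h) h$evalue %||% NA_real_, 1),
    rescued = vapply(hits, function(h) isTRUE(h$rescued), TRUE),
    stringsAsFactors = FALSE)
  out[order(out$read_start, out$read_end), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rescue short unexplained read termini and gaps as ungapped anchors
#'
#' A back-splice arm as short as the seed word can never pass the e-value
#' threshold on its own, so after significant hits are found, maximal
#' unexplained read intervals of at least `min_word` nt are matched
#' ungapped against the consensus of the fragment's best hit (same strand);
#' a placement is accepted at identity `>= min_identity`, ties going to the
#' leftmost consensus position. Rescued hits carry `evalue = NA`.
#'
#' @param fragment fragment sequence.
#' @param hits data frame from [align_fragment()].
#' @param index a `ConsensusIndex`.
#' @param min_word minimum rescued interval length.
#' @param min_identity minimum identity of the ungapped placement.
#' @param params scoring parameters (for the reported score).
#' @return `hits` with rescued rows appended, sorted by read position.
#' @export
rescue_anchors <- function(fragment, hits, index, min_word = 11L,
                           min_identity = 0.85, params = align_params()) {
  if (nrow(hits) == 0) return(hits)
  if (!inherits(index, "ConsensusIndex"))
    index <- consensus_index(index, word = min_word)
  top <- hits[which.max(hits$score), ]
  e <- index$entries[[match(top$consensus_id,
                            vapply(index$entries, `[[`, "", "id"))]]
  m <- nchar(fragment)
  covered <- rep(FALSE, m)
  for (i in seq_len(nrow(hits)))
    covered[hits$read_start[i]:hits$read_end[i]] <- TRUE
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  gaps <- which(!runs$values & runs$lengths >= min_word)
  cc <- chars(e$seq)
  new_hits <- list()
  # a composite interval (e.g. retained piece + circle continuation) has no
  # single ungapped placement: place the best anchored sub-interval, then
  # recurse on what is left
  rescue_interval <- function(lo, hi) {
    glen <- hi - lo + 1L
    if (glen < min_word || glen > e$len) return(invisible())
    qsub <- substr(fragment, lo, hi)
    if (top$strand == "-") qsub <- revcomp(qsub)
    qc <- chars(qsub)
    noff <- e$len - glen + 1L
    # candidate offsets come from exact word seeds (as in the main
    # search): a composite interval's true placement can carry many
    # mismatches over its foreign part, so a global mismatch scan would
    # rank it behind shifted chance placements
    w <- index$word
    cand_off <- integer(0)
    if (glen >= w) {
      qwords <- substring(qsub, 1:(glen - w + 1L), w:glen)
      seeds <- e$index[qwords]
      cand_off <- unique(unlist(lapply(seq_along(seeds), function(k) {
        if (is.null(seeds[[k]])) return(integer(0))
        seeds[[k]] - k + 1L
      })))
      cand_off <- sort(cand_off[cand_off >= 1L & cand_off <= noff])
    }
    if (length(cand_off) == 0) {
      # fallback for error-bearing short arms without an exact seed
      mism <- integer(noff)
      for (k in seq_len(glen))
        mism <- mism + (cc[k:(k + noff - 1L)] != qc[k])
      cand_off <- which(mism <= min(mism) + 2L)
      cand_off <- cand_off[order(mism[cand_off], cand_off)]
      if (length(cand_off) > 20L) cand_off <- cand_off[1:20]
    }
    off <- NA_integer_; rg <- NULL; mflag <- NULL
    best_key <- c(Inf, 0L)  # (mismatches asc, matched length desc)
    for (o in cand_off) {
      mf <- as.integer(qc == cc[o:(o + glen - 1L)])
      # rescue intervals cannot over-extend (they are bounded by the read
      # and by accepted hits), so a lighter 4-match anchor suffices here
      r <- anchor_trim_range(mf, 4L)
      if (is.null(r)) next
      rlen <- r[2] - r[1] + 1L
      alen <- sum(mf[r[1]:r[2]])
      # only placements that would be accepted compete; an exact placement
      # beats a longer one carrying mismatches (a shifted placement can
      # absorb foreign bases at the cost of a mismatch)
      if (rlen < min_word || alen / rlen < min_identity) next
      mmr <- rlen - alen
      if (mmr < best_key[1] ||
          (mmr == best_key[1] && alen > best_key[2])) {
        best_key <- c(mmr, alen); off <- o; rg <- r; mflag <- mf
      }
    }
    if (is.null(rg)) return(invisible())
    sub <- rg[1]:rg[2]
    nm <- sum(mflag[sub])
    ident <- nm / length(sub)
    if (length(sub) >= min_word && ident >= min_identity) {
      # map the qsub sub-interval back to fragment coordinates
      if (top$strand == "+") {
        rs <- lo + rg[1] - 1L; re <- lo + rg[2] - 1L
      } else {
        rs <- hi - rg[2] + 1L; re <- hi - rg[1] + 1L
      }
      mm <- length(sub) - nm
      new_hits[[length(new_hits) + 1L]] <<- list(
        read_start = rs, read_end = re, consensus_id = e$id,
        c_start = off + rg[1] - 1L, c_end = off + rg[2] - 1L,
        strand = top$strand,
        score = nm * params$match + mm * params$mismatch,
        n_match = nm, n_col = length(sub),
        identity = ident, evalue = NULL, rescued = TRUE)
      if (top$strand == "+") {
        rescue_interval(lo, rs - 1L)
        rescue_interval(re + 1L, hi)
      } else {
        rescue_interval(lo, rs - 1L)
        rescue_interval(re + 1L, hi)
      }
    }
    invisible()
  }
  for (g in gaps) rescue_interval(starts[g], ends[g])
  if (length(new_hits) == 0) return(hits)
  extra <- hits_df(new_hits, hits$read_id[1])
  out <- rbind(hits, extra)
  out[order(out$read_start, out$read_end), , drop = FALSE]
}

#' Chain read-adjacent hits into ordered segment structures
#'
#' Greedily builds maximal chains of hits adjacent on the read (gap
#' `<= max_read_gap`, overlap `<= max_read_overlap`) on one consensus and
#' strand; leftover hits form singleton chains. Chains are scored by summed
#' hit scores and the best-scoring chain is marked primary (ties broken by
#' read order).
#'
#' @param hits data frame of hits from one fragment.
#' @param max_read_gap,max_read_overlap adjacency tolerances in nt.
#' @return list of `SegmentChain`s: each a list with `hits` (data frame),
#'   `consensus_id`, `strand`, `score`, `primary`.
#' @export
chain_segments <- function(hits, max_read_gap = 10L, max_read_overlap = 10L) {
  if (nrow(hits) == 0) return(list())
  hits <- hits[order(hits$read_start, hits$read_end), , drop = FALSE]
  chains <- list()
  cur <- hits[1, , drop = FALSE]
  for (i in seq_len(nrow(hits))[-1]) {
    h <- hits[i, , drop = FALSE]
    last <- cur[nrow(cur), ]
    gap <- h$read_start - last$read_end - 1L
    ok <- h$consensus_id == last$consensus_id &&
      h$strand == last$strand &&
      gap <= max_read_gap && -gap <= max_read_overlap
    if (ok) {
      cur <- rbind(cur, h)
    } else {
      chains[[length(chains) + 1L]] <- cur
      cur <- h
    }
  }
  chains[[length(chains) + 1L]] <- cur
  scores <- vapply(chains, function(ch) sum(ch$score), 1)
  primary <- which.max(scores)
  lapply(seq_along(chains), function(i) {
    structure(list(hits = chains[[i]],
                   consensus_id = chains[[i]]$consensus_id[1],
                   strand = chains[[i]]$strand[1],
                   score = scores[i], primary = i == primary),
              class = "SegmentChain")
  })
}

#' @export
print.SegmentChain <- function(x, ...) {
  cat(sprintf("SegmentChain on %s (%s), %d segment(s), score %g%s\n",
              x$consensus_id, x$strand, nrow(x$hits), x$score,
              if (x$primary) " [primary]" else ""))
  print(x$hits, row.names = FALSE)
  invisible(x)
}

#' Write segment hits as TSV (1-based inclusive coordinates)
#' @param hits hit data frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
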