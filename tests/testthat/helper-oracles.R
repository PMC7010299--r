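# Independent oracles. The alignment oracle performs an exhaustive local
# scan with Biostrings::pairwiseAlignment (its own C implementation) under
# the same contract as the package's seeded search: accept the best local
# alignment of an interval if it passes the thresholds after anchor
# trimming, mask its read interval, recurse on the flanks.

# per-column view of a pairwiseAlignment result
pa_columns <- function(pa) {
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qi <- BiocGenerics::start(Biostrings::pattern(pa)) - 1L
  si <- BiocGenerics::start(Biostrings::subject(pa)) - 1L
  n <- length(p)
  qpos <- integer(n); spos <- integer(n)
  for (k in seq_len(n)) {
    if (p[k] != "-") { qi <- qi + 1L; qpos[k] <- qi }
    if (s[k] != "-") { si <- si + 1L; spos[k] <- si }
  }
  list(qpos = qpos, spos = spos,
       match_col = as.integer(p == s & p != "-"))
}

# anchor-trim rule, written out independently: keep from the first to the
# last run of >= trim_k consecutive matches
oracle_trim <- function(cols, trim_k = 6L) {
  ok <- cols$match_col == 1
  run <- 0L; first <- NA_integer_
  for (k in seq_along(ok)) {
    run <- if (ok[k]) run + 1L else 0L
    if (run == trim_k && is.na(first)) first <- k - trim_k + 1L
  }
  if (is.na(first)) return(NULL)
  run <- 0L; last <- NA_integer_
  for (k in rev(seq_along(ok))) {
    run <- if (ok[k]) run + 1L else 0L
    if (run == trim_k) { last <- k + trim_k - 1L; break }
  }
  idx <- first:last
  lapply(cols, `[`, idx)
}

oracle_col_score <- function(cols, params) {
  diag <- cols$qpos > 0 & cols$spos > 0
  sc <- sum(cols$match_col[diag]) * params$match +
    sum(diag & cols$match_col == 0) * params$mismatch
  gap <- !diag
  if (any(gap)) {
    r <- rle(gap)
    sc <- sc - sum(r$values) * params$gap_open - sum(gap) * params$gap_ext
  }
  sc
}

# exhaustive recursive scan; mirrors the align_fragment contract
oracle_align <- function(fragment, cons_list, min_word = 11L,
                         evalue_max = 1e-5, min_identity = 0.85,
                         trim_k = 6L, params = align_params()) {
  if (inherits(cons_list, "RepeatConsensus")) cons_list <- list(cons_list)
  ids <- vapply(cons_list, `[[`, "", "id")
  cons_list <- cons_list[order(ids)]
  mat <- Biostrings::nucleotideSubstitutionMatrix(params$match,
                                                  params$mismatch,
                                                  baseOnly = TRUE)
  m <- nchar(fragment)
  total_len <- sum(vapply(cons_list, function(x) nchar(x$sequence), 1))
  hits <- list()
  recurse <- function(qs, qe) {
    if (qe - qs + 1L < min_word) return(invisible())
    sub <- substr(fragment, qs, qe)
    ns <- nchar(sub)
    cands <- list()
    for (strand in c("+", "-")) {
      q <- if (strand == "+") sub else revcomp(sub)
      for (cons in cons_list) {
        pa <- Biostrings::pairwiseAlignment(
          q, cons$sequence, type = "local", substitutionMatrix = mat,
          gapOpening = params$gap_open, gapExtension = params$gap_ext)
        sc <- Biostrings::score(pa)
        if (sc <= 0) next
        cands[[length(cands) + 1L]] <- list(
          score = sc, pa = pa, strand = strand, id = cons$id,
          s_start = BiocGenerics::start(Biostrings::subject(pa)))
      }
    }
    if (length(cands) == 0) return(invisible())
    ord <- order(-vapply(cands, `[[`, 1, "score"),
                 vapply(cands, `[[`, "", "strand"),
                 vapply(cands, `[[`, "", "id"),
                 vapply(cands, function(x) as.numeric(x$s_start), 1))
    best <- cands[[ord[1]]]
    cols <- oracle_trim(pa_columns(best$pa), trim_k)
    if (is.null(cols)) return(invisible())
    score <- oracle_col_score(cols, params)
    nm <- sum(cols$match_col)
    nc <- length(cols$match_col)
    ev <- params$K * m * total_len * exp(-params$lambda * score)
    if (ev > evalue_max || nm / nc < min_identity) return(invisible())
    qv <- cols$qpos[cols$qpos > 0]; sv <- cols$spos[cols$spos > 0]
    q1 <- min(qv); q2 <- max(qv)
    if (best$strand == "+") {
      rs <- qs + q1 - 1L; re <- qs + q2 - 1L
    } else {
      rs <- qs + (ns - q2 + 1L) - 1L; re <- qs + (ns - q1 + 1L) - 1L
    }
    hits[[length(hits) + 1L]] <<- data.frame(
      read_start = rs, read_end = re, consensus_id = best$id,
      c_start = min(sv), c_end = max(sv), strand = best$strand,
      score = score, stringsAsFactors = FALSE)
    recurse(qs, rs - 1L)
    recurse(re + 1L, qe)
    invisible()
  }
  recurse(1L, m)
  if (length(hits) == 0) {
    return(data.frame(read_start = integer(0), read_end = integer(0),
                      consensus_id = character(0), c_start = integer(0),
                      c_end = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$read_start), , drop = FALSE]
}

# comparable view of align_fragment output
hit_view <- function(hits) {
  v <- hits[, c("read_start", "read_end", "consensus_id", "c_start",
                "c_end", "strand", "score")]
  v <- v[order(v$read_start), , drop = FALSE]
  rownames(v) <- NULL
  v$score <- as.numeric(v$score)
  v
}

# brute-force best-overlap oracle for pair merging: try every overlap
# length, score = matches - 2*mismatches, mismatch fraction capped
oracle_merge_len <- function(r1, r2, min_overlap = 15L,
                             max_mismatch_rate = 0.1) {
  r2rc <- revcomp(r2)
  n1 <- nchar(r1); n2 <- nchar(r2rc)
  best_score <- -Inf; best_s <- 0L
  for (s in seq(min(n1, n2), min_overlap)) {
    a <- substring(r1, n1 - s + 1L, n1)
    b <- substring(r2rc, 1L, s)
    mm <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (mm / s > max_mismatch_rate) next
    sc <- s - 3L * mm
    if (sc > best_score) { best_score <- sc; best_s <- s }
  }
  if (best_s == 0L) return(NA_integer_)
  n1 + n2 - best_s
}
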