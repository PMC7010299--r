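# Read preparation: FASTQ parsing and overlap-merging of paired-end reads
# into single fragments, mirroring a SeqPrep-style join with a quality
# floor of 30 and a minimum merged length of 25.

#' Read a FASTQ file
#'
#' @param path FASTQ path (gz-transparent).
#' @return list with `seq` and `qual`, both named character vectors.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  seqs <- stats::setNames(as.character(x), names(x))
  assert_dna(seqs, what = basename(path))
  list(seq = seqs,
       qual = stats::setNames(as.character(S4Vectors::mcols(x)$qualities),
                              names(x)))
}

#' Write sequences and qualities as FASTQ
#'
#' @param seq named character vector of sequences.
#' @param qual character vector of Sanger-encoded quality strings.
#' @param path output path (gz-transparent via extension).
#' @return invisibly, the path.
#' @export
write_fastq <- function(seq, qual, path) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- names(seq)
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(unname(qual)),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# trim trailing bases whose quality is below `floor` (3' quality trimming,
# applied before the overlap search)
trim3p <- function(seq, qual, floor) {
  q <- utf8ToInt(qual) - 33L
  keep <- length(q)
  while (keep > 0 && q[keep] < floor) keep <- keep - 1L
  list(seq = substr(seq, 1L, keep), qual = substr(qual, 1L, keep))
}

#' Merge overlapping paired-end reads into single fragments
#'
#' For each pair, reads are 3'-quality-trimmed at `qual_floor`, then the
#' best 3' overlap of R1 with the reverse complement of R2 is searched over
#' all overlap lengths `>= min_overlap`. A pair merges when the best-scoring
#' admissible overlap (score = matches - 2*mismatches, ties broken towards
#' the longest overlap) has mismatch fraction `<= max_mismatch_rate`.
#' Overlap bases take the higher-quality call. Merged products shorter than
#' `min_len` are discarded and the pair is carried forward unmerged.
#'
#' @param r1,r2 named character vectors of read sequences (paired, in
#'   order), or lists as returned by [read_fastq()].
#' @param q1,q2 quality strings (ignored when `r1`/`r2` are `read_fastq()`
#'   lists).
#' @param min_overlap minimum admissible overlap in nt.
#' @param max_mismatch_rate maximum mismatch fraction in the overlap.
#' @param qual_floor Phred floor for 3' trimming (the "-q 30" behaviour).
#' @param min_len minimum merged fragment length (the "-L 25" behaviour).
#' @return a `MergeResult` list: `fragments` (data frame: `id`, `sequence`,
#'   `qual`, `source` in MERGED/UNMERGED_R1/UNMERGED_R2), `n_pairs`,
#'   `n_merged`, `n_unmerged`.
#' @export
merge_pairs <- function(r1, r2, q1 = NULL, q2 = NULL, min_overlap = 15L,
                        max_mismatch_rate = 0.1, qual_floor = 30L,
                        min_len = 25L) {
  if (is.list(r1)) { q1 <- r1$qual; r1 <- r1$seq }
  if (is.list(r2)) { q2 <- r2$qual; r2 <- r2$seq }
  if (length(r1) != length(r2))
    stop("r1 and r2 have different numbers of reads (pairing error)",
         call. = FALSE)
  assert_dna(r1, "r1"); assert_dna(r2, "r2")
  if (is.null(q1)) q1 <- strrep("I", nchar(r1))
  if (is.null(q2)) q2 <- strrep("I", nchar(r2))
  if (min_overlap < 1) stop("min_overlap must be >= 1", call. = FALSE)
  n <- length(r1)
  ids <- names(r1)
  if (is.null(ids)) ids <- sprintf("pair_%06d", seq_len(n))
  merged_id <- character(0); merged_seq <- character(0)
  merged_qual <- character(0)
  un_idx <- integer(0)
  r2rc_all <- revcomp(r2)
  for (i in seq_len(n)) {
    t1 <- trim3p(r1[i], q1[i], qual_floor)
    t2 <- trim3p(r2[i], q2[i], qual_floor)
    s1 <- t1$seq
    s2rc <- if (nchar(t2$seq) == nchar(r2[i])) r2rc_all[i] else revcomp(t2$seq)
    q2rc <- paste(rev(chars(t2$qual)), collapse = "")
    n1 <- nchar(s1); n2 <- nchar(s2rc)
    if (n1 < min_overlap || n2 < min_overlap) { un_idx <- c(un_idx, i); next }
    c1 <- chars(s1); c2 <- chars(s2rc)
    best_score <- -Inf; best_s <- 0L; best_mm <- 0L
    for (s in seq(min(n1, n2), min_overlap)) {
      mm <- sum(c1[(n1 - s + 1L):n1] != c2[1:s])
      if (mm / s > max_mismatch_rate) next
      score <- s - 3L * mm  # (s - mm) matches at +1, mm mismatches at -2
      if (score > best_score) { best_score <- score; best_s <- s; best_mm <- mm }
    }
    if (best_s == 0L) { un_idx <- c(un_idx, i); next }
    s <- best_s
    qa <- utf8ToInt(t1$qual)
    qb <- utf8ToInt(q2rc)
    ov1 <- (n1 - s + 1L):n1
    take2 <- qb[1:s] > qa[ov1]
    ov_chars <- c1[ov1]; ov_chars[take2] <- c2[1:s][take2]
    ov_q <- pmax(qa[ov1], qb[1:s])
    mseq <- paste0(substr(s1, 1L, n1 - s), paste(ov_chars, collapse = ""),
                   substr(s2rc, s + 1L, n2))
    mq <- paste0(substr(t1$qual, 1L, n1 - s),
                 intToUtf8(ov_q, multiple = FALSE),
                 substr(q2rc, s + 1L, n2))
    if (nchar(mseq) < min_len) { un_idx <- c(un_idx, i); next }
    merged_id <- c(merged_id, ids[i])
    merged_seq <- c(merged_seq, mseq)
    merged_qual <- c(merged_qual, mq)
  }
  un_ids <- if (length(un_idx)) ids[un_idx] else character(0)
  tag <- function(x, suffix) if (length(x)) paste0(x, suffix) else character(0)
  frag <- data.frame(
    id = c(merged_id, tag(un_ids, "/1"), tag(un_ids, "/2")),
    sequence = c(merged_seq, unname(r1[un_idx]), unname(r2[un_idx])),
    qual = c(merged_qual, unname(q1[un_idx]), unname(q2[un_idx])),
    source = c(rep("MERGED", length(merged_id)),
               rep("UNMERGED_R1", length(un_idx)),
               rep("UNMERGED_R2", length(un_idx))),
    stringsAsFactors = FALSE)
  structure(list(fragments = frag, n_pairs = n,
                 n_merged = length(merged_id), n_unmerged = length(un_idx)),
            class = "MergeResult")
}

#' @export
print.MergeResult <- function(x, ...) {
  cat(sprintf("MergeResult: %d pairs -> %d merged + %d unmerged (%.1f%% merge rate)\n",
              x$n_pairs, x$n_merged, x$n_unmerged,
              if (x$n_pairs) 100 * x$n_merged / x$n_pairs else 0))
  invisible(x)
}
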