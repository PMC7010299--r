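# Synthetic genome construction: full-length and fragmented copies of the
# consensus element planted in i.i.d. background sequence, with optional
# per-copy substitution divergence. Used for the genomic-origin exclusion
# test: the genome never contains the fused back-splice sequence unless one
# is planted on purpose.

#' Plant consensus copies into a synthetic genome
#'
#' Inserts `n_full` full-length and `n_fragmented` partial copies of the
#' consensus (random sub-intervals, random strand, optional substitution
#' divergence) at non-overlapping positions in an i.i.d. A/C/G/T background.
#' Insertions replace background so the genome length stays `genome_len`.
#'
#' @param genome_len total genome length in nt.
#' @param consensus a `RepeatConsensus`.
#' @param n_full number of full-length copies.
#' @param n_fragmented number of fragmented copies.
#' @param seed integer seed.
#' @param divergence per-base substitution rate applied to each planted copy
#'   (default 0.02; the source study does not state a divergence among
#'   genomic copies, so this default is a documented guess).
#' @param min_fragment minimum fragmented-copy length.
#' @param extra_sequences optional named character vector of extra sequences
#'   to plant verbatim (used to plant an artificial fused junction copy).
#' @return a `PlantedGenome`: list with `sequence`, `id`, and `insertions`
#'   (data frame: `type`, `start`, `end`, `strand`, `cons_start`, `cons_end`),
#'   1-based inclusive.
#' @export
plant_elements <- function(genome_len, consensus, n_full, n_fragmented,
                           seed = 1L, divergence = 0.02,
                           min_fragment = 200L, extra_sequences = NULL) {
  L <- nchar(consensus$sequence)
  if (genome_len < n_full * L)
    stop("genome_len too small for the requested full-length copies",
         call. = FALSE)
  with_seed(seed, {
    frag_iv <- NULL
    if (n_fragmented > 0) {
      maxlen <- max(min_fragment, L - 1L)
      lens <- sample(seq(min(min_fragment, L - 1L), maxlen), n_fragmented,
                     replace = TRUE)
      starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L), 1L)
      frag_iv <- cbind(starts, starts + lens - 1L)
    }
    pieces <- c(
      rep(list(c(1L, L)), n_full),
      if (n_fragmented > 0) split(frag_iv, row(frag_iv)[, 1]) else NULL)
    types <- c(rep("full_element", n_full), rep("fragment", n_fragmented))
    seqs <- vapply(pieces, function(iv)
      substr(consensus$sequence, iv[1], iv[2]), character(1))
    cons_start <- vapply(pieces, `[`, 1L, 1)
    cons_end <- vapply(pieces, `[`, 1L, 2)
    if (!is.null(extra_sequences)) {
      seqs <- c(seqs, unname(extra_sequences))
      types <- c(types, names(extra_sequences))
      cons_start <- c(cons_start, rep(NA_integer_, length(extra_sequences)))
      cons_end <- c(cons_end, rep(NA_integer_, length(extra_sequences)))
    }
    n <- length(seqs)
    if (n == 0) {
      return(structure(list(id = "synth_genome",
                            sequence = random_dna(genome_len),
                            insertions = data.frame(
                              type = character(0), start = integer(0),
                              end = integer(0), strand = character(0),
                              cons_start = integer(0),
                              cons_end = integer(0))),
                       class = "PlantedGenome"))
    }
    strands <- sample(c("+", "-"), n, replace = TRUE)
    emitted <- ifelse(strands == "-", revcomp(seqs), seqs)
    if (divergence > 0)
      emitted <- vapply(emitted, mutate_seq, character(1), rate = divergence)
    total <- sum(nchar(emitted))
    free <- genome_len - total
    if (free < 0)
      stop("genome_len too small for the requested insertions", call. = FALSE)
    ord <- sample.int(n)
    emitted <- emitted[ord]; types <- types[ord]; strands <- strands[ord]
    cons_start <- cons_start[ord]; cons_end <- cons_end[ord]
    gaps <- as.vector(stats::rmultinom(1, free, rep(1, n + 1)))
    chunks <- character(2 * n + 1)
    starts <- integer(n); ends <- integer(n)
    pos <- 0L
    for (i in seq_len(n)) {
      chunks[2 * i - 1] <- random_dna(gaps[i])
      pos <- pos + gaps[i]
      starts[i] <- pos + 1L
      chunks[2 * i] <- emitted[i]
      pos <- pos + nchar(emitted[i])
      ends[i] <- pos
    }
    chunks[2 * n + 1] <- random_dna(gaps[n + 1])
    structure(list(
      id = "synth_genome",
      sequence = paste(chunks, collapse = ""),
      insertions = data.frame(type = types, start = starts, end = ends,
                              strand = strands,
                              cons_start = as.integer(cons_start),
                              cons_end = as.integer(cons_end),
                              stringsAsFactors = FALSE)),
      class = "PlantedGenome")
  })
}

#' @export
print.PlantedGenome <- function(x, ...) {
  cat(sprintf("PlantedGenome '%s': %d nt, %d insertions\n", x$id,
              nchar(x$sequence), nrow(x$insertions)))
  invisible(x)
}

#' Write a planted genome to FASTA + GFF3
#' @param genome a `PlantedGenome`.
#' @param fasta,gff output paths.
#' @return invisibly, the paths.
#' @export
write_genome <- function(genome, fasta, gff) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(genome$sequence, genome$id)),
    fasta)
  ins <- genome$insertions
  if (nrow(ins) > 0) {
    gr <- GenomicRanges::GRanges(
      seqnames = genome$id,
      ranges = IRanges::IRanges(ins$start, ins$end),
      strand = ins$strand, type = ins$type,
      cons_start = ins$cons_start, cons_end = ins$cons_end)
  } else {
    gr <- GenomicRanges::GRanges()
  }
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta = fasta, gff = gff))
}
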