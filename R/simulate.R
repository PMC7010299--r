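# Paired-end read simulation with full per-read provenance. Circular
# templates are sampled with uniform start position and wrap-around (a
# fragment is a substring of the doubled circle string), so a read crosses
# the back-splice junction exactly when its fragment spans the wrap point
# of the canonical rotation.

#' Does a placement on a circular template cross the wrap point?
#'
#' The canonical rotation starts at the acceptor, so the wrap point between
#' the last and first stored base is the back-splice junction.
#'
#' @param start 1-based fragment start on the canonical rotation.
#' @param frag_len fragment length.
#' @param circ_len circle length.
#' @return logical.
#' @export
crosses_wrap <- function(start, frag_len, circ_len) {
  (start + frag_len - 1L) > circ_len
}

#' Simulate paired-end reads from a transcript pool
#'
#' Templates are sampled by abundance (times a compartment enrichment factor
#' for RIP libraries). Fragments are drawn uniformly along each template
#' (with wrap-around for circles); R1 reads the fragment's 5' end, R2 the
#' reverse complement of its 3' end. Substitution errors are applied
#' uniformly at `err_rate`; qualities are constant Sanger-encoded values.
#' Linear templates shorter than `read_len` are skipped with a warning.
#'
#' @param transcripts a `TranscriptSet` (or data frame with columns `id`,
#'   `kind`, `strand`, `abundance`, `length`, `seq_plus`).
#' @param n_pairs number of read pairs to emit.
#' @param read_len read length (default 125, the RIP-seq read length).
#' @param insert_mean,insert_sd fragment-length distribution (normal,
#'   rounded, clamped to `[read_len, template length]`).
#' @param err_rate per-base substitution probability in `[0, 1)`.
#' @param compartment `"INPUT"`, `"RIP"` or `"DNA"` (a label recorded in the
#'   truth table; RIP applies `enrichment`).
#' @param enrichment named numeric vector of per-template over-sampling
#'   factors applied in the RIP compartment (default none).
#' @param seed integer seed; identical seeds and parameters give identical
#'   output.
#' @param qual constant Phred quality for every base.
#' @return a `SimReads` list: `r1`, `r2` (named character), `q1`, `q2`
#'   (quality strings), and `truth` (data frame: `read_id`, `template_id`,
#'   `start`, `insert`, `strand`, `compartment`, `crosses_junction`,
#'   `donor_arm`, `acceptor_arm`).
#' @export
simulate_reads <- function(transcripts, n_pairs,
                           read_len = 125L, insert_mean = 180,
                           insert_sd = 20, err_rate = 0,
                           compartment = c("INPUT", "RIP", "DNA"),
                           enrichment = NULL, seed = 1L, qual = 37L) {
  compartment <- match.arg(compartment)
  if (read_len < 1) stop("read_len must be >= 1", call. = FALSE)
  if (err_rate < 0 || err_rate >= 1)
    stop("err_rate must be in [0, 1)", call. = FALSE)
  tt <- as.data.frame(transcripts)
  w <- tt$abundance
  if (compartment == "RIP" && !is.null(enrichment)) {
    i <- match(names(enrichment), tt$id)
    if (anyNA(i)) stop("enrichment names not in transcript ids", call. = FALSE)
    w[i] <- w[i] * enrichment
  }
  # circles shorter than a read would wrap more than once; skipped as well
  short <- tt$length < read_len & w > 0
  if (any(short)) {
    warning(sprintf("skipping %d template(s) shorter than read_len: %s",
                    sum(short), paste(tt$id[short], collapse = ", ")))
    w[short] <- 0
  }
  if (all(w == 0)) stop("no template with positive weight", call. = FALSE)
  with_seed(seed, {
    idx <- sample.int(nrow(tt), n_pairs, replace = TRUE, prob = w)
    len <- tt$length[idx]
    ins <- as.integer(round(stats::rnorm(n_pairs, insert_mean, insert_sd)))
    ins <- pmax(read_len, pmin(ins, len))
    circ <- tt$kind[idx] == "CIRCULAR"
    start <- integer(n_pairs)
    start[circ] <- 1L + floor(stats::runif(sum(circ)) * len[circ])
    start[!circ] <- 1L + floor(stats::runif(sum(!circ)) *
                                 (len[!circ] - ins[!circ] + 1L))
    doubled <- stats::setNames(
      ifelse(tt$kind == "CIRCULAR",
             paste0(tt$seq_plus, tt$seq_plus), tt$seq_plus), tt$id)
    frag <- substr(doubled[idx], start, start + ins - 1L)
    minus <- tt$strand[idx] == "-"
    frag[minus] <- revcomp(frag[minus])
    r1 <- substr(frag, 1L, read_len)
    r2 <- revcomp(substr(frag, ins - read_len + 1L, ins))
    if (err_rate > 0) {
      r1 <- vapply(r1, mutate_seq, character(1), rate = err_rate,
                   USE.NAMES = FALSE)
      r2 <- vapply(r2, mutate_seq, character(1), rate = err_rate,
                   USE.NAMES = FALSE)
    }
    ids <- sprintf("%s_%06d", tolower(compartment), seq_len(n_pairs))
    names(r1) <- names(r2) <- ids
    crossing <- circ & crosses_wrap(start, ins, len)
    donor_arm <- ifelse(crossing, len - start + 1L, NA_integer_)
    acceptor_arm <- ifelse(crossing, ins - (len - start + 1L), NA_integer_)
    qs <- strrep(rawToChar(as.raw(qual + 33L)), read_len)
    truth <- data.frame(read_id = ids, template_id = tt$id[idx],
                        start = start, insert = ins,
                        strand = tt$strand[idx], compartment = compartment,
                        crosses_junction = crossing,
                        donor_arm = as.integer(donor_arm),
                        acceptor_arm = as.integer(acceptor_arm),
                        stringsAsFactors = FALSE)
    structure(list(r1 = r1, r2 = r2,
                   q1 = stats::setNames(rep(qs, n_pairs), ids),
                   q2 = stats::setNames(rep(qs, n_pairs), ids),
                   truth = truth),
              class = "SimReads")
  })
}

#' @export
print.SimReads <- function(x, ...) {
  cat(sprintf("SimReads: %d pairs (%s), %d junction-crossing\n",
              length(x$r1), x$truth$compartment[1],
              sum(x$truth$crosses_junction)))
  invisible(x)
}

#' Simulate single-end genomic DNA reads from a planted genome
#'
#' Error-free uniform single-end sampling used by the genomic-origin test;
#' provenance records each read's interval on the genome.
#'
#' @param genome a `PlantedGenome` (or any list with `sequence`).
#' @param n_reads number of reads.
#' @param read_len read length.
#' @param seed integer seed.
#' @param err_rate per-base substitution probability.
#' @return list `reads` (named character) and `truth` (data frame with
#'   `read_id`, `start`, `end`, `strand`).
#' @export
simulate_dna_reads <- function(genome, n_reads, read_len = 100L, seed = 1L,
                               err_rate = 0) {
  L <- nchar(genome$sequence)
  if (read_len > L) stop("read_len exceeds genome length", call. = FALSE)
  with_seed(seed, {
    start <- 1L + floor(stats::runif(n_reads) * (L - read_len + 1L))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    reads <- substr(rep(genome$sequence, n_reads), start,
                    start + read_len - 1L)
    reads[strand == "-"] <- revcomp(reads[strand == "-"])
    if (err_rate > 0)
      reads <- vapply(reads, mutate_seq, character(1), rate = err_rate,
                      USE.NAMES = FALSE)
    ids <- sprintf("dna_%06d", seq_len(n_reads))
    names(reads) <- ids
    list(reads = reads,
         truth = data.frame(read_id = ids, start = start,
                            end = start + read_len - 1L, strand = strand,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate per-feature library counts for enrichment recovery
#'
#' Draws multinomial read counts for an input and a RIP library from the
#' same base abundances, with RIP weights multiplied by per-feature
#' enrichment factors. This is the count-level view of the RIP experiment
#' used when full read emission would be needlessly heavy.
#'
#' @param abundance named numeric vector of base feature weights.
#' @param n_input,n_rip library sizes (total reads).
#' @param enrichment named numeric vector of RIP enrichment factors
#'   (features absent from it get factor 1).
#' @param seed integer seed.
#' @return data frame: `feature`, `input_count`, `rip_count` plus totals as
#'   attributes `n_input`, `n_rip`.
#' @export
simulate_library_counts <- function(abundance, n_input, n_rip,
                                    enrichment = NULL, seed = 1L) {
  stopifnot(!is.null(names(abundance)), all(abundance >= 0))
  wr <- abundance
  if (!is.null(enrichment)) {
    i <- match(names(enrichment), names(abundance))
    if (anyNA(i)) stop("enrichment names not in abundance", call. = FALSE)
    wr[i] <- wr[i] * enrichment
  }
  with_seed(seed, {
    ci <- as.vector(stats::rmultinom(1, n_input, abundance / sum(abundance)))
    cr <- as.vector(stats::rmultinom(1, n_rip, wr / sum(wr)))
    out <- data.frame(feature = names(abundance), input_count = ci,
                      rip_count = cr, stringsAsFactors = FALSE)
    attr(out, "n_input") <- n_input
    attr(out, "n_rip") <- n_rip
    out
  })
}

#' Write simulated reads as a FASTQ pair plus a JSON truth sidecar
#'
#' @param sim a `SimReads`.
#' @param r1_path,r2_path,truth_path output paths (FASTQ uncompressed or
#'   `.gz`; truth as JSON).
#' @return invisibly, the paths.
#' @export
write_sim_reads <- function(sim, r1_path, r2_path, truth_path = NULL) {
  write_fastq(sim$r1, sim$q1, r1_path)
  write_fastq(sim$r2, sim$q2, r2_path)
  if (!is.null(truth_path)) {
    jsonlite::write_json(sim$truth, truth_path, dataframe = "rows",
                         na = "null", digits = NA)
  }
  invisible(c(r1_path, r2_path, truth_path))
}
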