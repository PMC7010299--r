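# Synthetic repeat consensus: a CRM1-like centromeric retrotransposon whose
# internal "donor" region carries the 85/253/269-nt architecture that gives
# rise to the back-spliced circular RNAs. The two LTRs are identical copies,
# as in a real element, so LTR-derived reads are genuinely ambiguous.

#' Region-length parameters for a synthetic retrotransposon consensus
#'
#' Defaults emulate a CRM1-like element at reduced scale: two identical LTRs
#' flank gag/pol coding regions, followed by the back-splice donor region
#' made of three contiguous sub-regions of 85, 253 and 269 nt (607 nt total)
#' and a spacer standing in for the adjacent intergenic sequence.
#'
#' @param ltr length of each LTR (both copies are identical).
#' @param gag,pr,rt,rnh,int lengths of the internal coding regions.
#' @param region85,region253,region269 lengths of the three donor
#'   sub-regions, in 5'-to-3' order on the plus strand.
#' @param spacer length of the intergenic spacer after the donor region.
#' @return named integer vector of region lengths.
#' @export
consensus_params <- function(ltr = 450L, gag = 900L, pr = 300L, rt = 900L,
                             rnh = 300L, int = 600L,
                             region85 = 85L, region253 = 253L,
                             region269 = 269L, spacer = 200L) {
  p <- c(ltr = ltr, gag = gag, pr = pr, rt = rt, rnh = rnh, int = int,
         region85 = region85, region253 = region253, region269 = region269,
         spacer = spacer)
  if (any(p < 0)) stop("all region lengths must be >= 0", call. = FALSE)
  storage.mode(p) <- "integer"
  p
}

#' Build a synthetic repeat consensus element
#'
#' Generates an i.i.d.-random nucleotide sequence partitioned into labelled
#' regions (LTR5, GAG, PR, RT, RNH, INT, REGION85, REGION253, REGION269,
#' OTHER, LTR3). The 3' LTR is a verbatim copy of the 5' LTR. The three
#' donor sub-regions are disjoint, adjacent, and in 85/253/269 order on the
#' plus strand; zero-length regions are dropped from the annotation.
#'
#' @param seed integer seed; the same seed and parameters give the same
#'   element.
#' @param params region lengths from [consensus_params()].
#' @param id element identifier.
#' @return a `RepeatConsensus`: list with `id`, `sequence`, and a `regions`
#'   data frame (`label`, `start`, `end`, `strand`), 1-based inclusive.
#' @export
build_consensus <- function(seed = 1L, params = consensus_params(),
                            id = "CRM1like") {
  if (any(params < 0)) stop("all region lengths must be >= 0", call. = FALSE)
  with_seed(seed, {
    ltr_seq <- random_dna(params[["ltr"]])
    inner <- c("gag" = "GAG", "pr" = "PR", "rt" = "RT", "rnh" = "RNH",
               "int" = "INT", "region85" = "REGION85",
               "region253" = "REGION253", "region269" = "REGION269",
               "spacer" = "OTHER")
    pieces <- c(LTR5 = ltr_seq,
                vapply(names(inner), function(k) random_dna(params[[k]]),
                       character(1)),
                LTR3 = ltr_seq)
    labels <- c("LTR5", unname(inner), "LTR3")
    lens <- nchar(pieces)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    keep <- lens > 0L
    regions <- data.frame(label = labels[keep],
                          start = as.integer(starts[keep]),
                          end = as.integer(ends[keep]),
                          strand = "+",
                          stringsAsFactors = FALSE)
    structure(list(id = id,
                   sequence = paste(pieces, collapse = ""),
                   regions = regions),
              class = "RepeatConsensus")
  })
}

#' @export
print.RepeatConsensus <- function(x, ...) {
  cat(sprintf("RepeatConsensus '%s': %d nt, %d annotated regions\n",
              x$id, nchar(x$sequence), nrow(x$regions)))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Look up an annotated region of a consensus
#'
#' @param consensus a `RepeatConsensus`.
#' @param label region label, e.g. `"REGION85"`.
#' @return integer `c(start, end)`, 1-based inclusive.
#' @export
consensus_region <- function(consensus, label) {
  i <- match(label, consensus$regions$label)
  if (is.na(i)) stop(sprintf("no region labelled '%s'", label), call. = FALSE)
  c(start = consensus$regions$start[i], end = consensus$regions$end[i])
}

# extract the subsequence of a region
region_seq <- function(consensus, label) {
  r <- consensus_region(consensus, label)
  substr(consensus$sequence, r[1], r[2])
}

#' The canonical back-splice junction of a consensus element
#'
#' The junction fuses the 3' end of the most downstream donor sub-region
#' (the donor) to the 5' start of the most upstream one (the acceptor).
#'
#' @param consensus a `RepeatConsensus` carrying REGION85/REGION253/REGION269
#'   annotations (REGION253 may be absent for two-segment architectures).
#' @param strand strand of the circular RNA; coordinates stay on the plus
#'   consensus frame.
#' @return a `BackspliceJunction`-style list with `consensus_id`, `acceptor`,
#'   `donor`, `strand`.
#' @export
element_junction <- function(consensus, strand = "+") {
  acc <- consensus_region(consensus, "REGION85")[["start"]]
  don <- consensus_region(consensus, "REGION269")[["end"]]
  junction(consensus$id, acc, don, strand)
}

#' Construct a back-splice junction record
#'
#' @param consensus_id element identifier.
#' @param acceptor 5' start of the upstream (acceptor-side) segment.
#' @param donor 3' end of the downstream (donor-side) segment.
#' @param strand strand of the circular RNA.
#' @return a `BackspliceJunction` list.
#' @export
junction <- function(consensus_id, acceptor, donor, strand = "+") {
  stopifnot(acceptor < donor)
  structure(list(consensus_id = consensus_id,
                 acceptor = as.integer(acceptor),
                 donor = as.integer(donor),
                 strand = strand),
            class = "BackspliceJunction")
}

#' @export
print.BackspliceJunction <- function(x, ...) {
  cat(sprintf("BackspliceJunction %s:%d..%d (%s)%s\n", x$consensus_id,
              x$acceptor, x$donor, x$strand,
              if (!is.null(x$support)) sprintf(", support %d", x$support)
              else ""))
  invisible(x)
}

#' Write a consensus to FASTA + GFF3
#'
#' @param consensus a `RepeatConsensus`.
#' @param fasta,gff output paths.
#' @return invisibly, the paths.
#' @export
write_consensus <- function(consensus, fasta, gff) {
  seqs <- Biostrings::DNAStringSet(stats::setNames(consensus$sequence,
                                                   consensus$id))
  Biostrings::writeXStringSet(seqs, fasta)
  gr <- GenomicRanges::GRanges(
    seqnames = consensus$id,
    ranges = IRanges::IRanges(consensus$regions$start, consensus$regions$end),
    strand = consensus$regions$strand,
    type = "region",
    Name = consensus$regions$label)
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta = fasta, gff = gff))
}

#' Read a consensus from FASTA + GFF3
#'
#' @param fasta,gff paths written by [write_consensus()].
#' @return a `RepeatConsensus`.
#' @export
read_consensus <- function(fasta, gff) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  gr <- rtracklayer::import(gff, format = "gff3")
  id <- names(seqs)[1]
  regions <- data.frame(label = as.character(gr$Name),
                        start = BiocGenerics::start(gr),
                        end = BiocGenerics::end(gr),
                        strand = as.character(BiocGenerics::strand(gr)),
                        stringsAsFactors = FALSE)
  structure(list(id = id, sequence = as.character(seqs[[1]]),
                 regions = regions),
            class = "RepeatConsensus")
}
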