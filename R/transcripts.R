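# Transcript construction: linear RNAs are concatenations of consensus
# intervals; circular RNAs are stored in their canonical rotation, which
# starts at the acceptor (the 5' end of the most upstream retained segment)
# so the back-splice junction sits at the wrap point between the last and
# first base of the stored string.

#' Describe one transcript isoform
#'
#' @param id transcript identifier.
#' @param kind `"LINEAR"` or `"CIRCULAR"`.
#' @param segments list of `c(start, end)` consensus intervals, in transcript
#'   order; for circular isoforms the first segment must start at the
#'   acceptor and the last must end at the donor.
#' @param strand `"+"` or `"-"`; coordinates always refer to the plus frame.
#' @param abundance non-negative sampling weight.
#' @return an `IsoformSpec` list.
#' @export
isoform_spec <- function(id, kind = c("LINEAR", "CIRCULAR"), segments,
                         strand = "+", abundance = 1) {
  kind <- match.arg(kind)
  if (abundance < 0) stop("abundance must be >= 0", call. = FALSE)
  if (!is.list(segments)) segments <- list(segments)
  structure(list(id = id, kind = kind, segments = segments, strand = strand,
                 abundance = abundance),
            class = "IsoformSpec")
}

#' Default isoform set emulating the CRM1 system
#'
#' Circular isoforms sharing the element's single back-splice site:
#' the 354-nt circle (269+85 segments, both strands), the fully retained
#' 607-nt circle (sense strand only), and 277-296-nt partial-retention
#' variants keeping the first k nt of the 85-nt acceptor-side region
#' (k = 8, 17, 27; both strands).  Linear RNAs cover the same region:
#' RNA-85, RNA-269 and the forward-spliced RNA-85+269.  Circular
#' abundances are set 5-fold below linear ones: the study finds back-spliced
#' reads orders of magnitude rarer than nonspliced ones, but a desk-scale
#' generator needs circles frequent enough to test against.
#'
#' @param consensus a `RepeatConsensus` with REGION85/253/269 annotations.
#' @param circ_abundance,linear_abundance sampling weights.
#' @param partial_k retained acceptor-side lengths for the short variants.
#' @return list of `IsoformSpec`s.
#' @export
default_isoform_specs <- function(consensus, circ_abundance = 1,
                                  linear_abundance = 5,
                                  partial_k = c(8L, 17L, 27L)) {
  r85 <- consensus_region(consensus, "REGION85")
  r269 <- consensus_region(consensus, "REGION269")
  seg85 <- c(r85[["start"]], r85[["end"]])
  seg269 <- c(r269[["start"]], r269[["end"]])
  full <- c(r85[["start"]], r269[["end"]])
  specs <- list(
    isoform_spec("circ354_plus", "CIRCULAR", list(seg85, seg269), "+",
                 circ_abundance),
    isoform_spec("circ354_minus", "CIRCULAR", list(seg85, seg269), "-",
                 circ_abundance),
    isoform_spec("circ607_plus", "CIRCULAR", list(full), "+", circ_abundance))
  for (k in partial_k) {
    part <- c(r85[["start"]], r85[["start"]] + k - 1L)
    len <- k + (seg269[2] - seg269[1] + 1L)
    for (s in c("+", "-")) {
      specs[[length(specs) + 1L]] <- isoform_spec(
        sprintf("circ%d_%s", len, if (s == "+") "plus" else "minus"),
        "CIRCULAR", list(part, seg269), s, circ_abundance)
    }
  }
  specs <- c(specs, list(
    isoform_spec("RNA-85", "LINEAR", list(seg85), "+", linear_abundance),
    isoform_spec("RNA-269", "LINEAR", list(seg269), "+", linear_abundance),
    isoform_spec("RNA-85+269", "LINEAR", list(seg85, seg269), "+",
                 linear_abundance)))
  specs
}

#' Materialise transcript sequences from isoform specs
#'
#' Linear sequences are the concatenation of their segments; circular
#' sequences are stored in canonical rotation starting at the acceptor.
#' Sequences are kept on the plus consensus frame; the emitted RNA of a
#' minus-strand isoform is the reverse complement (`sequence` column).
#'
#' @param consensus a `RepeatConsensus`.
#' @param specs list of `IsoformSpec`s (default: [default_isoform_specs()]).
#' @return a `TranscriptSet`: data frame with columns `id`, `kind`, `strand`,
#'   `abundance`, `length`, `acceptor`, `donor` (NA for linear), `seq_plus`
#'   (plus-frame), `sequence` (emitted RNA); `segments` kept as an attribute.
#' @export
make_transcripts <- function(consensus, specs = default_isoform_specs(consensus)) {
  L <- nchar(consensus$sequence)
  rows <- lapply(specs, function(sp) {
    for (seg in sp$segments) {
      if (seg[1] < 1 || seg[2] > L || seg[1] > seg[2])
        stop(sprintf("segment [%d,%d] of '%s' outside consensus", seg[1],
                     seg[2], sp$id), call. = FALSE)
    }
    seq_plus <- paste(vapply(sp$segments, function(seg)
      substr(consensus$sequence, seg[1], seg[2]), character(1)),
      collapse = "")
    acc <- don <- NA_integer_
    if (sp$kind == "CIRCULAR") {
      acc <- sp$segments[[1]][1]
      don <- sp$segments[[length(sp$segments)]][2]
    }
    data.frame(id = sp$id, kind = sp$kind, strand = sp$strand,
               abundance = sp$abundance, length = nchar(seq_plus),
               acceptor = acc, donor = don,
               seq_plus = seq_plus,
               sequence = if (sp$strand == "-") revcomp(seq_plus) else seq_plus,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$id)) stop("duplicate transcript ids", call. = FALSE)
  attr(out, "segments") <- stats::setNames(lapply(specs, `[[`, "segments"),
                                           out$id)
  attr(out, "consensus_id") <- consensus$id
  class(out) <- c("TranscriptSet", "data.frame")
  out
}

#' @export
print.TranscriptSet <- function(x, ...) {
  cat(sprintf("TranscriptSet: %d transcripts on '%s'\n", nrow(x),
              attr(x, "consensus_id")))
  print(as.data.frame(x)[, c("id", "kind", "strand", "length", "abundance")],
        row.names = FALSE)
  invisible(x)
}
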