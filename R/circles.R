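# Junction clustering, circular isoform reconstruction, in-silico divergent
# PCR, the genomic-origin exclusion test, and junction-spanning target
# design.

#' Cluster per-read junction calls
#'
#' Calls agreeing in (acceptor, donor, strand) within `tolerance` nt merge
#' by single linkage; cluster coordinates are the support-weighted mode
#' (most frequent exact pair, ties to the smallest coordinates); support is
#' the member count. Clusters are sorted by support, descending.
#'
#' @param calls data frame from [call_junctions()].
#' @param tolerance coordinate slack in nt (0 = exact-match clustering).
#' @return data frame: `consensus_id`, `acceptor`, `donor`, `strand`,
#'   `support`, `read_ids` (comma-separated).
#' @export
cluster_junctions <- function(calls, tolerance = 0L) {
  empty <- data.frame(consensus_id = character(0), acceptor = integer(0),
                      donor = integer(0), strand = character(0),
                      support = integer(0), read_ids = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0) return(empty)
  out <- list()
  for (key in unique(paste(calls$consensus_id, calls$strand))) {
    grp <- calls[paste(calls$consensus_id, calls$strand) == key, ,
                 drop = FALSE]
    n <- nrow(grp)
    comp <- seq_len(n)  # union-find by repeated relabelling (n is small)
    if (tolerance >= 0 && n > 1) {
      for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
          if (abs(grp$acceptor[i] - grp$acceptor[j]) <= tolerance &&
              abs(grp$donor[i] - grp$donor[j]) <= tolerance) {
            comp[comp == comp[j]] <- comp[i]
          }
        }
      }
    }
    for (cid in unique(comp)) {
      mem <- grp[comp == cid, , drop = FALSE]
      keys <- paste(mem$acceptor, mem$donor)
      tab <- sort(table(keys), decreasing = TRUE)
      modal <- names(tab)[tab == tab[1]]
      pick <- sort(modal)[1]
      ad <- as.integer(strsplit(pick, " ", fixed = TRUE)[[1]])
      out[[length(out) + 1L]] <- data.frame(
        consensus_id = mem$consensus_id[1], acceptor = ad[1], donor = ad[2],
        strand = mem$strand[1], support = nrow(mem),
        read_ids = paste(mem$read_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(-res$support, res$acceptor, res$donor, res$strand), ,
      drop = FALSE]
}

#' Reconstruct circular isoforms at a junction
#'
#' Each retention pattern describes which internal intervals between the
#' acceptor and the donor are spliced out; the remaining intervals, read
#' from the acceptor, form the circle. Full retention gives a circle of
#' `donor - acceptor + 1` nt; skipping an interval removes its length;
#' keeping only the first k nt of the acceptor-side region is expressed by
#' skipping from `acceptor + k` through the end of the skipped interior.
#'
#' @param junction a `BackspliceJunction` (e.g. [element_junction()]) or a
#'   one-row cluster from [cluster_junctions()].
#' @param consensus a `RepeatConsensus`.
#' @param retention list of patterns; each pattern is a list of
#'   `c(start, end)` intervals to skip (an empty list = full retention).
#'   Default: the single full-retention pattern.
#' @param ids optional isoform ids (default circ<length>).
#' @return list of `CircularIsoform`s: `consensus_id`, `junction`,
#'   `segments`, `length`, `seq_plus` (canonical rotation, plus frame),
#'   `strand`.
#' @export
reconstruct_isoforms <- function(junction, consensus, retention = list(list()),
                                 ids = NULL) {
  acc <- junction$acceptor
  don <- junction$donor
  L <- nchar(consensus$sequence)
  stopifnot(acc >= 1, don <= L, acc < don)
  isos <- lapply(seq_along(retention), function(p) {
    skips <- retention[[p]]
    keep <- rep(TRUE, don - acc + 1L)
    for (iv in skips) {
      if (iv[1] < acc || iv[2] > don || iv[1] > iv[2])
        stop(sprintf("retention interval [%d,%d] outside [%d,%d]",
                     iv[1], iv[2], acc, don), call. = FALSE)
      keep[(iv[1]:iv[2]) - acc + 1L] <- FALSE
    }
    if (!keep[1] || !keep[length(keep)])
      stop("acceptor and donor bases must be retained", call. = FALSE)
    runs <- rle(keep)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    seg <- lapply(which(runs$values), function(i)
      c(acc + starts[i] - 1L, acc + ends[i] - 1L))
    seq_plus <- paste(vapply(seg, function(s)
      substr(consensus$sequence, s[1], s[2]), character(1)), collapse = "")
    structure(list(consensus_id = consensus$id,
                   junction = junction,
                   segments = seg,
                   length = nchar(seq_plus),
                   seq_plus = seq_plus,
                   strand = junction$strand %||% "+"),
              class = "CircularIsoform")
  })
  nm <- ids %||% vapply(isos, function(x) sprintf("circ%d", x$length), "")
  for (i in seq_along(isos)) isos[[i]]$id <- nm[i]
  isos
}

#' @export
print.CircularIsoform <- function(x, ...) {
  segs <- paste(vapply(x$segments, function(s)
    sprintf("%d..%d", s[1], s[2]), ""), collapse = " + ")
  cat(sprintf("CircularIsoform %s: %d nt (%s) on %s, junction %d..%d\n",
              x$id %||% "", x$length, x$strand, x$consensus_id,
              x$junction$acceptor, x$junction$donor))
  cat("  segments:", segs, "\n")
  invisible(x)
}

#' Rotate a circular sequence
#' @param x circle string.
#' @param k offset (the string starting at position k+1 comes first).
#' @return rotated string.
#' @export
rotate_circle <- function(x, k) {
  n <- nchar(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  paste0(substr(x, k + 1, n), substr(x, 1, k))
}

#' Lexicographically minimal rotation of a circle string
#'
#' Rotation-equivalent circles map to the same canonical form, which makes
#' circles comparable regardless of where they were linearized.
#'
#' @param x circle string.
#' @return canonical rotation.
#' @export
canonical_rotation <- function(x) {
  n <- nchar(x)
  if (n <= 1) return(x)
  rots <- vapply(0:(n - 1), function(k) rotate_circle(x, k), "")
  sort(rots)[1]
}

#' Circle sequence of an isoform in canonical (acceptor-first) rotation
#'
#' @param isoform a `CircularIsoform`.
#' @return the circle string, starting at the acceptor; minus-strand
#'   isoforms return the reverse complement of the plus-frame circle.
#' @export
circular_sequence <- function(isoform) {
  if (isoform$strand == "-") revcomp(isoform$seq_plus) else isoform$seq_plus
}

#' In-silico divergent PCR
#'
#' Searches the (doubled, for circles) template for a forward-primer site
#' followed by the reverse complement of the reverse primer within
#' `max_product` nt, in either primer orientation, and returns the shortest
#' product. Divergent primers give a product only on the circular template,
#' which is the circularity discriminator.
#'
#' @param template template sequence.
#' @param fwd_primer,rev_primer primer sequences (>= 15 nt, A/C/G/T).
#' @param circular is the template a circle?
#' @param max_product maximum product length (capped at the circle length).
#' @param max_mismatch allowed mismatches per primer site (default 0).
#' @return the amplicon string, or NULL when no productive orientation
#'   exists.
#' @export
divergent_pcr <- function(template, fwd_primer, rev_primer, circular = TRUE,
                          max_product = Inf, max_mismatch = 0L) {
  assert_dna(fwd_primer, "fwd_primer", allow_n = FALSE)
  assert_dna(rev_primer, "rev_primer", allow_n = FALSE)
  if (nchar(fwd_primer) < 15 || nchar(rev_primer) < 15)
    stop("primers must be >= 15 nt", call. = FALSE)
  L <- nchar(template)
  search <- if (circular) paste0(template, template) else template
  cap <- min(max_product, L)
  sites <- function(p) {
    m <- Biostrings::matchPattern(p, Biostrings::DNAString(search),
                                  max.mismatch = max_mismatch)
    BiocGenerics::start(m)
  }
  products <- character(0)
  for (orient in 1:2) {
    f <- if (orient == 1) fwd_primer else rev_primer
    r <- if (orient == 1) rev_primer else fwd_primer
    fpos <- sites(f)
    rpos <- sites(revcomp(r))
    if (circular) fpos <- fpos[fpos <= L]
    for (i in fpos) {
      ends <- rpos + nchar(r) - 1L
      ok <- rpos >= i & ends - i + 1L <= cap
      if (any(ok)) {
        j <- min(ends[ok])
        products <- c(products, substr(search, i, j))
      }
    }
  }
  if (length(products) == 0) return(NULL)
  products[order(nchar(products), products)][1]
}

#' Test a candidate junction for a genomic origin
#'
#' Builds the assumed junction DNA (`flank` nt upstream of the donor fused
#' to `flank` nt downstream of the acceptor; 177+177 mirrors the assumed
#' 354-bp DNA), locally aligns each DNA read (both orientations) to it, and
#' counts reads whose alignment covers the fusion point with at least
#' `min_overhang` matched nt on each side. If no genomic copy of the fused
#' sequence exists, only residual reads can cross the fusion, and the
#' verdict is NO_GENOMIC_COPY when the count is `<= max_residual`.
#'
#' @param junction a `BackspliceJunction`-style list.
#' @param consensus a `RepeatConsensus`.
#' @param dna_reads character vector of DNA reads.
#' @param flank flank length on each side of the fusion.
#' @param min_overhang matched nt required on each side.
#' @param max_residual tolerated junction-covering reads.
#' @param params scoring parameters.
#' @return a `GenomicOriginReport`: `assumed_junction_sequence`, `fusion_point`,
#'   `n_reads_checked`, `n_junction_covering`, `covering_ids`, `verdict`.
#' @export
genomic_origin_test <- function(junction, consensus, dna_reads, flank = 177L,
                                min_overhang = 10L, max_residual = 1L,
                                params = align_params()) {
  if (flank < min_overhang)
    stop("flank must be >= min_overhang", call. = FALSE)
  acc <- junction$acceptor; don <- junction$donor
  L <- nchar(consensus$sequence)
  if (don - flank + 1L < 1 || acc + flank - 1L > L)
    stop("flank exceeds available consensus sequence", call. = FALSE)
  template <- paste0(substr(consensus$sequence, don - flank + 1L, don),
                     substr(consensus$sequence, acc, acc + flank - 1L))
  fusion <- flank  # fusion sits between template positions flank, flank+1
  ids <- names(dna_reads) %||% sprintf("read_%06d", seq_along(dna_reads))
  covering <- character(0)
  for (i in seq_along(dna_reads)) {
    best <- NULL
    for (q in c(dna_reads[[i]], revcomp(dna_reads[[i]]))) {
      al <- .sw_align_cpp(q, template, params$match, params$mismatch,
                          params$gap_open, params$gap_ext)
      if (al$score > 0 && (is.null(best) || al$score > best$score)) best <- al
    }
    if (is.null(best)) next
    mcols <- best$spos[best$match_col == 1]
    if (sum(mcols <= fusion) >= min_overhang &&
        sum(mcols > fusion) >= min_overhang) {
      covering <- c(covering, ids[i])
    }
  }
  structure(list(
    junction = junction,
    assumed_junction_sequence = template,
    fusion_point = fusion,
    n_reads_checked = length(dna_reads),
    n_junction_covering = length(covering),
    covering_ids = covering,
    verdict = if (length(covering) <= max_residual) "NO_GENOMIC_COPY"
              else "GENOMIC_COPY_SUSPECTED"),
    class = "GenomicOriginReport")
}

#' @export
print.GenomicOriginReport <- function(x, ...) {
  cat(sprintf("GenomicOriginReport: %d/%d reads cover the fusion point -> %s\n",
              x$n_junction_covering, x$n_reads_checked, x$verdict))
  invisible(x)
}

#' Design a junction-spanning RNAi/probe target
#'
#' The target is the last `upstream_len` nt before the donor followed by
#' the entire acceptor-side region (the annotated region starting at the
#' acceptor), i.e. the sequence a junction-covering trigger must span.
#' With the CRM1 defaults this is 204 + 85 = 289 nt.
#'
#' @param junction a `BackspliceJunction`-style list.
#' @param consensus a `RepeatConsensus`.
#' @param upstream_len nt taken upstream of the donor (default 204).
#' @param acceptor_region_len length of the acceptor-side region; inferred
#'   from the annotation when a region starts at the acceptor.
#' @return the target sequence (character scalar).
#' @export
design_junction_target <- function(junction, consensus, upstream_len = 204L,
                                   acceptor_region_len = NULL) {
  if (upstream_len < 0) stop("upstream_len must be >= 0", call. = FALSE)
  acc <- junction$acceptor; don <- junction$donor
  if (don - upstream_len + 1L < 1)
    stop("upstream_len exceeds the donor-side sequence", call. = FALSE)
  if (is.null(acceptor_region_len)) {
    i <- which(consensus$regions$start == acc)
    if (length(i) == 0)
      stop("no annotated region starts at the acceptor; supply acceptor_region_len",
           call. = FALSE)
    acceptor_region_len <- consensus$regions$end[i[1]] - acc + 1L
  }
  paste0(substr(consensus$sequence, don - upstream_len + 1L, don),
         substr(consensus$sequence, acc, acc + acceptor_region_len - 1L))
}

#' Insert restriction sites (or any marker sequences) into a template
#'
#' Positions refer to the original template: `position` is the number of
#' original bases preceding the inserted site (0 = prepend). Edits are
#' applied right-to-left so earlier insertions do not shift later ones.
#'
#' @param template template sequence.
#' @param insertions list of `list(position =, site =)` entries (or a data
#'   frame with those columns).
#' @return the edited sequence; its length is the template length plus the
#'   summed site lengths.
#' @export
insert_restriction_sites <- function(template, insertions) {
  if (is.data.frame(insertions))
    insertions <- lapply(seq_len(nrow(insertions)), function(i)
      list(position = insertions$position[i], site = insertions$site[i]))
  if (length(insertions) == 0) return(template)
  pos <- vapply(insertions, function(x) as.integer(x$position), 1L)
  sites <- vapply(insertions, function(x) as.character(x$site), "")
  assert_dna(sites, "site", allow_n = FALSE)
  L <- nchar(template)
  if (any(pos < 0 | pos > L))
    stop("insertion position outside template", call. = FALSE)
  if (anyDuplicated(pos))
    stop("overlapping insertion positions (conflict)", call. = FALSE)
  ord <- order(pos, decreasing = TRUE)
  out <- template
  for (i in ord) {
    out <- paste0(substr(out, 1, pos[i]), sites[i],
                  substr(out, pos[i] + 1, nchar(out)))
  }
  out
}

#' Write isoforms as FASTA plus a JSON sidecar
#'
#' @param isoforms list of `CircularIsoform`s.
#' @param fasta,json output paths.
#' @return invisibly, the paths.
#' @export
write_isoforms <- function(isoforms, fasta, json) {
  seqs <- stats::setNames(
    vapply(isoforms, circular_sequence, ""),
    vapply(isoforms, function(x) x$id %||% sprintf("circ%d", x$length), ""))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta)
  meta <- lapply(isoforms, function(x) list(
    id = x$id, consensus_id = x$consensus_id, length = x$length,
    strand = x$strand,
    acceptor = x$junction$acceptor, donor = x$junction$donor,
    support = x$junction$support %||% NA,
    segments = lapply(x$segments, function(s) c(start = s[1], end = s[2]))))
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta, json))
}
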