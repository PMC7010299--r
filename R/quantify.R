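# Quantification: class-count tables (Table-1 style), RPM coverage tracks,
# RIP/input relative enrichment, fold-coverage arithmetic, and 3C-qPCR
# normalized interaction frequencies.

#' Tabulate read classes per consensus family
#'
#' @param classifications data frame from [classify_fragments()].
#' @param total_fragments total merged fragments in the library (the
#'   normalization denominator reported alongside the counts).
#' @return a `ClassCountTable`: data frame of counts with one row per
#'   (consensus family x category), plus `total_fragments` attribute.
#' @export
tabulate_classes <- function(classifications, total_fragments = nrow(classifications)) {
  if (nrow(classifications) == 0) {
    return(structure(
      data.frame(consensus_id = character(0),
                 category = character(0), n = integer(0)),
      total_fragments = total_fragments,
      class = c("ClassCountTable", "data.frame")))
  }
  fam <- ifelse(is.na(classifications$consensus_id), "(none)",
                classifications$consensus_id)
  tab <- as.data.frame(table(consensus_id = fam,
                             category = factor(classifications$category,
                                               levels = CATEGORIES)),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab <- tab[order(tab$consensus_id, tab$category), , drop = FALSE]
  structure(tab, total_fragments = total_fragments,
            class = c("ClassCountTable", "data.frame"))
}

#' @export
print.ClassCountTable <- function(x, ...) {
  cat(sprintf("ClassCountTable (total merged fragments: %s)\n",
              format(attr(x, "total_fragments"), big.mark = ",")))
  print(as.data.frame(x)[x$n > 0 | x$category %in%
                           c("NONSPLICED", "BACK_SPLICED"), ],
        row.names = FALSE)
  invisible(x)
}

#' Reads-per-million coverage track
#'
#' Bins read placements by start position and scales counts to reads per
#' million: `1e6 * reads_in_bin / library_total`. Placements with mapping
#' quality below `mapq_min` are excluded (uniquely mapped reads only).
#'
#' @param placements data frame with columns `pos` (1-based start) and
#'   optionally `mapq` (assumed passing when absent).
#' @param bin_size bin width in nt.
#' @param library_total total reads in the library (> 0).
#' @param mapq_min minimum mapping quality.
#' @param region_len track length (default: last placement's bin).
#' @return data frame: `start`, `end`, `rpm` (one row per bin).
#' @export
rpm_track <- function(placements, bin_size, library_total, mapq_min = 20,
                      region_len = NULL) {
  if (library_total <= 0)
    stop("library_total must be > 0 (division error)", call. = FALSE)
  keep <- placements
  if ("mapq" %in% names(placements))
    keep <- placements[placements$mapq >= mapq_min, , drop = FALSE]
  if (is.null(region_len))
    region_len <- if (nrow(keep)) max(keep$pos) else bin_size
  n_bins <- ceiling(region_len / bin_size)
  bin <- pmin(((keep$pos - 1L) %/% bin_size) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  data.frame(start = (seq_len(n_bins) - 1L) * bin_size + 1L,
             end = pmin(seq_len(n_bins) * bin_size, region_len),
             rpm = 1e6 * counts / library_total)
}

#' Write an RPM track as BedGraph
#' @param track data frame from [rpm_track()].
#' @param path output path.
#' @param seqname chromosome/contig name.
#' @return invisibly, the path.
#' @export
write_bedgraph <- function(track, path, seqname = "consensus") {
  # BedGraph is 0-based half-open on disk
  lines <- sprintf("%s\t%d\t%d\t%g", seqname, track$start - 1L, track$end,
                   track$rpm)
  writeLines(c("track type=bedGraph", lines), path)
  invisible(path)
}

#' RIP/input relative enrichment of a feature
#'
#' The ratio of library proportions, pseudocount-adjusted on the counts:
#' `((rip_count + p) / rip_total) / ((input_count + p) / input_total)`.
#'
#' @param rip_count,input_count feature read counts (vectorized).
#' @param rip_total,input_total library totals (> 0).
#' @param pseudocount added to each count (default 1).
#' @return numeric enrichment ratio(s); 1 when proportions match.
#' @export
relative_enrichment <- function(rip_count, rip_total, input_count,
                                input_total, pseudocount = 1) {
  if (any(rip_count < 0) || any(input_count < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (rip_total <= 0 || input_total <= 0)
    stop("library totals must be > 0", call. = FALSE)
  ((rip_count + pseudocount) / rip_total) /
    ((input_count + pseudocount) / input_total)
}

#' Fold coverage of a region
#'
#' Total sequenced bases divided by the region size. (Read counts alone
#' would give reads/nt; the 140-900x centromere coverages only make sense
#' at base level, so the base-level reading is the default and
#' `reads * read_len` is the caller's responsibility.)
#'
#' @param total_read_bases summed read bases mapped to the region.
#' @param region_size region size in nt (> 0).
#' @return fold coverage.
#' @export
coverage_estimate <- function(total_read_bases, region_size) {
  if (region_size <= 0)
    stop("region_size must be > 0 (division error)", call. = FALSE)
  total_read_bases / region_size
}

#' 3C-qPCR relative interaction frequency
#'
#' Double normalization of quantification cycles: the target amplicon is
#' normalized to a reference amplicon within each sample, and the sample
#' ratio is normalized to the same ratio measured on the randomized-ligation
#' control template (digested + ligated BAC), i.e.
#' `(E^-ct_target_sample / E^-ct_ref_sample) /
#'  (E^-ct_target_control / E^-ct_ref_control)`.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_control,ct_ref_control
#'   quantification cycles (all > 0).
#' @param E amplification efficiency in (1, 2]; 2 = perfect doubling.
#' @return relative interaction frequency.
#' @export
normalize_3c <- function(ct_target_sample, ct_ref_sample, ct_target_control,
                         ct_ref_control, E = 2) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_control,
           ct_ref_control)
  if (anyNA(cts) || length(cts) != 4)
    stop("all four Ct values are required", call. = FALSE)
  if (any(cts <= 0)) stop("Ct values must be > 0", call. = FALSE)
  if (E <= 1 || E > 2)
    stop("amplification efficiency E must be in (1, 2]", call. = FALSE)
  (E^(-ct_target_sample) / E^(-ct_ref_sample)) /
    (E^(-ct_target_control) / E^(-ct_ref_control))
}

#' Read a Ct table from CSV
#'
#' Expected columns: `amplicon`, `sample`, `ct`, and optionally
#' `efficiency`.
#' @param path CSV path.
#' @return data frame.
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("amplicon", "sample", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(ct$efficiency)) ct$efficiency <- 2
  ct
}
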