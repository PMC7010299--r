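# Pipeline orchestration: one parameter object holding every stage
# threshold, and a deterministic runner that executes
# merge -> align -> classify -> call-circles -> check-genome -> quantify
# and writes a run manifest (parameters, seed, checksums) so a rerun with
# the same configuration is byte-identical.

PARAM_DEFAULTS <- list(
  qual_floor = 30, min_merged_len = 25, min_overlap = 15,
  max_mismatch_rate = 0.1, evalue_max = 1e-5, min_word = 11,
  min_identity = 0.85, max_read_gap = 10, max_read_overlap = 10,
  min_ltr_overlap = 20, junction_tolerance = 0, flank = 177,
  min_overhang = 10, max_residual = 1, mapq_min = 20, pseudocount = 1,
  E = 2, seed = 1)

#' Pipeline parameters
#'
#' All stage thresholds with their defaults: the quality floor 30 and
#' minimum merged length 25 of the joining step, the e-value ceiling 1e-5
#' of the consensus search, MAPQ 20 for track filtering, and the declared
#' defaults of every other stage. Unknown names are rejected.
#'
#' @param ... name = value overrides of the defaults.
#' @return a validated `PipelineParams` list.
#' @export
retrocirc_params <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(PARAM_DEFAULTS))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p <- utils::modifyList(PARAM_DEFAULTS, over)
  stopifnot(p$qual_floor >= 0, p$min_merged_len >= 1, p$min_overlap >= 1,
            p$max_mismatch_rate >= 0, p$max_mismatch_rate < 1,
            p$evalue_max > 0, p$min_word >= 4, p$min_identity > 0,
            p$min_identity <= 1, p$max_read_gap >= 0,
            p$max_read_overlap >= 0, p$min_ltr_overlap >= 1,
            p$junction_tolerance >= 0, p$flank >= p$min_overhang,
            p$min_overhang >= 1, p$max_residual >= 0, p$mapq_min >= 0,
            p$pseudocount >= 0, p$E > 1, p$E <= 2)
  structure(p, class = "PipelineParams")
}

#' Read a key-value configuration file
#'
#' One `key: value` pair per line (DCF); numeric-looking values are
#' converted.
#' @param path configuration file.
#' @return named list.
#' @export
read_config <- function(path) {
  raw <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  lapply(raw, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
}

#' Run the full detection pipeline
#'
#' Stages run in order: pair merging, consensus alignment (with anchor
#' rescue and chaining), read classification, junction calling and
#' clustering, genomic-origin checking (when DNA reads are supplied), and
#' quantification. Every output is written under `out_dir` together with a
#' `manifest.json` recording parameters, seed and MD5 checksums.
#'
#' @param consensus a `RepeatConsensus` (or list of them).
#' @param r1,r2 read pairs: named character vectors, `read_fastq()` lists,
#'   or FASTQ paths.
#' @param out_dir output directory (created).
#' @param params a `PipelineParams`.
#' @param dna_reads optional character vector (or FASTA/FASTQ path) of
#'   genomic DNA reads for the origin test.
#' @param library_total denominator for the class table (default: number of
#'   fragments).
#' @return invisibly, a list with `classifications`, `junctions`,
#'   `clusters`, `isoforms`, `origin_reports`, `class_table`, `manifest`.
#' @export
run_pipeline <- function(consensus, r1, r2, out_dir,
                         params = retrocirc_params(), dna_reads = NULL,
                         library_total = NULL) {
  stopifnot(inherits(params, "PipelineParams"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(r1) && length(r1) == 1 && file.exists(r1))
    r1 <- read_fastq(r1)
  if (is.character(r2) && length(r2) == 1 && file.exists(r2))
    r2 <- read_fastq(r2)
  if (is.character(dna_reads) && length(dna_reads) == 1 &&
      file.exists(dna_reads))
    dna_reads <- read_fastq(dna_reads)$seq

  merged <- merge_pairs(r1, r2, min_overlap = params$min_overlap,
                        max_mismatch_rate = params$max_mismatch_rate,
                        qual_floor = params$qual_floor,
                        min_len = params$min_merged_len)
  frag <- merged$fragments
  utils::write.table(frag[, c("id", "source")],
                     file.path(out_dir, "fragments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cons_list <- if (inherits(consensus, "RepeatConsensus")) list(consensus)
               else consensus
  index <- consensus_index(cons_list, word = params$min_word)
  cls <- classify_fragments(frag, index,
                            consensus = cons_list[[1]],
                            min_word = params$min_word,
                            evalue_max = params$evalue_max,
                            min_identity = params$min_identity,
                            max_read_gap = params$max_read_gap,
                            max_read_overlap = params$max_read_overlap,
                            min_ltr_overlap = params$min_ltr_overlap)
  write_classifications(cls, file.path(out_dir, "classifications.tsv"))
  hits <- attr(cls, "hits")
  if (!is.null(hits)) write_hits(hits, file.path(out_dir, "hits.tsv"))

  calls <- call_junctions(cls, cons_list[[1]])
  clusters <- cluster_junctions(calls, tolerance = params$junction_tolerance)
  utils::write.table(clusters, file.path(out_dir, "junctions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  isoforms <- list()
  origin_reports <- list()
  if (nrow(clusters) > 0) {
    for (i in seq_len(nrow(clusters))) {
      jx <- junction(clusters$consensus_id[i], clusters$acceptor[i],
                     clusters$donor[i], clusters$strand[i])
      jx$support <- clusters$support[i]
      isoforms <- c(isoforms, reconstruct_isoforms(jx, cons_list[[1]]))
      if (!is.null(dna_reads)) {
        flank <- min(params$flank, jx$donor,
                     nchar(cons_list[[1]]$sequence) - jx$acceptor + 1L)
        origin_reports[[length(origin_reports) + 1L]] <-
          genomic_origin_test(jx, cons_list[[1]], dna_reads, flank = flank,
                              min_overhang = params$min_overhang,
                              max_residual = params$max_residual)
      }
    }
    write_isoforms(isoforms, file.path(out_dir, "isoforms.fasta"),
                   file.path(out_dir, "isoforms.json"))
  }
  if (length(origin_reports)) {
    or <- data.frame(
      acceptor = vapply(origin_reports, function(x) x$junction$acceptor, 1L),
      donor = vapply(origin_reports, function(x) x$junction$donor, 1L),
      n_reads_checked = vapply(origin_reports, `[[`, 1L, "n_reads_checked"),
      n_junction_covering = vapply(origin_reports, `[[`, 1L,
                                   "n_junction_covering"),
      verdict = vapply(origin_reports, `[[`, "", "verdict"))
    utils::write.table(or, file.path(out_dir, "genomic_origin.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  tab <- tabulate_classes(cls, library_total %||% nrow(frag))
  utils::write.table(as.data.frame(tab),
                     file.path(out_dir, "class_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "retrocirc",
    version = as.character(utils::packageVersion("retrocirc")),
    params = unclass(params),
    n_pairs = merged$n_pairs, n_merged = merged$n_merged,
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(classifications = cls, junctions = calls,
                 clusters = clusters, isoforms = isoforms,
                 origin_reports = origin_reports, class_table = tab,
                 manifest = manifest))
}
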