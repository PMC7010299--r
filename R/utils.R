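# Shared low-level helpers. Sequences are plain upper-case character strings
# internally; Biostrings is used at the I/O boundary and for reverse
# complements. All coordinates are 1-based inclusive.

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# run `code` under a temporary RNG state seeded with `seed`; restores the
# caller's stream so generators do not perturb user code
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# i.i.d. uniform A/C/G/T background sequence (the simplest null composition)
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# apply uniform substitutions at rate `rate`; substituted base is drawn
# uniformly from the three alternatives
mutate_seq <- function(x, rate) {
  if (rate <= 0 || nchar(x) == 0) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    alt <- c("A", "C", "G", "T")
    for (i in hit) {
      choices <- alt[alt != chars[i]]
      chars[i] <- choices[sample.int(3L, 1L)]
    }
  }
  paste(chars, collapse = "")
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains non-%s characters", what,
                 if (allow_n) "ACGTN" else "ACGT"), call. = FALSE)
  }
  invisible(x)
}
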