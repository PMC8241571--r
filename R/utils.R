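#' Reverse complement of a nucleotide string
#'
#' Vectorised over its input. Ambiguity codes other than N are not handled;
#' N maps to N.
#'
#' @param x Character vector of nucleotide sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random nucleotide sequence
#'
#' Uniform i.i.d. bases, deterministic for a fixed seed. Used throughout the
#' synthetic-data generators.
#'
#' @param length Sequence length in bases.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param gc Target GC fraction in (0, 1); bases are drawn with
#'   P(G) = P(C) = gc/2.
#' @return A single nucleotide string.
#' @export
random_dna <- function(length, seed = NULL, gc = 0.5) {
  stopifnot(length >= 1, gc > 0, gc < 1)
  draw <- function() {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(probs), length, replace = TRUE, prob = probs),
          collapse = "")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' GC content of nucleotide strings
#'
#' Computed over non-N bases only; returns NA for sequences that are all N.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Numeric vector of GC fractions in \[0, 1\].
#' @export
gc_content <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    chars <- chars[chars != "N"]
    if (length(chars) == 0) return(NA_real_)
    mean(chars %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

# split a sequence into a character vector of single bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
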