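#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rexp rbinom rlnorm cor lm coef approx
#'   wilcox.test dhyper dnorm complete.cases setNames quantile median
#' @importFrom utils read.delim write.table head tail
#' @importFrom methods is
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

# Normalize a transcript sequence source to a named character vector of
# upper-case sequences. Accepts a named character vector, a DNAStringSet,
# or a path to a FASTA file.
as_sequence_set <- function(sequences) {
  if (is.character(sequences) && length(sequences) == 1L &&
      is.null(names(sequences)) && file.exists(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
  }
  if (methods::is(sequences, "XStringSet")) {
    out <- as.character(sequences)
    names(out) <- sub("\\s.*$", "", names(sequences))
    return(toupper(out))
  }
  if (!is.character(sequences) || is.null(names(sequences))) {
    stop2("`sequences` must be a named character vector, DNAStringSet, or FASTA path")
  }
  toupper(sequences)
}

BASES <- c("A", "C", "G", "T")

# Integer base codes (A=1, C=2, G=3, T=4, other=NA) for one sequence string.
base_codes <- function(seq) {
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("T")] <- 4L
  cp <- utf8ToInt(seq)
  cp[cp > 128L] <- 128L
  lut[cp]
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
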