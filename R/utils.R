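#' Reverse complement of DNA sequences
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T}`.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("AGTCCCGGCTGGCGAAT")
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_dna <- function(x) grepl("^[ACGT]+$", x)

#' @keywords internal
stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

# valid feature classes of the mitochondrial annotation
FEATURE_TYPES <- c("tRNA", "rRNA", "mRNA", "D-loop", "origin")

# the five-treatment anoxia/recovery design and the four embryonic stages
TREATMENTS <- c("t0", "EA", "LA", "ER", "LR")
STAGES <- c("D2", "WS36", "WS40", "WS42")
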