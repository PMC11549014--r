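#' 4-mer tokenization of haplotype sequences
#'
#' Haplotype sequences are represented as 4-mer tokens: each consecutive,
#' non-overlapping block of 4 bases maps to one of 256 vocabulary ids under a
#' fixed big-endian base order (A=0, C=1, G=2, T=3), so e.g. "ACGT" has id
#' 0*64 + 1*16 + 2*4 + 3 = 27. Tokenization and detokenization are exact
#' inverses over all 256 4-mers.
#'
#' @param seq A character scalar of A/C/G/T bases whose length is a multiple
#'   of 4 (or a `DNAString`).
#' @return `tokenize()`: an integer vector of token ids in `[0, 255]`.
#' @examples
#' tokenize("ACGTAAAA")
#' detokenize(c(27L, 0L))
#' @export
tokenize <- function(seq) {
  seq <- as.character(seq)
  stopifnot(length(seq) == 1L)
  n <- nchar(seq)
  if (n %% 4L != 0L)
    stop("sequence length (", n, ") is not a multiple of the k-mer size 4")
  if (n == 0L) return(integer(0))
  codes <- .base_codes(seq)
  if (anyNA(codes))
    stop("sequence contains bases outside {A,C,G,T}; targets must be unambiguous")
  m <- matrix(codes, nrow = 4L)
  as.integer(64L * m[1L, ] + 16L * m[2L, ] + 4L * m[3L, ] + m[4L, ])
}

#' @rdname tokenize
#' @param ids Integer vector of token ids in `[0, 255]`.
#' @return `detokenize()`: the base sequence as a character scalar.
#' @export
detokenize <- function(ids) {
  if (length(ids) == 0L) return("")
  ids <- as.integer(ids)
  if (anyNA(ids) || any(ids < 0L) || any(ids > 255L))
    stop("token ids must be integers in [0, 255]")
  b1 <- ids %/% 64L
  b2 <- (ids %/% 16L) %% 4L
  b3 <- (ids %/% 4L) %% 4L
  b4 <- ids %% 4L
  bases <- c("A", "C", "G", "T")
  paste(bases[rbind(b1, b2, b3, b4) + 1L], collapse = "")
}

## integer codes A=0 C=1 G=2 T=3; NA for anything else
.base_codes <- function(seq) {
  x <- utf8ToInt(seq)
  codes <- rep(NA_integer_, length(x))
  codes[x == 65L | x == 97L]  <- 0L  # A
  codes[x == 67L | x == 99L]  <- 1L  # C
  codes[x == 71L | x == 103L] <- 2L  # G
  codes[x == 84L | x == 116L] <- 3L  # T
  codes
}

#' Structural constants of the model vocabulary
#'
#' @return A named list with `kmer_size` (4), `vocab_size` (256),
#'   `max_output_tokens` (37) and `max_output_bases` (148).
#' @export
vocabConstants <- function() {
  list(kmer_size = 4L, vocab_size = 256L,
       max_output_tokens = 37L, max_output_bases = 148L)
}
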