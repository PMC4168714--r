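# Shared internal helpers: alphabet handling and seeded evaluation.

# profile rows / target letters
RNA_LETTERS <- c("A", "C", "G", "U", "X")
PROFILE_LETTERS <- c("A", "C", "G", "U", "X", "-")

# canonical base pairs (both orders)
CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Normalize a nucleotide string to the search alphabet
#'
#' Uppercases, maps T to U and any character outside `{A,C,G,U,-,.}` to X;
#' both `.` and `-` become the gap character `-`.
#' @param x character vector of sequences
#' @param allow_gap keep gap characters (alignments) or treat them as X
#'   (plain target sequences should not contain gaps)
#' @return character vector over `{A,C,G,U,X,-}`
#' @keywords internal
normalize_seq <- function(x, allow_gap = TRUE) {
  x <- toupper(x)
  x <- gsub("T", "U", x, fixed = TRUE)
  x <- gsub("\\.", "-", x)
  x <- gsub("[^ACGU-]", "X", x)
  if (!allow_gap) x <- gsub("-", "X", x, fixed = TRUE)
  x
}

# split into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# encode a normalized gapless sequence as integers 1..5 (A,C,G,U,X)
encode_target <- function(x) {
  ch <- seq_chars(normalize_seq(x, allow_gap = FALSE))
  code <- match(ch, RNA_LETTERS)
  code[is.na(code)] <- 5L
  code
}

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
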