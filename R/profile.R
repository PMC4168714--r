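# Compile a family alignment into the search profile: per-column frequency
# vectors over {A,C,G,U,X,-}, per-column pairedness flags (0 = paired,
# 1 = unpaired), and the retained consensus pair table.

#' Build a search profile from a family alignment
#'
#' Columns formed by a majority of gaps (gap fraction strictly greater than
#' `gap_exclusion_fraction`) are excluded.  Pairedness comes from the
#' consensus structure restricted to retained columns; a consensus pair with
#' exactly one excluded end is demoted to unpaired at the surviving end, so
#' the pair table only ever references columns that both survived.
#'
#' @param aln a `stockholm_aln` object (see [read_stockholm()])
#' @param gap_exclusion_fraction columns with gap fraction strictly above
#'   this are dropped (default 0.5; must be in \[0.5, 1\])
#' @param pseudocount optional Laplace pseudocount added to every letter
#'   count before normalization (default 0, i.e. plain frequencies)
#' @return an `rna_profile` object: list with `n` (number of retained
#'   columns), `p` (n x 6 frequency matrix, columns A,C,G,U,X,-), `s`
#'   (integer pairedness flags, 0 = paired), `pair_table` (1-based partner
#'   indices over retained columns, 0 = unpaired), `source_column_map`
#'   (retained index -> original alignment column) and `id`
#' @export
build_profile <- function(aln, gap_exclusion_fraction = 0.5, pseudocount = 0) {
  stopifnot(inherits(aln, "stockholm_aln"))
  if (gap_exclusion_fraction < 0.5 || gap_exclusion_fraction > 1) {
    stop("gap_exclusion_fraction must be in [0.5, 1]")
  }
  chars <- do.call(rbind, lapply(aln$records, seq_chars))
  L <- ncol(chars)
  nrec <- nrow(chars)
  counts <- vapply(PROFILE_LETTERS, function(l) colSums(chars == l),
                   numeric(L))
  if (L == 1) counts <- matrix(counts, nrow = 1,
                               dimnames = list(NULL, PROFILE_LETTERS))
  gap_frac <- counts[, "-"] / nrec
  keep <- gap_frac <= gap_exclusion_fraction
  if (!any(keep)) stop("profile empty: all columns exceed the gap threshold")
  freq <- (counts + pseudocount) / (nrec + 6 * pseudocount)

  partner_orig <- parse_pair_table(aln$ss_cons)
  src <- which(keep)
  new_idx <- integer(L)
  new_idx[src] <- seq_along(src)

  n <- length(src)
  s <- integer(n)
  pair_table <- integer(n)
  for (k in seq_len(n)) {
    i <- src[k]
    j <- partner_orig[i]
    if (j > 0 && keep[j]) {
      s[k] <- 0L
      pair_table[k] <- new_idx[j]
    } else {
      s[k] <- 1L           # unpaired, or orphaned pair end demoted
      pair_table[k] <- 0L
    }
  }
  p <- freq[src, , drop = FALSE]
  rownames(p) <- NULL
  structure(list(n = n, p = p, s = s, pair_table = pair_table,
                 source_column_map = src, id = aln$id %||% "query"),
            class = "rna_profile")
}

#' @export
print.rna_profile <- function(x, ...) {
  cat("RNA search profile '", x$id, "': ", x$n, " columns, ",
      sum(x$s == 0L), " paired (", sum(x$pair_table > 0) / 2,
      " consensus pairs)\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a profile
#'
#' Per-column argmax over the four nucleotides (A, C, G, U); ties resolve
#' in alphabetical order.
#' @param profile an `rna_profile`
#' @return character scalar of length `profile$n`
#' @export
profile_consensus <- function(profile) {
  stopifnot(inherits(profile, "rna_profile"))
  idx <- apply(profile$p[, c("A", "C", "G", "U"), drop = FALSE], 1, which.max)
  paste0(c("A", "C", "G", "U")[idx], collapse = "")
}
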