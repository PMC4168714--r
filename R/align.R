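# The aligner: profile-column sequence similarity, the three-matrix
# semi-global affine-gap DP (compiled), traceback, the post-traceback
# structure-consistency bonus, and greedy multi-hit scanning.

#' Sequence similarity between a profile column and a target base
#'
#' The expected substitution score of the column's letter distribution
#' against the base: `sum_x v_x * m(x, base)` over x in `{A,C,G,U,X,-}`.
#'
#' @param column frequency vector of length 6 (A,C,G,U,X,-)
#' @param base target base, one of A,C,G,U,X
#' @param subst 6 x 5 substitution matrix
#' @return numeric score
#' @export
sigma_score <- function(column, base, subst = default_subst_matrix()) {
  stopifnot(length(column) == 6, base %in% RNA_LETTERS)
  sum(column * subst[, base])
}

# cell score matrix: cell[i, j] = alpha * tau(s_i, r_j) + beta * sigma(p_i, b_j)
cell_scores <- function(profile, tcode, track, params) {
  n <- profile$n
  m <- length(tcode)
  sig <- (profile$p %*% params$subst)[, tcode, drop = FALSE]
  r <- if (is.null(track)) rep(NA_real_, m) else {
    v <- track$values
    v[!track$defined] <- NA_real_
    v
  }
  t0 <- tau(rep(0L, m), r, params$scoring)
  t1 <- tau(rep(1L, m), r, params$scoring)
  taumat <- matrix(t1, n, m, byrow = TRUE)
  if (any(profile$s == 0L)) {
    taumat[profile$s == 0L, ] <- matrix(t0, sum(profile$s == 0L), m, byrow = TRUE)
  }
  params$alpha * taumat + params$beta * sig
}

#' Align a profile to a target with reactivity guidance
#'
#' Semi-global (glocal) alignment: the full profile must align, the target's
#' flanks are free.  The match term for profile column i against target base
#' j is `alpha * tau(s_i, r_j) + beta * sigma(p_i, b_j)`; gaps are affine
#' (`gap_open + k * gap_extend`).  After traceback, consensus pairs whose
#' two columns are both matched to target bases forming a canonical pair
#' (AU, UA, GC, CG, GU, UG) earn `consistency_bonus` each; the combined
#' score adds that total when `use_consistency` is set.
#'
#' @param profile an `rna_profile`
#' @param target target sequence (character scalar; normalized internally)
#' @param track a `reactivity_track` of the same length, or NULL for an
#'   all-undefined track (the structural term then contributes 0 everywhere)
#' @param params an `align_params`
#' @param target_id identifier recorded in the hit
#' @return a `probe_hit`: list with query/target ids, 1-based inclusive
#'   `target_start`/`target_end`, `dp_score`, `consistency_score`,
#'   `combined_score`, `aligned_pairs` (k x 2 matrix of (column, position)
#'   matches) and `p_value` (NA until calibrated)
#' @export
align_profile <- function(profile, target, track = NULL,
                          params = align_params(), target_id = "target") {
  stopifnot(inherits(profile, "rna_profile"))
  if (!is.character(target)) target <- as.character(target)
  if (nchar(target) == 0) stop("empty target")
  if (profile$n == 0) stop("empty profile")
  tcode <- encode_target(target)
  if (!is.null(track)) {
    stopifnot(inherits(track, "reactivity_track"))
    if (length(track$values) != length(tcode)) {
      stop("reactivity track length (", length(track$values),
           ") does not match target length (", length(tcode), ")")
    }
  }
  cell <- cell_scores(profile, tcode, track, params)
  res <- dp_semiglobal(cell, params$gap_open, params$gap_extend)
  hit <- structure(list(
    query_id = profile$id,
    target_id = target_id,
    target_start = res$target_start,
    target_end = res$target_end,
    dp_score = res$score,
    aligned_pairs = res$pairs,
    p_value = NA_real_), class = "probe_hit")
  cons <- consistency_score(hit, profile, target,
                            bonus = params$consistency_bonus)
  hit$consistency_score <- cons
  hit$combined_score <- res$score + if (params$use_consistency) cons else 0
  hit
}

#' Structure-consistency score of a hit
#'
#' For every consensus pair (i, i') in the profile's pair table with both
#' columns matched to target positions, add `bonus` when the two target
#' bases form a canonical pair.  X never pairs.
#'
#' @param hit a `probe_hit` with `aligned_pairs` from a completed traceback
#' @param profile the `rna_profile` that produced the hit
#' @param target the target sequence
#' @param bonus score per consistent pair (default 1)
#' @return nonnegative total bonus
#' @export
consistency_score <- function(hit, profile, target, bonus = 1) {
  pairs <- hit$aligned_pairs
  if (is.null(pairs) || nrow(pairs) == 0) return(0)
  pt <- profile$pair_table
  if (all(pt == 0L)) return(0)
  tchars <- seq_chars(normalize_seq(target, allow_gap = FALSE))
  colpos <- integer(profile$n)
  colpos[pairs[, 1]] <- pairs[, 2]
  count <- 0L
  for (i in seq_len(profile$n)) {
    j <- pt[i]
    if (j <= i) next                       # each pair once
    if (colpos[i] == 0L || colpos[j] == 0L) next
    bp <- paste0(tchars[colpos[i]], tchars[colpos[j]])
    if (bp %in% CANONICAL_PAIRS) count <- count + 1L
  }
  bonus * count
}

#' @export
print.probe_hit <- function(x, ...) {
  cat(sprintf("hit %s ~ %s [%d-%d]  dp=%.3f  consistency=%.2f  combined=%.3f  p=%s\n",
              x$query_id, x$target_id, x$target_start, x$target_end,
              x$dp_score, x$consistency_score, x$combined_score,
              ifelse(is.na(x$p_value), "NA", format(x$p_value, digits = 3))))
  invisible(x)
}

#' Scan a target for multiple non-overlapping hits
#'
#' Greedy iteration: align, take the best-scoring hit, mask its span
#' (plus `min_separation` on each side), realign the remaining segments,
#' until `max_hits` are collected or no positive-scoring hit remains.
#'
#' @param profile an `rna_profile`
#' @param target target sequence
#' @param track reactivity track or NULL
#' @param params an `align_params`
#' @param max_hits maximum number of hits to report (>= 1)
#' @param min_separation masked margin around an accepted hit (default 0)
#' @param target_id identifier recorded in hits
#' @return list of `probe_hit`s with coordinates on the full target,
#'   ordered by decreasing combined score
#' @export
scan_target <- function(profile, target, track = NULL, params = align_params(),
                        max_hits = 10, min_separation = 0,
                        target_id = "target") {
  stopifnot(max_hits >= 1)
  if (!is.character(target)) target <- as.character(target)
  m <- nchar(target)
  if (is.null(track)) track <- undefined_track(m)
  segments <- list(list(from = 1L, to = m))
  hits <- list()
  while (length(hits) < max_hits && length(segments) > 0) {
    best <- NULL
    best_seg <- 0L
    for (k in seq_along(segments)) {
      seg <- segments[[k]]
      if (seg$to - seg$from + 1L < 1L) next
      if (is.null(seg$hit)) {
        sub <- substr(target, seg$from, seg$to)
        subtrack <- reactivity_track(track$values[seg$from:seg$to],
                                     track$defined[seg$from:seg$to])
        seg$hit <- align_profile(profile, sub, subtrack, params,
                                 target_id = target_id)
        segments[[k]] <- seg
      }
      h <- seg$hit
      if (h$target_start == 0L) next      # nothing consumed
      if (is.null(best) || h$combined_score > best$combined_score + 1e-12) {
        best <- h
        best_seg <- k
      }
    }
    if (is.null(best) || best$combined_score <= 0) break
    seg <- segments[[best_seg]]
    off <- seg$from - 1L
    best$target_start <- best$target_start + off
    best$target_end <- best$target_end + off
    best$aligned_pairs[, 2] <- best$aligned_pairs[, 2] + off
    hits[[length(hits) + 1L]] <- best
    left <- list(from = seg$from,
                 to = best$target_start - 1L - as.integer(min_separation))
    right <- list(from = best$target_end + 1L + as.integer(min_separation),
                  to = seg$to)
    segments[[best_seg]] <- NULL
    for (s2 in list(left, right)) {
      if (s2$to - s2$from + 1L >= 1L) segments[[length(segments) + 1L]] <- s2
    }
  }
  hits
}

#' Attach p-values to hits under a fitted null
#' @param hits list of `probe_hit`s or a hits data frame
#' @param null a `gamma_null` (see [fit_null()])
#' @return hits with `p_value` filled from the combined score
#' @export
add_p_values <- function(hits, null) {
  if (is.data.frame(hits)) {
    hits$p_value <- p_value(hits$combined_score, null)
    return(hits)
  }
  lapply(hits, function(h) {
    h$p_value <- p_value(h$combined_score, null)
    h
  })
}
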