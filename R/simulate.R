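# Benchmark simulator: synthetic families, mutated homologs planted in decoy
# backgrounds with structure-concordant reactivities, and ROC evaluation
# against the truth.

#' Simulate a stem-loop ncRNA family alignment
#'
#' Generates an ungapped family alignment around a two-helix stem-loop
#' consensus (outer helix, spacer, inner helix, hairpin loop, 3' tail) with
#' a consensus structure line.  Members diverge from the consensus by
#' compensatory replacement of whole pairs (at `pair_variation` per pair)
#' and random substitutions at unpaired columns (at `loop_variation` per
#' site), emulating the covariation pattern of real families: structure is
#' conserved, sequence drifts.  Low variation gives a high-identity family;
#' values near 0.5 give the diffuse, low-identity regime where sequence
#' similarity alone struggles.
#'
#' @param n_seqs number of members
#' @param helix1,helix2 lengths of the outer and inner helices (bp)
#' @param loop hairpin loop length; `spacer` separates the helices and
#'   `tail` dangles at the 3' end (nt)
#' @param spacer,tail see above
#' @param pair_variation per-pair probability of a compensatory replacement
#'   in a member
#' @param loop_variation per-site substitution probability at unpaired
#'   columns in a member
#' @param seed RNG seed
#' @param id family identifier
#' @return a `stockholm_aln`
#' @export
simulate_family <- function(n_seqs = 8, helix1 = 8, helix2 = 5, loop = 6,
                            spacer = 2, tail = 8, pair_variation = 0.25,
                            loop_variation = 0.2, seed = 101,
                            id = "synthetic_family") {
  with_seed(seed, {
    ss <- paste0(strrep("<", helix1), strrep(".", spacer),
                 strrep("<", helix2), strrep(".", loop),
                 strrep(">", helix2), strrep(".", spacer),
                 strrep(">", helix1), strrep(".", tail))
    L <- nchar(ss)
    partner <- parse_pair_table(ss)
    pool <- CANONICAL_PAIRS
    cons <- character(L)
    for (i in seq_len(L)) {
      j <- partner[i]
      if (j > i) {
        bp <- sample(pool[1:4], 1)      # consensus favors Watson-Crick pairs
        cons[i] <- substr(bp, 1, 1)
        cons[j] <- substr(bp, 2, 2)
      } else if (j == 0) {
        cons[i] <- sample(c("A", "C", "G", "U"), 1)
      }
    }
    recs <- character(n_seqs)
    for (k in seq_len(n_seqs)) {
      b <- cons
      for (i in seq_len(L)) {
        j <- partner[i]
        if (j > i && runif(1) < pair_variation) {
          bp <- sample(pool, 1)
          b[i] <- substr(bp, 1, 1)
          b[j] <- substr(bp, 2, 2)
        } else if (j == 0 && runif(1) < loop_variation) {
          b[i] <- sample(c("A", "C", "G", "U"), 1)
        }
      }
      recs[k] <- paste0(b, collapse = "")
    }
    names(recs) <- paste0("member", seq_len(n_seqs))
    stockholm_aln(recs, ss, id = id)
  })
}

#' Sample a mutated homolog of a profile
#'
#' Starts from the profile consensus (per-column argmax base, ties broken
#' A < C < G < U), applies i.i.d. substitutions at `mutation_rate` and
#' single-base indels at `indel_rate`.  In compensatory mode substitutions
#' hitting a consensus pair replace both partners with a random canonical
#' pair, preserving the structure.
#'
#' @param profile an `rna_profile`
#' @param mutation_rate per-site substitution probability (0 to 0.5)
#' @param indel_rate per-site indel probability (0 to 0.5); split evenly
#'   between single-base deletions and insertions
#' @param seed RNG seed (NULL = current stream)
#' @param compensatory preserve consensus pairs under substitution?
#' @return a `homolog`: list with `sequence`, `pairedness` (0 = paired,
#'   per emitted base; inserted bases are unpaired) and `columns` (emitted
#'   base -> source profile column, 0 for insertions)
#' @export
mutate_homolog <- function(profile, mutation_rate = 0.25, indel_rate = 0,
                           seed = NULL, compensatory = FALSE) {
  stopifnot(inherits(profile, "rna_profile"),
            mutation_rate >= 0, mutation_rate <= 0.5,
            indel_rate >= 0, indel_rate <= 0.5)
  with_seed(seed, {
    bases <- seq_chars(profile_consensus(profile))
    n <- profile$n
    sub_mask <- runif(n) < mutation_rate
    if (compensatory) {
      done <- rep(FALSE, n)
      for (i in seq_len(n)) {
        j <- profile$pair_table[i]
        if (j > i && (sub_mask[i] || sub_mask[j])) {
          pair <- sample(CANONICAL_PAIRS, 1)
          bases[i] <- substr(pair, 1, 1)
          bases[j] <- substr(pair, 2, 2)
          done[i] <- done[j] <- TRUE
        }
      }
      for (i in which(sub_mask & !done & profile$pair_table == 0L)) {
        bases[i] <- sample(setdiff(c("A", "C", "G", "U"), bases[i]), 1)
      }
    } else {
      for (i in which(sub_mask)) {
        bases[i] <- sample(setdiff(c("A", "C", "G", "U"), bases[i]), 1)
      }
    }
    out_base <- character(0)
    out_s <- integer(0)
    out_col <- integer(0)
    u <- runif(n)
    for (i in seq_len(n)) {
      if (u[i] < indel_rate / 2) next               # deletion
      out_base <- c(out_base, bases[i])
      out_s <- c(out_s, profile$s[i])
      out_col <- c(out_col, i)
      if (u[i] >= indel_rate / 2 && u[i] < indel_rate) {  # insertion after i
        out_base <- c(out_base, sample(c("A", "C", "G", "U"), 1))
        out_s <- c(out_s, 1L)
        out_col <- c(out_col, 0L)
      }
    }
    structure(list(sequence = paste0(out_base, collapse = ""),
                   pairedness = out_s, columns = out_col),
              class = "homolog")
  })
}

# reactivities where each site is drawn from the correct conditional density
# with probability `concordance` and from the wrong one otherwise
simulate_reactivities_concordant <- function(pairedness, model, concordance) {
  flip <- runif(length(pairedness)) >= concordance
  eff <- ifelse(flip, 1L - pairedness, pairedness)
  simulate_reactivities(eff, model, seed = NULL)
}

#' Build a planted-homolog benchmark
#'
#' Positives are mutated homologs of the profile planted between decoy
#' flanks; decoy-only targets carry a decoy core of the same length instead.
#' Decoy regions get reactivities fully concordant with their
#' Nussinov-assigned structure (they behave like real folded molecules);
#' the planted homolog's reactivities follow its consensus-derived
#' structure with probability `concordance` per site (1 = ideal probing,
#' 0.5 = uninformative probing).
#'
#' @param profile an `rna_profile`
#' @param n_positives number of targets containing a planted homolog
#' @param n_decoys number of decoy-only targets
#' @param spec a `decoy_spec`; `segment_length` sets the flank length and
#'   `gc_content` the background composition
#' @param concordance fraction of homolog sites probed concordantly (0-1)
#' @param mutation_rate substitution rate of planted homologs
#' @param indel_rate indel rate of planted homologs
#' @param compensatory preserve consensus pairs under substitution?
#' @param seed RNG seed
#' @param sim_model reactivity density model used for simulation
#' @return a `planted_benchmark`: list with `targets` (named character),
#'   `tracks` (named list of `reactivity_track`), `truth` (data frame of
#'   target_id, start, end, family_id; 1-based inclusive) and `params`
#' @export
build_benchmark <- function(profile, n_positives = 20, n_decoys = 20,
                            spec = decoy_spec(), concordance = 1,
                            mutation_rate = 0.25, indel_rate = 0.02,
                            compensatory = FALSE, seed = spec$seed,
                            sim_model = default_shape_model()) {
  stopifnot(inherits(profile, "rna_profile"),
            concordance >= 0, concordance <= 1)
  with_seed(seed, {
    targets <- character(0)
    tracks <- list()
    truth <- list()
    make_flank <- function() scfg_segment(spec$segment_length, spec$gc_content)
    for (k in seq_len(n_positives + n_decoys)) {
      positive <- k <= n_positives
      id <- if (positive) sprintf("pos_%03d", k)
            else sprintf("dec_%03d", k - n_positives)
      fl <- make_flank()
      fr <- make_flank()
      if (positive) {
        hom <- mutate_homolog(profile, mutation_rate, indel_rate,
                              seed = NULL, compensatory = compensatory)
        core <- hom$sequence
        core_s <- hom$pairedness
        core_track <- simulate_reactivities_concordant(core_s, sim_model,
                                                       concordance)
      } else {
        core <- scfg_segment(profile$n, spec$gc_content)
        core_s <- assign_structure(core)$pairedness
        core_track <- simulate_reactivities(core_s, sim_model, seed = NULL)
      }
      fl_track <- simulate_reactivities(assign_structure(fl)$pairedness,
                                        sim_model, seed = NULL)
      fr_track <- simulate_reactivities(assign_structure(fr)$pairedness,
                                        sim_model, seed = NULL)
      seqs <- paste0(fl, core, fr)
      track <- reactivity_track(c(fl_track$values, core_track$values,
                                  fr_track$values))
      targets[[id]] <- seqs
      tracks[[id]] <- track
      if (positive) {
        truth[[length(truth) + 1L]] <- data.frame(
          target_id = id,
          start = nchar(fl) + 1L,
          end = nchar(fl) + nchar(core),
          family_id = profile$id,
          stringsAsFactors = FALSE)
      }
    }
    truth_df <- if (length(truth) > 0) do.call(rbind, truth) else
      data.frame(target_id = character(0), start = integer(0),
                 end = integer(0), family_id = character(0))
    structure(list(targets = targets, tracks = tracks, truth = truth_df,
                   params = list(n_positives = n_positives,
                                 n_decoys = n_decoys,
                                 concordance = concordance,
                                 mutation_rate = mutation_rate,
                                 indel_rate = indel_rate,
                                 compensatory = compensatory,
                                 gc_content = spec$gc_content,
                                 segment_length = spec$segment_length,
                                 seed = seed)),
              class = "planted_benchmark")
  })
}

#' Write a benchmark to disk
#'
#' Emits `<prefix>_targets.fasta`, `<prefix>_reactivities.tsv` (keyed
#' three-column dialect) and `<prefix>_truth.tsv` (1-based inclusive).
#'
#' @param bm a `planted_benchmark`
#' @param dir output directory (created if missing)
#' @param prefix file name prefix
#' @return named character vector of the written paths
#' @export
write_benchmark <- function(bm, dir, prefix = "benchmark") {
  stopifnot(inherits(bm, "planted_benchmark"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, "_targets.fasta"))
  react <- file.path(dir, paste0(prefix, "_reactivities.tsv"))
  truth <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write_targets(bm$targets, fasta)
  lines <- unlist(lapply(names(bm$tracks), function(id) {
    tr <- bm$tracks[[id]]
    v <- ifelse(tr$defined, tr$values, -999)
    sprintf("%s\t%d\t%.6g", id, seq_along(v), v)
  }))
  writeLines(lines, react)
  write.table(bm$truth, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  c(targets = fasta, reactivities = react, truth = truth)
}

#' Evaluate ranked hits against a truth set
#'
#' A hit is a true positive when it overlaps a not-yet-credited truth
#' interval on the same target by at least `overlap_fraction` of the
#' shorter interval; each truth interval is creditable once, so repeat
#' hits count as false positives.  Hits are processed in ascending
#' p-value order (descending combined score as tie-break).
#'
#' @param hits hits data frame (see [hits_table()])
#' @param truth truth data frame with target_id, start, end
#' @param overlap_fraction minimum overlap fraction of the shorter
#'   interval (default 0.5)
#' @return list with `tp`, `fp`, `points` (data frame of cumulative TP/FP
#'   counts and rates per rank) and `auc` (area under the rank-threshold
#'   ROC; 1 when no false positive is ranked)
#' @export
evaluate_roc <- function(hits, truth, overlap_fraction = 0.5) {
  hits <- hits_table(hits)
  n_truth <- nrow(truth)
  if (nrow(hits) > 0) {
    p <- hits$p_value
    p[is.na(p)] <- Inf
    hits <- hits[order(p, -hits$combined_score), , drop = FALSE]
  }
  credited <- rep(FALSE, n_truth)
  is_tp <- logical(nrow(hits))
  for (h in seq_len(nrow(hits))) {
    cand <- which(!credited & truth$target_id == hits$target_id[h])
    for (t in cand) {
      ov <- min(hits$target_end[h], truth$end[t]) -
            max(hits$target_start[h], truth$start[t]) + 1L
      shorter <- min(hits$target_end[h] - hits$target_start[h] + 1L,
                     truth$end[t] - truth$start[t] + 1L)
      if (ov >= overlap_fraction * shorter) {
        is_tp[h] <- TRUE
        credited[t] <- TRUE
        break
      }
    }
  }
  cum_tp <- cumsum(is_tp)
  cum_fp <- cumsum(!is_tp)
  tot_tp <- if (n_truth > 0) n_truth else 1L
  tot_fp <- if (length(cum_fp)) cum_fp[length(cum_fp)] else 0L
  points <- data.frame(rank = seq_along(is_tp), tp = cum_tp, fp = cum_fp,
                       tp_rate = cum_tp / tot_tp,
                       fp_rate = if (tot_fp > 0) cum_fp / tot_fp
                                 else rep(0, length(cum_fp)))
  auc <- if (nrow(points) == 0) 0 else if (tot_fp == 0) 1 else {
    x <- c(0, points$fp_rate, 1)
    y <- c(0, points$tp_rate, max(points$tp_rate))
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
  list(tp = if (length(cum_tp)) cum_tp[length(cum_tp)] else 0L,
       fp = if (length(cum_fp)) cum_fp[length(cum_fp)] else 0L,
       points = points, auc = auc)
}
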