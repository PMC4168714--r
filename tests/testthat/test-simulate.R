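# Benchmark simulator: homolog mutation, planted benchmarks, ROC scoring.

test_that("simulated families are reproducible with covarying stems", {
  a1 <- simulate_family(seed = 5)
  a2 <- simulate_family(seed = 5)
  expect_identical(a1$records, a2$records)
  expect_identical(nchar(a1$ss_cons), nchar(a1$records[[1]]))

  # higher variation lowers mean pairwise identity
  ident <- function(aln) {
    m <- do.call(rbind, lapply(aln$records, seq_chars))
    mean(vapply(2:nrow(m), function(i) mean(m[i, ] == m[1, ]), numeric(1)))
  }
  lo <- simulate_family(pair_variation = 0.1, loop_variation = 0.05, seed = 5)
  hi <- simulate_family(pair_variation = 0.5, loop_variation = 0.45, seed = 5)
  expect_gt(ident(lo), ident(hi))

  # every member keeps canonical pairs at the consensus helices
  pt <- parse_pair_table(a1$ss_cons)
  for (rec in a1$records) {
    ch <- seq_chars(rec)
    for (i in which(pt > seq_along(pt))) {
      expect_true(paste0(ch[i], ch[pt[i]]) %in%
                    c("AU", "UA", "GC", "CG", "GU", "UG"))
    }
  }
})

test_that("zero rates reproduce the consensus exactly", {
  prof <- family_profile(seed = 61)
  hom <- mutate_homolog(prof, 0, 0, seed = 1)
  expect_identical(hom$sequence, profile_consensus(prof))
  expect_identical(hom$pairedness, prof$s)
  expect_identical(hom$columns, seq_len(prof$n))
})

test_that("substitution counts follow the binomial mean", {
  seqs <- setNames(rep(paste0(rep("A", 100), collapse = ""), 3),
                   paste0("s", 1:3))
  prof <- build_profile(stockholm_aln(seqs, strrep(".", 100)))
  cons <- seq_chars(profile_consensus(prof))
  nsub <- vapply(1:400, function(k) {
    hom <- mutate_homolog(prof, 0.1, 0, seed = k)
    sum(seq_chars(hom$sequence) != cons)
  }, numeric(1))
  expect_lt(abs(mean(nsub) - 10), 1)
})

test_that("indels change the length at the expected rate", {
  prof <- family_profile(seed = 61)
  lens <- vapply(1:200, function(k) {
    nchar(mutate_homolog(prof, 0, 0.2, seed = 1000 + k)$sequence)
  }, numeric(1))
  # insertions and deletions each at rate 0.1 -> mean length ~ n
  expect_lt(abs(mean(lens) - prof$n), 1.5)
  expect_gt(var(lens), 0)
})

test_that("compensatory homologs keep every consensus pair canonical", {
  prof <- family_profile(seed = 61)
  npairs <- sum(prof$pair_table > 0) / 2
  expect_gt(npairs, 0)
  for (k in 1:5) {
    hom <- mutate_homolog(prof, 0.4, 0, seed = 70 + k, compensatory = TRUE)
    # the true alignment is the identity (no indels): every consensus pair
    # must land on a canonical base pair by construction
    true_hit <- list(aligned_pairs = cbind(seq_len(prof$n), seq_len(prof$n)))
    expect_equal(consistency_score(true_hit, prof, hom$sequence, bonus = 1),
                 npairs, label = paste("compensatory homolog", k))
  }
  # toggling the bonus changes neither the DP score nor the traceback
  hom <- mutate_homolog(prof, 0.25, 0, seed = 91, compensatory = TRUE)
  track <- simulate_reactivities(hom$pairedness, seed = 91)
  on <- align_profile(prof, hom$sequence, track,
                      align_params(use_consistency = TRUE))
  off <- align_profile(prof, hom$sequence, track,
                       align_params(use_consistency = FALSE))
  expect_identical(on$dp_score, off$dp_score)
  expect_identical(on$aligned_pairs, off$aligned_pairs)
  expect_equal(on$combined_score - off$combined_score, on$consistency_score)
})

test_that("planted benchmarks record valid truth intervals", {
  prof <- family_profile(seed = 61)
  bm <- build_benchmark(prof, n_positives = 5, n_decoys = 4,
                        decoy_spec(segment_length = 60, seed = 5),
                        concordance = 1, mutation_rate = 0.2,
                        indel_rate = 0.02, seed = 5)
  expect_s3_class(bm, "planted_benchmark")
  expect_length(bm$targets, 9)
  expect_identical(nrow(bm$truth), 5L)
  for (i in seq_len(nrow(bm$truth))) {
    id <- bm$truth$target_id[i]
    expect_gte(bm$truth$start[i], 1L)
    expect_lte(bm$truth$end[i], nchar(bm$targets[[id]]))
    expect_identical(length(bm$tracks[[id]]$values), nchar(bm$targets[[id]]))
  }
  expect_identical(nrow(build_benchmark(prof, 0, 3,
                                        decoy_spec(segment_length = 40, seed = 1),
                                        seed = 1)$truth), 0L)
})

test_that("half-concordant probing contributes ~0 structural score on average", {
  prof <- family_profile(seed = 61)
  cfg <- scoring_config("simplified", r_c = 0.3)
  tot <- 0
  nsites <- 0
  set.seed(77)
  for (k in 1:60) {
    bm <- build_benchmark(prof, 1, 0, decoy_spec(segment_length = 30,
                                                 seed = 7000 + k),
                          concordance = 0.5, mutation_rate = 0,
                          indel_rate = 0, seed = 7000 + k)
    tr <- bm$truth[1, ]
    track <- bm$tracks[[tr$target_id]]
    r <- track$values[tr$start:tr$end]
    tot <- tot + sum(tau(prof$s, r, cfg))
    nsites <- nsites + prof$n
  }
  expect_lt(abs(tot / nsites), 0.1)  # symmetric +/-1 coin
})

test_that("benchmark files are byte-identical across reruns of one seed", {
  prof <- family_profile(seed = 61)
  d1 <- withr_tempdir()
  d2 <- withr_tempdir()
  for (d in c(d1, d2)) {
    bm <- build_benchmark(prof, 3, 3, decoy_spec(segment_length = 50, seed = 9),
                          seed = 9)
    write_benchmark(bm, d, "bm")
  }
  for (f in c("bm_targets.fasta", "bm_reactivities.tsv", "bm_truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("ROC evaluation applies the single-credit overlap rule", {
  truth <- data.frame(target_id = c("t1", "t2"), start = c(10L, 5L),
                      end = c(30L, 25L), family_id = "f")
  mk <- function(id, s, e, p) data.frame(
    query_id = "f", target_id = id, target_start = s, target_end = e,
    dp_score = 1, consistency_score = 0, combined_score = 1, p_value = p,
    stringsAsFactors = FALSE)

  exact <- rbind(mk("t1", 10, 30, 0.001), mk("t2", 5, 25, 0.002))
  res <- evaluate_roc(exact, truth)
  expect_identical(c(res$tp, res$fp), c(2L, 0L))
  expect_equal(res$auc, 1)

  disjoint <- rbind(mk("t1", 50, 70, 0.001), mk("t2", 40, 60, 0.002))
  res2 <- evaluate_roc(disjoint, truth)
  expect_identical(c(res2$tp, res2$fp), c(0L, 2L))

  double <- rbind(mk("t1", 10, 30, 0.001), mk("t1", 11, 29, 0.002))
  res3 <- evaluate_roc(double, truth)
  expect_identical(c(res3$tp, res3$fp), c(1L, 1L))

  # sub-threshold overlap is a false positive
  graze <- mk("t1", 28, 48, 0.001)
  res4 <- evaluate_roc(graze, truth, overlap_fraction = 0.5)
  expect_identical(c(res4$tp, res4$fp), c(0L, 1L))
})
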