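# The DP aligner: column similarity, oracle equivalence, reductions,
# consistency bonus, invariances, multi-hit scanning.

test_that("sigma_score is the expected substitution score of the column", {
  subst <- default_subst_matrix()
  one_hot <- c(A = 1, C = 0, G = 0, U = 0, X = 0, `-` = 0)
  expect_equal(sigma_score(one_hot, "A", subst), subst["A", "A"])

  half_gap <- c(A = 0.5, C = 0, G = 0, U = 0, X = 0, `-` = 0.5)
  expect_equal(sigma_score(half_gap, "A", subst),
               0.5 * subst["A", "A"] + 0.5 * subst["-", "A"])

  uniform <- c(A = 0.25, C = 0.25, G = 0.25, U = 0.25, X = 0, `-` = 0)
  expect_equal(sigma_score(uniform, "G", subst),
               mean(subst[c("A", "C", "G", "U"), "G"]))  # (2 - 3) / 4
  expect_equal(sigma_score(uniform, "G", subst), -0.25)
})

test_that("perfect ungapped match scores n * (alpha + beta * m_match)", {
  seqs <- setNames(rep("ACGU", 3), paste0("s", 1:3))
  prof <- build_profile(stockholm_aln(seqs, "...."))
  track <- reactivity_track(rep(1, 4))     # all above r_c, all sites unpaired
  params <- align_params(alpha = 0.7, beta = 2.6,
                         scoring = scoring_config("simplified", r_c = 0.3))
  hit <- align_profile(prof, "ACGU", track, params)
  expect_equal(hit$dp_score, 4 * (0.7 + 2.6 * 2))  # 23.6
  expect_identical(c(hit$target_start, hit$target_end), c(1L, 4L))
})

test_that("DP equals exhaustive enumeration on random small instances", {
  for (seed in 1:60) {
    mode <- if (seed %% 2 == 0) "protocol_specific" else "simplified"
    inst <- random_instance(seed, mode)
    obj <- instance_objects(inst)
    model <- if (mode == "protocol_specific") obj$params$scoring$model else NULL
    cell <- ref_cell_matrix(inst$p, inst$s, inst$target_chars, inst$r,
                            inst$defined, inst$alpha, inst$beta, inst$subst,
                            inst$mode, inst$r_c, model)
    expected <- oracle_semiglobal(cell, inst$e0, inst$ee)
    got <- align_profile(obj$profile, inst$target, obj$track, obj$params)$dp_score
    expect_equal(got, expected, tolerance = 1e-9,
                 label = paste("instance seed", seed))
  }
})

test_that("alpha = 0 equals undefined reactivities equals a reference sequence aligner", {
  for (seed in 1:15) {
    set.seed(seed + 400)
    n <- sample(5:15, 1)
    m <- sample(10:30, 1)
    q <- paste0(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
    t <- paste0(sample(c("A", "C", "G", "U"), m, replace = TRUE), collapse = "")
    prof <- build_profile(stockholm_aln(setNames(q, "s1"), strrep(".", n)))
    track <- reactivity_track(runif(m))
    p0 <- align_params(alpha = 0, beta = 1, use_consistency = FALSE)
    pu <- align_params(alpha = 0.7, beta = 1, use_consistency = FALSE)
    a0 <- align_profile(prof, t, track, p0)$dp_score
    au <- align_profile(prof, t, NULL, pu)$dp_score
    expect_identical(a0, au)

    sm <- matrix(-1, 4, 4, dimnames = list(c("A","C","G","U"), c("A","C","G","U")))
    diag(sm) <- 2
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::RNAString(q), Biostrings::RNAString(t),
      type = "global-local", substitutionMatrix = sm,
      gapOpening = 4, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(a0, ref, tolerance = 1e-9)
  }
})

test_that("consistency score counts canonical pairs at matched pair columns", {
  prof <- build_profile(stockholm_aln(c(a = "GCUAGC", b = "GCUAGC"), "<<..>>"))
  params <- align_params(alpha = 0, beta = 2.6)
  hit <- align_profile(prof, "GCUAGC", NULL, params)
  expect_equal(hit$consistency_score, 2)  # G-C and C-G both canonical
  expect_equal(hit$combined_score, hit$dp_score + 2)

  # G aligned opposite G cannot pair; U-A still canonical
  hit2 <- align_profile(prof, "GCUAGG", NULL, params)
  expect_equal(hit2$consistency_score, 1)

  # no consensus pairs -> zero
  prof_np <- build_profile(stockholm_aln(c(a = "GCUAGC"), "......"))
  expect_equal(align_profile(prof_np, "GCUAGC", NULL, params)$consistency_score, 0)

  # X never pairs even opposite a would-be partner
  hit3 <- align_profile(prof, "GCUAGN", NULL, params)
  expect_equal(hit3$consistency_score, 1)
})

test_that("consistency bonus scales the combined score but never the DP score", {
  prof <- family_profile(seed = 21)
  target <- paste0("ACGAUC", profile_consensus(prof), "GGCUAA")
  base <- align_profile(prof, target, NULL,
                        align_params(consistency_bonus = 0))
  for (b in c(0.5, 1, 2, 5)) {
    hit <- align_profile(prof, target, NULL,
                         align_params(consistency_bonus = b))
    expect_identical(hit$dp_score, base$dp_score)
    expect_gte(hit$combined_score, base$combined_score)
    # integer multiple decomposition
    npairs <- hit$consistency_score / b
    expect_equal(npairs, round(npairs))
    expect_equal(hit$combined_score - hit$dp_score, b * npairs)
  }
})

test_that("free target flanks: prepending bases leaves the score unchanged", {
  prof <- family_profile(seed = 31)
  cons <- profile_consensus(prof)
  s0 <- align_profile(prof, cons, NULL, align_params())$dp_score
  set.seed(9)
  prefix <- paste0(sample(c("A", "C", "G", "U"), 25, replace = TRUE),
                   collapse = "")
  s1 <- align_profile(prof, paste0(prefix, cons), NULL, align_params())$dp_score
  expect_equal(s1, s0)
})

test_that("scan finds two planted copies and masks between hits", {
  prof <- family_profile(seed = 41)
  cons <- profile_consensus(prof)
  set.seed(17)
  gap <- paste0(sample(c("A", "C", "G", "U"), 50, replace = TRUE), collapse = "")
  lead <- paste0(sample(c("A", "C", "G", "U"), 20, replace = TRUE), collapse = "")
  target <- paste0(lead, cons, gap, cons)
  hits <- scan_target(prof, target, NULL, align_params(), max_hits = 5)
  expect_gte(length(hits), 2)
  spans <- vapply(hits[1:2], function(h) c(h$target_start, h$target_end),
                  integer(2))
  starts <- sort(spans[1, ])
  expect_identical(starts, c(21L, 21L + prof$n + 50L))
  # non-overlap across all reported hits
  ivs <- t(vapply(hits, function(h) c(h$target_start, h$target_end), integer(2)))
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
  if (nrow(ivs) > 1) {
    expect_true(all(ivs[-1, 1] > ivs[-nrow(ivs), 2]))
  }
})

test_that("max_hits = 1 returns exactly the single best alignment", {
  prof <- family_profile(seed = 41)
  set.seed(23)
  target <- paste0(paste0(sample(c("A","C","G","U"), 30, replace = TRUE),
                          collapse = ""), profile_consensus(prof))
  one <- scan_target(prof, target, NULL, align_params(), max_hits = 1)
  full <- align_profile(prof, target, NULL, align_params())
  expect_length(one, 1)
  expect_identical(one[[1]]$combined_score, full$combined_score)
  expect_identical(one[[1]]$target_start, full$target_start)
})

test_that("track length mismatches and empty inputs are fatal", {
  prof <- family_profile(seed = 41)
  expect_error(align_profile(prof, "ACGU", reactivity_track(c(1, 2))),
               "length")
  expect_error(align_profile(prof, ""), "empty")
})
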