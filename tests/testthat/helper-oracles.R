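# Independent oracles used across the suite.  These deliberately avoid the
# package's DP / folding code paths: alignment scores come from exhaustive
# enumeration of all semi-global alignments, pair counts from a plain
# recursive maximizer, and cell scores from a from-scratch reimplementation
# of the similarity terms.

# Exhaustive best semi-global alignment score: full profile consumed, free
# target flanks, affine gaps (a run of k costs e0 + k*ee).  Enumerates every
# move string; feasible for n <= 6, m <= 8.
oracle_semiglobal <- function(cell, e0, ee) {
  n <- nrow(cell)
  m <- ncol(cell)
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i > n) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (j <= m) rec(i + 1L, j + 1L, "M", sc + cell[i, j])
    rec(i + 1L, j, "D", sc + if (identical(prev, "D")) ee else e0 + ee)
    if (j <= m) rec(i, j + 1L, "I", sc + if (identical(prev, "I")) ee else e0 + ee)
  }
  for (j0 in 0:m) rec(1L, j0 + 1L, "start", 0)
  best
}

# Brute-force maximum number of canonical nested pairs (incl. GU), minimum
# hairpin loop 3.  code: integers 1..5 (A,C,G,U,X).
oracle_maxpairs <- function(code) {
  canon <- function(a, b) {
    lo <- min(a, b); hi <- max(a, b)
    (lo == 1 && hi == 4) || (lo == 2 && hi == 3) || (lo == 3 && hi == 4)
  }
  rec <- function(i, j) {
    if (j - i < 4) return(0L)
    best <- rec(i, j - 1L)
    for (k in i:(j - 4L)) {
      if (canon(code[k], code[j])) {
        v <- 1L + (if (k > i) rec(i, k - 1L) else 0L) + rec(k + 1L, j - 1L)
        if (v > best) best <- v
      }
    }
    best
  }
  rec(1L, length(code))
}

# From-scratch cell scores: alpha * tau(s_i, r_j) + beta * sigma(p_i, b_j),
# written without reusing the package's vectorized implementation.
ref_cell_matrix <- function(p, s, target_chars, r, defined,
                            alpha, beta, subst, mode, r_c, model = NULL) {
  n <- nrow(p)
  m <- length(target_chars)
  cell <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sig <- 0
      for (x in rownames(subst)) sig <- sig + p[i, x] * subst[x, target_chars[j]]
      tv <- 0
      if (defined[j]) {
        if (mode == "simplified") {
          agree <- (r[j] > r_c && s[i] == 1) || (r[j] <= r_c && s[i] == 0)
          tv <- if (agree) 1 else -1
        } else {
          dp <- max(reactscan::r_density(model$paired, r[j]), 1e-12)
          du <- max(reactscan::r_density(model$unpaired, r[j]), 1e-12)
          tv <- if (s[i] == 0) log(dp) - log(du) else log(du) - log(dp)
        }
      }
      cell[i, j] <- alpha * tv + beta * sig
    }
  }
  cell
}

# Random small alignment instance (profile, target, reactivities, params)
# for the oracle-equivalence checks.
random_instance <- function(seed, mode = c("simplified", "protocol_specific")) {
  mode <- match.arg(mode)
  set.seed(seed)
  n <- sample(2:6, 1)
  m <- sample(2:8, 1)
  p <- matrix(runif(n * 6), n, 6, dimnames = list(NULL, c("A","C","G","U","X","-")))
  p <- p / rowSums(p)
  s <- sample(0:1, n, replace = TRUE)
  target_chars <- sample(c("A", "C", "G", "U", "X"), m, replace = TRUE,
                         prob = c(0.23, 0.23, 0.23, 0.23, 0.08))
  defined <- runif(m) < 0.8
  r <- ifelse(defined, round(runif(m, 0, 1.5), 3), NA_real_)
  subst <- matrix(round(runif(30, -3, 3), 2), 6, 5,
                  dimnames = list(c("A","C","G","U","X","-"), c("A","C","G","U","X")))
  list(n = n, m = m, p = p, s = s, target_chars = target_chars,
       target = paste0(target_chars, collapse = ""),
       r = r, defined = defined, subst = subst,
       alpha = runif(1, 0, 2), beta = runif(1, 0, 4),
       e0 = -runif(1, 1, 6), ee = -runif(1, 0.2, 2),
       r_c = runif(1, 0.1, 0.8), mode = mode)
}

# Wrap a random instance into package objects.
instance_objects <- function(inst, model = NULL) {
  profile <- structure(list(n = inst$n, p = inst$p, s = as.integer(inst$s),
                            pair_table = integer(inst$n),
                            source_column_map = seq_len(inst$n), id = "rand"),
                       class = "rna_profile")
  track <- reactscan::reactivity_track(ifelse(inst$defined, inst$r, NA_real_),
                                       inst$defined)
  scoring <- if (inst$mode == "simplified") {
    reactscan::scoring_config(mode = "simplified", r_c = inst$r_c)
  } else {
    reactscan::scoring_config(mode = "protocol_specific", r_c = inst$r_c,
                              model = model %||% reactscan::default_shape_model())
  }
  params <- reactscan::align_params(alpha = inst$alpha, beta = inst$beta,
                                    gap_open = inst$e0, gap_extend = inst$ee,
                                    subst = inst$subst, scoring = scoring,
                                    use_consistency = FALSE)
  list(profile = profile, track = track, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
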