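# Alignment parameters: similarity weights, affine gap penalties,
# substitution matrix, structural scoring configuration.

#' Default substitution matrix
#'
#' Rows index the profile letter x in `{A,C,G,U,X,-}`, columns the target
#' base y in `{A,C,G,U,X}`.  Default: +2 match / -1 mismatch among the four
#' nucleotides; X scores 0 against everything; a profile gap scores -1
#' against any base.  Fully replaceable via [read_subst_matrix()].
#'
#' @param match match score (default 2)
#' @param mismatch mismatch score (default -1)
#' @param gap_vs_base score of a profile gap against a target base (default -1)
#' @return 6 x 5 numeric matrix with dimnames
#' @export
default_subst_matrix <- function(match = 2, mismatch = -1, gap_vs_base = -1) {
  m <- matrix(mismatch, nrow = 6, ncol = 5,
              dimnames = list(PROFILE_LETTERS, RNA_LETTERS))
  diag(m[1:4, 1:4]) <- match
  m["X", ] <- 0
  m[, "X"] <- 0
  m["-", ] <- gap_vs_base
  m["-", "X"] <- 0
  m
}

#' Read a substitution matrix file
#'
#' Whitespace-delimited labeled table: header row of target letters
#' (A C G U X), one row per profile letter (A C G U X -).
#' @param path matrix file
#' @return 6 x 5 numeric matrix
#' @export
read_subst_matrix <- function(path) {
  tab <- read.table(path, header = TRUE, row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  if (!all(PROFILE_LETTERS %in% rownames(m)) ||
      !all(RNA_LETTERS %in% colnames(m))) {
    stop("Substitution matrix must have rows A,C,G,U,X,- and columns A,C,G,U,X")
  }
  m[PROFILE_LETTERS, RNA_LETTERS]
}

#' Alignment parameters
#'
#' @param alpha weight of the structural similarity term (>= 0; default 0.7)
#' @param beta weight of the sequence similarity term (>= 0; default 2.6)
#' @param gap_open gap opening penalty (<= 0; default -4).  A gap of length
#'   k costs `gap_open + k * gap_extend`.
#' @param gap_extend gap extension penalty (<= 0; default -1)
#' @param subst 6 x 5 substitution matrix (see [default_subst_matrix()])
#' @param scoring a `scoring_config` (see [scoring_config()])
#' @param consistency_bonus bonus per consensus pair whose aligned target
#'   bases form a canonical pair (>= 0; default 1)
#' @param use_consistency add the consistency bonus to the combined score?
#' @return an `align_params` object
#' @export
align_params <- function(alpha = 0.7, beta = 2.6,
                         gap_open = -4, gap_extend = -1,
                         subst = default_subst_matrix(),
                         scoring = scoring_config(),
                         consistency_bonus = 1,
                         use_consistency = TRUE) {
  stopifnot(alpha >= 0, beta >= 0, gap_open <= 0, gap_extend <= 0,
            consistency_bonus >= 0,
            inherits(scoring, "scoring_config"),
            is.matrix(subst), nrow(subst) == 6, ncol(subst) == 5)
  structure(list(alpha = alpha, beta = beta,
                 gap_open = gap_open, gap_extend = gap_extend,
                 subst = subst, scoring = scoring,
                 consistency_bonus = consistency_bonus,
                 use_consistency = use_consistency),
            class = "align_params")
}

# readable cache/report key for a parameter set
params_key <- function(params) {
  sc <- params$scoring
  paste(params$alpha, params$beta, params$gap_open, params$gap_extend,
        sc$mode, sc$r_c, as.integer(isTRUE(sc$invert)),
        params$consistency_bonus, as.integer(params$use_consistency),
        paste(signif(params$subst, 6), collapse = ","),
        sep = "|")
}
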