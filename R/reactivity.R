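# Structural similarity scoring: the protocol-specific Bayesian log-ratio,
# the simplified cutoff score, and the conditional reactivity densities
# p(r | paired) / p(r | unpaired) they require.

DENSITY_FAMILIES <- c("exponential", "gamma", "gev")

# -- density model ----------------------------------------------------------

#' Conditional reactivity density model
#'
#' Holds the densities of the reactivity given the pairing state of the
#' probed nucleotide: `p(r | paired)` and `p(r | unpaired)`.  Supported
#' parametric families: `exponential` (params: `rate`), `gamma` (params:
#' `shape`, `scale`) and `gev` (params: `loc`, `scale`, `shape`).
#'
#' @param paired list(family, params) for the paired-state density
#' @param unpaired list(family, params) for the unpaired-state density
#' @return a `reactivity_model` object
#' @export
reactivity_model <- function(paired, unpaired) {
  check_part <- function(part, label) {
    if (!is.list(part) || is.null(part$family) || is.null(part$params)) {
      stop("density model '", label, "' needs $family and $params")
    }
    if (!part$family %in% DENSITY_FAMILIES) {
      stop("unknown density family '", part$family, "'")
    }
    part
  }
  structure(list(paired = check_part(paired, "paired"),
                 unpaired = check_part(unpaired, "unpaired")),
            class = "reactivity_model")
}

#' Evaluate one conditional density of a reactivity model
#' @param part `model$paired` or `model$unpaired`
#' @param x reactivity values
#' @return density values (vectorized)
#' @export
r_density <- function(part, x) {
  p <- part$params
  switch(part$family,
    exponential = dexp(x, rate = p$rate),
    gamma = dgamma(x, shape = p$shape, scale = p$scale),
    gev = dgev(x, loc = p$loc, scale = p$scale, shape = p$shape),
    stop("unknown density family"))
}

#' Sample from one conditional density of a reactivity model
#' @param part `model$paired` or `model$unpaired`
#' @param n number of draws
#' @return numeric vector of draws
#' @export
r_sample <- function(part, n) {
  p <- part$params
  switch(part$family,
    exponential = rexp(n, rate = p$rate),
    gamma = rgamma(n, shape = p$shape, scale = p$scale),
    gev = qgev(runif(n), loc = p$loc, scale = p$scale, shape = p$shape),
    stop("unknown density family"))
}

#' Mean of one conditional density
#' @param part `model$paired` or `model$unpaired`
#' @return expectation of the density
#' @export
r_mean <- function(part) {
  p <- part$params
  switch(part$family,
    exponential = 1 / p$rate,
    gamma = p$shape * p$scale,
    gev = {
      if (abs(p$shape) < 1e-8) p$loc + 0.5772156649 * p$scale
      else p$loc + p$scale * (gamma(1 - p$shape) - 1) / p$shape
    })
}

#' Default SHAPE-like reactivity density model
#'
#' Loads the density pair shipped with the package (inst/extdata/
#' shape_densities.json): paired sites follow an exponential concentrated
#' near zero, unpaired sites a right-tailed Gamma.  These are repo defaults
#' meant to be tuned per probing protocol, not universal constants.
#'
#' @return a `reactivity_model`
#' @export
default_shape_model <- function() {
  path <- system.file("extdata", "shape_densities.json", package = "reactscan")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  reactivity_model(paired = list(family = cfg$paired$family,
                                 params = as.list(cfg$paired$params)),
                   unpaired = list(family = cfg$unpaired$family,
                                   params = as.list(cfg$unpaired$params)))
}

# -- scoring configuration --------------------------------------------------

#' Structural scoring configuration
#'
#' @param mode `"simplified"` (cutoff-based, protocol-agnostic) or
#'   `"protocol_specific"` (Bayesian log-ratio using a density model)
#' @param r_c reactivity cutoff for the simplified mode (dimensionless)
#' @param model a `reactivity_model`, required in protocol_specific mode
#' @param invert flip the reactivity convention (treat high reactivity as
#'   evidence of pairing); for protocols whose raw signal is inverted
#' @return a `scoring_config` object
#' @export
scoring_config <- function(mode = c("simplified", "protocol_specific"),
                           r_c = 0.3, model = NULL, invert = FALSE) {
  mode <- match.arg(mode)
  if (!is.finite(r_c)) stop("r_c must be finite")
  if (mode == "protocol_specific") {
    if (is.null(model)) model <- default_shape_model()
    stopifnot(inherits(model, "reactivity_model"))
  }
  structure(list(mode = mode, r_c = r_c, model = model, invert = invert),
            class = "scoring_config")
}

# -- scoring functions ------------------------------------------------------

#' Simplified cutoff structural score
#'
#' +1 when the observed reactivity agrees with the query pairedness flag
#' (reactivity above the cutoff at an unpaired site, or at/below it at a
#' paired site), -1 otherwise.  The boundary `r == r_c` counts as paired.
#'
#' @param s pairedness flag (0 = paired, 1 = unpaired); vectorized
#' @param r defined reactivity; vectorized
#' @param r_c reactivity cutoff
#' @return +1 / -1 (vectorized)
#' @export
f_simplified <- function(s, r, r_c) {
  ifelse((r > r_c & s == 1) | (r <= r_c & s == 0), 1, -1)
}

DENSITY_FLOOR <- 1e-12

#' Bayesian log-ratio structural score
#'
#' `log p(r | pi = s) - log p(r | pi != s)` under equal pairing priors
#' (natural log).  Densities are floored at 1e-12 before the log so the
#' score saturates rather than becoming infinite.
#'
#' @param s pairedness flag (0 = paired, 1 = unpaired); vectorized
#' @param r defined reactivity; vectorized
#' @param model a `reactivity_model`
#' @return log-ratio score (vectorized)
#' @export
f_bayesian <- function(s, r, model) {
  dp <- pmax(r_density(model$paired, r), DENSITY_FLOOR)
  du <- pmax(r_density(model$unpaired, r), DENSITY_FLOOR)
  ifelse(s == 0, log(dp) - log(du), log(du) - log(dp))
}

#' Structural similarity term
#'
#' Returns 0 wherever the reactivity is undefined; otherwise dispatches to
#' the simplified cutoff score or the Bayesian log-ratio per the
#' configuration.  `NA` reactivities count as undefined.
#'
#' @param s pairedness flag(s), 0 = paired, 1 = unpaired
#' @param r reactivities, `NA` = undefined
#' @param cfg a `scoring_config`
#' @return structural scores (vectorized)
#' @export
tau <- function(s, r, cfg) {
  stopifnot(inherits(cfg, "scoring_config"))
  if (length(s) == 1 && length(r) > 1) s <- rep(s, length(r))
  if (length(r) == 1 && length(s) > 1) r <- rep(r, length(s))
  s_eff <- if (isTRUE(cfg$invert)) 1L - s else s
  out <- numeric(length(r))
  ok <- !is.na(r)
  if (any(ok)) {
    out[ok] <- if (cfg$mode == "simplified") {
      f_simplified(s_eff[ok], r[ok], cfg$r_c)
    } else {
      f_bayesian(s_eff[ok], r[ok], cfg$model)
    }
  }
  out
}
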