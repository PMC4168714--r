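Package: reactscan
Title: Reactivity-Guided Non-Coding RNA Homology Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profile-based homology search for non-coding RNA families that
    incorporates per-nucleotide structure-probing reactivities (SHAPE,
    nuclease-based protocols) into a semi-global affine-gap alignment.
    A family alignment with a consensus secondary structure is compiled
    into a frequency profile with per-column pairedness flags; targets are
    scored with a weighted sum of sequence similarity and a structural
    similarity term driven by the observed reactivities, plus a
    post-traceback bonus for consensus pairs whose aligned target bases
    are canonical.  Statistical significance is calibrated by aligning the
    profile against stochastic-grammar decoys with folded structures and
    simulated reactivities, fitting the score distribution with a shifted
    Gamma model (normal, Gumbel and GEV fits are kept as diagnostics), and
    reporting upper-tail p-values.  Includes a planted-homolog benchmark
    simulator and ROC evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    fitdistrplus,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
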