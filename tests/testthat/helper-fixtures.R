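# Synthetic family fixture: a stem-loop ncRNA family with a consensus
# structure, built in code so no binary fixtures are needed.

# A family alignment: two helices (8 bp outer stem, 5 bp inner stem) and
# loops, 44 columns, with compensatory variation at paired columns.
make_family <- function(n_seqs = 8, seed = 101, id = "stemloop") {
  reactscan::simulate_family(n_seqs = n_seqs, seed = seed, id = id)
}

family_profile <- function(...) reactscan::build_profile(make_family(...))

# Write the fixture family to a Stockholm file; returns the path.
write_family_sto <- function(dir = withr_tempdir(), ...) {
  aln <- make_family(...)
  path <- file.path(dir, paste0(aln$id, ".sto"))
  reactscan::write_stockholm(aln, path)
  path
}

withr_tempdir <- function() {
  d <- file.path(tempdir(), paste0("fix", sample.int(1e6, 1)))
  dir.create(d, showWarnings = FALSE)
  d
}

# Random balanced bracket string over mixed WUSS classes (for the pair-table
# involution property).
random_structure <- function(len, seed) {
  set.seed(seed)
  classes <- list(c("<", ">"), c("(", ")"), c("[", "]"), c("{", "}"))
  out <- character(0)
  open_stacks <- list(character(0), character(0), character(0), character(0))
  depth <- integer(4)
  while (length(out) < len) {
    cls <- sample(1:4, 1)
    move <- sample(c("open", "close", "dot"), 1, prob = c(0.35, 0.35, 0.3))
    if (move == "open") {
      out <- c(out, classes[[cls]][1])
      depth[cls] <- depth[cls] + 1L
    } else if (move == "close" && depth[cls] > 0L) {
      out <- c(out, classes[[cls]][2])
      depth[cls] <- depth[cls] - 1L
    } else {
      out <- c(out, ".")
    }
  }
  for (cls in 1:4) {
    if (depth[cls] > 0L) out <- c(out, rep(classes[[cls]][2], depth[cls]))
  }
  paste0(out, collapse = "")
}
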