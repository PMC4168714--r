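# I/O: Stockholm alignments with consensus structure, FASTA targets,
# SHAPE-style reactivity tracks, and the tabular hits report.

#' Read a Stockholm alignment with a consensus structure line
#'
#' Parses a (possibly multi-block) Stockholm file.  Sequences are normalized
#' to the alphabet `{A,C,G,U,X,-}` (T becomes U, `.` and `-` are both gaps,
#' anything else becomes X).  The `#=GC SS_cons` annotation is required: the
#' scoring model needs per-column pairedness.
#'
#' @param path path to a Stockholm file
#' @return an object of class `stockholm_aln`: list with `records` (named
#'   character vector of aligned sequences, input order preserved) and
#'   `ss_cons` (consensus-structure string of the same length)
#' @export
read_stockholm <- function(path) {
  if (!file.exists(path)) stop("Stockholm file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  seqs <- character(0)
  ss <- character(0)
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (ln == "" || ln == "//") next
    if (startsWith(ln, "#")) {
      if (grepl("^#=GC\\s+SS_cons\\s+", ln)) {
        ss <- c(ss, sub("^#=GC\\s+SS_cons\\s+", "", ln))
      }
      next
    }
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) != 2) stop("Malformed sequence line in ", path, ": '", ln, "'")
    id <- parts[1]
    if (id %in% names(seqs)) {
      seqs[[id]] <- paste0(seqs[[id]], parts[2])
    } else {
      seqs[[id]] <- parts[2]
    }
  }
  if (length(seqs) == 0) stop("No sequences found in ", path)
  if (length(ss) == 0) {
    stop("No consensus structure (#=GC SS_cons) line in ", path)
  }
  ss_cons <- paste0(ss, collapse = "")
  records <- vapply(seqs, normalize_seq, character(1))
  lens <- nchar(records)
  if (length(unique(lens)) != 1) {
    stop("Ragged alignment in ", path, ": sequence lengths ",
         paste(unique(lens), collapse = ", "))
  }
  if (nchar(ss_cons) != lens[1]) {
    stop("SS_cons length (", nchar(ss_cons), ") does not match alignment length (",
         lens[1], ") in ", path)
  }
  structure(list(records = records, ss_cons = ss_cons,
                 id = sub("\\.[^.]*$", "", basename(path))),
            class = "stockholm_aln")
}

#' Construct a Stockholm alignment object in memory
#'
#' @param records named character vector of aligned sequences
#' @param ss_cons consensus structure string
#' @param id family identifier
#' @return a `stockholm_aln` object (normalized)
#' @export
stockholm_aln <- function(records, ss_cons, id = "query") {
  if (is.null(names(records))) {
    names(records) <- paste0("seq", seq_along(records))
  }
  records <- vapply(records, normalize_seq, character(1))
  lens <- nchar(records)
  if (length(unique(lens)) != 1) stop("Ragged alignment")
  if (nchar(ss_cons) != lens[1]) {
    stop("SS_cons length (", nchar(ss_cons), ") does not match alignment length (",
         lens[1], ")")
  }
  structure(list(records = records, ss_cons = ss_cons, id = id),
            class = "stockholm_aln")
}

#' Write a Stockholm alignment
#'
#' @param aln a `stockholm_aln` object
#' @param path output path
#' @export
write_stockholm <- function(aln, path) {
  stopifnot(inherits(aln, "stockholm_aln"))
  w <- max(nchar(names(aln$records)), nchar("#=GC SS_cons"))
  lines <- c("# STOCKHOLM 1.0",
             sprintf("%-*s %s", w, names(aln$records), aln$records),
             sprintf("%-*s %s", w, "#=GC SS_cons", aln$ss_cons),
             "//")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.stockholm_aln <- function(x, ...) {
  cat("Stockholm alignment '", x$id, "': ", length(x$records),
      " sequences x ", nchar(x$ss_cons), " columns\n", sep = "")
  invisible(x)
}

#' Parse a WUSS/dot-bracket consensus structure into a pair table
#'
#' All four nested bracket classes `<>`, `()`, `[]`, `{}` are honored.
#' Pseudoknot letter annotations (`Aa`, `Bb`, ...) and all other characters
#' are treated as unpaired: the scoring model consumes only per-site
#' pairedness plus a nested pair table.
#'
#' @param ss_cons structure string
#' @return integer vector: position i holds its 1-based partner, 0 if unpaired
#' @export
parse_pair_table <- function(ss_cons) {
  ch <- seq_chars(ss_cons)
  n <- length(ch)
  partner <- integer(n)
  opens <- c("<" = ">", "(" = ")", "[" = "]", "{" = "}")
  for (k in seq_along(opens)) {
    op <- names(opens)[k]
    cl <- opens[[k]]
    stack <- integer(0)
    for (i in seq_len(n)) {
      if (ch[i] == op) {
        stack <- c(stack, i)
      } else if (ch[i] == cl) {
        if (length(stack) == 0) {
          stop("Unbalanced structure: unmatched '", cl, "'")
        }
        j <- stack[length(stack)]
        stack <- stack[-length(stack)]
        partner[i] <- j
        partner[j] <- i
      }
    }
    if (length(stack) > 0) {
      stop("Unbalanced structure: ", length(stack), " unmatched '", op, "'")
    }
  }
  partner
}

#' Construct a reactivity track
#'
#' @param values numeric reactivities (dimensionless), one per target position
#' @param defined logical mask: was a reactivity observed at this position?
#' @return a `reactivity_track` object
#' @export
reactivity_track <- function(values, defined = rep(TRUE, length(values))) {
  stopifnot(length(values) == length(defined))
  values[!defined] <- NA_real_
  structure(list(values = values, defined = defined), class = "reactivity_track")
}

#' An all-undefined reactivity track of a given length
#' @param n track length
#' @export
undefined_track <- function(n) {
  reactivity_track(rep(NA_real_, n), rep(FALSE, n))
}

#' Read a two-column SHAPE-style reactivity file
#'
#' Lines hold `position reactivity` (1-based positions).  The sentinel value
#' -999 (and any value below `sentinel_threshold`) marks an undefined
#' position; positions absent from the file are also undefined.
#'
#' @param path reactivity file
#' @param target_length length of the target sequence the track annotates
#' @param sentinel_threshold values at or below this are undefined (default -500)
#' @return a `reactivity_track` of length `target_length`
#' @export
read_reactivities <- function(path, target_length, sentinel_threshold = -500) {
  if (!file.exists(path)) stop("Reactivity file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  values <- rep(NA_real_, target_length)
  defined <- rep(FALSE, target_length)
  if (length(lines) > 0) {
    tab <- tryCatch(
      read.table(text = lines, colClasses = "numeric",
                 col.names = c("pos", "value")),
      error = function(e) stop("Malformed reactivity file ", path, ": ",
                               conditionMessage(e)))
    pos <- as.integer(tab$pos)
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > target_length)) {
      stop("Reactivity position out of range [1, ", target_length, "] in ", path)
    }
    ok <- tab$value > sentinel_threshold
    values[pos[ok]] <- tab$value[ok]
    defined[pos[ok]] <- TRUE
    defined[pos[!ok]] <- FALSE
  }
  reactivity_track(values, defined)
}

#' Write a reactivity track in the two-column SHAPE dialect
#'
#' Undefined positions are written with the -999 sentinel.
#' @param track a `reactivity_track`
#' @param path output path
#' @export
write_reactivities <- function(track, path) {
  stopifnot(inherits(track, "reactivity_track"))
  v <- ifelse(track$defined, track$values, -999)
  writeLines(sprintf("%d\t%.6g", seq_along(v), v), path)
  invisible(path)
}

#' Read a keyed multi-target reactivity table
#'
#' Tab- or space-delimited `target_id position reactivity` rows, one file for
#' many targets.  Targets absent from the file get all-undefined tracks.
#'
#' @param path table path
#' @param target_lengths named integer vector of target lengths
#' @param sentinel_threshold see [read_reactivities()]
#' @return named list of `reactivity_track`s, one per target
#' @export
read_reactivity_table <- function(path, target_lengths, sentinel_threshold = -500) {
  if (!file.exists(path)) stop("Reactivity table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  tracks <- lapply(target_lengths, undefined_track)
  if (length(lines) == 0) return(tracks)
  tab <- tryCatch(
    read.table(text = lines, colClasses = c("character", "numeric", "numeric"),
               col.names = c("target_id", "pos", "value")),
    error = function(e) stop("Malformed reactivity table ", path, ": ",
                             conditionMessage(e)))
  for (id in unique(tab$target_id)) {
    if (!id %in% names(target_lengths)) {
      stop("Reactivity table names unknown target '", id, "'")
    }
    sub <- tab[tab$target_id == id, , drop = FALSE]
    len <- target_lengths[[id]]
    pos <- as.integer(sub$pos)
    if (any(pos < 1L) || any(pos > len)) {
      stop("Reactivity position out of range for target '", id, "'")
    }
    values <- rep(NA_real_, len)
    defined <- rep(FALSE, len)
    ok <- sub$value > sentinel_threshold
    values[pos[ok]] <- sub$value[ok]
    defined[pos[ok]] <- TRUE
    tracks[[id]] <- reactivity_track(values, defined)
  }
  tracks
}

#' Read target sequences from FASTA
#'
#' Sequences are normalized to `{A,C,G,U,X}` (gaps are not meaningful in
#' targets and become X).
#' @param path FASTA file
#' @return named character vector of target sequences
#' @export
read_targets <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- vapply(as.character(set), normalize_seq, character(1),
                 allow_gap = FALSE)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write target sequences to FASTA
#' @param seqs named character vector
#' @param path output path
#' @export
write_targets <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

HITS_COLUMNS <- c("query_id", "target_id", "target_start", "target_end",
                  "dp_score", "consistency_score", "combined_score", "p_value")

#' Convert a list of alignment hits to a data frame
#' @param hits list of `probe_hit` objects (or an already-tabular data frame)
#' @return data frame with one row per hit
#' @export
hits_table <- function(hits) {
  if (is.data.frame(hits)) return(hits)
  if (length(hits) == 0) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(HITS_COLUMNS)),
                                 HITS_COLUMNS))
    df$query_id <- character(0)
    df$target_id <- character(0)
    return(df[, HITS_COLUMNS])
  }
  do.call(rbind, lapply(hits, function(h) {
    data.frame(query_id = h$query_id, target_id = h$target_id,
               target_start = h$target_start, target_end = h$target_end,
               dp_score = h$dp_score, consistency_score = h$consistency_score,
               combined_score = h$combined_score,
               p_value = h$p_value %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Write a hits report
#'
#' Tab-delimited with a header row; 1-based inclusive target coordinates;
#' sorted by ascending p-value then descending combined score.
#'
#' @param hits list of hits or a hits data frame
#' @param path output path
#' @export
write_hits <- function(hits, path) {
  df <- hits_table(hits)
  if (nrow(df) > 0) {
    p <- df$p_value
    p[is.na(p)] <- Inf
    df <- df[order(p, -df$combined_score), , drop = FALSE]
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("Cannot write hits to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hits report written by [write_hits()]
#' @param path hits file
#' @return data frame of hits
#' @export
read_hits <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  for (col in c("target_start", "target_end")) df[[col]] <- as.integer(df[[col]])
  for (col in c("dp_score", "consistency_score", "combined_score", "p_value")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}
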