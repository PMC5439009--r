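# Corpus containers and input/output: native JSON-lines format, a
# best-effort **kern (Humdrum) importer, the single-time-signature corpus
# filter, and seeded cross-validation fold assignment.

#' Construct a rhythm corpus
#'
#' A corpus is a list of [rhythm_sequence()] objects with class
#' `rhythm_corpus`; subsetting preserves the class.
#'
#' @param rhythms list of `rhythm_sequence` objects.
#' @return a `rhythm_corpus`.
#' @export
rhythm_corpus <- function(rhythms = list()) {
  .assert(all(vapply(rhythms, inherits, TRUE, "rhythm_sequence")),
          "all elements must be rhythm_sequence objects")
  structure(rhythms, class = "rhythm_corpus")
}

#' @export
`[.rhythm_corpus` <- function(x, i) rhythm_corpus(unclass(x)[i])

#' @export
print.rhythm_corpus <- function(x, ...) {
  cat(sprintf("<rhythm_corpus> %d rhythms\n", length(x)))
  h <- meter_histogram(x)
  if (nrow(h)) {
    for (i in seq_len(nrow(h))) {
      cat(sprintf("  %-6s %d\n", h$meter[i], h$n[i]))
    }
  }
  invisible(x)
}

#' Histogram of meter annotations in a corpus
#'
#' @param corpus a list of `rhythm_sequence` objects.
#' @return data.frame with columns `meter` (including `"<none>"` for
#'   unannotated rhythms) and `n`.
#' @export
meter_histogram <- function(corpus) {
  labels <- vapply(corpus, function(r) r$meter %||% "<none>", "")
  if (!length(labels)) {
    return(data.frame(meter = character(0), n = integer(0)))
  }
  tab <- table(labels)
  data.frame(meter = names(tab), n = as.integer(tab), stringsAsFactors = FALSE)
}

# ---- native JSONL format ---------------------------------------------------

#' Read and write the native JSON-lines rhythm format
#'
#' One rhythm per line: `{"id": ..., "onsets": [ticks...], "meter": label or
#' null, "region": optional}`. The round trip is lossless for onsets (ticks),
#' annotation and ids.
#'
#' @param path file path.
#' @param corpus a `rhythm_corpus` or list of `rhythm_sequence` objects.
#' @return `read_rhythm_jsonl` returns a `rhythm_corpus`;
#'   `write_rhythm_jsonl` returns `path` invisibly.
#' @export
read_rhythm_jsonl <- function(path) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rhythms <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$onsets)) {
      stop(sprintf("malformed rhythm record at line %d of %s", i, path),
           call. = FALSE)
    }
    rhythms[[i]] <- tryCatch(
      rhythm_sequence(rec$onsets, meter = rec$meter, id = rec$id %||% "",
                      region = rec$region),
      error = function(e) {
        stop(sprintf("invalid rhythm at line %d of %s: %s", i, path,
                     conditionMessage(e)), call. = FALSE)
      })
  }
  rhythm_corpus(rhythms)
}

#' @rdname read_rhythm_jsonl
#' @export
write_rhythm_jsonl <- function(corpus, path) {
  lines <- vapply(corpus, function(r) {
    rec <- list(id = r$id, onsets = r$onsets, meter = r$meter)
    if (!is.null(r$region)) rec$region <- r$region
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# ---- **kern import ---------------------------------------------------------

# Duration of a **kern recip token in 96th-note ticks, or NA if unparseable.
# recip "n" is 1/n of a whole note (0 = breve); each dot extends by half the
# previous value.
.kern_ticks <- function(token) {
  m <- regmatches(token, regexec("([0-9]+)(\\.*)", token))[[1]]
  if (length(m) < 2L || !nzchar(m[2])) return(NA_real_)
  num <- as.numeric(m[2])
  base <- if (num == 0) 192 else 96 / num
  ndots <- nchar(m[3])
  ticks <- base * (2 - 0.5^ndots)
  if (abs(ticks - round(ticks)) > 1e-9) return(NA_real_)
  round(ticks)
}

.parse_kern_song <- function(lines, id) {
  kcol <- NA_integer_
  t <- 0
  onsets <- integer(0)
  meters <- character(0)
  region <- NULL
  first_bar_t <- NA_real_
  for (line in lines) {
    if (!nzchar(line)) next
    if (startsWith(line, "!")) {
      m <- regmatches(line, regexec("^!!!ARE:\\s*(.*)$", line))[[1]]
      if (length(m) == 2L) region <- trimws(m[2])
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (startsWith(line, "**") || any(startsWith(fields, "**"))) {
      kcol <- match(TRUE, fields == "**kern")
      if (is.na(kcol)) kcol <- 1L
      next
    }
    if (is.na(kcol)) kcol <- 1L
    tok <- if (kcol <= length(fields)) fields[kcol] else "."
    if (startsWith(tok, "*")) {
      m <- regmatches(tok, regexec("^\\*M([0-9]+/[0-9]+)$", tok))[[1]]
      if (length(m) == 2L) meters <- c(meters, m[2])
      next
    }
    if (startsWith(tok, "=")) {
      if (is.na(first_bar_t)) first_bar_t <- t
      next
    }
    if (tok == ".") next
    tok <- strsplit(tok, " ", fixed = TRUE)[[1]][1]  # chords: take first note
    if (grepl("q", tok, fixed = TRUE)) next          # grace note, no duration
    ticks <- .kern_ticks(tok)
    if (is.na(ticks)) {
      warning(sprintf("skipping song '%s': unparseable duration token '%s'",
                      id, tok), call. = FALSE)
      return(NULL)
    }
    is_rest <- grepl("r", tok, fixed = TRUE)
    tie_cont <- grepl("[]_]", tok)  # tie continuation or close: no new onset
    if (!is_rest && !tie_cont) onsets <- c(onsets, as.integer(t))
    t <- t + ticks
  }
  if (!length(onsets)) return(NULL)
  meters <- unique(meters)
  # Anacrusis: shift so that onset 0 is the downbeat of the first complete
  # bar; pickup notes become negative.
  if (length(meters) == 1L) {
    period <- tryCatch(meter_category(meters)$period, error = function(e) NA)
    if (!is.na(period) && !is.na(first_bar_t) && first_bar_t > 0 &&
        first_bar_t %% period != 0) {
      onsets <- onsets - as.integer(first_bar_t)
    }
  }
  r <- rhythm_sequence(onsets,
                       meter = if (length(meters) == 1L) meters else NULL,
                       id = id, region = region)
  attr(r, "n_meters") <- length(meters)
  r
}

#' Import **kern (Humdrum) scores as a rhythm corpus
#'
#' A best-effort importer for monophonic **kern files such as those in the
#' Essen folksong collection: note onsets are accumulated from recip
#' duration tokens (dots, breves, tuplet denominators; ties summed; rests
#' and grace notes advance/skip time), `*M` tokens collect time-signature
#' annotations, `!!!ARE` records are kept as region tags, and pickup bars
#' are shifted so that onset 0 falls on the first complete bar's downbeat
#' (anacrusis onsets become negative). Songs with unparseable durations are
#' skipped with a warning. Songs with zero or multiple time signatures are
#' kept unannotated and flagged for [filter_single_meter()].
#'
#' @param paths character vector of file paths; files containing multiple
#'   songs (separated by `*-` terminators) are split.
#' @return a `rhythm_corpus`.
#' @export
import_kern <- function(paths) {
  rhythms <- list()
  for (path in paths) {
    .assert(file.exists(path), sprintf("file not found: %s", path))
    lines <- readLines(path, warn = FALSE)
    ends <- grep("^\\*-", lines)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    if (!length(ends)) {
      starts <- 1L
      ends <- length(lines)
    }
    for (s in seq_along(starts)) {
      id <- if (length(starts) > 1L) {
        sprintf("%s#%d", basename(path), s)
      } else basename(path)
      song <- .parse_kern_song(lines[starts[s]:ends[s]], id)
      if (!is.null(song)) rhythms[[length(rhythms) + 1L]] <- song
    }
  }
  rhythm_corpus(rhythms)
}

# ---- filtering and folds ---------------------------------------------------

#' Keep only rhythms annotated with exactly one time signature
#'
#' Mirrors the corpus filter used when preparing folksong data: songs
#' without an annotated time signature, or flagged as containing several,
#' are dropped. Idempotent.
#'
#' @param corpus a `rhythm_corpus`.
#' @param verbose print how many rhythms were dropped.
#' @return the filtered `rhythm_corpus`.
#' @export
filter_single_meter <- function(corpus, verbose = FALSE) {
  keep <- vapply(corpus, function(r) {
    !is.null(r$meter) && (attr(r, "n_meters") %||% 1L) == 1L
  }, TRUE)
  if (verbose) {
    message(sprintf("filter_single_meter: kept %d of %d rhythms",
                    sum(keep), length(keep)))
  }
  corpus[keep]
}

#' Assign cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment, so fold sizes differ
#' by at most one and the partition is exact and reproducible.
#'
#' @param corpus a list of rhythms (only its length, and meters when
#'   stratifying, are used).
#' @param k number of folds.
#' @param seed integer RNG seed.
#' @param stratify if `TRUE`, round-robin within each meter annotation so
#'   folds have near-identical category composition.
#' @return integer vector of fold indices in `1..k`, one per rhythm.
#' @export
make_folds <- function(corpus, k = 10, seed = 1, stratify = FALSE) {
  n <- length(corpus)
  .assert(n >= k, "need at least k rhythms for k folds")
  .with_seed(seed, {
    fold <- integer(n)
    if (stratify) {
      labels <- vapply(corpus, function(r) r$meter %||% "<none>", "")
      for (l in unique(labels)) {
        idx <- which(labels == l)
        fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    }
    fold
  })
}
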