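# Integer-tick rhythm representation, metrical categories/interpretations and
# the viewpoint machinery (onset, inter-onset interval, metrical position,
# bar number, bar distance and the linked position/bar-distance symbol).
#
# Time is measured in ticks of 1/96 whole note, so a sixteenth note is 6
# ticks, a 32nd is 3 and a sixteenth triplet is 4. This is the coarsest unit
# that represents common folk-rhythm subdivisions exactly.

#' Construct a rhythm sequence
#'
#' A rhythm is an ordered sequence of note-onset times in integer ticks
#' (1 tick = 1/96 whole note; a sixteenth note is 6 ticks), optionally
#' annotated with a time-signature label. Annotated rhythms are assumed to be
#' encoded at phase zero: onset 0 coincides with a bar downbeat of the
#' annotated meter. Anacrusis (pickup) notes carry negative onsets.
#'
#' @param onsets integer vector of onset times in ticks, strictly increasing.
#' @param meter optional time-signature label, e.g. `"3/4"`, or `NULL` if
#'   unannotated.
#' @param id identifier string used in reports and fold bookkeeping.
#' @param region optional free-form provenance tag (e.g. geographic region).
#' @return an object of class `rhythm_sequence`.
#' @examples
#' rhythm_sequence(c(0, 24, 48, 72), meter = "2/4", id = "example")
#' @export
rhythm_sequence <- function(onsets, meter = NULL, id = "", region = NULL) {
  if (length(onsets)) {
    .assert(all(onsets == round(onsets)), "onsets must be integers (ticks)")
    onsets <- as.integer(round(onsets))
    .assert(!is.unsorted(onsets, strictly = TRUE),
            "onsets must be strictly increasing")
  } else {
    onsets <- integer(0)
  }
  if (!is.null(meter)) .assert(is.character(meter) && length(meter) == 1L,
                               "meter must be a single label or NULL")
  structure(list(onsets = onsets, meter = meter, id = as.character(id),
                 region = region),
            class = "rhythm_sequence")
}

#' @export
print.rhythm_sequence <- function(x, ...) {
  cat(sprintf("<rhythm_sequence '%s'> %d onsets, meter %s\n", x$id,
              length(x$onsets), x$meter %||% "<none>"))
  invisible(x)
}

#' Construct a metrical category from a time-signature label
#'
#' The bar period in ticks is `numerator * 96 / denominator`, e.g. 48 for
#' 2/4, 72 for 3/4 or 6/8, 96 for 4/4, 36 for 3/8.
#'
#' @param label a time-signature string such as `"3/4"`.
#' @return an object of class `meter_category` with fields `label` and
#'   `period` (ticks).
#' @export
meter_category <- function(label) {
  if (inherits(label, "meter_category")) return(label)
  m <- regmatches(label, regexec("^([0-9]+)/([0-9]+)$", label))[[1]]
  .assert(length(m) == 3L, sprintf("cannot parse time signature '%s'", label))
  num <- as.integer(m[2]); den <- as.integer(m[3])
  .assert(den > 0L && 96L %% den == 0L,
          sprintf("denominator of '%s' does not divide the 96-tick whole note", label))
  period <- num * (96L %/% den)
  .assert(period > 0L && period %% .phase_res == 0L,
          sprintf("period of '%s' is not a multiple of the phase resolution", label))
  structure(list(label = label, period = period), class = "meter_category")
}

#' Construct a metrical interpretation (category plus phase)
#'
#' A metrical interpretation pairs a metrical category with a phase: the
#' offset in ticks between the rhythm's time origin and the downbeat of the
#' first bar. Phases live on the sixteenth-note grid (multiples of 6 ticks)
#' in `[0, period)`.
#'
#' @param category a `meter_category` or time-signature label.
#' @param phase integer phase in ticks.
#' @return an object of class `metrical_interpretation` with fields `label`,
#'   `period` and `phase`.
#' @export
metrical_interpretation <- function(category, phase = 0L) {
  cat <- meter_category(category)
  phase <- as.integer(phase)
  .assert(phase >= 0L && phase < cat$period, "phase must lie in [0, period)")
  .assert(phase %% .phase_res == 0L,
          "phase must be a multiple of the 6-tick sixteenth grid")
  structure(list(label = cat$label, period = cat$period, phase = phase),
            class = "metrical_interpretation")
}

.onsets <- function(x) {
  if (inherits(x, "rhythm_sequence")) x$onsets else as.integer(x)
}

#' Basic and derived viewpoint functions
#'
#' Viewpoints are partial functions from event sequences to symbols; `NA`
#' plays the role of the undefined marker. All of them look at the *last*
#' event of the sequence they are applied to:
#' \describe{
#'   \item{`vp_onset`}{onset time of the last event.}
#'   \item{`vp_ioi`}{inter-onset interval between the final and penultimate
#'     event; undefined for sequences of fewer than two events.}
#'   \item{`vp_mp`}{metrical position: `(onset - phase) mod period`, using
#'     floored modulo so negative (anacrusis) onsets map into `[0, period)`.}
#'   \item{`vp_bn`}{bar number: floored integer division of `(onset - phase)`
#'     by the period.}
#'   \item{`vp_bd`}{bar distance: difference between the bar numbers of the
#'     last and penultimate event. For a single-event sequence the previous
#'     bar number is taken to be 0 (virtual-origin convention), so the first
#'     event carries phase evidence.}
#'   \item{`vp_mp_bd`}{the linked symbol `c(mp, bd)`; elements of its
#'     alphabet map one-to-one onto concrete onset times given the previous
#'     onset (see [symbol_to_onset()]).}
#' }
#'
#' @param seq a `rhythm_sequence` or integer vector of onsets.
#' @param interp a `metrical_interpretation` (for the metrical viewpoints).
#' @return an integer symbol (length 2 for `vp_mp_bd`), or `NA` if undefined.
#' @examples
#' i34 <- metrical_interpretation("3/4", 0)
#' vp_mp(c(0, 78), i34)   # 78 mod 72
#' vp_bd(c(0, 78), i34)   # one bar apart
#' vp_mp_bd(c(0, 78), i34)
#' @export
vp_onset <- function(seq) {
  o <- .onsets(seq)
  if (!length(o)) NA_integer_ else o[length(o)]
}

#' @rdname vp_onset
#' @export
vp_ioi <- function(seq) {
  o <- .onsets(seq)
  if (length(o) < 2L) NA_integer_ else o[length(o)] - o[length(o) - 1L]
}

#' @rdname vp_onset
#' @export
vp_mp <- function(seq, interp) {
  o <- vp_onset(seq)
  if (is.na(o)) return(NA_integer_)
  (o - interp$phase) %% interp$period
}

#' @rdname vp_onset
#' @export
vp_bn <- function(seq, interp) {
  o <- vp_onset(seq)
  if (is.na(o)) return(NA_integer_)
  (o - interp$phase) %/% interp$period
}

#' @rdname vp_onset
#' @export
vp_bd <- function(seq, interp) {
  o <- .onsets(seq)
  if (!length(o)) return(NA_integer_)
  bn_last <- (o[length(o)] - interp$phase) %/% interp$period
  bn_prev <- if (length(o) >= 2L) {
    (o[length(o) - 1L] - interp$phase) %/% interp$period
  } else 0L  # virtual origin: previous bar number taken as 0
  bn_last - bn_prev
}

#' @rdname vp_onset
#' @export
vp_mp_bd <- function(seq, interp) {
  mp <- vp_mp(seq, interp)
  bd <- vp_bd(seq, interp)
  if (is.na(mp) || is.na(bd)) return(NA_integer_)
  c(mp = mp, bd = bd)
}

#' Apply a viewpoint incrementally to all prefixes of a sequence
#'
#' Evaluates the viewpoint on every prefix of increasing length and drops
#' undefined (`NA`) results, mirroring the prefix-wise symbol-sequence
#' construction used to train the sequence models.
#'
#' @param vp a viewpoint function such as [vp_ioi()] or [vp_mp_bd()].
#' @param seq a `rhythm_sequence` or onset vector.
#' @param interp a `metrical_interpretation`, required by metrical viewpoints.
#' @return a list of symbols (integers, or length-2 vectors for linked
#'   viewpoints); never contains `NA`.
#' @examples
#' apply_viewpoint(vp_ioi, c(0, 24, 36))  # the undefined first prefix is dropped
#' @export
apply_viewpoint <- function(vp, seq, interp = NULL) {
  o <- .onsets(seq)
  out <- vector("list", length(o))
  n_out <- 0L
  for (i in seq_along(o)) {
    v <- if (is.null(interp)) vp(o[seq_len(i)]) else vp(o[seq_len(i)], interp)
    if (!anyNA(v)) {
      n_out <- n_out + 1L
      out[[n_out]] <- v
    }
  }
  out[seq_len(n_out)]
}

#' Inter-onset-interval alphabet of a corpus
#'
#' The onset alphabet is built online from the training data: the set of
#' inter-onset intervals observed across all training rhythms. Candidate
#' onsets for a prediction context ending at onset `o` are `o + ioi` for
#' each interval in the alphabet.
#'
#' @param corpus a list of `rhythm_sequence` objects (or onset vectors).
#' @return sorted integer vector of distinct IOIs.
#' @export
ioi_alphabet <- function(corpus) {
  iois <- unlist(lapply(corpus, function(r) diff(.onsets(r))), use.names = FALSE)
  iois <- sort(unique(as.integer(iois)))
  .assert(length(iois) > 0L,
          "corpus contains no inter-onset intervals (all rhythms are singletons)")
  iois
}

#' Candidate next onsets from a previous onset and an IOI alphabet
#'
#' @param prev_onset integer onset in ticks.
#' @param iois integer vector of inter-onset intervals (see [ioi_alphabet()]).
#' @return integer vector `prev_onset + iois`.
#' @export
candidate_onsets <- function(prev_onset, iois) as.integer(prev_onset + iois)

#' Map a linked (mp, bd) symbol back to a concrete onset time
#'
#' Inverse of [vp_mp_bd()] for a fixed previous onset and interpretation:
#' `onset = phase + (bn(prev_onset) + bd) * period + mp`. Results that do not
#' exceed `prev_onset` are unreachable as predictions and should be excluded
#' from candidate sets.
#'
#' @param sym length-2 integer vector `c(mp, bd)`.
#' @param prev_onset onset of the previous event in ticks.
#' @param interp a `metrical_interpretation`.
#' @return integer onset in ticks.
#' @export
symbol_to_onset <- function(sym, prev_onset, interp) {
  .assert(length(sym) == 2L && !anyNA(sym), "sym must be a defined (mp, bd) pair")
  bn_prev <- (as.integer(prev_onset) - interp$phase) %/% interp$period
  as.integer(interp$phase + (bn_prev + sym[[2L]]) * interp$period + sym[[1L]])
}

# Vectorized (mp, bd) encoding of a whole onset vector at a given period and
# phase, using the virtual-origin convention for the first event. Returns a
# list with integer vectors mp and bd.
.mp_bd_encode <- function(onsets, period, phase = 0L) {
  rel <- onsets - phase
  mp <- rel %% period
  bn <- rel %/% period
  bd <- if (length(bn)) c(bn[1L], diff(bn)) else integer(0)
  list(mp = as.integer(mp), bd = as.integer(bd))
}
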