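# Meter-agnostic baseline: a PPM* model over inter-onset intervals that
# predicts the next onset without inferring meter or phase. Used as the
# comparison point for the prediction-error (information-content) analyses.
# First events are never scored (the IOI of a single event is undefined),
# which makes the baseline comparable, event for event, with a meter model
# configured with include_first_event = FALSE.

#' Train the inter-onset-interval baseline model
#'
#' @param corpus list of `rhythm_sequence` objects (annotations ignored).
#' @param order_bound PPM order bound.
#' @param ppm_star use the PPM* starting-context rule.
#' @return an object of class `ioi_model`.
#' @export
train_ioi_model <- function(corpus, order_bound = 1, ppm_star = TRUE) {
  alphabet <- ioi_alphabet(corpus)
  seqs <- lapply(corpus, function(r) match(diff(.onsets(r)), alphabet))
  seqs <- seqs[vapply(seqs, length, 0L) > 0L]
  structure(
    list(alphabet = alphabet,
         ppm = ppm_train(seqs, n_symbols = length(alphabet),
                         order_bound = order_bound, ppm_star = ppm_star),
         order_bound = order_bound),
    class = "ioi_model")
}

#' @export
print.ioi_model <- function(x, ...) {
  cat(sprintf("<ioi_model> %d intervals, order bound %s\n",
              length(x$alphabet), format(x$order_bound)))
  invisible(x)
}

#' Evaluate a rhythm under the IOI baseline
#'
#' Scores every event from the second onward: the candidate next onsets are
#' the previous onset plus each training IOI, the predictive distribution is
#' the smoothed PPM distribution over IOI symbols, and the information
#' content of the observed onset is recorded. An observed IOI not in the
#' alphabet extends the candidate set for that event only, receiving the
#' escape-to-base mass, and is counted as out-of-alphabet.
#'
#' @param model an `ioi_model`.
#' @param rhythm a `rhythm_sequence` (or onset vector).
#' @return a list with `id`, `ic` (bits per scored event), `mean_ic`,
#'   `n_scored` and `n_oov`.
#' @export
evaluate_ioi_model <- function(model, rhythm) {
  stopifnot(inherits(model, "ioi_model"))
  onsets <- .onsets(rhythm)
  iois <- diff(onsets)
  ids <- match(iois, model$alphabet)
  oov <- is.na(ids)
  ids[oov] <- 0L
  ic <- numeric(length(ids))
  for (i in seq_along(ids)) {
    ctx <- ids[seq_len(i - 1L)]
    p <- .ppm_predict_ids(model$ppm, ctx, ids[i])
    # In-alphabet: the full-alphabet distribution sums to 1. Out-of-alphabet:
    # the support is extended by the observed symbol, so renormalize.
    lik <- if (ids[i] == 0L) p / (1 + p) else p
    ic[i] <- -log2(lik)
  }
  list(id = if (inherits(rhythm, "rhythm_sequence")) rhythm$id else "",
       ic = ic, mean_ic = if (length(ic)) mean(ic) else NA_real_,
       n_scored = length(ic), n_oov = sum(oov))
}
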