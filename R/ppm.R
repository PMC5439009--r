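# Variable-order PPM* sequence model over a finite alphabet of integer
# symbol ids 1..n_symbols.
#
# Configuration implemented here: escape method C (the escape weight at a
# context equals the number of distinct symbols observed in it), interpolated
# smoothing (each context level blends its maximum-likelihood weights with
# the next-shorter context's distribution rather than backing off by
# exclusion), a uniform base distribution over the alphabet, and a PPM*
# starting-context rule (shortest deterministic matching context if one
# exists, otherwise the longest matching context), optionally capped by an
# order bound. Only a corpus-trained (long-term) model is provided; there is
# no online short-term component.

#' Train a PPM* model on symbol sequences
#'
#' @param sequences list of integer vectors with values in `1..n_symbols`.
#' @param n_symbols alphabet size; the alphabet is fixed at training time.
#' @param order_bound maximum number of preceding symbols conditioned on
#'   (`Inf` for unbounded). An order bound of `b` means predictions use at
#'   most the last `b` symbols of the context.
#' @param ppm_star if `TRUE` (default), the prediction starts from the
#'   shortest deterministic matching context when one exists; if `FALSE`,
#'   always from the longest matching context within the bound.
#' @return an object of class `ppm_model`.
#' @examples
#' m <- ppm_train(list(c(1L, 1L, 2L)), n_symbols = 2, order_bound = 1)
#' ppm_predict(m, context = 1L)
#' @export
ppm_train <- function(sequences, n_symbols, order_bound = Inf, ppm_star = TRUE) {
  n_symbols <- as.integer(n_symbols)
  .assert(n_symbols >= 1L, "alphabet must contain at least one symbol")
  counts <- new.env(hash = TRUE, parent = emptyenv())
  model <- structure(
    list(n_symbols = n_symbols, order_bound = order_bound,
         ppm_star = isTRUE(ppm_star), counts = counts, n_sequences = 0L),
    class = "ppm_model")
  ppm_add_sequences(model, sequences)
}

#' Add training sequences to an existing PPM model
#'
#' @param model a `ppm_model`.
#' @param sequences list of integer symbol vectors in `1..n_symbols`.
#' @return the updated model (counts are stored in an environment, so the
#'   update is in place; the returned object is the same model).
#' @export
ppm_add_sequences <- function(model, sequences) {
  stopifnot(inherits(model, "ppm_model"))
  counts <- model$counts
  L <- model$order_bound
  for (s in sequences) {
    s <- as.integer(s)
    if (!length(s)) next
    .assert(all(s >= 1L & s <= model$n_symbols),
            "sequence contains symbols outside the alphabet")
    n <- length(s)
    for (i in seq_len(n)) {
      kmax <- min(L, i - 1L)
      sym <- s[i]
      for (k in 0:kmax) {
        key <- if (k == 0L) "k" else
          paste0("k", paste(s[(i - k):(i - 1L)], collapse = ","))
        cur <- counts[[key]]
        if (is.null(cur)) {
          counts[[key]] <- list(sym = sym, cnt = 1, tot = 1)
        } else {
          j <- match(sym, cur$sym)
          if (is.na(j)) {
            cur$sym <- c(cur$sym, sym)
            cur$cnt <- c(cur$cnt, 1)
          } else {
            cur$cnt[j] <- cur$cnt[j] + 1
          }
          cur$tot <- cur$tot + 1
          counts[[key]] <- cur
        }
      }
    }
    model$n_sequences <- model$n_sequences + 1L
  }
  model
}

# Core prediction over integer symbol ids. `query` may contain 0 to denote
# an out-of-alphabet symbol: it never matches any count, so it receives the
# escape-to-base mass of one (virtual) unseen base symbol. The caller is
# responsible for renormalizing when such symbols extend the support.
.ppm_predict_ids <- function(model, context, query) {
  nA <- model$n_symbols
  nc <- length(context)
  kmax <- min(model$order_bound, nc)
  counts <- model$counts
  levels <- vector("list", kmax + 1L)
  n_lv <- 0L
  det <- -1L
  for (k in 0:kmax) {
    key <- if (k == 0L) "k" else
      paste0("k", paste(context[(nc - k + 1L):nc], collapse = ","))
    cur <- counts[[key]]
    if (is.null(cur)) break  # contexts are suffix-closed, longer ones absent
    n_lv <- n_lv + 1L
    levels[[n_lv]] <- cur
    if (det < 0L && length(cur$sym) == 1L) det <- k
  }
  p <- rep.int(1 / nA, length(query))
  if (n_lv > 0L) {
    start <- if (model$ppm_star && det >= 0L) det else n_lv - 1L
    for (k in 0:start) {
      cur <- levels[[k + 1L]]
      t <- length(cur$sym)
      cq <- cur$cnt[match(query, cur$sym)]
      cq[is.na(cq)] <- 0
      p <- (cq + t * p) / (cur$tot + t)
    }
  }
  p
}

#' Predictive distribution of a PPM model
#'
#' Returns the full smoothed distribution over the alphabet given a context,
#' via the interpolated escape-method-C recursion grounded in a uniform base
#' distribution. Every symbol receives strictly positive probability and the
#' distribution sums to one.
#'
#' @param model a `ppm_model`.
#' @param context integer vector of preceding symbol ids (may be empty).
#' @param symbols optional integer vector of symbol ids to evaluate; default
#'   is the whole alphabet. Ids outside the alphabet may be passed as `0` and
#'   receive the escape-to-base mass of a single unseen symbol.
#' @return numeric vector of probabilities, one per requested symbol.
#' @export
ppm_predict <- function(model, context = integer(0), symbols = NULL) {
  stopifnot(inherits(model, "ppm_model"))
  if (is.null(symbols)) symbols <- seq_len(model$n_symbols)
  .ppm_predict_ids(model, as.integer(context), as.integer(symbols))
}

#' Log-likelihood of a symbol sequence under a PPM model
#'
#' Sum over positions of the log2 predictive probability of each symbol
#' given its preceding symbols. The empty sequence has log-likelihood 0.
#'
#' @param model a `ppm_model`.
#' @param seq integer vector of symbol ids.
#' @return log2 probability (non-positive; in bits).
#' @export
ppm_loglik <- function(model, seq) {
  seq <- as.integer(seq)
  ll <- 0
  for (i in seq_along(seq)) {
    ll <- ll + log2(.ppm_predict_ids(model, seq[seq_len(i - 1L)], seq[i]))
  }
  ll
}

#' @export
print.ppm_model <- function(x, ...) {
  cat(sprintf(
    "<ppm_model> alphabet %d, order bound %s, %s, %d training sequences, %d contexts\n",
    x$n_symbols, format(x$order_bound),
    if (x$ppm_star) "PPM*" else "longest-match", x$n_sequences,
    length(ls(x$counts, all.names = TRUE))))
  invisible(x)
}

#' Serialize / restore a PPM model as a plain list (JSON-safe)
#'
#' @param model a `ppm_model`.
#' @return `ppm_as_list` returns a versioned plain list; `ppm_from_list`
#'   rebuilds the model from such a list (e.g. after
#'   `jsonlite::fromJSON(..., simplifyVector = FALSE)`).
#' @export
ppm_as_list <- function(model) {
  stopifnot(inherits(model, "ppm_model"))
  keys <- ls(model$counts, all.names = TRUE)
  list(format = "rhythmeter-ppm", version = 1L,
       n_symbols = model$n_symbols,
       order_bound = if (is.finite(model$order_bound))
         model$order_bound else "unbounded",
       ppm_star = model$ppm_star,
       n_sequences = model$n_sequences,
       contexts = stats::setNames(
         lapply(keys, function(k) {
           cur <- model$counts[[k]]
           list(sym = as.integer(cur$sym), cnt = as.numeric(cur$cnt))
         }), keys))
}

#' @rdname ppm_as_list
#' @param x a list produced by `ppm_as_list` (possibly round-tripped
#'   through JSON).
#' @export
ppm_from_list <- function(x) {
  .assert(identical(x$format, "rhythmeter-ppm"), "not a serialized PPM model")
  ob <- x$order_bound
  if (identical(ob, "unbounded")) ob <- Inf
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (k in names(x$contexts)) {
    cur <- x$contexts[[k]]
    sym <- as.integer(unlist(cur$sym))
    cnt <- as.numeric(unlist(cur$cnt))
    counts[[k]] <- list(sym = sym, cnt = cnt, tot = sum(cnt))
  }
  structure(list(n_symbols = as.integer(x$n_symbols), order_bound = ob,
                 ppm_star = isTRUE(x$ppm_star), counts = counts,
                 n_sequences = as.integer(x$n_sequences %||% 0L)),
            class = "ppm_model")
}
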