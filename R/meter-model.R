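# The generative model of meter and its Bayesian inversion.
#
# A rhythm is modeled as generated by (i) drawing a metrical category m from
# a prior p(m), (ii) drawing a phase uniformly over the sixteenth-note grid
# of the category's bar period, and (iii) emitting onsets from a
# per-category PPM* sequence model over linked metrical-position /
# bar-distance (mp (x) bd) symbols. Inference inverts this model: the
# posterior over interpretations (m, phi) is updated incrementally with the
# per-event likelihood of each observed onset, and the predictive onset
# distribution marginalizes the per-interpretation predictions over the
# posterior. Prediction error is measured as information content, the
# negative log2 probability of the observed onset.

# ---- per-category symbol coding --------------------------------------------

# Symbol ids enumerate the (mp, bd) alphabet of a category in ascending
# lexicographic (mp, bd) order: id = mp * n_bd + (bd - bd_min) + 1.
# Id 0 marks an out-of-alphabet symbol (bd outside the trained range).
.sym_id <- function(mp, bd, n_bd, bd_min) {
  id <- mp * n_bd + (bd - bd_min) + 1L
  id[bd < bd_min | bd > bd_min + n_bd - 1L] <- 0L
  as.integer(id)
}

.new_category_model <- function(period, bd_min, bd_max, order_bound, ppm_star,
                                train_ids = list()) {
  n_bd <- bd_max - bd_min + 1L
  list(period = as.integer(period), bd_min = as.integer(bd_min),
       bd_max = as.integer(bd_max), n_bd = n_bd,
       ppm = ppm_train(train_ids, n_symbols = period * n_bd,
                       order_bound = order_bound, ppm_star = ppm_star))
}

.interp_grid <- function(categories) {
  # categories: data.frame(label, period), sorted by label
  do.call(rbind, lapply(seq_len(nrow(categories)), function(i) {
    phases <- seq.int(0L, categories$period[i] - .phase_res, by = .phase_res)
    data.frame(cat = i, label = categories$label[i],
               period = categories$period[i], phase = phases,
               stringsAsFactors = FALSE)
  }))
}

# ---- priors ----------------------------------------------------------------

#' Estimate the prior over metrical categories and interpretations
#'
#' The category prior is the maximum-likelihood estimate `p(m) = N_m / N`
#' from the annotated training rhythms. Each interpretation `(m, phi)` then
#' receives mass proportional to `p(m)`, with a normalizer that compensates
#' for period length so that categories with many admissible phases are not
#' penalized: `p(m, phi) = p(m) / sum_m' n(m') p(m')`, where `n(m')` is the
#' number of sixteenth-note phases `period / 6` (default) or the period in
#' ticks (`eq4_normalizer = "ticks"`). The two normalizers give identical
#' posteriors (they differ by a constant factor); only the "phases" choice
#' makes the interpretation prior sum to exactly 1 on the searched grid.
#'
#' @param corpus list of annotated `rhythm_sequence` objects.
#' @param eq4_normalizer `"phases"` or `"ticks"`; see Details.
#' @return list with `prior_m` (named numeric) and `prior_interp`
#'   (data.frame with columns `label`, `period`, `phase`, `p`).
#' @export
estimate_prior <- function(corpus, eq4_normalizer = c("phases", "ticks")) {
  eq4_normalizer <- match.arg(eq4_normalizer)
  labels <- vapply(corpus, function(r) r$meter %||% NA_character_, "")
  .assert(!anyNA(labels), "every rhythm must carry exactly one meter annotation")
  .assert(length(labels) > 0L, "empty corpus")
  tab <- table(labels)
  prior_m <- as.numeric(tab) / sum(tab)
  names(prior_m) <- names(tab)
  cats <- data.frame(label = names(tab),
                     period = vapply(names(tab),
                                     function(l) meter_category(l)$period, 0L),
                     stringsAsFactors = FALSE)
  list(prior_m = prior_m,
       prior_interp = .prior_interp(cats, prior_m, eq4_normalizer))
}

.prior_interp <- function(categories, prior_m, eq4_normalizer = "phases") {
  grid <- .interp_grid(categories)
  nphase <- if (eq4_normalizer == "phases") {
    categories$period / .phase_res
  } else {
    categories$period
  }
  z <- sum(nphase * prior_m[categories$label])
  grid$p <- as.numeric(prior_m[grid$label]) / z
  grid
}

# ---- model training --------------------------------------------------------

#' Train the generative meter model
#'
#' Fits one PPM* sequence model per metrical category occurring in the
#' training data, each trained only on the rhythms annotated with that
#' category, interpreted at their annotated meter and phase 0. The symbol
#' alphabet of a category is the Cartesian product of metrical positions
#' `{0, ..., period - 1}` and a bar-distance range wide enough to cover
#' every inter-onset interval observed in training. The category prior is
#' estimated by relative frequency (see [estimate_prior()]).
#'
#' @param corpus list of annotated `rhythm_sequence` objects.
#' @param order_bound PPM order bound (0 to 4 in typical use; `Inf` allowed).
#' @param ppm_star use the PPM* deterministic starting-context rule.
#' @param include_first_event if `TRUE` (default), the first event of every
#'   rhythm is encoded with a virtual previous bar number of 0 and enters
#'   both training and inference, so a rhythm starting on or off the downbeat
#'   provides phase evidence. If `FALSE`, first events are dropped, matching
#'   the strict prefix-function convention under which the bar-distance
#'   viewpoint is undefined for a single event.
#' @param eq4_normalizer normalizer for the interpretation prior; see
#'   [estimate_prior()].
#' @return an object of class `meter_model`.
#' @export
train_meter_model <- function(corpus, order_bound = 1, ppm_star = TRUE,
                              include_first_event = TRUE,
                              eq4_normalizer = c("phases", "ticks")) {
  eq4_normalizer <- match.arg(eq4_normalizer)
  .assert(length(corpus) > 0L, "empty corpus")
  labels <- vapply(corpus, function(r) r$meter %||% NA_character_, "")
  .assert(!anyNA(labels), "every training rhythm must carry a meter annotation")
  iois <- ioi_alphabet(corpus)
  cat_labels <- sort(unique(labels))
  categories <- data.frame(
    label = cat_labels,
    period = vapply(cat_labels, function(l) meter_category(l)$period, 0L),
    stringsAsFactors = FALSE)

  models <- vector("list", nrow(categories))
  names(models) <- categories$label
  for (i in seq_len(nrow(categories))) {
    T <- categories$period[i]
    rs <- corpus[labels == categories$label[i]]
    enc <- lapply(rs, function(r) .mp_bd_encode(r$onsets, T, 0L))
    bds <- unlist(lapply(enc, `[[`, "bd"), use.names = FALSE)
    bd_min <- min(0L, bds)
    bd_max <- max(1L, bds, as.integer(ceiling(max(iois) / T)))
    n_bd <- bd_max - bd_min + 1L
    train_ids <- lapply(enc, function(e) {
      ids <- .sym_id(e$mp, e$bd, n_bd, bd_min)
      if (!include_first_event && length(ids)) ids[-1L] else ids
    })
    train_ids <- train_ids[vapply(train_ids, length, 0L) > 0L]
    models[[i]] <- .new_category_model(T, bd_min, bd_max, order_bound,
                                       ppm_star, train_ids)
  }

  prior_m <- as.numeric(table(labels)[categories$label])
  prior_m <- prior_m / sum(prior_m)
  names(prior_m) <- categories$label

  structure(
    list(categories = categories, prior_m = prior_m,
         prior_interp = .prior_interp(categories, prior_m, eq4_normalizer),
         interps = .interp_grid(categories), models = models,
         ioi = iois, order_bound = order_bound, ppm_star = isTRUE(ppm_star),
         include_first_event = isTRUE(include_first_event),
         eq4_normalizer = eq4_normalizer),
    class = "meter_model")
}

#' Construct an untrained (prior-only) meter model
#'
#' Useful for studying the effect of priors in isolation: every per-category
#' sequence model is empty, so all per-event likelihoods fall through to the
#' uniform base distribution.
#'
#' @param labels character vector of time-signature labels.
#' @param iois integer IOI alphabet (candidate-set construction).
#' @param prior_m optional named prior over `labels` (default uniform).
#' @inheritParams train_meter_model
#' @return a `meter_model`.
#' @export
prior_only_meter_model <- function(labels, iois, prior_m = NULL,
                                   order_bound = 1, ppm_star = TRUE,
                                   include_first_event = TRUE,
                                   eq4_normalizer = c("phases", "ticks")) {
  eq4_normalizer <- match.arg(eq4_normalizer)
  labels <- sort(unique(labels))
  iois <- sort(unique(as.integer(iois)))
  categories <- data.frame(
    label = labels,
    period = vapply(labels, function(l) meter_category(l)$period, 0L),
    stringsAsFactors = FALSE)
  models <- lapply(seq_along(labels), function(i) {
    T <- categories$period[i]
    .new_category_model(T, 0L, max(1L, as.integer(ceiling(max(iois) / T))),
                        order_bound, ppm_star)
  })
  names(models) <- labels
  if (is.null(prior_m)) {
    prior_m <- stats::setNames(rep(1 / length(labels), length(labels)), labels)
  } else {
    .assert(setequal(names(prior_m), labels), "prior names must match labels")
    .assert(abs(sum(prior_m) - 1) < 1e-8, "prior must sum to 1")
    prior_m <- prior_m[labels]
  }
  structure(
    list(categories = categories, prior_m = prior_m,
         prior_interp = .prior_interp(categories, prior_m, eq4_normalizer),
         interps = .interp_grid(categories), models = models,
         ioi = iois, order_bound = order_bound, ppm_star = isTRUE(ppm_star),
         include_first_event = isTRUE(include_first_event),
         eq4_normalizer = eq4_normalizer),
    class = "meter_model")
}

#' Replace the category prior of a trained meter model
#'
#' Sets `p(m)` to manually chosen values (e.g. to induce an inferential
#' bias) and recomputes the interpretation prior; the per-category sequence
#' models are untouched, so differences in behavior are attributable to the
#' prior alone.
#'
#' @param model a `meter_model`.
#' @param prior_m named numeric vector over the model's categories, summing
#'   to 1.
#' @return the modified `meter_model`.
#' @export
set_manual_prior <- function(model, prior_m) {
  stopifnot(inherits(model, "meter_model"))
  .assert(setequal(names(prior_m), model$categories$label),
          "prior categories must match the trained categories")
  .assert(abs(sum(prior_m) - 1) < 1e-8, "prior must sum to 1")
  model$prior_m <- prior_m[model$categories$label]
  model$prior_interp <- .prior_interp(model$categories, model$prior_m,
                                      model$eq4_normalizer)
  model
}

#' @export
print.meter_model <- function(x, ...) {
  cat(sprintf("<meter_model> %d categories (%s), %d interpretations, order bound %s\n",
              nrow(x$categories), paste(x$categories$label, collapse = ", "),
              nrow(x$interps), format(x$order_bound)))
  invisible(x)
}

# ---- per-event likelihood --------------------------------------------------

# Likelihood of `next_onset` for interpretation row j given preceding onsets.
# syms: precomputed symbol ids of the whole rhythm under interpretation j
# (may be NULL, in which case they are computed on the fly).
.event_lik_j <- function(gm, j, onsets, i, syms = NULL) {
  interps <- gm$interps
  T <- interps$period[j]
  phi <- interps$phase[j]
  md <- gm$models[[interps$cat[j]]]
  first_i <- if (gm$include_first_event) 1L else 2L
  if (is.null(syms)) {
    enc <- .mp_bd_encode(onsets[seq_len(i)], T, phi)
    syms <- .sym_id(enc$mp, enc$bd, md$n_bd, md$bd_min)
  }
  if (i == 1L) {
    # First event: the candidate set is the category's full symbol alphabet.
    s <- syms[1L]
    p <- .ppm_predict_ids(md$ppm, integer(0), s)
    if (s == 0L) p / (1 + p) else p
  } else {
    prev <- onsets[i - 1L]
    obs <- onsets[i]
    cand <- prev + gm$ioi
    oi <- match(obs, cand)
    if (is.na(oi)) {  # unseen IOI: extend the candidate set for this event
      cand <- c(cand, obs)
      oi <- length(cand)
    }
    bn_prev <- (prev - phi) %/% T
    mpc <- (cand - phi) %% T
    bdc <- (cand - phi) %/% T - bn_prev
    ids <- .sym_id(mpc, bdc, md$n_bd, md$bd_min)
    ctx <- if (i - 1L >= first_i) syms[first_i:(i - 1L)] else integer(0)
    p <- .ppm_predict_ids(md$ppm, ctx, ids)
    p[oi] / sum(p)
  }
}

#' Per-event likelihood of an onset under one interpretation
#'
#' Probability that the generative model, restricted to interpretation
#' `(category, phase)`, emits `next_onset` after the context. The candidate
#' set is the previous onset plus each training IOI (the full symbol
#' alphabet for the first event); candidate probabilities are read from the
#' category's PPM model via the one-to-one (mp, bd)-to-onset mapping and
#' renormalized over the candidate set. An observed onset whose IOI never
#' occurred in training extends the candidate set for that event only.
#'
#' @param model a `meter_model`.
#' @param category time-signature label of the interpretation.
#' @param phase phase of the interpretation in ticks.
#' @param context integer vector of preceding onsets (may be empty when the
#'   model includes first events).
#' @param next_onset the onset whose probability is evaluated; must exceed
#'   the last context onset.
#' @return a probability in (0, 1].
#' @export
per_event_likelihood <- function(model, category, phase, context, next_onset) {
  stopifnot(inherits(model, "meter_model"))
  context <- as.integer(context)
  if (length(context)) .assert(next_onset > context[length(context)],
                               "next_onset must exceed the last context onset")
  j <- which(model$interps$label == category & model$interps$phase == phase)
  .assert(length(j) == 1L, "unknown interpretation")
  onsets <- c(context, as.integer(next_onset))
  .event_lik_j(model, j, onsets, length(onsets))
}

# ---- posterior inference ---------------------------------------------------

#' Initial posterior state over metrical interpretations
#'
#' @param model a `meter_model`.
#' @return an object of class `posterior_state` holding log2 weights per
#'   interpretation (initially the interpretation prior) and the number of
#'   events observed so far.
#' @export
initial_posterior <- function(model) {
  stopifnot(inherits(model, "meter_model"))
  structure(list(log_weights = log2(model$prior_interp$p),
                 interps = model$interps, n_events = 0L),
            class = "posterior_state")
}

#' @export
print.posterior_state <- function(x, ...) {
  p <- posterior_probabilities(x)
  top <- order(p$p, decreasing = TRUE)[seq_len(min(3L, nrow(p)))]
  cat(sprintf("<posterior_state> %d events; top: %s\n", x$n_events,
              paste(sprintf("%s@%d (%.3f)", p$label[top], p$phase[top],
                            p$p[top]), collapse = ", ")))
  invisible(x)
}

#' Normalized posterior probabilities of a posterior state
#'
#' @param state a `posterior_state`.
#' @return data.frame with columns `label`, `period`, `phase`, `p`.
#' @export
posterior_probabilities <- function(state) {
  lw <- state$log_weights
  w <- 2^(lw - max(lw))
  out <- state$interps
  out$p <- w / sum(w)
  out
}

#' Update the posterior with one observed event
#'
#' Multiplies each interpretation's weight by the per-event likelihood of
#' `new_onset` and renormalizes (in the log2 domain, with a max-shift for
#' numerical stability).
#'
#' @param model a `meter_model`.
#' @param state a `posterior_state`.
#' @param context integer vector of the onsets already observed.
#' @param new_onset the newly observed onset in ticks.
#' @return the updated `posterior_state`.
#' @export
update_posterior <- function(model, state, context, new_onset) {
  stopifnot(inherits(model, "meter_model"), inherits(state, "posterior_state"))
  onsets <- c(as.integer(context), as.integer(new_onset))
  i <- length(onsets)
  if (i == 1L && !model$include_first_event) {
    # first events carry no evidence under this configuration
    state$n_events <- state$n_events + 1L
    return(state)
  }
  lik <- vapply(seq_len(nrow(model$interps)),
                function(j) .event_lik_j(model, j, onsets, i), 0)
  .assert(all(lik > 0), "per-event likelihoods must be positive")
  lw <- state$log_weights + log2(lik)
  state$log_weights <- lw - max(lw)
  state$n_events <- state$n_events + 1L
  state
}

#' Predictive distribution over the next onset
#'
#' Marginalizes the per-interpretation candidate-onset distributions over
#' the current posterior: `p(o) = sum_(m,phi) p(o | m, phi, context) *
#' p(m, phi | context)`.
#'
#' @param model a `meter_model`.
#' @param state a `posterior_state` consistent with `context`.
#' @param context integer vector of observed onsets (non-empty).
#' @return data.frame with columns `onset` and `p`, summing to 1; all
#'   candidate onsets exceed the last context onset.
#' @export
predictive_distribution <- function(model, state, context) {
  stopifnot(inherits(model, "meter_model"), inherits(state, "posterior_state"))
  context <- as.integer(context)
  .assert(length(context) >= 1L,
          "predictive distribution requires at least one observed onset")
  prev <- context[length(context)]
  cand <- prev + model$ioi
  post <- posterior_probabilities(state)$p
  i <- length(context) + 1L
  pmix <- numeric(length(cand))
  for (j in seq_len(nrow(model$interps))) {
    pj <- vapply(seq_along(cand), function(ci)
      .event_lik_j(model, j, c(context, cand[ci]), i), 0)
    pmix <- pmix + post[j] * pj
  }
  data.frame(onset = cand, p = pmix)
}

# ---- whole-rhythm evaluation -----------------------------------------------

# Fast inference over a whole rhythm: per-event information content under
# the marginal predictive distribution, incremental posterior updates, and
# the final posterior. Returns scored event indices, their IC, the final
# normalized posterior and an out-of-alphabet IOI count.
.meter_trace <- function(gm, onsets) {
  interps <- gm$interps
  nI <- nrow(interps)
  nE <- length(onsets)
  first_i <- if (gm$include_first_event) 1L else 2L
  syms <- vector("list", nI)
  for (j in seq_len(nI)) {
    md <- gm$models[[interps$cat[j]]]
    enc <- .mp_bd_encode(onsets, interps$period[j], interps$phase[j])
    syms[[j]] <- .sym_id(enc$mp, enc$bd, md$n_bd, md$bd_min)
  }
  lw <- log2(gm$prior_interp$p)
  ic <- rep(NA_real_, nE)
  n_oov <- 0L
  if (nE >= first_i) {
    for (i in first_i:nE) {
      lik <- numeric(nI)
      if (i > 1L && is.na(match(onsets[i] - onsets[i - 1L], gm$ioi))) {
        n_oov <- n_oov + 1L
      }
      for (j in seq_len(nI)) {
        lik[j] <- .event_lik_j(gm, j, onsets, i, syms[[j]])
      }
      w <- 2^(lw - max(lw))
      w <- w / sum(w)
      ic[i] <- -log2(sum(w * lik))
      lw <- lw + log2(lik)
      lw <- lw - max(lw)
    }
  }
  post <- 2^(lw - max(lw))
  scored <- if (nE >= first_i) first_i:nE else integer(0)
  list(posterior = post / sum(post), ic = ic[scored], scored = scored,
       n_oov = n_oov)
}

#' Classify a rhythm into a metrical interpretation
#'
#' Returns the interpretation with the highest posterior probability after
#' the entire rhythm has been observed. Ties are broken deterministically by
#' category label (alphabetical) and then smallest phase.
#'
#' @param model a `meter_model`.
#' @param rhythm a `rhythm_sequence` (or onset vector).
#' @return a `metrical_interpretation`.
#' @export
classify_rhythm <- function(model, rhythm) {
  stopifnot(inherits(model, "meter_model"))
  onsets <- .onsets(rhythm)
  .assert(length(onsets) >= 1L, "cannot classify an empty rhythm")
  tr <- .meter_trace(model, onsets)
  j <- which.max(tr$posterior)  # interps are sorted by (label, phase)
  metrical_interpretation(model$interps$label[j], model$interps$phase[j])
}

#' Information content of a probability
#'
#' `-log2(p)`: the model's operationalization of prediction error in bits.
#'
#' @param p probability in (0, 1].
#' @return bits (non-negative).
#' @export
information_content <- function(p) {
  .assert(all(p > 0 & p <= 1), "p must lie in (0, 1]")
  -log2(p)
}

#' Evaluate a rhythm: prediction error and classification
#'
#' Runs the predictive-coding loop over the rhythm (predict the next onset
#' from the posterior-marginalized distribution, observe it, update the
#' posterior) and records the information content of every scored event, the
#' classification, and its correctness against the annotation (category must
#' match and the inferred phase must be 0, since annotated corpora are
#' encoded at phase zero).
#'
#' @param model a `meter_model`.
#' @param rhythm a `rhythm_sequence`.
#' @return an object of class `meter_evaluation`: a list with `id`,
#'   `annotation`, `category`, `phase`, `correct` (`NA` when unannotated),
#'   `ic` (per scored event, bits), `mean_ic` (`NA` if no events were
#'   scored), `n_scored`, `n_oov` and the final `posterior` data.frame.
#' @export
evaluate_rhythm <- function(model, rhythm) {
  stopifnot(inherits(model, "meter_model"))
  if (!inherits(rhythm, "rhythm_sequence")) rhythm <- rhythm_sequence(rhythm)
  onsets <- rhythm$onsets
  .assert(length(onsets) >= 1L, "cannot evaluate an empty rhythm")
  tr <- .meter_trace(model, onsets)
  j <- which.max(tr$posterior)
  post <- model$interps
  post$p <- tr$posterior
  correct <- if (is.null(rhythm$meter)) NA else {
    identical(model$interps$label[j], rhythm$meter) &&
      model$interps$phase[j] == 0L
  }
  structure(
    list(id = rhythm$id, annotation = rhythm$meter,
         category = model$interps$label[j], phase = model$interps$phase[j],
         correct = correct, ic = tr$ic,
         mean_ic = if (length(tr$ic)) mean(tr$ic) else NA_real_,
         n_scored = length(tr$ic), n_oov = tr$n_oov, posterior = post),
    class = "meter_evaluation")
}

#' @export
print.meter_evaluation <- function(x, ...) {
  cat(sprintf(
    "<meter_evaluation '%s'> classified %s@%d%s; mean IC %.3f bits over %d events\n",
    x$id, x$category, x$phase,
    if (is.na(x$correct)) "" else if (x$correct) " (correct)" else
      sprintf(" (annotated %s)", x$annotation),
    x$mean_ic, x$n_scored))
  invisible(x)
}

#' Serialize / restore a meter model as a plain list (JSON-safe)
#'
#' Together with [jsonlite::toJSON()] / [jsonlite::fromJSON()] this allows a
#' trained generative model to be written to disk and reused across
#' sessions or command-line invocations.
#'
#' @param model a `meter_model`.
#' @return `meter_model_as_list` returns a versioned plain list;
#'   `meter_model_from_list` rebuilds the model.
#' @export
meter_model_as_list <- function(model) {
  stopifnot(inherits(model, "meter_model"))
  list(format = "rhythmeter-meter-model", version = 1L,
       categories = model$categories,
       prior_m = as.list(model$prior_m),
       ioi = model$ioi,
       order_bound = if (is.finite(model$order_bound))
         model$order_bound else "unbounded",
       ppm_star = model$ppm_star,
       include_first_event = model$include_first_event,
       eq4_normalizer = model$eq4_normalizer,
       models = lapply(model$models, function(md) {
         list(period = md$period, bd_min = md$bd_min, bd_max = md$bd_max,
              ppm = ppm_as_list(md$ppm))
       }))
}

#' @rdname meter_model_as_list
#' @param x a list produced by `meter_model_as_list` (possibly round-tripped
#'   through JSON with `simplifyVector = FALSE`).
#' @export
meter_model_from_list <- function(x) {
  .assert(identical(x$format, "rhythmeter-meter-model"),
          "not a serialized meter model")
  labels <- as.character(unlist(lapply(x$categories, `[[`, "label")) %||%
                           x$categories$label)
  periods <- as.integer(unlist(lapply(x$categories, `[[`, "period")) %||%
                          x$categories$period)
  categories <- data.frame(label = labels, period = periods,
                           stringsAsFactors = FALSE)
  ob <- x$order_bound
  if (identical(ob, "unbounded")) ob <- Inf
  models <- lapply(x$models, function(md) {
    list(period = as.integer(md$period), bd_min = as.integer(md$bd_min),
         bd_max = as.integer(md$bd_max),
         n_bd = as.integer(md$bd_max) - as.integer(md$bd_min) + 1L,
         ppm = ppm_from_list(md$ppm))
  })
  names(models) <- names(x$models)
  prior_m <- unlist(x$prior_m)[categories$label]
  structure(
    list(categories = categories, prior_m = prior_m,
         prior_interp = .prior_interp(categories, prior_m,
                                      x$eq4_normalizer %||% "phases"),
         interps = .interp_grid(categories),
         models = models[categories$label],
         ioi = as.integer(unlist(x$ioi)), order_bound = ob,
         ppm_star = isTRUE(x$ppm_star),
         include_first_event = isTRUE(x$include_first_event),
         eq4_normalizer = x$eq4_normalizer %||% "phases"),
    class = "meter_model")
}

#' Evaluate a corpus of rhythms
#'
#' @param model a `meter_model`.
#' @param corpus list of `rhythm_sequence` objects.
#' @return data.frame with one row per rhythm: `id`, `annotation`,
#'   `category`, `phase`, `correct`, `mean_ic`, `n_scored`, `n_oov`.
#' @export
evaluate_corpus <- function(model, corpus) {
  rows <- lapply(corpus, function(r) {
    ev <- evaluate_rhythm(model, r)
    data.frame(id = ev$id, annotation = ev$annotation %||% NA_character_,
               category = ev$category, phase = ev$phase,
               correct = if (is.na(ev$correct)) NA else ev$correct,
               mean_ic = ev$mean_ic, n_scored = ev$n_scored,
               n_oov = ev$n_oov, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
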