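# Simulation harnesses: cross-validated classification vs order bound,
# prediction-error comparison against the IOI baseline, the
# inferential-bias contrast on the exhaustive grid test set, and the
# enculturation train/test matrix.

#' Cross-validated meter classification and prediction error
#'
#' Trains and evaluates the meter model on `k` seeded folds for each order
#' bound. Fold-level scores (proportion of rhythms whose inferred category
#' and phase match the annotation; mean per-rhythm information content) are
#' computed first and then averaged across folds; per-event pooled averaging
#' is available via `aggregate = "pooled"`.
#'
#' @param corpus an annotated `rhythm_corpus`.
#' @param order_bounds integer vector of PPM order bounds to compare.
#' @param k number of folds.
#' @param seed RNG seed for the fold assignment.
#' @param include_first_event passed to [train_meter_model()].
#' @param stratify stratify folds by meter annotation.
#' @param aggregate `"fold"` (average of fold averages, the default) or
#'   `"pooled"` (weight folds by their number of scored rhythms/events).
#' @return data.frame with one row per order bound: `order_bound`,
#'   `accuracy`, `accuracy_sd`, `mean_ic`, `ic_sd` (SDs across folds); the
#'   fold-level results are attached as attribute `"folds"`.
#' @export
run_crossval <- function(corpus, order_bounds = 0:4, k = 10, seed = 1,
                         include_first_event = TRUE, stratify = FALSE,
                         aggregate = c("fold", "pooled")) {
  aggregate <- match.arg(aggregate)
  fold <- make_folds(corpus, k = k, seed = seed, stratify = stratify)
  detail <- list()
  for (b in order_bounds) {
    for (f in seq_len(k)) {
      gm <- train_meter_model(corpus[fold != f], order_bound = b,
                              include_first_event = include_first_event)
      ev <- evaluate_corpus(gm, corpus[fold == f])
      detail[[length(detail) + 1L]] <- data.frame(
        order_bound = b, fold = f, n = nrow(ev),
        accuracy = mean(ev$correct), mean_ic = mean(ev$mean_ic),
        n_events = sum(ev$n_scored))
    }
  }
  detail <- do.call(rbind, detail)
  out <- do.call(rbind, lapply(order_bounds, function(b) {
    d <- detail[detail$order_bound == b, ]
    if (aggregate == "fold") {
      data.frame(order_bound = b, accuracy = mean(d$accuracy),
                 accuracy_sd = stats::sd(d$accuracy),
                 mean_ic = mean(d$mean_ic), ic_sd = stats::sd(d$mean_ic))
    } else {
      data.frame(order_bound = b,
                 accuracy = sum(d$accuracy * d$n) / sum(d$n),
                 accuracy_sd = stats::sd(d$accuracy),
                 mean_ic = sum(d$mean_ic * d$n) / sum(d$n),
                 ic_sd = stats::sd(d$mean_ic))
    }
  }))
  attr(out, "folds") <- detail
  out
}

#' Compare the meter model with the meter-agnostic IOI baseline
#'
#' Both models are trained and evaluated on identical folds and score
#' exactly the same events: every event from the second onward (the meter
#' model is run with `include_first_event = FALSE` so that its scored
#' events coincide with those of the baseline, whose first event has no
#' defined inter-onset interval).
#'
#' @inheritParams run_crossval
#' @return data.frame with one row per order bound: `order_bound`,
#'   `meter_ic`, `meter_ic_sd`, `baseline_ic`, `baseline_ic_sd`,
#'   `n_events`; fold-level results attached as attribute `"folds"`.
#' @export
run_baseline_comparison <- function(corpus, order_bounds = 0:4, k = 10,
                                    seed = 1, stratify = FALSE) {
  fold <- make_folds(corpus, k = k, seed = seed, stratify = stratify)
  detail <- list()
  for (b in order_bounds) {
    for (f in seq_len(k)) {
      tr <- corpus[fold != f]
      te <- corpus[fold == f]
      gm <- train_meter_model(tr, order_bound = b,
                              include_first_event = FALSE)
      bl <- train_ioi_model(tr, order_bound = b)
      ev_m <- evaluate_corpus(gm, te)
      ev_b <- lapply(te, evaluate_ioi_model, model = bl)
      n_b <- vapply(ev_b, `[[`, 0L, "n_scored")
      .assert(all(ev_m$n_scored == n_b),
              "meter model and baseline scored different event counts")
      detail[[length(detail) + 1L]] <- data.frame(
        order_bound = b, fold = f, n = nrow(ev_m),
        meter_ic = mean(ev_m$mean_ic),
        baseline_ic = mean(vapply(ev_b, `[[`, 0, "mean_ic")),
        n_events = sum(ev_m$n_scored))
    }
  }
  detail <- do.call(rbind, detail)
  out <- do.call(rbind, lapply(order_bounds, function(b) {
    d <- detail[detail$order_bound == b, ]
    data.frame(order_bound = b,
               meter_ic = mean(d$meter_ic),
               meter_ic_sd = stats::sd(d$meter_ic),
               baseline_ic = mean(d$baseline_ic),
               baseline_ic_sd = stats::sd(d$baseline_ic),
               n_events = sum(d$n_events))
  }))
  attr(out, "folds") <- detail
  out
}

#' Manually biased priors for the inferential-bias contrast
#'
#' The two prior settings contrasted in the bias simulation over the
#' categories 2/4, 3/4 and 6/8: the `"3/4"`-biased prior is (4/9, 4/9, 1/9)
#' and the `"6/8"`-biased prior is (4/9, 1/9, 4/9).
#'
#' @param bias `"3/4"` or `"6/8"`.
#' @return named numeric prior over c("2/4", "3/4", "6/8").
#' @export
bias_prior <- function(bias = c("3/4", "6/8")) {
  bias <- match.arg(bias)
  if (bias == "3/4") {
    c(`2/4` = 4 / 9, `3/4` = 4 / 9, `6/8` = 1 / 9)
  } else {
    c(`2/4` = 4 / 9, `3/4` = 1 / 9, `6/8` = 4 / 9)
  }
}

#' Inferential-bias experiment
#'
#' Trains one generative model on the (balanced) training corpus, creates
#' two copies differing only in a manually set category prior, classifies
#' every rhythm of the test set under both, and tabulates agreement.
#'
#' @param train_corpus annotated training corpus (typically balanced over
#'   2/4, 3/4 and 6/8 so the sequence models are matched).
#' @param prior_a,prior_b named priors for the two contrasted models (by
#'   default the `"3/4"`- and `"6/8"`-biased priors of [bias_prior()]).
#' @param test_corpus unannotated test rhythms; defaults to the exhaustive
#'   [grid_test_set()].
#' @param order_bound PPM order bound.
#' @return a list with `table` (a contingency matrix of category
#'   classifications, model B in rows, model A in columns, with margins),
#'   `disagreements` (data.frame `id`, `model_a`, `model_b`) and `n`.
#' @export
run_bias_experiment <- function(train_corpus, prior_a = bias_prior("3/4"),
                                prior_b = bias_prior("6/8"),
                                test_corpus = grid_test_set(),
                                order_bound = 4) {
  gm <- train_meter_model(train_corpus, order_bound = order_bound)
  gm_a <- set_manual_prior(gm, prior_a)
  gm_b <- set_manual_prior(gm, prior_b)
  labels <- gm$categories$label
  cl_a <- vapply(test_corpus, function(r) classify_rhythm(gm_a, r)$label, "")
  cl_b <- vapply(test_corpus, function(r) classify_rhythm(gm_b, r)$label, "")
  tab <- table(factor(cl_b, levels = labels), factor(cl_a, levels = labels))
  tab <- stats::addmargins(tab, FUN = list(All = sum), quiet = TRUE)
  names(dimnames(tab)) <- c("model_b", "model_a")
  dis <- which(cl_a != cl_b)
  list(table = tab,
       disagreements = data.frame(
         id = vapply(test_corpus[dis], `[[`, "", "id"),
         model_a = cl_a[dis], model_b = cl_b[dis],
         stringsAsFactors = FALSE),
       n = length(test_corpus))
}

#' Enculturation experiment: train/test matrix across two cultures
#'
#' Trains one model per culture and evaluates both on both held-out test
#' sets, reporting the 2x2 matrices of mean information content and
#' classification accuracy, per-rhythm mean-IC pairs, and the
#' product-moment correlation between the two models' per-rhythm ICs within
#' each test set.
#'
#' @param train_a,train_b annotated training corpora of cultures A and B.
#' @param test_a,test_b held-out test corpora; ids must not overlap with
#'   the corresponding training corpora.
#' @param order_bound PPM order bound.
#' @param prior_mode `"empirical"` (each model's prior estimated from its
#'   own training set) or `"shared"` (both models get the pooled empirical
#'   category distribution; requires identical category sets).
#' @param include_first_event passed to [train_meter_model()].
#' @return a list with `ic` and `accuracy` (2x2 matrices, training culture
#'   in rows, test culture in columns), `per_rhythm` (data.frame `test_set`,
#'   `id`, `ic_a`, `ic_b`) and `correlation` (named vector, one entry per
#'   test set).
#' @export
run_enculturation <- function(train_a, train_b, test_a, test_b,
                              order_bound = 4,
                              prior_mode = c("empirical", "shared"),
                              include_first_event = TRUE) {
  prior_mode <- match.arg(prior_mode)
  ids <- function(cs) vapply(cs, `[[`, "", "id")
  .assert(!length(intersect(ids(train_a), ids(test_a))) &&
            !length(intersect(ids(train_b), ids(test_b))),
          "train and test sets must not overlap")
  gm_a <- train_meter_model(train_a, order_bound = order_bound,
                            include_first_event = include_first_event)
  gm_b <- train_meter_model(train_b, order_bound = order_bound,
                            include_first_event = include_first_event)
  if (prior_mode == "shared") {
    .assert(identical(gm_a$categories$label, gm_b$categories$label),
            "shared prior requires identical category sets")
    pooled <- estimate_prior(c(unclass(train_a), unclass(train_b)))$prior_m
    gm_a <- set_manual_prior(gm_a, pooled)
    gm_b <- set_manual_prior(gm_b, pooled)
  }
  tests <- list(A = test_a, B = test_b)
  ic <- acc <- matrix(NA_real_, 2, 2,
                      dimnames = list(train = c("A", "B"),
                                      test = c("A", "B")))
  per <- list()
  for (tn in names(tests)) {
    ev_a <- evaluate_corpus(gm_a, tests[[tn]])
    ev_b <- evaluate_corpus(gm_b, tests[[tn]])
    ic["A", tn] <- mean(ev_a$mean_ic)
    ic["B", tn] <- mean(ev_b$mean_ic)
    acc["A", tn] <- mean(ev_a$correct)
    acc["B", tn] <- mean(ev_b$correct)
    per[[tn]] <- data.frame(test_set = tn, id = ev_a$id,
                            ic_a = ev_a$mean_ic, ic_b = ev_b$mean_ic,
                            stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, per)
  correlation <- vapply(names(tests), function(tn) {
    d <- per[per$test_set == tn, ]
    stats::cor(d$ic_a, d$ic_b)
  }, 0)
  list(ic = ic, accuracy = acc, per_rhythm = per, correlation = correlation)
}
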