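test_that("the category prior is the relative annotation frequency", {
  corpus <- rhythm_corpus(c(
    lapply(1:3, function(i) downbeat_rhythm("2/4", 4, paste0("a", i))),
    lapply(1:3, function(i) downbeat_rhythm("3/4", 4, paste0("b", i))),
    lapply(1:3, function(i) downbeat_rhythm("6/8", 4, paste0("c", i)))))
  pr <- estimate_prior(corpus)
  expect_equal(unname(pr$prior_m), rep(1 / 3, 3))
  expect_equal(sum(pr$prior_interp$p), 1, tolerance = 1e-12)
})

test_that("interpretation priors compensate for period length", {
  # categories 2/4, 3/4, 6/8 have 8, 12 and 12 sixteenth-note phases;
  # with category priors (4/9, 4/9, 1/9) every 2/4 or 3/4 interpretation
  # gets 4/92 and every 6/8 interpretation 1/92, since
  # 8*4 + 12*4 + 12*1 = 92 ninths normalize the grid
  gm <- prior_only_meter_model(c("2/4", "3/4", "6/8"), iois = c(6L, 12L))
  gm <- set_manual_prior(gm, c(`2/4` = 4 / 9, `3/4` = 4 / 9, `6/8` = 1 / 9))
  p <- gm$prior_interp
  expect_equal(unique(p$p[p$label == "2/4"]), 4 / 92, tolerance = 1e-12)
  expect_equal(unique(p$p[p$label == "3/4"]), 4 / 92, tolerance = 1e-12)
  expect_equal(unique(p$p[p$label == "6/8"]), 1 / 92, tolerance = 1e-12)
  expect_equal(sum(p$p), 1, tolerance = 1e-12)
  # a single category spreads its mass uniformly over its phases
  gm1 <- prior_only_meter_model("3/4", iois = 6L)
  expect_equal(gm1$prior_interp$p, rep(1 / 12, 12))
})

test_that("manual priors are validated and leave sequence models untouched", {
  co <- sample_corpus(three_meter_spec(30, 5))
  gm <- train_meter_model(co, order_bound = 1)
  expect_error(set_manual_prior(gm, c(`2/4` = 0.5, `3/4` = 0.4)), "match")
  expect_error(
    set_manual_prior(gm, c(`2/4` = 0.4, `3/4` = 0.3, `6/8` = 0.2)), "sum")
  gm2 <- set_manual_prior(gm, bias_prior("6/8"))
  expect_equal(sum(gm2$prior_interp$p), 1, tolerance = 1e-9)
  r <- co[[1]]$onsets
  # likelihoods are prior-independent
  expect_equal(per_event_likelihood(gm2, "2/4", 0, r[1:2], r[3]),
               per_event_likelihood(gm, "2/4", 0, r[1:2], r[3]))
  # uniform manual prior equals the estimated prior on a balanced corpus
  gm3 <- set_manual_prior(gm, c(`2/4` = 1, `3/4` = 1, `6/8` = 1) / 3)
  expect_equal(gm3$prior_interp$p, gm$prior_interp$p, tolerance = 0.05)
})

test_that("eq4 normalizer variants differ only by a constant factor", {
  gm_p <- prior_only_meter_model(c("2/4", "6/8"), iois = c(6L, 12L),
                                 eq4_normalizer = "phases")
  gm_t <- prior_only_meter_model(c("2/4", "6/8"), iois = c(6L, 12L),
                                 eq4_normalizer = "ticks")
  ratio <- gm_p$prior_interp$p / gm_t$prior_interp$p
  expect_equal(ratio, rep(6, length(ratio)))
  expect_equal(sum(gm_p$prior_interp$p), 1, tolerance = 1e-12)
})

test_that("untrained per-event likelihoods are uniform over candidates", {
  gm <- prior_only_meter_model(c("2/4", "3/4"), iois = c(6L, 12L, 24L),
                               include_first_event = FALSE)
  lik <- vapply(candidate_onsets(24L, gm$ioi), function(o)
    per_event_likelihood(gm, "2/4", 0, c(0L, 24L), o), 0)
  expect_equal(lik, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(sum(lik), 1, tolerance = 1e-12)
})

test_that("the model sees only symbols: equal histories, equal likelihoods", {
  co <- sample_corpus(mini_culture(40, 3))
  gm <- train_meter_model(co, order_bound = 1)
  # the last events of the two contexts carry the same (mp, bd) symbol
  l1 <- per_event_likelihood(gm, "2/4", 0, c(0L, 24L), 48L)
  l2 <- per_event_likelihood(gm, "2/4", 0, c(48L, 72L), 96L)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("incremental posterior updates equal direct Bayes", {
  co <- sample_corpus(mini_culture(40, 3))
  gm <- train_meter_model(co, order_bound = 1)
  probe <- sample_corpus(mini_culture(1, 17))[[1]]$onsets
  onsets <- probe[seq_len(min(8L, length(probe)))]
  st <- initial_posterior(gm)
  expect_equal(posterior_probabilities(st)$p, gm$prior_interp$p)
  for (i in seq_along(onsets)) {
    st <- update_posterior(gm, st, onsets[seq_len(i - 1)], onsets[i])
  }
  inc <- posterior_probabilities(st)$p
  # direct Bayes: prior times the product of per-event likelihoods
  loglik <- vapply(seq_len(nrow(gm$interps)), function(j) {
    sum(vapply(seq_along(onsets), function(i)
      log2(per_event_likelihood(gm, gm$interps$label[j], gm$interps$phase[j],
                                onsets[seq_len(i - 1)], onsets[i])), 0))
  }, 0)
  w <- gm$prior_interp$p * 2^(loglik - max(loglik))
  expect_equal(inc, w / sum(w), tolerance = 1e-9)
})

test_that("an untrained model leaves the posterior at the prior", {
  gm <- prior_only_meter_model(c("3/4", "6/8"), iois = c(6L, 12L, 18L),
                               prior_m = c(`3/4` = 0.6, `6/8` = 0.4),
                               include_first_event = FALSE)
  st <- initial_posterior(gm)
  onsets <- c(0L, 12L, 24L, 30L, 42L)
  for (i in seq_along(onsets)) {
    st <- update_posterior(gm, st, onsets[seq_len(i - 1)], onsets[i])
  }
  expect_equal(posterior_probabilities(st)$p, gm$prior_interp$p,
               tolerance = 1e-9)
})

test_that("the predictive distribution is a posterior-weighted mixture", {
  co <- sample_corpus(mini_culture(40, 3))
  gm <- train_meter_model(co, order_bound = 1)
  st <- initial_posterior(gm)
  ctx <- c(0L, 24L)
  st <- update_posterior(gm, st, integer(0), 0L)
  st <- update_posterior(gm, st, 0L, 24L)
  pd <- predictive_distribution(gm, st, ctx)
  expect_equal(sum(pd$p), 1, tolerance = 1e-9)
  expect_true(all(pd$onset > 24L))
  # single-category, single-phase model: mixture equals the component
  r34 <- lapply(1:8, function(i) downbeat_rhythm("3/4", 4, paste0("r", i)))
  gm1 <- train_meter_model(rhythm_corpus(r34), order_bound = 1)
  gm1$interps <- gm1$interps[gm1$interps$phase == 0, ]
  gm1$prior_interp <- gm1$prior_interp[gm1$prior_interp$phase == 0, ]
  gm1$prior_interp$p <- 1
  st1 <- initial_posterior(gm1)
  pd1 <- predictive_distribution(gm1, st1, 0L)
  direct <- vapply(pd1$onset, function(o)
    per_event_likelihood(gm1, "3/4", 0, 0L, o), 0)
  expect_equal(pd1$p, direct, tolerance = 1e-12)
})

test_that("information content is the negative log2 probability", {
  expect_equal(information_content(0.25), 2)
  expect_equal(information_content(1), 0)
  expect_equal(information_content(1 / 1024), 10)
  expect_error(information_content(0), "\\(0, 1\\]")
})

test_that("rhythms from a known meter are classified with phase zero", {
  co <- separable_corpus(n_each = 6, n_bars = 6)
  gm <- train_meter_model(co, order_bound = 1)
  cl <- classify_rhythm(gm, downbeat_rhythm("3/4", 6, "probe"))
  expect_equal(cl$label, "3/4")
  expect_equal(cl$phase, 0L)
  cl2 <- classify_rhythm(gm, downbeat_rhythm("2/4", 6, "probe2"))
  expect_equal(cl2$label, "2/4")
  expect_equal(cl2$phase, 0L)
})

test_that("prior-only classification follows the prior with deterministic ties", {
  gm <- prior_only_meter_model(c("2/4", "3/4", "6/8"), iois = c(6L, 12L),
                               include_first_event = FALSE)
  gm <- set_manual_prior(gm, bias_prior("3/4"))
  # all likelihoods are uniform on this grid-aligned rhythm, so the argmax
  # is the prior's: 2/4 and 3/4 interpretations tie at 4/92 and the
  # lexicographic tie-break picks 2/4 at phase 0
  cl <- classify_rhythm(gm, rhythm_sequence(c(0, 12, 24, 36)))
  expect_equal(cl$label, "2/4")
  expect_equal(cl$phase, 0L)
})

test_that("evaluation records mean IC, correctness and scored counts", {
  co <- separable_corpus(6, 6)
  gm <- train_meter_model(co, order_bound = 1)
  ev <- evaluate_rhythm(gm, downbeat_rhythm("2/4", 6, "p"))
  expect_equal(ev$mean_ic, mean(ev$ic))
  expect_true(ev$correct)
  expect_gte(min(ev$ic), 0)
  expect_equal(ev$n_scored, 6)
  # with first events excluded, a one-event rhythm scores nothing
  gm0 <- train_meter_model(co, order_bound = 1, include_first_event = FALSE)
  ev0 <- evaluate_rhythm(gm0, rhythm_sequence(0L, meter = "2/4", id = "one"))
  expect_equal(ev0$n_scored, 0)
  expect_true(is.na(ev0$mean_ic))
})

test_that("prediction error vanishes as a deterministic pattern is learned", {
  # quarter-note rhythms plus one eighth-note contrast rhythm (so the
  # interval alphabet has two candidates); as quarter-note evidence grows,
  # the probe's prediction error converges toward zero
  quarters <- function(id) rhythm_sequence(seq(0L, 264L, by = 24L),
                                           meter = "2/4", id = id)
  contrast <- rhythm_sequence(c(0L, 12L, 24L, 48L), meter = "2/4",
                              id = "contrast")
  ics <- vapply(c(2, 8, 32), function(n) {
    co <- rhythm_corpus(c(list(contrast),
                          lapply(seq_len(n), function(i)
                            quarters(paste0("r", i)))))
    gm <- train_meter_model(co, order_bound = 1,
                            include_first_event = FALSE)
    evaluate_rhythm(gm, quarters("probe"))$mean_ic
  }, 0)
  expect_true(all(diff(ics) < 0))
  expect_lt(ics[3], 0.5)
})

test_that("order-0 likelihood depends only on the symbol multiset", {
  # two rhythms whose mp/bd symbol sequences are permutations of each
  # other: under a zeroth-order model they are indistinguishable
  co <- sample_corpus(mini_culture(40, 3))
  gm <- train_meter_model(co, order_bound = 0)
  md <- gm$models[["2/4"]]
  i24 <- metrical_interpretation("2/4", 0)
  syms_of <- function(onsets) {
    vapply(seq_along(onsets), function(i) {
      s <- vp_mp_bd(onsets[seq_len(i)], i24)
      s[["mp"]] * md$n_bd + (s[["bd"]] - md$bd_min) + 1L
    }, 0L)
  }
  r1 <- c(0L, 30L, 60L)   # symbols (0,0) (30,0) (12,1)
  r2 <- c(0L, 60L, 78L)   # symbols (0,0) (12,1) (30,0)
  s1 <- syms_of(r1)
  s2 <- syms_of(r2)
  expect_setequal(s1, s2)
  expect_false(identical(s1, s2))
  expect_equal(ppm_loglik(md$ppm, s1), ppm_loglik(md$ppm, s2),
               tolerance = 1e-12)
})

test_that("translating a rhythm translates the posterior over phases", {
  co <- sample_corpus(mini_culture(40, 3))
  gm <- train_meter_model(co, order_bound = 1, include_first_event = FALSE)
  probe <- sample_corpus(mini_culture(1, 23))[[1]]$onsets
  onsets <- probe[seq_len(min(10L, length(probe)))]
  for (delta in c(6L, 18L, 30L)) {
    ev1 <- evaluate_rhythm(gm, rhythm_sequence(onsets))
    ev2 <- evaluate_rhythm(gm, rhythm_sequence(onsets + delta))
    p1 <- ev1$posterior
    p2 <- ev2$posterior
    # category masses are unchanged ...
    for (lab in gm$categories$label) {
      expect_equal(sum(p2$p[p2$label == lab]), sum(p1$p[p1$label == lab]),
                   tolerance = 1e-9)
    }
    # ... and phase masses shift by delta mod period within each category
    for (j in seq_len(nrow(p1))) {
      shifted <- (p1$phase[j] + delta) %% p1$period[j]
      k <- which(p2$label == p1$label[j] & p2$phase == shifted)
      expect_equal(p2$p[k], p1$p[j], tolerance = 1e-9)
    }
    # per-event prediction error is translation invariant
    expect_equal(ev2$ic, ev1$ic, tolerance = 1e-9)
  }
})

test_that("meter models survive a JSON round trip", {
  co <- sample_corpus(mini_culture(25, 9))
  gm <- train_meter_model(co, order_bound = 1)
  json <- jsonlite::toJSON(meter_model_as_list(gm), auto_unbox = TRUE,
                           digits = NA)
  gm2 <- meter_model_from_list(jsonlite::fromJSON(json, simplifyVector = FALSE))
  probe <- sample_corpus(mini_culture(3, 77), "probe")
  for (r in probe) {
    e1 <- evaluate_rhythm(gm, r)
    e2 <- evaluate_rhythm(gm2, r)
    expect_equal(e2$ic, e1$ic, tolerance = 1e-12)
    expect_equal(e2$category, e1$category)
  }
})
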