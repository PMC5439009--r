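test_that("meter categories map time signatures to tick periods", {
  expect_equal(meter_category("2/4")$period, 48L)
  expect_equal(meter_category("3/4")$period, 72L)
  expect_equal(meter_category("4/4")$period, 96L)
  expect_equal(meter_category("6/8")$period, 72L)
  expect_equal(meter_category("3/8")$period, 36L)
  expect_error(meter_category("waltz"), "parse")
})

test_that("rhythm sequences enforce integer, strictly increasing onsets", {
  r <- rhythm_sequence(c(0, 24, 36), meter = "2/4", id = "x")
  expect_s3_class(r, "rhythm_sequence")
  expect_identical(r$onsets, c(0L, 24L, 36L))
  expect_error(rhythm_sequence(c(0, 24, 24)), "increasing")
  expect_error(rhythm_sequence(c(0, 12.5)), "integer")
  expect_length(rhythm_sequence(integer(0))$onsets, 0)
})

test_that("basic viewpoints return the last event's attribute or NA", {
  expect_equal(vp_onset(c(0L)), 0L)
  expect_equal(vp_onset(c(0L, 30L)), 30L)
  expect_true(is.na(vp_onset(integer(0))))
  expect_equal(vp_ioi(c(0L, 24L, 36L)), 12L)
  expect_equal(vp_ioi(c(0L, 6L)), 6L)
  expect_true(is.na(vp_ioi(c(0L))))
})

test_that("metrical position and bar number use floored arithmetic", {
  i34 <- metrical_interpretation("3/4", 0)
  expect_equal(vp_mp(c(0L, 30L), i34), 30L)
  expect_equal(vp_mp(c(0L, 78L), i34), 6L)
  expect_equal(vp_mp(c(0L, 30L), metrical_interpretation("3/4", 6)), 24L)
  # anacrusis: -6 = (-1) * 48 + 42 under floored division
  i24 <- metrical_interpretation("2/4", 0)
  expect_equal(vp_mp(c(-6L), i24), 42L)
  expect_equal(vp_bn(c(-6L), i24), -1L)
  expect_equal(vp_bn(c(0L, 78L), i34), 1L)
  expect_equal(vp_bn(c(0L), i34), 0L)
})

test_that("bar distance uses the virtual-origin convention for first events", {
  i34 <- metrical_interpretation("3/4", 0)
  expect_equal(vp_bd(c(0L, 78L), i34), 1L)
  expect_equal(vp_bd(c(0L, 30L), i34), 0L)
  expect_equal(vp_bd(c(96L), metrical_interpretation("2/4", 0)), 2L)
  expect_equal(vp_mp_bd(c(0L, 78L), i34), c(mp = 6L, bd = 1L))
  expect_equal(vp_mp_bd(c(0L), i34), c(mp = 0L, bd = 0L))
  # floored bar numbers: under phase 6 the origin lies in bar -1, so the
  # event at onset 30 (bar 0) is one bar after the event at onset 0
  expect_equal(vp_mp_bd(c(0L, 30L), metrical_interpretation("3/4", 6)),
               c(mp = 24L, bd = 1L))
})

test_that("prefix application drops undefined symbols and extends by one", {
  expect_equal(apply_viewpoint(vp_ioi, c(0L, 24L, 36L)), list(24L, 12L))
  i34 <- metrical_interpretation("3/4", 0)
  expect_equal(apply_viewpoint(vp_mp_bd, c(0L, 30L, 78L), i34),
               list(c(mp = 0L, bd = 0L), c(mp = 30L, bd = 0L),
                    c(mp = 6L, bd = 1L)))
  expect_equal(apply_viewpoint(vp_mp_bd, integer(0), i34), list())
  # prefix monotonicity: each prefix adds at most one symbol
  ons <- c(-6L, 0L, 18L, 48L, 60L)
  for (n in seq_along(ons)) {
    a <- apply_viewpoint(vp_mp_bd, ons[seq_len(n)], i34)
    b <- apply_viewpoint(vp_mp_bd, ons[seq_len(n - 1)], i34)
    expect_true(length(a) - length(b) <= 1)
    expect_identical(a[seq_along(b)], b)
  }
})

test_that("the IOI alphabet collects observed intervals and candidates", {
  corpus <- list(rhythm_sequence(c(0, 24, 48)), rhythm_sequence(c(0, 12, 24)))
  expect_equal(ioi_alphabet(corpus), c(12L, 24L))
  expect_equal(ioi_alphabet(list(rhythm_sequence(c(0, 6)),
                                 rhythm_sequence(c(0, 6)))), 6L)
  expect_equal(candidate_onsets(48L, c(12L, 24L)), c(60L, 72L))
  expect_error(ioi_alphabet(list(rhythm_sequence(0L))), "singleton")
})

test_that("linked symbols map back to unique onsets (round trip)", {
  i34 <- metrical_interpretation("3/4", 0)
  expect_equal(symbol_to_onset(c(6L, 1L), 0L, i34), 78L)
  expect_equal(symbol_to_onset(c(24L, 1L), 0L, metrical_interpretation("3/4", 6)),
               30L)
  # a symbol may map to an onset at or before the previous event: such
  # symbols are unreachable as predictions
  expect_lte(symbol_to_onset(c(0L, 0L), 30L, i34), 30L)

  # property: round trip over random onsets, periods and phases
  set.seed(42)
  for (rep in 1:200) {
    cat <- sample(c("2/4", "3/4", "4/4", "6/8", "3/8"), 1)
    period <- meter_category(cat)$period
    phase <- sample(seq(0L, period - 6L, by = 6L), 1)
    interp <- metrical_interpretation(cat, phase)
    prev <- sample(-48:96, 1)
    onset <- prev + sample(1:200, 1)
    sym <- vp_mp_bd(c(prev, onset), interp)
    expect_identical(symbol_to_onset(sym, prev, interp), as.integer(onset))
    expect_true(sym[["mp"]] >= 0 && sym[["mp"]] < period)
    expect_gte(sym[["bd"]], 0)
  }
})

test_that("distinct reachable symbols map to distinct onsets", {
  interp <- metrical_interpretation("3/4", 6)
  prev <- 30L
  syms <- expand.grid(mp = seq(0L, 66L, by = 6L), bd = 0:2)
  onsets <- mapply(function(mp, bd) symbol_to_onset(c(mp, bd), prev, interp),
                   syms$mp, syms$bd)
  reachable <- onsets > prev
  expect_false(any(duplicated(onsets[reachable])))
})
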