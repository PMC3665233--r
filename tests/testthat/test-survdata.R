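test_that("the packaged AB-recipient records load with the right structure", {
  ab <- read_cohort(ab_path)
  expect_s3_class(ab, "survcohort")
  expect_equal(nrow(ab), 11L)
  expect_equal(sum(ab$event), 1L)
  expect_equal(sort(ab$time)[1:3], c(72, 387, 616))
  expect_equal(ab$time[ab$event == 1], 616)
})

test_that("cohort construction enforces the record invariants", {
  expect_error(survival_cohort(data.frame(time = numeric(0),
                                          event = integer(0))),
               "no records")
  one <- survival_cohort(data.frame(time = 10, event = 1))
  expect_equal(nrow(one), 1L)
  expect_equal(sum(one$event), 1L)
  expect_warning(
    ok <- survival_cohort(data.frame(time = c(-1, 5), event = c(1, 1))),
    "nonpositive")
  expect_equal(nrow(ok), 1L)
  expect_error(survival_cohort(data.frame(time = c(1, 2), event = c(1, 2))),
               "event code")
  expect_error(survival_cohort(data.frame(id = c(1, 1), time = c(1, 2),
                                          event = c(0, 1)), id = "id"),
               "unique")
})

test_that("round-trip write/read preserves times, events and covariates", {
  d <- data.frame(time = c(3.5, 1.25, 7), event = c(1, 0, 1),
                  x = c(0.5, -1, 2), g = c("a", "b", "a"))
  co <- survival_cohort(d, categorical = "g")
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path, categorical = "g")
  expect_equal(back$time, co$time)
  expect_equal(back$event, co$event)
  expect_equal(back$x, co$x)
  expect_equal(as.character(back$g), as.character(co$g))
})

test_that("categorical encoding is reference-coded with block registry", {
  d <- survival_cohort(
    data.frame(time = 1:8, event = rep(1, 8),
               bt = c("O", "A", "B", "AB", "O", "O", "A", "O"),
               vent = c(0, 1, 0, 0, 0, 0, 1, 0)),
    categorical = "bt")
  enc <- encode_categoricals(d, reference = c(bt = "O"))
  blocks <- attr(enc, "blocks")
  expect_setequal(blocks$bt, c("bt.A", "bt.B", "bt.AB"))
  # indicators of one categorical sum to at most 1 per row
  expect_true(all(rowSums(as.data.frame(enc)[blocks$bt]) <= 1))
  expect_equal(sum(enc$bt.A), 2)
  expect_equal(enc$vent, d$vent)          # binary passes through
  # no variation
  dc <- survival_cohort(data.frame(time = 1:3, event = c(1, 1, 1),
                                   k = c("x", "x", "x")),
                        categorical = "k")
  expect_warning(encode_categoricals(dc), "no variation")
})

test_that("missing cells are masked, not dropped, until complete_cases", {
  d <- survival_cohort(data.frame(time = c(1, 2, 3), event = c(1, 1, 0),
                                  x = c(0.5, NA, 1)))
  expect_equal(nrow(d), 3L)
  cc <- complete_cases(d)
  expect_equal(nrow(cc), 2L)
  expect_false(anyNA(cc$x))
})

test_that("risk structure counts risk and death sets correctly", {
  ab <- read_cohort(ab_path)
  rs <- build_risk_structure(ab)
  expect_equal(rs$event_times, 616)
  expect_equal(rs$d, 1L)
  expect_equal(length(rs$risk_sets[[1L]]), 9L)   # 72 and 387 censored before
  d3 <- data.frame(time = c(1, 2, 3), event = c(1, 1, 1))
  rs3 <- build_risk_structure(d3)
  expect_equal(length(rs3$event_times), 3L)
  expect_equal(unname(rs3$d), c(1L, 1L, 1L))
  dt <- data.frame(time = c(5, 5, 9), event = c(1, 1, 0))
  rst <- build_risk_structure(dt)
  expect_equal(rst$event_times, 5)
  expect_equal(unname(rst$d), 2L)
  expect_equal(sum(rst$d), 2L)
  expect_error(build_risk_structure(data.frame(time = 1:2,
                                               event = c(0, 0))),
               "no events")
})

test_that("episode splitting conserves exposure and events", {
  d <- survival_cohort(data.frame(time = c(100, 30), event = c(1, 0),
                                  x = c(2, -1)))
  kn <- knot_set(50, 100)
  ep <- split_episodes(d, kn)
  expect_equal(ep$start[ep$id == 1], c(0, 50))
  expect_equal(ep$stop[ep$id == 1], c(50, 100))
  expect_equal(ep$event[ep$id == 1], c(0L, 1L))
  expect_equal(nrow(ep[ep$id == 2, ]), 1L)       # censored before the knot
  expect_equal(ep$stop[ep$id == 2], 30)
  # conservation on a larger random cohort
  r <- rand_surv(40, p = 1, seed = 11)
  co <- survival_cohort(r)
  kk <- place_knots(co, K = 3)
  ee <- split_episodes(co, kk)
  exposure <- tapply(ee$stop - ee$start, ee$id, sum)
  expect_equal(as.numeric(exposure[order(as.numeric(names(exposure)))]),
               co$time, tolerance = 1e-12)
  expect_equal(sum(ee$event), sum(co$event))
  # K = 1: one episode per subject
  ab <- read_cohort(ab_path)
  ep1 <- split_episodes(ab, place_knots(ab, K = 1))
  expect_equal(nrow(ep1), 11L)
})
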