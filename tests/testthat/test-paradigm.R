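test_that("the standard block reproduces the exact token bookkeeping", {
  plan <- roving_plan(seed = 11)
  ev <- generate_sequence(plan)
  expect_equal(sum(ev$stimulus == plan$stim_a), 608)
  expect_equal(sum(ev$stimulus == plan$stim_b), 600)
  expect_equal(nrow(ev), 1208)
  # 100 trains per stimulus, each length 4-8 exactly 20 times
  trains <- ev[ev$train_id > 0, ]
  len_by <- tapply(trains$position_in_train, trains$train_id, max)
  stim_by <- tapply(trains$stimulus, trains$train_id, `[`, 1)
  for (s in c(plan$stim_a, plan$stim_b)) {
    expect_equal(sum(stim_by == s), 100)
    expect_equal(as.integer(table(len_by[stim_by == s])), rep(20L, 5))
  }
  # roles: 100 deviants and 200 standards per stimulus
  for (s in c(plan$stim_a, plan$stim_b)) {
    expect_equal(sum(ev$role == "deviant" & ev$stimulus == s), 100)
    expect_equal(sum(ev$role == "standard" & ev$stimulus == s), 200)
  }
  expect_equal(sum(ev$role == "lead_in"), 8)
})

test_that("alternation, onsets and per-seed histograms hold across seeds", {
  for (seed in 1:4) {
    plan <- roving_plan(train_lengths = 4:6, reps_per_length = 3, lead_in = 2,
                        seed = seed)
    ev <- generate_sequence(plan)
    expect_equal(diff(ev$onset), rep(plan$soa, nrow(ev) - 1))
    stim_by <- tapply(ev$stimulus[ev$train_id > 0],
                      ev$train_id[ev$train_id > 0], `[`, 1)
    expect_true(all(stim_by[-1] != stim_by[-length(stim_by)]))
    len_by <- tapply(ev$position_in_train[ev$train_id > 0],
                     ev$train_id[ev$train_id > 0], max)
    for (s in unique(stim_by))
      expect_equal(sort(as.integer(len_by[stim_by == s])),
                   rep(4:6, each = 3))
    # conservation: lead-in plus the sum of all train lengths
    expect_equal(nrow(ev), plan$lead_in + sum(len_by))
  }
})

test_that("same seed reproduces the sequence; different seeds only reorder", {
  a <- generate_sequence(roving_plan(seed = 5))
  b <- generate_sequence(roving_plan(seed = 5))
  c <- generate_sequence(roving_plan(seed = 6))
  expect_identical(a, b)
  expect_false(identical(a$train_id, c$train_id) &&
               identical(a$stimulus, c$stimulus))
  expect_equal(table(a$stimulus), table(c$stimulus))
})

test_that("a toy plan produces two alternating trains", {
  plan <- roving_plan(stim_a = "A", stim_b = "B", lead_in = 0,
                      train_lengths = 4, reps_per_length = 1)
  ev <- generate_sequence(plan)
  expect_equal(nrow(ev), 8)
  expect_equal(ev$stimulus, c(rep("B", 4), rep("A", 4)))
  expect_equal(ev$role[ev$train_id == 1],
               c("deviant", "filler", "standard", "standard"))
})

test_that("role assignment follows the first / last-two rule", {
  mk <- function(len) data.frame(index = seq_len(len), onset = 0,
                                 stimulus = "A", train_id = 1L,
                                 position_in_train = seq_len(len),
                                 role = "filler")
  expect_equal(assign_roles(mk(4))$role,
               c("deviant", "filler", "standard", "standard"))
  r8 <- assign_roles(mk(8))$role
  expect_equal(sum(r8 == "filler"), 5)
  expect_error(assign_roles(mk(2)), "overlap")
})

test_that("block timing matches the stated total duration", {
  plan <- roving_plan(seed = 2)
  ev <- generate_sequence(plan)
  d <- total_duration(ev, plan)
  expect_equal(d$seconds, 1208 * 1.09)
  expect_equal(d$seconds, 1316.72)
  expect_equal(d$minutes_rounded, 22)
  lead_only <- roving_plan(lead_in = 8, train_lengths = 4, reps_per_length = 1)
  ev2 <- generate_sequence(lead_only)[1:8, ]
  expect_equal(total_duration(ev2, lead_only)$seconds, 8 * 1.09)
})

test_that("event tables round-trip through TSV and are validated on read", {
  ev <- generate_sequence(roving_plan(train_lengths = 4:5, reps_per_length = 2,
                                      lead_in = 2, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back$stimulus, ev$stimulus)
  expect_equal(back$onset, ev$onset)
  expect_equal(back$role, ev$role)
  expect_equal(back$train_id, ev$train_id)
  # hand-written toy file
  toy <- withr::local_tempfile(lines = c(
    "onset\tduration\tstimulus\ttrain_id\tposition_in_train\trole",
    paste(seq(0, by = 1.09, length.out = 8), 0,
          rep(c("B", "A"), each = 4), rep(1:2, each = 4), rep(1:4, 2),
          c("deviant", "filler", "standard", "standard"), sep = "\t")))
  tev <- read_events(toy)
  expect_equal(tev$stimulus, rep(c("B", "A"), each = 4))
  # validation errors
  bad <- withr::local_tempfile(lines = c("onset\tstimulus", "0\tA"))
  expect_error(read_events(bad), "lacks columns")
  nonmono <- withr::local_tempfile(lines = c(
    "onset\tduration\tstimulus\ttrain_id\tposition_in_train\trole",
    "1.09\t0\tA\t1\t1\tdeviant", "0\t0\tA\t1\t2\tfiller"))
  expect_error(read_events(nonmono), "non-decreasing")
})

test_that("inconsistent plans are rejected", {
  plan <- roving_plan()
  plan$trains_per_stim <- 99
  expect_error(generate_sequence(plan), "inconsistent")
})
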