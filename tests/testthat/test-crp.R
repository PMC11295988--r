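test_that("transition scoring reproduces the hand-worked short-list example", {
  sc <- score_transitions(c(3L, 4L, 2L), list_length = 5)
  expect_equal(sc$actual[match(c(1, -2), sc$lag)], c(1L, 1L))
  expect_equal(sum(sc$actual), 2L)
  expect_equal(sc$possible[match(c(-3, -2, -1, 1, 2), sc$lag)],
               c(1L, 2L, 1L, 2L, 1L))
  expect_equal(sc$crp[match(1, sc$lag)], 0.5)
  expect_equal(sc$crp[match(-2, sc$lag)], 0.5)
  expect_equal(sc$crp[match(c(-3, -1, 2), sc$lag)], c(0, 0, 0))
  expect_true(all(is.na(sc$crp[abs(sc$lag) > 3])))
})

test_that("single recalls and intrusion-adjacent pairs score nothing", {
  expect_equal(sum(score_transitions(3L, 14)$possible), 0L)
  sc <- score_transitions(c(3L, NA, 4L), 14)
  expect_equal(sum(sc$actual) + sum(sc$possible), 0L)
  # repetition breaks the chain in both directions
  sc2 <- score_transitions(c(3L, 4L, 4L, 5L), 14)
  expect_equal(sum(sc2$actual), 1L)  # only 3 -> 4 scored
})

test_that("serial positions outside the list raise a malformed-trial error", {
  expect_error(score_transitions(c(3L, 15L), 14), "malformed")
})

test_that("scoring matches the brute-force available-set oracle on random trials", {
  withr::with_seed(101, {
    for (r in 1:1000) {
      L <- sample(2:7, 1)
      W <- sample(1:5, 1)
      sp <- random_trial(L)
      got <- score_transitions(sp, L, W)
      want <- brute_force_crp(sp, L, W)
      expect_equal(got$actual, want$actual,
                   info = paste("actual:", paste(sp, collapse = ",")))
      expect_equal(got$possible, want$possible,
                   info = paste("possible:", paste(sp, collapse = ",")))
    }
  })
})

test_that("anchored scoring matches the brute-force oracle restricted to the anchor", {
  withr::with_seed(202, {
    for (r in 1:300) {
      L <- sample(4:7, 1)
      anchor <- sample(seq_len(L), 1)
      sp <- random_trial(L)
      got <- oddballcrp:::score_sequence(sp, L, 5L, anchor)
      want <- brute_force_crp(sp, L, 5L, anchor)
      expect_equal(got$actual[c(1:5, 7:11)], want$actual)
      expect_equal(got$possible[c(1:5, 7:11)], want$possible)
    }
  })
})

test_that("anchored curves follow the worked oddball example", {
  ds <- manual_dataset(list(c(9L, 10L, 6L)), oddball_pos = 9L)
  cur <- anchored_crp(ds, "oddball")
  expect_equal(cur$actual[cur$lag == 1], 1L)
  expect_equal(sum(cur$actual), 1L)
  expect_true(all(cur$possible == 1L))  # 14-item list, all lags reachable
  expect_equal(cur$crp[cur$lag == 1], 1)
  expect_equal(sum(cur$crp), 1)  # all other defined lags are 0

  # anchor never recalled, and anchor as final recall: zero counts
  ds2 <- manual_dataset(list(c(3L, 4L), c(3L, 9L)), oddball_pos = 9L)
  cur2 <- anchored_crp(ds2, "oddball")
  expect_equal(sum(cur2$actual) + sum(cur2$possible), 0L)
})

test_that("per-subject pooling is ratio-of-sums and order/duplication stable", {
  # perfect forward chaining: CRP(+1) = 1, all other defined lags 0
  chain <- lapply(1:3, function(i) 1:6)
  ds <- manual_dataset(chain)
  cur <- lag_crp(ds)
  expect_equal(unique(cur$crp[cur$lag == 1]), 1)
  expect_true(all(cur$crp[cur$lag != 1] %in% c(0, NA_real_)))

  # duplicating a subject's trials leaves per-subject ratios unchanged
  d <- generate_design(4)
  ds1 <- simulate_experiment(d, sim_params(n_subjects = 2, seed = 14))
  # pool-then-divide invariance checked by doubling counts manually
  cur1 <- lag_crp(ds1)
  pooled_twice <- dplyr::mutate(cur1, actual = actual * 2L,
                                possible = possible * 2L,
                                crp = ifelse(possible > 0, actual / possible,
                                             NA_real_))
  expect_equal(pooled_twice$crp, cur1$crp)

  # permuting trial order within a subject never changes pooled curves
  shuf <- ds1
  withr::with_seed(3, {
    ord <- dplyr::slice_sample(dplyr::distinct(ds1$recalls, subject_id,
                                               list_id),
                               prop = 1)
  })
  shuf$recalls <- dplyr::arrange(
    dplyr::left_join(dplyr::mutate(ord, ord = dplyr::row_number()),
                     ds1$recalls, by = c("subject_id", "list_id")),
    ord, output_position)[, names(ds1$recalls)]
  expect_equal(dplyr::arrange(lag_crp(shuf), subject_id, lag),
               dplyr::arrange(cur1, subject_id, lag))
})

test_that("anchored counts are a sub-count of unanchored counts", {
  d <- generate_design(6)
  ds <- simulate_experiment(d, sim_params(n_subjects = 5, seed = 31))
  full <- lag_crp(ds)
  for (role in c("oddball", "control")) {
    anc <- anchored_crp(ds, role)
    merged <- dplyr::inner_join(
      anc, full, by = c("subject_id", "lag"), suffix = c("_anc", "_full"))
    expect_true(all(merged$actual_anc <= merged$actual_full))
    expect_true(all(merged$possible_anc <= merged$possible_full))
  }
})

test_that("curve values stay inside their bounds", {
  d <- generate_design(9)
  ds <- simulate_experiment(d, sim_params(n_subjects = 8, seed = 77))
  cur <- lag_crp(ds, by = "oddball_type")
  expect_true(all(cur$actual <= cur$possible))
  ok <- !is.na(cur$crp)
  expect_true(all(cur$crp[ok] >= 0 & cur$crp[ok] <= 1))
})

test_that("directional means average only defined lags", {
  curve <- tibble::tibble(subject_id = "S001",
                          lag = c(-5:-1, 1:5),
                          actual = c(rep(0L, 5), 1L, rep(0L, 4)),
                          possible = c(rep(1L, 5), rep(1L, 5)),
                          crp = c(rep(0, 5), 1, 0, 0, 0, 0))
  expect_equal(mean_directional_crp(curve, "forward")$mean_crp, 0.2)

  part <- curve
  part$possible[part$lag %in% 2:5] <- 0L
  part$crp[part$lag %in% 2:5] <- NA_real_
  part$crp[part$lag == 1] <- 0.5
  expect_equal(mean_directional_crp(part, "forward")$mean_crp, 0.5)

  sc <- score_transitions(c(3L, 4L, 2L), 5)
  sc$subject_id <- "S001"
  expect_equal(mean_directional_crp(sc, "backward")$mean_crp, 1 / 6)

  none <- curve
  none$possible[none$lag > 0] <- 0L
  none$crp[none$lag > 0] <- NA_real_
  expect_true(is.na(mean_directional_crp(none, "forward")$mean_crp))
})

test_that("an empty filtered trial set warns and returns an empty curve set", {
  d <- generate_design(5)
  ds <- simulate_experiment(d, sim_params(n_subjects = 2, seed = 8))
  empty <- filter_trials(ds, soa_s > 100)
  expect_warning(cur <- lag_crp(empty), "no trials")
  expect_equal(nrow(cur), 0L)
})
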