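one_list <- function(oddball_pos = 9L, type = "emotional") {
  d <- generate_design(1)
  m <- oddballcrp:::list_meta(d)
  lid <- m$list_id[m$oddball_type == type & m$oddball_pos == oddball_pos][1]
  if (is.na(lid)) {  # build directly if this seed lacks the combination
    items <- manual_dataset(list(1L), oddball_pos = oddball_pos,
                            oddball_type = type)$design
    return(items)
  }
  d[d$list_id == lid, ]
}

test_that("association strength follows the exponential-contiguity formula", {
  li <- one_list(9L, "emotional")
  p_sym <- sim_params(tau = 1, phi_fwd = 1, sigma_odd = 1, b_E = 1, b_P = 1)
  expect_equal(association_strength(3, 4, li, p_sym), exp(-1))
  expect_equal(association_strength(3, 2, li, p_sym), exp(-1))

  p_fwd <- sim_params(tau = 1, phi_fwd = 2, sigma_odd = 1, b_E = 1, b_P = 1)
  expect_equal(association_strength(3, 4, li, p_fwd) /
                 association_strength(3, 2, li, p_fwd), 2)

  # emotional oddball at 9 cues its forward neighbour
  p <- sim_params(tau = 2, phi_fwd = 1.5, sigma_odd = 1, b_E = 3, b_P = 1)
  expect_equal(association_strength(9, 10, li, p), exp(-0.5) * 1.5 * 3)
  # backward from the oddball gets no binding boost
  expect_equal(association_strength(9, 8, li, p), exp(-0.5))
  # transitions into the oddball get the salience boost
  p_s <- sim_params(tau = 2, phi_fwd = 1, sigma_odd = 1.8, b_E = 1, b_P = 1)
  expect_equal(association_strength(8, 9, li, p_s), exp(-0.5) * 1.8)

  expect_error(association_strength(5, 5, li, p), "i != j")
})

test_that("the assoc matrix agrees with association_strength everywhere", {
  li <- one_list(11L, "perceptual")
  p <- sim_params(tau = 1.7, phi_fwd = 1.4, sigma_odd = 1.6, b_E = 2.2,
                  b_P = 1.3)
  A <- oddballcrp:::assoc_matrix(14, 11L, "perceptual", p)
  for (i in c(1, 7, 11, 14)) {
    for (j in c(2, 10, 11, 12)) {
      if (i == j) next
      expect_equal(A[i, j], association_strength(i, j, li, p))
    }
  }
})

test_that("simulate_trial honours stop, intrusion and contiguity limits", {
  li <- one_list()
  # overwhelming stop rule: every trial has exactly one event
  p_stop <- sim_params(rho0 = 1, rho1 = 0, rho_min = 0.99)
  withr::with_seed(4, {
    lens <- replicate(50, nrow(simulate_trial(li, p_stop)))
  })
  expect_true(all(lens == 1L))

  # no intrusions when p_intrusion = 0
  p_noint <- sim_params(p_intrusion = 0)
  withr::with_seed(5, {
    tr <- dplyr::bind_rows(replicate(30, simulate_trial(li, p_noint),
                                     simplify = FALSE))
  })
  expect_false(any(tr$is_intrusion))

  # tau -> 0: every transition goes to the nearest still-available item
  # (adjacent, i.e. |lag| = 1, whenever a neighbour remains unrecalled)
  p_adj <- sim_params(tau = 1e-6, phi_fwd = 1, sigma_odd = 1, b_E = 1,
                      b_P = 1, p_intrusion = 0, rho0 = 0.1, rho1 = 0)
  withr::with_seed(6, {
    for (r in 1:20) {
      sp <- simulate_trial(li, p_adj)$serial_position
      for (k in seq_along(sp)[-1]) {
        avail <- setdiff(1:14, sp[seq_len(k - 1)])
        expect_equal(abs(sp[k] - sp[k - 1]),
                     min(abs(avail - sp[k - 1])))
        if (any(abs(avail - sp[k - 1]) == 1L))
          expect_equal(abs(sp[k] - sp[k - 1]), 1L)
      }
    }
  })
})

test_that("simulated experiments are deterministic and subject-stream stable", {
  d <- generate_design(2)
  p <- sim_params(n_subjects = 4, seed = 9)
  ds1 <- simulate_experiment(d, p)
  ds2 <- simulate_experiment(d, p)
  expect_identical(ds1$recalls, ds2$recalls)
  expect_equal(dplyr::n_distinct(ds1$recalls$subject_id), 4L)
  expect_equal(nrow(dplyr::distinct(ds1$recalls, subject_id, list_id)),
               4L * 40L)
  # first subjects of a larger run reproduce the smaller run exactly
  ds3 <- simulate_experiment(d, sim_params(n_subjects = 6, seed = 9))
  expect_identical(
    dplyr::filter(ds3$recalls, subject_id %in% unique(ds1$recalls$subject_id)),
    ds1$recalls)
})

test_that("symmetric parameters give a symmetric pooled lag-CRP", {
  d <- generate_design(8)
  p <- sim_params(phi_fwd = 1, b_E = 1, b_P = 1, sigma_odd = 1, theta_p = 0,
                  n_subjects = 150, seed = 21)   # 6000 trials
  ds <- simulate_experiment(d, p)
  cur <- lag_crp(ds)
  pooled <- dplyr::summarise(dplyr::group_by(cur, lag),
                             crp = sum(actual) / sum(possible),
                             .groups = "drop")
  fwd <- pooled$crp[match(1:5, pooled$lag)]
  bwd <- pooled$crp[match(-(1:5), pooled$lag)]
  expect_lt(max(abs(fwd - bwd)), 0.02)
})

test_that("forward asymmetry and oddball salience leave their signatures", {
  d <- generate_design(12)
  ds <- simulate_experiment(d, sim_params(n_subjects = 70, seed = 33))
  cur <- lag_crp(ds)
  dir_means <- dplyr::bind_rows(mean_directional_crp(cur, "forward"),
                                mean_directional_crp(cur, "backward"))
  fwd <- mean(dir_means$mean_crp[dir_means$direction == "forward"],
              na.rm = TRUE)
  bwd <- mean(dir_means$mean_crp[dir_means$direction == "backward"],
              na.rm = TRUE)
  expect_gt(fwd, bwd)

  # Von Restorff: oddballs recalled more often than matched controls
  odd <- item_recall_proportion(ds, "oddball")
  ctl <- item_recall_proportion(ds, "control")
  expect_gt(mean(odd$value, na.rm = TRUE), mean(ctl$value, na.rm = TRUE))

  # recall grows with SOA when the stop rate falls with SOA
  rec <- total_recall_by_soa(ds)
  by_soa <- dplyr::summarise(dplyr::group_by(rec, soa_s),
                             m = mean(value), .groups = "drop")
  expect_true(all(diff(by_soa$m[order(by_soa$soa_s)]) > 0))
})

test_that("emotional forward binding raises the emotional anchored contrast", {
  d <- generate_design(19)
  ds <- simulate_experiment(d, sim_params(n_subjects = 220, seed = 55))
  cells <- anchored_cell_means(ds, "forward")
  w <- tidyr::pivot_wider(
    cells[, c("subject_id", "oddball_type", "anchor_role", "mean_crp")],
    names_from = c("oddball_type", "anchor_role"), values_from = "mean_crp")
  emo <- mean(w$emotional_oddball - w$emotional_control, na.rm = TRUE)
  per <- mean(w$perceptual_oddball - w$perceptual_control, na.rm = TRUE)
  expect_gt(emo, 0)
  expect_gt(emo, per)
})

test_that("derived intrusion and repetition flags are trustworthy", {
  ds <- manual_dataset(list(c(3L, NA, 4L, 3L, 7L)))
  expect_equal(ds$recalls$is_intrusion, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(ds$recalls$is_repetition, c(FALSE, FALSE, FALSE, TRUE, FALSE))
})
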