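# Independent brute-force CRP scorer: materializes the available-item set
# explicitly at every output step and walks consecutive pairs. Kept naive on
# purpose so it shares no code with score_transitions().
brute_force_crp <- function(sp, list_length, window, anchor_pos = NULL) {
  lags <- setdiff(seq.int(-window, window), 0L)
  actual <- stats::setNames(rep(0L, length(lags)), lags)
  possible <- actual
  n <- length(sp)
  is_valid <- function(k) {
    if (is.na(sp[k])) return(FALSE)           # intrusion
    earlier <- sp[seq_len(k - 1)]
    !(sp[k] %in% earlier[!is.na(earlier)])    # repetition
  }
  for (k in seq_len(n - 1)) {
    if (!is_valid(k) || !is_valid(k + 1)) next
    if (!is.null(anchor_pos) && sp[k] != anchor_pos) next
    seen <- sp[seq_len(k)]
    available <- setdiff(seq_len(list_length), seen[!is.na(seen)])
    for (j in available) {
      lg <- j - sp[k]
      if (abs(lg) <= window) {
        possible[as.character(lg)] <- possible[as.character(lg)] + 1L
      }
    }
    lg_a <- sp[k + 1] - sp[k]
    if (abs(lg_a) <= window) {
      actual[as.character(lg_a)] <- actual[as.character(lg_a)] + 1L
    }
  }
  tibble::tibble(lag = lags, actual = unname(actual),
                 possible = unname(possible))
}

# Random recall sequence possibly containing intrusions and repetitions,
# for property tests against the brute-force scorer.
random_trial <- function(list_length) {
  n_events <- sample.int(list_length + 3L, 1L)
  sp <- integer(0)
  for (k in seq_len(n_events)) {
    r <- stats::runif(1)
    sp <- c(sp, if (r < 0.15) NA_integer_  # intrusion
           else if (r < 0.3 && length(sp[!is.na(sp)]) > 0)
             sample(sp[!is.na(sp)], 1L)    # repetition
           else sample.int(list_length, 1L))
  }
  sp
}

# Brute-force sum-of-squares decomposition for a 2x2 within-subject design,
# written directly from the textbook formulas (cell/marginal means), fully
# independent of aov().
ss_oracle_2x2 <- function(y) {
  # y: n x 4 matrix with columns A1B1, A1B2, A2B1, A2B2
  n <- nrow(y)
  grand <- mean(y)
  subj_means <- rowMeans(y)
  a_means <- c(mean(y[, 1:2]), mean(y[, 3:4]))
  b_means <- c(mean(y[, c(1, 3)]), mean(y[, c(2, 4)]))
  cell_means <- colMeans(y)
  ss_a <- 2 * n * sum((a_means - grand)^2)
  ss_b <- 2 * n * sum((b_means - grand)^2)
  cells_ab <- matrix(cell_means, 2, 2, byrow = TRUE)  # rows A, cols B
  ss_ab <- n * sum((cells_ab - outer(a_means, rep(0, 2), "+") -
                      outer(rep(0, 2), b_means, "+") + grand)^2)
  # subject x effect interaction error terms
  ya <- cbind(rowMeans(y[, 1:2, drop = FALSE]),
              rowMeans(y[, 3:4, drop = FALSE]))
  ss_as <- 2 * sum((ya - outer(subj_means, rep(0, 2), "+") -
                      matrix(a_means, n, 2, byrow = TRUE) + grand)^2)
  yb <- cbind(rowMeans(y[, c(1, 3), drop = FALSE]),
              rowMeans(y[, c(2, 4), drop = FALSE]))
  ss_bs <- 2 * sum((yb - outer(subj_means, rep(0, 2), "+") -
                      matrix(b_means, n, 2, byrow = TRUE) + grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_subj <- 4 * sum((subj_means - grand)^2)
  ss_abs <- ss_tot - ss_subj - ss_a - ss_b - ss_ab - ss_as - ss_bs
  list(
    A = list(ss = ss_a, ss_err = ss_as, df = 1, df_err = n - 1),
    B = list(ss = ss_b, ss_err = ss_bs, df = 1, df_err = n - 1),
    AB = list(ss = ss_ab, ss_err = ss_abs, df = 1, df_err = n - 1)
  )
}

# Long-format tibble from an n x 4 cell matrix (A1B1, A1B2, A2B1, A2B2).
cells_to_long <- function(y) {
  tidyr::expand_grid(subject = seq_len(nrow(y)), a = c("A1", "A2"),
                     b = c("B1", "B2")) |>
    dplyr::mutate(value = as.vector(t(y)))
}

# Small simulated dataset shared across measure tests.
tiny_dataset <- function(n_subjects = 4, seed = 11, ...) {
  design <- generate_design(seed)
  simulate_experiment(design, sim_params(n_subjects = n_subjects,
                                         seed = seed, ...))
}

# Hand-built dataset: one 14-item emotional list (oddball at 9, control 12)
# and given recall sequences (list of integer vectors, NA = intrusion).
manual_dataset <- function(recalls_by_subject,
                           oddball_pos = 9L, control_pos = 12L,
                           oddball_type = "emotional", soa = 2) {
  items <- tibble::tibble(
    list_id = "L01", list_index = 1L, oddball_type = oddball_type,
    soa_s = soa, serial_position = 1:14,
    item_role = ifelse(1:14 == oddball_pos,
                       paste0(oddball_type, "_oddball"),
                       ifelse(1:14 == control_pos, "control", "standard")),
    word_id = sprintf("L01_w%02d", 1:14),
    font_deviant = oddball_type == "perceptual" & 1:14 == oddball_pos,
    semantic_category = "cat_01"
  )
  class(items) <- c("experiment_design", class(items))
  recalls <- purrr::imap(recalls_by_subject, function(sp, i) {
    tibble::tibble(subject_id = sprintf("S%03d", i), list_id = "L01",
                   output_position = seq_along(sp),
                   serial_position = as.integer(sp))
  })
  new_recall_dataset(items, dplyr::bind_rows(recalls))
}
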