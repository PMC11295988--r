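#' Score lag transitions for a single recall sequence
#'
#' Implements conditional-response-probability (CRP) transition scoring for
#' one trial. Consecutive recall pairs are scored only when both events are
#' correct first-time recalls: intrusions and repetitions are excluded and
#' never bridged (the pair following an excluded event is also unscored,
#' because its source is the excluded event). For a scored pair with source
#' at serial position `i` and target at `j`, the actual count at lag `j - i`
#' is incremented when `|lag| <= window`, and the possible count at lag
#' `j' - i` is incremented for every not-yet-recalled serial position `j'`
#' (an item is "recalled" once it has appeared as a correct recall at any
#' earlier output position, including the source itself).
#'
#' @param trial Either an integer vector of recalled serial positions in
#'   output order (NA marking intrusions) or a tibble of recall events with a
#'   `serial_position` column ordered by `output_position`.
#' @param list_length Number of items in the studied list.
#' @param window Maximum |lag| scored (default 5).
#'
#' @return A tibble with columns `lag` (-window..-1, 1..window), `actual`,
#'   `possible` and `crp` (`actual / possible`, NA where `possible` is 0).
#' @export
#' @examples
#' score_transitions(c(3L, 4L, 2L), list_length = 5)
score_transitions <- function(trial, list_length, window = 5L) {
  sp <- if (is.data.frame(trial)) {
    trial$serial_position[order(trial$output_position %||%
                                  seq_len(nrow(trial)))]
  } else {
    as.integer(trial)
  }
  counts <- score_sequence(sp, list_length, as.integer(window))
  lags <- setdiff(seq.int(-window, window), 0L)
  tibble::tibble(
    lag = lags,
    actual = counts$actual[lags + window + 1L],
    possible = counts$possible[lags + window + 1L],
    crp = ifelse(counts$possible[lags + window + 1L] > 0,
                 counts$actual[lags + window + 1L] /
                   counts$possible[lags + window + 1L], NA_real_)
  )
}

# Core per-trial counting loop. Counts are indexed by lag + window + 1 over
# -window..window (the lag-0 slot stays zero). If anchor_pos is given, only
# the pair whose source is the anchor item contributes.
score_sequence <- function(sp, list_length, window, anchor_pos = NULL) {
  if (any(!is.na(sp) & (sp < 1L | sp > list_length))) {
    stop("malformed trial: serial position outside 1..", list_length,
         call. = FALSE)
  }
  valid <- !is.na(sp) & !duplicated(sp, incomparables = NA)
  k_len <- 2L * window + 1L
  actual <- integer(k_len)
  possible <- integer(k_len)
  recalled <- logical(list_length)
  n <- length(sp)
  for (k in seq_len(n)) {
    if (valid[k]) recalled[sp[k]] <- TRUE
    if (k < n && valid[k] && valid[k + 1L] &&
        (is.null(anchor_pos) || sp[k] == anchor_pos)) {
      lag_p <- which(!recalled) - sp[k]
      lag_p <- lag_p[lag_p >= -window & lag_p <= window]
      possible[lag_p + window + 1L] <- possible[lag_p + window + 1L] + 1L
      lag_a <- sp[k + 1L] - sp[k]
      if (abs(lag_a) <= window)
        actual[lag_a + window + 1L] <- actual[lag_a + window + 1L] + 1L
    }
  }
  list(actual = actual, possible = possible)
}

# Shared pooling engine behind lag_crp() and anchored_crp(). Scores every
# trial, pools actual/possible counts per subject (x metadata groups), then
# forms the ratio (pool-then-divide, not mean of per-list ratios).
pool_crp <- function(dataset, window, by, anchored_role = NULL) {
  meta <- list_meta(dataset$design)
  list_length <- max(dataset$design$serial_position)
  recalls <- dataset$recalls
  if (nrow(recalls) == 0L) {
    warning("no trials after filtering; returning empty curve set",
            call. = FALSE)
    out <- tibble::tibble(subject_id = character())
    for (b in by) out[[b]] <- meta[[b]][0]
    out$lag <- integer()
    out$actual <- integer()
    out$possible <- integer()
    out$crp <- numeric()
    return(out)
  }

  trial_key <- paste(recalls$subject_id, recalls$list_id, sep = "\r")
  seqs <- split(recalls$serial_position, factor(trial_key,
                                                levels = unique(trial_key)))
  trials <- tibble::tibble(
    subject_id = sub("\r.*$", "", names(seqs)),
    list_id = sub("^.*\r", "", names(seqs))
  )
  trials <- dplyr::left_join(trials, meta, by = "list_id")
  anchor <- if (is.null(anchored_role)) {
    rep(list(NULL), nrow(trials))
  } else if (anchored_role == "oddball") {
    as.list(trials$oddball_pos)
  } else {
    as.list(trials$control_pos)
  }

  k_len <- 2L * window + 1L
  mat <- matrix(0L, nrow = length(seqs), ncol = 2L * k_len)
  for (t in seq_along(seqs)) {
    sc <- score_sequence(seqs[[t]], list_length, window, anchor[[t]])
    mat[t, ] <- c(sc$actual, sc$possible)
  }

  grp_cols <- c("subject_id", by)
  grp_key <- do.call(paste, c(trials[grp_cols], sep = "\r"))
  pooled <- rowsum(mat, grp_key, reorder = FALSE)
  keys <- trials[!duplicated(grp_key), grp_cols, drop = FALSE]
  keys <- keys[match(rownames(pooled), unique(grp_key)), , drop = FALSE]

  lags <- setdiff(seq.int(-window, window), 0L)
  idx <- lags + window + 1L
  out <- tidyr::expand_grid(keys, lag = lags)
  out$actual <- as.integer(t(pooled[, idx, drop = FALSE]))
  out$possible <- as.integer(t(pooled[, k_len + idx, drop = FALSE]))
  out$crp <- ifelse(out$possible > 0, out$actual / out$possible, NA_real_)
  out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(grp_cols)), .data$lag)
  attr(out, "window") <- window
  out
}

#' Per-subject lag-CRP curves
#'
#' Computes the standard lag conditional response probability per subject:
#' transition counts from [score_transitions()] are pooled over all of a
#' subject's trials (optionally within levels of list metadata given in
#' `by`), and the ratio actual/possible is formed from the pooled counts.
#' Lags where a subject has zero opportunities are undefined (NA).
#'
#' @param dataset A `recall_dataset` (optionally pre-restricted with
#'   [filter_trials()]).
#' @param window Maximum |lag| scored (default 5).
#' @param by Character vector of list-metadata columns to condition on
#'   (e.g. `"oddball_type"`, `"soa_s"`).
#'
#' @return A tibble with columns `subject_id`, the `by` columns, `lag`,
#'   `actual`, `possible`, `crp`.
#' @export
#' @examples
#' ds <- simulate_experiment(generate_design(1), sim_params(n_subjects = 2))
#' lag_crp(ds, by = "oddball_type")
lag_crp <- function(dataset, window = 5L, by = character()) {
  pool_crp(dataset, as.integer(window), by, anchored_role = NULL)
}

#' Per-subject anchored CRP curves
#'
#' The item-anchored variant of the lag-CRP: only transitions whose source
#' event is the designated anchor item (the list's oddball or its matched
#' control) are counted, and lags are measured from the anchor's encoding
#' position, so lag 0 denotes the anchor itself and carries no ratio.
#' Scoring and exclusion rules are identical to [score_transitions()];
#' counts are pooled per subject before ratios are formed, as in
#' [lag_crp()].
#'
#' @inheritParams lag_crp
#' @param anchor_role `"oddball"` or `"control"`: which designated item
#'   anchors the transitions.
#'
#' @return A tibble with columns `subject_id`, the `by` columns,
#'   `anchor_role`, `lag`, `actual`, `possible`, `crp`.
#' @export
#' @examples
#' ds <- simulate_experiment(generate_design(1), sim_params(n_subjects = 2))
#' anchored_crp(ds, "oddball", by = "oddball_type")
anchored_crp <- function(dataset, anchor_role = c("oddball", "control"),
                         window = 5L, by = character()) {
  anchor_role <- match.arg(anchor_role)
  out <- pool_crp(dataset, as.integer(window), by, anchored_role = anchor_role)
  out <- dplyr::mutate(out, anchor_role = anchor_role,
                       .after = dplyr::all_of(c("subject_id", by)))
  out
}

#' Mean CRP over forward or backward lags
#'
#' Averages the defined CRP values over positive lags (forward) or negative
#' lags (backward) within each curve; undefined lags (zero opportunities) are
#' excluded from the mean, and a curve with no defined lag in the requested
#' direction yields NA.
#'
#' @param curves A curve tibble from [lag_crp()] or [anchored_crp()].
#' @param direction `"forward"` (lags +1..+W) or `"backward"` (lags -W..-1).
#'
#' @return A tibble with one row per curve (grouping columns of `curves`
#'   other than lag/actual/possible/crp), plus `direction`, `mean_crp` and
#'   `n_defined` (number of defined lags entering the mean).
#' @export
mean_directional_crp <- function(curves,
                                 direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  keep <- if (direction == "forward") curves$lag > 0 else curves$lag < 0
  grp <- setdiff(names(curves), c("lag", "actual", "possible", "crp"))
  out <- dplyr::summarise(
    dplyr::group_by(curves[keep, ], dplyr::across(dplyr::all_of(grp))),
    mean_crp = if (any(!is.na(.data$crp))) mean(.data$crp, na.rm = TRUE)
               else NA_real_,
    n_defined = sum(!is.na(.data$crp)),
    .groups = "drop"
  )
  dplyr::mutate(out, direction = direction, .before = "mean_crp")
}

#' Per-subject anchored directional CRP means for the 2x2 design
#'
#' Convenience wrapper producing the cell means entering the central
#' repeated-measures analysis: for each subject, salience type (emotional,
#' perceptual list) and novelty (oddball vs control anchor), the mean
#' anchored CRP over the requested direction.
#'
#' @inheritParams lag_crp
#' @param direction `"forward"` or `"backward"`.
#'
#' @return A tibble with columns `subject_id`, `oddball_type`, `anchor_role`,
#'   `direction`, `mean_crp`, `n_defined`.
#' @export
anchored_cell_means <- function(dataset, direction = c("forward", "backward"),
                                window = 5L) {
  direction <- match.arg(direction)
  curves <- dplyr::bind_rows(
    anchored_crp(dataset, "oddball", window = window, by = "oddball_type"),
    anchored_crp(dataset, "control", window = window, by = "oddball_type")
  )
  mean_directional_crp(curves, direction)
}
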