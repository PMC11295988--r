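# Per-trial summary used by several measures: unique correct recalls and the
# output position at which each studied serial position was first recalled.
correct_recalls <- function(dataset) {
  dplyr::filter(dataset$recalls, !.data$is_intrusion, !.data$is_repetition)
}

trial_universe <- function(dataset) {
  dplyr::distinct(dataset$recalls, .data$subject_id, .data$list_id)
}

#' Percent of items recalled per list, by SOA
#'
#' For each subject and SOA level: 100 x (unique correct recalls) / (items
#' presented) over that subject's lists at that SOA. The denominator counts
#' all list items, oddballs included.
#'
#' @param dataset A `recall_dataset`.
#'
#' @return A tibble with columns `subject_id`, `soa_s`, `value` (percent)
#'   and `n_opportunities` (items presented).
#' @export
total_recall_by_soa <- function(dataset) {
  meta <- list_meta(dataset$design)
  n_items <- max(dataset$design$serial_position)
  trials <- dplyr::left_join(trial_universe(dataset),
                             meta[, c("list_id", "soa_s")], by = "list_id")
  hits <- dplyr::count(
    dplyr::left_join(correct_recalls(dataset),
                     meta[, c("list_id", "soa_s")], by = "list_id"),
    .data$subject_id, .data$soa_s, name = "n_correct")
  out <- dplyr::count(trials, .data$subject_id, .data$soa_s,
                      name = "n_trials")
  out <- dplyr::left_join(out, hits, by = c("subject_id", "soa_s"))
  out$n_correct[is.na(out$n_correct)] <- 0L
  dplyr::transmute(
    out, .data$subject_id, .data$soa_s,
    value = 100 * .data$n_correct / (.data$n_trials * n_items),
    n_opportunities = .data$n_trials * n_items
  )
}

# Join correct recalls of the designated item (oddball or control) onto the
# trial universe; `probe_pos` gives the probed serial position per list.
role_position <- function(meta, role) {
  if (role == "oddball") meta$oddball_pos else meta$control_pos
}

#' Recall proportion of the oddball or matched control item
#'
#' For each subject and oddball type: the fraction of lists in which the
#' designated item (the oddball, or the input-matched control) was correctly
#' recalled.
#'
#' @param dataset A `recall_dataset`.
#' @param role `"oddball"` or `"control"`.
#'
#' @return A tibble with columns `subject_id`, `oddball_type`, `role`,
#'   `value` (proportion, NA when a subject has no lists of a type) and
#'   `n_opportunities` (lists of that type).
#' @export
item_recall_proportion <- function(dataset, role = c("oddball", "control")) {
  role <- match.arg(role)
  meta <- list_meta(dataset$design)
  meta$probe_pos <- role_position(meta, role)
  trials <- dplyr::left_join(
    trial_universe(dataset),
    meta[, c("list_id", "oddball_type", "probe_pos")], by = "list_id")
  hit <- dplyr::semi_join(
    trials,
    dplyr::inner_join(correct_recalls(dataset),
                      meta[, c("list_id", "probe_pos")], by = "list_id") |>
      dplyr::filter(.data$serial_position == .data$probe_pos),
    by = c("subject_id", "list_id"))
  trials$hit <- paste(trials$subject_id, trials$list_id) %in%
    paste(hit$subject_id, hit$list_id)
  out <- dplyr::summarise(
    dplyr::group_by(trials, .data$subject_id, .data$oddball_type),
    value = mean(.data$hit),
    n_opportunities = dplyr::n(),
    .groups = "drop")
  dplyr::mutate(out, role = role, .after = "oddball_type")
}

#' Recall of items neighbouring the oddball (and its matched control)
#'
#' For each subject, oddball type, reference item and signed offset: the
#' proportion of lists in which the item studied at (reference position +
#' offset) was correctly recalled. The reference is either the list's oddball
#' or its input-matched control, giving the matched comparison used to test
#' retrograde (negative offsets, e.g. the E-1 item) and anterograde amnesic
#' effects. Lists where the probed position falls outside the list are
#' excluded and counted.
#'
#' @param dataset A `recall_dataset`.
#' @param offsets Nonzero integer offsets relative to the reference position.
#'
#' @return A tibble with columns `subject_id`, `oddball_type`, `role`
#'   (reference item), `offset`, `value` (proportion), `n_opportunities`
#'   (lists probed) and `n_excluded` (lists where the probe fell outside
#'   the list).
#' @export
peri_oddball_recall <- function(dataset, offsets = c(-2L, -1L, 1L, 2L)) {
  offsets <- as.integer(offsets)
  if (any(offsets == 0L))
    stop("offsets must be nonzero; offset 0 is the reference item itself",
         call. = FALSE)
  n_items <- max(dataset$design$serial_position)
  meta <- list_meta(dataset$design)
  cr <- correct_recalls(dataset)
  universe <- trial_universe(dataset)

  res <- purrr::map(c("oddball", "control"), function(role) {
    meta_r <- meta
    meta_r$ref_pos <- role_position(meta, role)
    purrr::map(offsets, function(off) {
      meta_o <- dplyr::mutate(meta_r, probe_pos = .data$ref_pos + off)
      trials <- dplyr::left_join(
        universe, meta_o[, c("list_id", "oddball_type", "probe_pos")],
        by = "list_id")
      trials$in_list <- trials$probe_pos >= 1L & trials$probe_pos <= n_items
      hit <- dplyr::inner_join(
        cr, meta_o[, c("list_id", "probe_pos")], by = "list_id") |>
        dplyr::filter(.data$serial_position == .data$probe_pos)
      trials$hit <- paste(trials$subject_id, trials$list_id) %in%
        paste(hit$subject_id, hit$list_id)
      out <- dplyr::summarise(
        dplyr::group_by(trials, .data$subject_id, .data$oddball_type),
        value = if (any(.data$in_list)) mean(.data$hit[.data$in_list])
                else NA_real_,
        n_opportunities = sum(.data$in_list),
        n_excluded = sum(!.data$in_list),
        .groups = "drop")
      dplyr::mutate(out, role = role, offset = off, .after = "oddball_type")
    })
  })
  dplyr::bind_rows(purrr::flatten(res))
}

#' Mean output position of the oddball or control item
#'
#' For each subject and condition: the mean recall output position of the
#' designated item over lists in which it was correctly recalled (first
#' occurrence). Undefined (NA) when the item was never recalled.
#'
#' @param dataset A `recall_dataset`.
#' @param role `"oddball"` or `"control"`.
#' @param by Extra list-metadata columns to condition on (e.g. `"soa_s"`).
#'
#' @return A tibble with columns `subject_id`, `oddball_type`, the `by`
#'   columns, `role`, `value` (mean output position) and `n_opportunities`
#'   (lists where the item was recalled).
#' @export
output_position <- function(dataset, role = c("oddball", "control"),
                            by = character()) {
  role <- match.arg(role)
  meta <- list_meta(dataset$design)
  meta$probe_pos <- role_position(meta, role)
  hits <- dplyr::inner_join(
    correct_recalls(dataset),
    meta[, c("list_id", "oddball_type", "probe_pos", by)], by = "list_id") |>
    dplyr::filter(.data$serial_position == .data$probe_pos)
  grp <- c("subject_id", "oddball_type", by)
  universe <- dplyr::distinct(
    dplyr::left_join(trial_universe(dataset), meta, by = "list_id"),
    dplyr::across(dplyr::all_of(grp)))
  out <- dplyr::summarise(
    dplyr::group_by(hits, dplyr::across(dplyr::all_of(grp))),
    value = mean(.data$output_position),
    n_opportunities = dplyr::n(),
    .groups = "drop")
  out <- dplyr::left_join(universe, out, by = grp)
  out$n_opportunities[is.na(out$n_opportunities)] <- 0L
  dplyr::mutate(out, role = role, .after = dplyr::last(grp))
}

#' Probability of first recall by serial position
#'
#' For each subject and serial position: the fraction of the subject's trials
#' whose first correct recall is the item studied at that position. Trials
#' that open with intrusions use the first correct recall; trials with no
#' correct recall contribute to no position, so per-subject probabilities sum
#' to at most 1.
#'
#' @param dataset A `recall_dataset`.
#'
#' @return A tibble with columns `subject_id`, `serial_position`, `value`
#'   and `n_opportunities` (the subject's trial count).
#' @export
probability_first_recall <- function(dataset) {
  n_items <- max(dataset$design$serial_position)
  n_trials <- dplyr::count(trial_universe(dataset), .data$subject_id,
                           name = "n_trials")
  firsts <- dplyr::slice_head(
    dplyr::group_by(correct_recalls(dataset), .data$subject_id,
                    .data$list_id), n = 1L)
  firsts <- dplyr::count(dplyr::ungroup(firsts), .data$subject_id,
                         .data$serial_position, name = "n_first")
  grid <- tidyr::expand_grid(
    subject_id = n_trials$subject_id,
    serial_position = seq_len(n_items))
  out <- dplyr::left_join(grid, firsts, by = c("subject_id",
                                               "serial_position"))
  out$n_first[is.na(out$n_first)] <- 0L
  out <- dplyr::left_join(out, n_trials, by = "subject_id")
  dplyr::transmute(out, .data$subject_id, .data$serial_position,
                   value = .data$n_first / .data$n_trials,
                   n_opportunities = .data$n_trials)
}

#' Per-subject pairs for the forward-flow vs E-1 recall correlation
#'
#' Assembles, for each subject, the forward flow from emotional oddballs
#' (mean anchored forward CRP over emotional lists) and recall of the item
#' studied immediately before the emotional oddball (the E-1 item), the two
#' quantities whose correlation tests whether a stronger tendency to leave
#' the oddball in the forward direction accompanies a retrograde amnesic
#' effect. Subjects with either component undefined are excluded and counted.
#'
#' @param dataset A `recall_dataset`.
#' @param window CRP window for the forward-flow component.
#' @param condition_on_oddball_recall If TRUE, the E-1 recall proportion is
#'   computed only over lists in which the oddball itself was recalled;
#'   default FALSE (all emotional lists).
#'
#' @return A tibble with columns `subject_id`, `forward_flow`, `e_minus_1`;
#'   the number of excluded subjects is attached as attribute `n_excluded`.
#'   Errors if fewer than 3 complete pairs remain.
#' @export
forwardflow_amnesia_correlation <- function(dataset, window = 5L,
                                            condition_on_oddball_recall =
                                              FALSE) {
  emo <- filter_trials(dataset, .data$oddball_type == "emotional")
  ff <- mean_directional_crp(
    anchored_crp(emo, "oddball", window = window), "forward")
  e1_ds <- emo
  if (condition_on_oddball_recall) {
    meta <- list_meta(emo$design)
    odd_hit <- dplyr::inner_join(
      correct_recalls(emo), meta[, c("list_id", "oddball_pos")],
      by = "list_id") |>
      dplyr::filter(.data$serial_position == .data$oddball_pos)
    e1_ds$recalls <- dplyr::semi_join(
      emo$recalls, odd_hit, by = c("subject_id", "list_id"))
  }
  e1 <- dplyr::filter(peri_oddball_recall(e1_ds, offsets = -1L),
                      .data$role == "oddball")
  pairs <- dplyr::inner_join(
    dplyr::select(ff, "subject_id", forward_flow = "mean_crp"),
    dplyr::select(e1, "subject_id", e_minus_1 = "value"),
    by = "subject_id")
  complete <- stats::complete.cases(pairs$forward_flow, pairs$e_minus_1)
  n_excluded <- nrow(pairs) - sum(complete)
  pairs <- pairs[complete, ]
  if (nrow(pairs) < 3L)
    stop("insufficient data: fewer than 3 subjects with both components ",
         "defined", call. = FALSE)
  attr(pairs, "n_excluded") <- n_excluded
  pairs
}
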