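#' Parameters of the generative recall simulator
#'
#' The simulator is a deliberately minimal strength-sampling model of free
#' recall: the first recall favours early serial positions, subsequent recalls
#' are drawn among not-yet-recalled items with probability proportional to an
#' association strength that decays exponentially with encoding distance, and
#' recall terminates by an SOA-dependent stop rule. Each qualitative recall
#' signature is controlled by one parameter, so any signature can be produced
#' or silenced independently.
#'
#' @param tau Contiguity length scale in items (> 0). Association strength
#'   between positions `i` and `j` decays as `exp(-|i - j| / tau)`.
#' @param phi_fwd Forward asymmetry multiplier (>= 1) applied when `j > i`;
#'   values above 1 produce forward-contiguous recall.
#' @param sigma_odd Oddball recallability boost (>= 1) applied whenever the
#'   target `j` is an oddball; values above 1 produce the Von Restorff
#'   recall enhancement.
#' @param b_E,b_P Emotional / perceptual forward-binding boosts (>= 1) applied
#'   to forward transitions whose source `i` is an emotional / perceptual
#'   oddball; `b_E > 1 = b_P` yields the selective emotional forward-flow
#'   enhancement.
#' @param theta_p Primacy rate (>= 0) of the first recall: first-recall
#'   probability is proportional to `exp(-theta_p * (sp - 1))`.
#' @param rho0,rho1,rho_min Stop rule: after each recall the trial stops with
#'   probability `max(rho_min, rho0 - rho1 * soa)`; `rho1 > 0` makes recall
#'   totals grow with SOA. `rho_min` must lie in (0, 1).
#' @param p_intrusion Per-step probability in \[0, 1) of emitting an
#'   extra-list intrusion instead of a within-list recall.
#' @param n_subjects Number of simulated subjects.
#' @param seed Integer seed; each subject gets an independent sub-stream
#'   derived from it, so results do not depend on subject iteration order.
#'
#' @return A list of class `sim_params`.
#' @export
#' @examples
#' sim_params(b_E = 1, b_P = 1) # null emotional binding
sim_params <- function(tau = 2.5, phi_fwd = 1.6, sigma_odd = 1.8,
                       b_E = 2.0, b_P = 1.0, theta_p = 0.35,
                       rho0 = 0.35, rho1 = 0.04, rho_min = 0.05,
                       p_intrusion = 0.02, n_subjects = 70L, seed = 1L) {
  p <- list(tau = tau, phi_fwd = phi_fwd, sigma_odd = sigma_odd,
            b_E = b_E, b_P = b_P, theta_p = theta_p,
            rho0 = rho0, rho1 = rho1, rho_min = rho_min,
            p_intrusion = p_intrusion,
            n_subjects = as.integer(n_subjects), seed = as.integer(seed))
  stopifnot(
    p$tau > 0, p$phi_fwd >= 1, p$sigma_odd >= 1, p$b_E >= 1, p$b_P >= 1,
    p$theta_p >= 0, p$rho_min > 0, p$rho_min < 1,
    p$p_intrusion >= 0, p$p_intrusion < 1, p$n_subjects >= 1
  )
  structure(p, class = "sim_params")
}

#' Association strength between two studied items
#'
#' The retrieval strength used by the simulator when the item at serial
#' position `i` cues recall of the item at position `j`:
#' `A(i, j) = exp(-|i - j| / tau) * phi_fwd^[j > i] * b_E^[i emotional oddball
#' & j > i] * b_P^[i perceptual oddball & j > i] * sigma_odd^[j oddball]`.
#'
#' @param i,j Serial positions (1-based, `i != j`).
#' @param list_items A one-list tibble of items with columns `serial_position`
#'   and `item_role` (one list from an [generate_design()] design).
#' @param params A [sim_params()] object.
#'
#' @return A positive scalar.
#' @export
association_strength <- function(i, j, list_items, params) {
  stopifnot(length(i) == 1L, length(j) == 1L)
  n <- max(list_items$serial_position)
  if (i == j) stop("association_strength requires i != j", call. = FALSE)
  if (i < 1 || i > n || j < 1 || j > n)
    stop("serial positions must lie in 1..", n, call. = FALSE)
  role <- list_items$item_role[order(list_items$serial_position)]
  a <- exp(-abs(i - j) / params$tau)
  if (j > i) {
    a <- a * params$phi_fwd
    if (role[i] == "emotional_oddball") a <- a * params$b_E
    if (role[i] == "perceptual_oddball") a <- a * params$b_P
  }
  if (role[j] %in% c("emotional_oddball", "perceptual_oddball"))
    a <- a * params$sigma_odd
  a
}

# Full n x n association matrix for a list with one oddball of the given type
# at oddball_pos; row = cue item i, column = target j. Diagonal is NA.
assoc_matrix <- function(n_items, oddball_pos, oddball_type, params) {
  sp <- seq_len(n_items)
  d <- abs(outer(sp, sp, "-"))
  fwd <- outer(sp, sp, "<")
  a <- exp(-d / params$tau) * ifelse(fwd, params$phi_fwd, 1)
  boost <- if (oddball_type == "emotional") params$b_E else params$b_P
  a[oddball_pos, ] <- a[oddball_pos, ] *
    ifelse(sp > oddball_pos, boost, 1)
  a[, oddball_pos] <- a[, oddball_pos] * params$sigma_odd
  diag(a) <- NA_real_
  a
}

# Simulate one trial given the list's association matrix. Returns the integer
# recall sequence with NA marking intrusions. The cue after an intrusion is
# the last correct recall; the sampler never repeats an item.
sample_trial_sequence <- function(A, n_items, soa, params) {
  p_stop <- max(params$rho_min, params$rho0 - params$rho1 * soa)
  w1 <- exp(-params$theta_p * (seq_len(n_items) - 1))
  cur <- sample.int(n_items, 1L, prob = w1)
  seq_out <- cur
  recalled <- logical(n_items)
  recalled[cur] <- TRUE
  while (!all(recalled)) {
    if (stats::runif(1) < p_stop) break
    if (params$p_intrusion > 0 && stats::runif(1) < params$p_intrusion) {
      seq_out <- c(seq_out, NA_integer_)
      next
    }
    avail <- which(!recalled)
    w <- A[cur, avail]
    if (!any(w > 0)) {
      # tau small enough to underflow exp(-|lag|/tau): nearest item wins
      w <- as.numeric(abs(avail - cur) == min(abs(avail - cur)))
    }
    nxt <- if (length(avail) == 1L) avail else
      avail[sample.int(length(avail), 1L, prob = w)]
    seq_out <- c(seq_out, nxt)
    recalled[nxt] <- TRUE
    cur <- nxt
  }
  seq_out
}

#' Simulate recall for a single study list
#'
#' Draws one recall sequence under the strength-sampling model: the first
#' recall is sampled with probability proportional to
#' `exp(-theta_p * (sp - 1))`; then, until the stop rule fires (probability
#' `max(rho_min, rho0 - rho1 * soa)` per step), either an intrusion is emitted
#' (probability `p_intrusion`) or the next item is drawn among not-yet-recalled
#' items with probability proportional to the association strength from the
#' last correct recall. Trials always terminate; the sampler never produces
#' repetitions.
#'
#' @param list_items A one-list tibble (rows of a design for one `list_id`).
#' @param params A [sim_params()] object.
#'
#' @return A tibble of recall events with columns `output_position`,
#'   `serial_position` (NA for intrusions), `is_intrusion`, `is_repetition`.
#' @export
simulate_trial <- function(list_items, params) {
  stopifnot(inherits(params, "sim_params"))
  n <- max(list_items$serial_position)
  role <- list_items$item_role[order(list_items$serial_position)]
  odd_pos <- which(role %in% c("emotional_oddball", "perceptual_oddball"))
  odd_type <- if (length(odd_pos) && role[odd_pos[1]] == "emotional_oddball")
    "emotional" else "perceptual"
  A <- assoc_matrix(n, if (length(odd_pos)) odd_pos[1] else 1L, odd_type,
                    params)
  sp <- sample_trial_sequence(A, n, list_items$soa_s[1], params)
  tibble::tibble(
    output_position = seq_along(sp),
    serial_position = sp,
    is_intrusion = is.na(sp),
    is_repetition = FALSE
  )
}

# Derive a per-subject seed from the master seed so that each subject's
# random sub-stream is reproducible independently of iteration order.
subject_seed <- function(seed, subject_index) {
  (as.double(seed) * 7919 + subject_index * 104729) %% 2147483647
}

#' Simulate a full free-recall experiment
#'
#' Runs [simulate_trial()] for every subject x list combination. Each subject
#' uses an independent random sub-stream derived from `params$seed`, so the
#' dataset is byte-identical across runs and per-subject data do not depend on
#' the order subjects are simulated in.
#'
#' @param design An [generate_design()] design.
#' @param params A [sim_params()] object; `params$n_subjects` sets the number
#'   of simulated subjects.
#'
#' @return A `recall_dataset` object: a list with elements `design` (the
#'   design tibble), `recalls` (tibble with columns `subject_id`, `list_id`,
#'   `output_position`, `serial_position`, `is_intrusion`, `is_repetition`)
#'   and `params` (the `sim_params` used, or NULL for loaded data).
#' @export
#' @examples
#' d <- generate_design(1)
#' ds <- simulate_experiment(d, sim_params(n_subjects = 2))
#' dplyr::n_distinct(ds$recalls$subject_id, ds$recalls$list_id) # 2 x 40
simulate_experiment <- function(design, params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  meta <- list_meta(design)
  n_items <- max(design$serial_position)
  n_lists <- nrow(meta)

  # one association matrix per list (depends only on oddball pos/type)
  mats <- lapply(seq_len(n_lists), function(k)
    assoc_matrix(n_items, meta$oddball_pos[k], meta$oddball_type[k], params))

  per_subject <- lapply(seq_len(params$n_subjects), function(s) {
    withr::with_seed(subject_seed(params$seed, s), {
      seqs <- lapply(seq_len(n_lists), function(k)
        sample_trial_sequence(mats[[k]], n_items, meta$soa_s[k], params))
      lens <- lengths(seqs)
      tibble::tibble(
        subject_id = sprintf("S%03d", s),
        list_id = rep(meta$list_id, lens),
        output_position = unlist(lapply(lens, seq_len)),
        serial_position = unlist(seqs)
      )
    })
  })
  recalls <- dplyr::bind_rows(per_subject)
  recalls$is_intrusion <- is.na(recalls$serial_position)
  recalls$is_repetition <- FALSE

  new_recall_dataset(design, recalls, params)
}

#' Construct a recall dataset
#'
#' Bundles a design with recall events. Intrusion and repetition flags are
#' derived from the data, never trusted from the caller: an intrusion is an
#' event with no serial position; a repetition is a correct recall of a serial
#' position already recalled earlier in the same trial.
#'
#' @param design An experiment design tibble.
#' @param recalls A tibble with columns `subject_id`, `list_id`,
#'   `output_position`, `serial_position` (NA = intrusion).
#' @param params The [sim_params()] that generated the recalls, or NULL for
#'   externally loaded data.
#'
#' @return A `recall_dataset` object.
#' @export
new_recall_dataset <- function(design, recalls, params = NULL) {
  recalls <- tibble::as_tibble(recalls)
  recalls <- dplyr::arrange(recalls, .data$subject_id, .data$list_id,
                            .data$output_position)
  recalls$is_intrusion <- is.na(recalls$serial_position)
  recalls <- dplyr::group_by(recalls, .data$subject_id, .data$list_id)
  recalls <- dplyr::mutate(
    recalls,
    is_repetition = !.data$is_intrusion &
      duplicated(.data$serial_position, incomparables = NA)
  )
  recalls <- dplyr::ungroup(recalls)
  structure(list(design = design, recalls = recalls, params = params),
            class = "recall_dataset")
}

#' @export
print.recall_dataset <- function(x, ...) {
  n_sub <- dplyr::n_distinct(x$recalls$subject_id)
  n_lists <- dplyr::n_distinct(x$design$list_id)
  cat("<recall_dataset> ", n_sub, " subjects x ", n_lists, " lists, ",
      nrow(x$recalls), " recall events",
      if (is.null(x$params)) " (loaded)" else " (simulated)", "\n", sep = "")
  invisible(x)
}

#' Restrict a recall dataset to trials matching a condition
#'
#' Filters trials by list-level metadata (`oddball_type`, `soa_s`,
#' `list_id`, `list_index`, `oddball_pos`, `control_pos`) using ordinary
#' dplyr filter expressions. The design is kept intact; only trials are
#' dropped, so anchored analyses can still resolve every list.
#'
#' @param dataset A `recall_dataset`.
#' @param ... Filter expressions evaluated on the list metadata, e.g.
#'   `oddball_type == "emotional"` or `soa_s >= 3`.
#'
#' @return A `recall_dataset` with the subset of trials.
#' @export
filter_trials <- function(dataset, ...) {
  meta <- dplyr::filter(list_meta(dataset$design), ...)
  recalls <- dplyr::semi_join(dataset$recalls, meta, by = "list_id")
  structure(list(design = dataset$design, recalls = recalls,
                 params = dataset$params),
            class = "recall_dataset")
}
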