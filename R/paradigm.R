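#' Configuration for an oddball free-recall encoding design
#'
#' Bundles the structural parameters of the encoding phase: how many lists of
#' each oddball type, list length, where oddballs may appear, the stimulus
#' onset asynchrony (SOA) levels, and the minimum serial-position distance
#' between an oddball and its within-list control item. Defaults reproduce the
#' canonical emotional/perceptual oddball design: 40 lists of 14 nouns, 20
#' lists per oddball type, oddballs at serial positions 7, 8, 9, 11 or 12,
#' SOAs of 1, 2, 3, 4 or 6 s (4 lists per SOA per type), and controls at least
#' 3 positions from the oddball.
#'
#' @param n_lists_per_type Number of lists per oddball type (emotional,
#'   perceptual). Must be divisible by `length(soa_levels)`.
#' @param n_items Items per list.
#' @param oddball_positions Integer vector of allowed oddball serial positions.
#'   All must exceed `n_context_items` (the oddball never appears among the
#'   context-setting initial items).
#' @param soa_levels SOA levels in seconds.
#' @param min_control_distance Minimum |control position - oddball position|.
#' @param n_context_items Number of initial items that are always standard.
#' @param word_ms,distractor_s Presentation timing metadata (word duration in
#'   ms, post-list distractor duration in s). Carried in the config for the
#'   run manifest only; no timing is simulated.
#'
#' @return A list of class `design_config`.
#' @export
#' @examples
#' cfg <- design_config()
#' cfg$oddball_positions
design_config <- function(n_lists_per_type = 20L,
                          n_items = 14L,
                          oddball_positions = c(7L, 8L, 9L, 11L, 12L),
                          soa_levels = c(1, 2, 3, 4, 6),
                          min_control_distance = 3L,
                          n_context_items = 5L,
                          word_ms = 800,
                          distractor_s = 30) {
  cfg <- list(
    n_lists_per_type = as.integer(n_lists_per_type),
    n_items = as.integer(n_items),
    oddball_positions = sort(as.integer(oddball_positions)),
    soa_levels = sort(as.numeric(soa_levels)),
    min_control_distance = as.integer(min_control_distance),
    n_context_items = as.integer(n_context_items),
    word_ms = word_ms,
    distractor_s = distractor_s
  )
  stopifnot(
    cfg$n_lists_per_type >= 1L,
    cfg$n_items >= 2L,
    length(cfg$oddball_positions) >= 1L,
    all(cfg$oddball_positions >= 1L & cfg$oddball_positions <= cfg$n_items),
    length(cfg$soa_levels) >= 1L,
    cfg$min_control_distance >= 0L,
    cfg$n_context_items >= 0L
  )
  if (cfg$n_lists_per_type %% length(cfg$soa_levels) != 0L) {
    stop("`n_lists_per_type` must be divisible by the number of SOA levels ",
         "so lists can be balanced across SOAs.", call. = FALSE)
  }
  structure(cfg, class = "design_config")
}

# Admissible control positions for one oddball position: drawn from the same
# allowed-position set (so controls are input-matched to oddballs across
# lists), beyond the context items, and at least min_control_distance away.
control_candidates <- function(oddball_pos, config) {
  cand <- config$oddball_positions
  cand[cand > config$n_context_items &
         abs(cand - oddball_pos) >= config$min_control_distance]
}

# Perfect matching of control slots (a permutation of the oddball-position
# multiset) onto lists, respecting the distance rule, via augmenting paths.
# Returns the per-list control positions, or NULL when no matching exists.
match_controls <- function(oddball_pos, config) {
  n <- length(oddball_pos)
  slots <- sample(oddball_pos)   # randomized multiset of control positions
  compat <- lapply(seq_len(n), function(s)
    which(abs(slots[s] - oddball_pos) >= config$min_control_distance &
            slots[s] > config$n_context_items))
  match_of_list <- rep(NA_integer_, n)  # list -> slot
  visited <- logical(n)
  try_assign <- function(s) {
    cand <- compat[[s]]
    for (l in (if (length(cand) > 1L) sample(cand) else cand)) {
      if (visited[l]) next
      visited[l] <<- TRUE
      if (is.na(match_of_list[l]) || try_assign(match_of_list[l])) {
        match_of_list[l] <<- s
        return(TRUE)
      }
    }
    FALSE
  }
  for (s in seq_len(n)) {
    visited <- logical(n)
    if (!try_assign(s)) return(NULL)
  }
  slots[match_of_list]
}

# Control positions input-matched to oddballs: within each oddball type the
# multiset of control positions equals the multiset of oddball positions (so
# every oddball has a control studied at the same serial position in another
# list), subject to the within-list distance rule. Oddball draws for which no
# such assignment exists are rejected and redrawn.
draw_positions <- function(n_lists, config, max_tries = 1000L) {
  for (. in seq_len(max_tries)) {
    op <- sample(config$oddball_positions, n_lists, replace = TRUE)
    cp <- match_controls(op, config)
    if (!is.null(cp)) return(list(oddball_pos = op, control_pos = cp))
  }
  stop("constraint-infeasible design config: could not input-match control ",
       "positions to oddball positions under the distance rule",
       call. = FALSE)
}

#' Generate an oddball free-recall encoding design
#'
#' Builds a randomized experiment design: for each list an oddball type,
#' an SOA (balanced so each SOA level gets an equal share of lists within each
#' oddball type), an oddball serial position drawn uniformly from the allowed
#' set, and a within-list control position drawn uniformly from the allowed
#' positions at least `min_control_distance` away. List order is shuffled.
#' Word tokens are synthetic placeholders unique within list; every list
#' carries a single shared semantic-category label.
#'
#' @param seed Integer seed; the same seed always yields the identical design.
#' @param config A [design_config()].
#'
#' @return A tibble of class `experiment_design` with one row per item and
#'   columns `list_id`, `list_index`, `oddball_type`, `soa_s`,
#'   `serial_position`, `item_role` (one of `standard`, `emotional_oddball`,
#'   `perceptual_oddball`, `control`), `word_id` and `font_deviant`. The seed
#'   and config are attached as attributes.
#' @export
#' @examples
#' d <- generate_design(seed = 1)
#' dplyr::count(d, oddball_type, soa_s) # 4 lists x 14 items per cell
generate_design <- function(seed, config = design_config()) {
  stopifnot(inherits(config, "design_config"), is.numeric(seed))
  infeasible <- config$oddball_positions[
    vapply(config$oddball_positions,
           function(op) length(control_candidates(op, config)) == 0L, logical(1))
  ]
  if (length(infeasible) > 0L) {
    stop("constraint-infeasible design config: no admissible control position ",
         "for oddball position(s) ", paste(infeasible, collapse = ", "),
         " given min_control_distance = ", config$min_control_distance,
         call. = FALSE)
  }

  n_per_soa <- config$n_lists_per_type %/% length(config$soa_levels)
  lists <- withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    meta <- tidyr::expand_grid(
      oddball_type = c("emotional", "perceptual"),
      soa_s = config$soa_levels,
      rep = seq_len(n_per_soa)
    )
    pos <- lapply(c("emotional", "perceptual"), function(ty)
      draw_positions(config$n_lists_per_type, config))
    meta$oddball_pos <- c(pos[[1]]$oddball_pos, pos[[2]]$oddball_pos)
    meta$control_pos <- c(pos[[1]]$control_pos, pos[[2]]$control_pos)
    meta[sample.int(nrow(meta)), ]
  })
  lists$list_index <- seq_len(nrow(lists))
  lists$list_id <- sprintf("L%02d", lists$list_index)
  lists$rep <- NULL

  items <- tidyr::expand_grid(
    lists[, c("list_id", "list_index", "oddball_type", "soa_s",
              "oddball_pos", "control_pos")],
    serial_position = seq_len(config$n_items)
  )
  items <- dplyr::mutate(
    items,
    item_role = dplyr::case_when(
      serial_position == oddball_pos & oddball_type == "emotional" ~
        "emotional_oddball",
      serial_position == oddball_pos & oddball_type == "perceptual" ~
        "perceptual_oddball",
      serial_position == control_pos ~ "control",
      TRUE ~ "standard"
    ),
    font_deviant = item_role == "perceptual_oddball",
    word_id = sprintf("%s_w%02d", list_id, serial_position),
    semantic_category = sprintf("cat_%02d", list_index),
    oddball_pos = NULL,
    control_pos = NULL
  )
  out <- tibble::as_tibble(items)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "config") <- config
  class(out) <- c("experiment_design", class(out))
  out
}

#' Validate an experiment design against the paradigm invariants
#'
#' Checks every structural rule a design must satisfy: 14 items per list with
#' gap-free 1-based serial positions, exactly one oddball and one control per
#' list, oddballs confined to the allowed positions, all context-setting
#' initial positions standard, the control beyond the context region and at
#' least the minimum distance from the oddball, font deviance if and only if
#' the item is a perceptual oddball, an equal split of lists between oddball
#' types, and SOA balance within each type.
#'
#' @param design A design tibble as returned by [generate_design()] (or read
#'   from CSV).
#' @param config The [design_config()] stating the rules; defaults to the
#'   config attached to `design`, or to `design_config()` if none.
#'
#' @return A tibble of violations with columns `list_id` (NA for design-level
#'   rules), `rule` and `detail`; zero rows iff the design is valid. This
#'   function reports, it never throws.
#' @export
validate_design <- function(design, config = NULL) {
  config <- config %||% attr(design, "config") %||% design_config()
  v <- list()
  bad <- function(list_id, rule, detail) {
    tibble::tibble(list_id = list_id, rule = rule, detail = detail)
  }

  per_list <- dplyr::group_by(tibble::as_tibble(design), .data$list_id)
  per_list <- dplyr::summarise(
    per_list,
    n_items = dplyr::n(),
    sp_ok = identical(sort(.data$serial_position), seq_len(dplyr::n())),
    n_oddball = sum(.data$item_role %in%
                      c("emotional_oddball", "perceptual_oddball")),
    n_control = sum(.data$item_role == "control"),
    oddball_pos = .data$serial_position[
      .data$item_role %in% c("emotional_oddball", "perceptual_oddball")][1],
    control_pos = .data$serial_position[.data$item_role == "control"][1],
    oddball_type = .data$oddball_type[1],
    soa_s = .data$soa_s[1],
    n_soa = dplyr::n_distinct(.data$soa_s),
    early_standard = all(.data$item_role[
      .data$serial_position <= config$n_context_items] == "standard"),
    font_ok = all(.data$font_deviant ==
                    (.data$item_role == "perceptual_oddball")),
    .groups = "drop"
  )

  for (i in seq_len(nrow(per_list))) {
    l <- per_list[i, ]
    if (l$n_items != config$n_items)
      v[[length(v) + 1]] <- bad(l$list_id, "item_count",
        sprintf("%d items, expected %d", l$n_items, config$n_items))
    if (!l$sp_ok)
      v[[length(v) + 1]] <- bad(l$list_id, "serial_positions",
        "serial positions are not 1..n without gaps")
    if (l$n_oddball != 1L)
      v[[length(v) + 1]] <- bad(l$list_id, "one_oddball",
        sprintf("%d oddball items, expected exactly 1", l$n_oddball))
    if (l$n_control != 1L)
      v[[length(v) + 1]] <- bad(l$list_id, "one_control",
        sprintf("%d control items, expected exactly 1", l$n_control))
    if (l$n_soa != 1L)
      v[[length(v) + 1]] <- bad(l$list_id, "soa_constant",
        "SOA varies within list")
    if (!is.na(l$oddball_pos) &&
        !(l$oddball_pos %in% config$oddball_positions))
      v[[length(v) + 1]] <- bad(l$list_id, "oddball_position",
        sprintf("oddball at position %d, allowed {%s}", l$oddball_pos,
                paste(config$oddball_positions, collapse = ",")))
    if (!l$early_standard)
      v[[length(v) + 1]] <- bad(l$list_id, "context_items_standard",
        sprintf("positions 1..%d must all be standard", config$n_context_items))
    if (!is.na(l$control_pos) && l$control_pos <= config$n_context_items)
      v[[length(v) + 1]] <- bad(l$list_id, "control_after_context",
        sprintf("control at position %d within context region", l$control_pos))
    if (!is.na(l$oddball_pos) && !is.na(l$control_pos) &&
        abs(l$control_pos - l$oddball_pos) < config$min_control_distance)
      v[[length(v) + 1]] <- bad(l$list_id, "control_distance",
        sprintf("|%d - %d| < %d", l$control_pos, l$oddball_pos,
                config$min_control_distance))
    if (!l$font_ok)
      v[[length(v) + 1]] <- bad(l$list_id, "font_deviant",
        "font_deviant must hold iff item is a perceptual oddball")
  }

  type_counts <- dplyr::count(per_list, .data$oddball_type)
  for (i in seq_len(nrow(type_counts))) {
    if (type_counts$n[i] != config$n_lists_per_type)
      v[[length(v) + 1]] <- bad(NA_character_, "lists_per_type",
        sprintf("%d %s lists, expected %d", type_counts$n[i],
                type_counts$oddball_type[i], config$n_lists_per_type))
  }
  n_per_soa <- config$n_lists_per_type %/% length(config$soa_levels)
  soa_counts <- dplyr::count(per_list, .data$oddball_type, .data$soa_s)
  cells <- tidyr::expand_grid(oddball_type = unique(per_list$oddball_type),
                              soa_s = config$soa_levels)
  soa_counts <- dplyr::left_join(cells, soa_counts,
                                 by = c("oddball_type", "soa_s"))
  soa_counts$n[is.na(soa_counts$n)] <- 0L
  for (i in seq_len(nrow(soa_counts))) {
    if (soa_counts$n[i] != n_per_soa)
      v[[length(v) + 1]] <- bad(NA_character_, "soa_balance",
        sprintf("%d %s lists at SOA %g, expected %d", soa_counts$n[i],
                soa_counts$oddball_type[i], soa_counts$soa_s[i], n_per_soa))
  }

  if (length(v) == 0L) {
    tibble::tibble(list_id = character(), rule = character(),
                   detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}

# One row per list: id, index, type, soa, oddball and control positions.
list_meta <- function(design) {
  d <- tibble::as_tibble(design)
  odd <- dplyr::filter(d, .data$item_role %in%
                         c("emotional_oddball", "perceptual_oddball"))
  odd <- dplyr::select(odd, "list_id", "list_index", "oddball_type", "soa_s",
                       oddball_pos = "serial_position")
  ctl <- dplyr::select(
    dplyr::filter(d, .data$item_role == "control"),
    "list_id", control_pos = "serial_position")
  dplyr::arrange(dplyr::left_join(odd, ctl, by = "list_id"), .data$list_index)
}
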