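design_cols <- c("list_id", "list_index", "oddball_type", "soa_s",
                 "serial_position", "item_role", "word_id")

#' Write / read an experiment design as CSV
#'
#' One row per item; columns `list_id`, `list_index`, `oddball_type`,
#' `soa_s`, `serial_position`, `item_role`, `word_id`. `font_deviant` is
#' derived on read (true iff the item is a perceptual oddball), not stored.
#'
#' @param design An [generate_design()] design.
#' @param path File path.
#' @return `write_design()` returns `path` invisibly; `read_design()`
#'   returns an `experiment_design` tibble.
#' @export
write_design <- function(design, path) {
  readr::write_csv(tibble::as_tibble(design)[, design_cols], path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(
    list_id = readr::col_character(),
    list_index = readr::col_integer(),
    oddball_type = readr::col_character(),
    soa_s = readr::col_double(),
    serial_position = readr::col_integer(),
    item_role = readr::col_character(),
    word_id = readr::col_character()
  ))
  missing <- setdiff(design_cols, names(d))
  if (length(missing) > 0L)
    stop("design CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  d$font_deviant <- d$item_role == "perceptual_oddball"
  class(d) <- c("experiment_design", class(d))
  d
}

#' Write / read recall events as CSV
#'
#' One row per recall event; columns `subject_id`, `list_id`,
#' `output_position`, `serial_position` (empty field = intrusion).
#' Intrusion and repetition flags are derived on read, never stored.
#'
#' @param dataset A `recall_dataset`.
#' @param path File path.
#' @return `write_recalls()` returns `path` invisibly.
#' @export
write_recalls <- function(dataset, path) {
  readr::write_csv(dataset$recalls[, c("subject_id", "list_id",
                                       "output_position",
                                       "serial_position")], path)
  invisible(path)
}

#' Read a recall dataset from design and recall CSVs
#'
#' Reads the two-file on-disk representation and validates it: every recall
#' row must reference a known list, (subject, list, output position) must be
#' unique, output positions must be consecutive from 1 within each trial,
#' and serial positions must lie within the list. Intrusion and repetition
#' flags are derived from the data.
#'
#' @param design_path Path to the design CSV (see [write_design()]).
#' @param recall_path Path to the recall CSV (see [write_recalls()]).
#'
#' @return A `recall_dataset`.
#' @export
read_recall_dataset <- function(design_path, recall_path) {
  design <- read_design(design_path)
  r <- readr::read_csv(recall_path, col_types = readr::cols(
    subject_id = readr::col_character(),
    list_id = readr::col_character(),
    output_position = readr::col_integer(),
    serial_position = readr::col_integer()
  ))
  needed <- c("subject_id", "list_id", "output_position", "serial_position")
  missing <- setdiff(needed, names(r))
  if (length(missing) > 0L)
    stop("recall CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(r) == 0L) {
    warning("recall file contains no events; dataset has zero trials",
            call. = FALSE)
    return(new_recall_dataset(design, r, params = NULL))
  }
  n_items <- max(design$serial_position)
  unknown <- which(!(r$list_id %in% design$list_id))
  if (length(unknown) > 0L)
    stop("schema error: unknown list_id '", r$list_id[unknown[1]],
         "' at recall row ", unknown[1], call. = FALSE)
  out_of_range <- which(!is.na(r$serial_position) &
                          (r$serial_position < 1L |
                             r$serial_position > n_items))
  if (length(out_of_range) > 0L)
    stop("schema error: serial_position ",
         r$serial_position[out_of_range[1]], " outside 1..", n_items,
         " at recall row ", out_of_range[1], call. = FALSE)
  key <- paste(r$subject_id, r$list_id, r$output_position)
  dup <- which(duplicated(key))
  if (length(dup) > 0L)
    stop("schema error: duplicate (subject_id, list_id, output_position) ",
         "at recall row ", dup[1], call. = FALSE)
  bad_seq <- dplyr::summarise(
    dplyr::group_by(r, .data$subject_id, .data$list_id),
    ok = identical(sort(.data$output_position), seq_len(dplyr::n())),
    .groups = "drop")
  if (any(!bad_seq$ok)) {
    b <- bad_seq[!bad_seq$ok, ][1, ]
    stop("schema error: output positions not consecutive from 1 for ",
         "subject ", b$subject_id, ", list ", b$list_id, call. = FALSE)
  }
  new_recall_dataset(design, r, params = NULL)
}

#' Pipeline configuration
#'
#' Bundles the design, simulation and analysis parameters of a full run.
#' Defaults reproduce the reference study conditions: 40 lists of 14 items,
#' oddballs at positions 7, 8, 9, 11, 12, SOAs of 1-6 s, CRP window 5, 70
#' subjects.
#'
#' @param design A [design_config()].
#' @param sim A [sim_params()].
#' @param window CRP window (max |lag| scored).
#' @param peri_offsets Offsets for [peri_oddball_recall()].
#' @param alpha Significance level for the inference stage.
#' @param seed Master seed (overrides `sim$seed`).
#' @param out_dir Output directory for [run_pipeline()].
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = design_config(), sim = sim_params(),
                            window = 5L, peri_offsets = c(-2L, -1L, 1L, 2L),
                            alpha = 0.05, seed = 1L, out_dir = "oddballcrp_out") {
  sim$seed <- as.integer(seed)
  structure(list(design = design, sim = sim, window = as.integer(window),
                 peri_offsets = as.integer(peri_offsets), alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# The full inference stage on a dataset: forward and backward 2x2 RM-ANOVAs
# on anchored directional CRP means, FDR-corrected post-hoc paired t-tests
# (oddball - control within each salience type), and the forward-flow vs E-1
# correlation. Returns a list; errors inside are converted to messages in
# `notes` so earlier pipeline stages still emit their outputs.
analyze_dataset <- function(dataset, window = 5L,
                            peri_offsets = c(-2L, -1L, 1L, 2L)) {
  res <- list(notes = character())
  res$recall_by_soa <- total_recall_by_soa(dataset)
  res$item_recall <- dplyr::bind_rows(
    item_recall_proportion(dataset, "oddball"),
    item_recall_proportion(dataset, "control"))
  res$output_position <- dplyr::bind_rows(
    output_position(dataset, "oddball"),
    output_position(dataset, "control"))
  res$pfr <- probability_first_recall(dataset)
  res$peri <- peri_oddball_recall(dataset, peri_offsets)
  res$cells <- dplyr::bind_rows(
    anchored_cell_means(dataset, "forward", window = window),
    anchored_cell_means(dataset, "backward", window = window))

  try_stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      res$notes <<- c(res$notes, paste0(label, ": ", conditionMessage(e)))
      NULL
    })
  }
  for (dir in c("forward", "backward")) {
    cells <- dplyr::filter(res$cells, .data$direction == dir)
    res$anova[[dir]] <- try_stage(
      paste0("rm_anova_", dir),
      rm_anova_2x2(cells, mean_crp, subject_id, oddball_type, anchor_role))
    ph <- try_stage(paste0("posthoc_", dir), {
      wide <- tidyr::pivot_wider(
        cells[, c("subject_id", "oddball_type", "anchor_role", "mean_crp")],
        names_from = "anchor_role", values_from = "mean_crp")
      tests <- purrr::map(c("emotional", "perceptual"), function(ty) {
        w <- dplyr::filter(wide, .data$oddball_type == ty)
        tt <- paired_t(w$control - w$oddball)
        dplyr::mutate(tidy(tt), contrast = paste0(ty, ": control - oddball"),
                      .before = 1)
      })
      out <- dplyr::bind_rows(tests)
      out$p_fdr <- fdr_adjust(out$p.value)
      out
    })
    res$posthoc[[dir]] <- ph
  }
  res$ff_pairs <- try_stage("forward_flow_correlation",
                            forwardflow_amnesia_correlation(dataset,
                                                            window = window))
  if (!is.null(res$ff_pairs))
    res$ff_corr <- try_stage(
      "forward_flow_correlation",
      pearson_corr(res$ff_pairs, forward_flow, e_minus_1))
  res
}

#' Run the full analysis pipeline
#'
#' Generates the design, simulates recall (or loads it from CSVs when
#' `design_path`/`recall_path` are given), computes the lag-CRP and anchored
#' CRP curves and all behavioural measures, runs the within-subject inference
#' stage, and writes every table as CSV together with a JSON run manifest
#' (configuration, seed, package version) and a plain-text summary report.
#' Inference-stage failures (e.g. too few subjects) are recorded in the
#' report; earlier stages still emit their outputs.
#'
#' @param config A [pipeline_config()].
#' @param design_path,recall_path Optional paths to an existing dataset; when
#'   NULL (default) a dataset is simulated from `config`.
#'
#' @return Invisibly, a list with the dataset, all measure tibbles, the
#'   inference results and the output paths.
#' @export
run_pipeline <- function(config = pipeline_config(), design_path = NULL,
                         recall_path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  if (is.null(design_path)) {
    design <- generate_design(config$seed, config$design)
    dataset <- simulate_experiment(design, config$sim)
  } else {
    dataset <- read_recall_dataset(design_path, recall_path)
    design <- dataset$design
  }
  write_design(design, out("design.csv"))
  write_recalls(dataset, out("recalls.csv"))

  curves <- lag_crp(dataset, window = config$window, by = "oddball_type")
  anchored <- dplyr::bind_rows(
    anchored_crp(dataset, "oddball", config$window, by = "oddball_type"),
    anchored_crp(dataset, "control", config$window, by = "oddball_type"))
  readr::write_csv(curves, out("lag_crp.csv"))
  readr::write_csv(anchored, out("anchored_crp.csv"))

  res <- analyze_dataset(dataset, config$window, config$peri_offsets)
  measures <- dplyr::bind_rows(
    dplyr::mutate(res$recall_by_soa, measure = "recall_pct_by_soa"),
    dplyr::mutate(res$item_recall, measure = "item_recall_proportion"),
    dplyr::mutate(res$output_position, measure = "output_position"),
    dplyr::mutate(dplyr::rename(res$pfr, position = "serial_position"),
                  measure = "probability_first_recall"),
    dplyr::mutate(res$peri, measure = "peri_oddball_recall"))
  readr::write_csv(measures, out("measures.csv"))
  readr::write_csv(res$cells, out("anchored_cell_means.csv"))

  inference <- dplyr::bind_rows(purrr::map(
    c("forward", "backward"), function(dir) {
      rows <- list()
      if (!is.null(res$anova[[dir]]))
        rows$anova <- dplyr::mutate(tidy(res$anova[[dir]]),
                                    analysis = paste0("rm_anova_", dir),
                                    .before = 1)
      if (!is.null(res$posthoc[[dir]]))
        rows$ph <- dplyr::mutate(res$posthoc[[dir]],
                                 analysis = paste0("posthoc_", dir),
                                 .before = 1)
      dplyr::bind_rows(rows)
    }))
  if (!is.null(res$ff_corr))
    inference <- dplyr::bind_rows(
      inference, dplyr::mutate(res$ff_corr,
                               analysis = "forwardflow_e1_correlation",
                               .before = 1))
  readr::write_csv(inference, out("inference.csv"))

  manifest <- list(
    package = "oddballcrp",
    version = as.character(utils::packageVersion("oddballcrp")),
    seed = config$seed,
    window = config$window,
    alpha = config$alpha,
    design = unclass(config$design),
    sim = unclass(config$sim),
    peri_offsets = config$peri_offsets
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  writeLines(render_report(res, config), out("report.txt"))

  invisible(list(dataset = dataset, curves = curves, anchored = anchored,
                 results = res, out_dir = config$out_dir))
}

# Plain-text summary of the full analysis, one section per measure family.
render_report <- function(res, config) {
  fmt_tbl <- function(x) utils::capture.output(print(as.data.frame(x),
                                                     row.names = FALSE))
  lines <- c(
    "oddballcrp pipeline report",
    paste0("seed: ", config$seed, "; window: ", config$window,
           "; subjects: ", config$sim$n_subjects),
    "",
    "== Mean recall (%) by SOA ==",
    fmt_tbl(dplyr::summarise(
      dplyr::group_by(res$recall_by_soa, .data$soa_s),
      mean_pct = mean(.data$value), .groups = "drop")),
    "",
    "== Oddball / control recall proportion ==",
    fmt_tbl(dplyr::summarise(
      dplyr::group_by(res$item_recall, .data$oddball_type, .data$role),
      mean_prop = mean(.data$value, na.rm = TRUE), .groups = "drop")),
    "",
    "== Mean output position ==",
    fmt_tbl(dplyr::summarise(
      dplyr::group_by(res$output_position, .data$oddball_type, .data$role),
      mean_output = mean(.data$value, na.rm = TRUE), .groups = "drop")),
    "",
    "== Anchored directional CRP means (group) ==",
    fmt_tbl(dplyr::summarise(
      dplyr::group_by(res$cells, .data$direction, .data$oddball_type,
                      .data$anchor_role),
      mean_crp = mean(.data$mean_crp, na.rm = TRUE), .groups = "drop"))
  )
  for (dir in c("forward", "backward")) {
    lines <- c(lines, "", paste0("== RM-ANOVA (", dir,
                                 " transitions): novelty x salience =="))
    lines <- c(lines, if (!is.null(res$anova[[dir]]))
      fmt_tbl(tidy(res$anova[[dir]])) else "  (not available)")
    lines <- c(lines, "", paste0("== Post-hoc paired t-tests (", dir,
                                 "), FDR-corrected =="))
    lines <- c(lines, if (!is.null(res$posthoc[[dir]]))
      fmt_tbl(res$posthoc[[dir]]) else "  (not available)")
  }
  lines <- c(lines, "", "== Forward flow vs E-1 recall correlation ==")
  lines <- c(lines, if (!is.null(res$ff_corr)) fmt_tbl(res$ff_corr)
             else "  (not available)")
  if (length(res$notes) > 0L)
    lines <- c(lines, "", "== Notes ==", paste0("  ", res$notes))
  lines
}
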