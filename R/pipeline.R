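table_specs <- function() {
  list(respondents = list(required = RESPONDENT_CORE_COLUMNS,
                          wave_cols = character(0)),
       rosters = list(required = ROSTER_COLUMNS, wave_cols = "wave"),
       matches = list(required = MATCH_COLUMNS,
                      wave_cols = c("wave_earlier", "wave_later")),
       attendance = list(required = ATTENDANCE_COLUMNS, wave_cols = "wave"))
}

check_waves <- function(df, table, cols) {
  for (cl in cols) {
    x <- df[[cl]]
    bad <- which(!is.na(x) & (x < 1 | x != floor(x)))
    if (length(bad) > 0)
      stop(sprintf(
        "%s: invalid wave index '%s' at row %d, column '%s' (waves are 1-based integers)",
        table, x[bad[1]], bad[1], cl), call. = FALSE)
  }
}

#' Read the four data-model tables from delimited text
#'
#' Strict, header-checked CSV reading (UTF-8, comma, header row). The
#' header must list the documented columns for the table, in order —
#' silently reordered columns are refused with a named-column error — and
#' wave indices must be 1-based integers (violations name the row and
#' column). The respondents table requires its core columns first and may
#' carry extra columns (per-wave orientation, recruitment) after them.
#'
#' @param paths named list/vector with entries `respondents`, `rosters`,
#'   `matches`, `attendance`.
#' @return named list of data frames.
#' @export
read_tables <- function(paths) {
  specs <- table_specs()
  missing <- setdiff(names(specs), names(paths))
  if (length(missing) > 0)
    stop(sprintf("missing input table(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  out <- list()
  for (tb in names(specs)) {
    path <- paths[[tb]]
    if (!file.exists(path))
      stop(sprintf("input file for table '%s' not found: %s", tb, path),
           call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    req <- specs[[tb]]$required
    have <- names(df)
    if (length(have) < length(req) ||
        !identical(have[seq_along(req)], req)) {
      diff <- union(setdiff(req, have),
                    head(have, length(req))[head(have, length(req)) !=
                                            req[seq_len(min(length(have),
                                                            length(req)))]])
      stop(sprintf(
        "%s: header mismatch (expected columns, in order: %s); offending column(s): %s",
        tb, paste(req, collapse = ", "),
        paste(unique(diff), collapse = ", ")), call. = FALSE)
    }
    for (cl in intersect(names(df),
                         c("attended", "is_primary_partner",
                           "alter_has_sex_with_men", "alter_hiv_positive",
                           "alter_exchange_sex", "alter_payment_received",
                           "hiv_positive", "employed", "income_lt_20k",
                           "stably_housed", "ever_jail", "insured",
                           "in_relationship")))
      df[[cl]] <- as.logical(df[[cl]])
    check_waves(df, tb, specs[[tb]]$wave_cols)
    out[[tb]] <- df
  }
  out
}

write_result_table <- function(df, path, digits = 6) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  utils::write.csv(df, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

#' Write a result bundle to disk
#'
#' Emits every computed component of a pipeline result as delimited text
#' (floats at 6 significant digits), the composite graph as GraphML, and
#' a single machine-readable `results.json` carrying the comparison
#' blocks with full metadata.
#'
#' @param bundle list as produced by [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, name)
    write_result_table(df, p)
    written <<- c(written, p)
  }
  ds <- bundle$dataset
  if (!is.null(ds)) {
    put(ds$respondents, "respondents.csv")
    put(ds$rosters, "rosters.csv")
    put(ds$matches, "matches.csv")
    put(ds$attendance, "attendance.csv")
  }
  if (!is.null(bundle$ground_truth)) {
    gt_dir <- file.path(dir, "ground_truth")
    dir.create(gt_dir, showWarnings = FALSE)
    # synthetic-only tables: true identities and tie persistence events
    write_result_table(bundle$ground_truth$identity,
                       file.path(gt_dir, "synthetic_identity.csv"))
    write_result_table(bundle$ground_truth$events,
                       file.path(gt_dir, "synthetic_tie_events.csv"))
    written <- c(written, file.path(gt_dir, "synthetic_identity.csv"),
                 file.path(gt_dir, "synthetic_tie_events.csv"))
  }
  if (!is.null(bundle$dynamics)) {
    put(bundle$dynamics$summaries, "tie_change_summaries.csv")
    put(bundle$dynamics$comparisons, "network_stability_comparison.csv")
  }
  if (!is.null(bundle$metrics)) put(bundle$metrics, "node_metrics.csv")
  if (!is.null(bundle$structure_comparison))
    put(bundle$structure_comparison, "structure_comparison.csv")
  if (!is.null(bundle$baseline)) put(bundle$baseline$table, "baseline.csv")
  if (!is.null(bundle$composition))
    put(bundle$composition, "ego_composition.csv")
  if (!is.null(bundle$odds_ratios)) put(bundle$odds_ratios,
                                        "odds_ratios.csv")
  if (!is.null(bundle$graph)) {
    p <- file.path(dir, "graph.graphml")
    write_graphml(bundle$graph, p)
    written <- c(written, p)
  }
  if (!is.null(bundle$summary)) {
    p <- file.path(dir, "results.json")
    jsonlite::write_json(bundle$summary, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    written <- c(written, p)
  }
  invisible(written)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> validate -> identity resolution ->
#' tie dynamics -> network structure -> comparative statistics -> report.
#' The run is deterministic given the seed; stage status is recorded in a
#' `manifest.json` in the output directory, and a stage failure leaves
#' the completed stages' outputs intact, records the failing stage, and
#' raises the error (a CLI wrapper should exit nonzero).
#'
#' @param config run configuration: a list or a YAML/JSON file path.
#'   Exactly one of `simulate` (a [sim_config()] field list) or `inputs`
#'   (paths to the four tables) is required; optional fields `seed`,
#'   `waves`, `edge_kinds`, `ttest` (`"welch"`/`"pooled"`),
#'   `or_direction`, `retained_rule` (`"strict"`/`"any_later"`).
#' @param out output directory.
#' @return the result bundle, invisibly.
#' @export
run_pipeline <- function(config, out) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp)
    stop("run config requires exactly one of 'simulate' or 'inputs'",
         call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  edge_kinds <- config$edge_kinds %||% c("rds", "confidant", "sexual")
  ttest <- config$ttest %||% "welch"
  retained_rule <- config$retained_rule %||% "strict"
  or_direction <- config$or_direction %||% "auto"
  waves <- config$waves

  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stages = list(), seed = seed,
                   package_version = as.character(
                     utils::packageVersion("netpanel")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   flags = list(edge_kinds = edge_kinds, ttest = ttest,
                                retained_rule = retained_rule,
                                or_direction = or_direction))
  bundle <- list()
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      write_manifest()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(res)), call. = FALSE)
    }
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  if (has_sim) {
    sim <- stage("simulate", {
      sc <- config$simulate
      sc$rng_seed <- sc$rng_seed %||% seed
      simulate_cohort(validate_sim_config(sc))
    })
    manifest$stages$simulate$records <- nrow(sim$respondents)
    bundle$ground_truth <- sim$ground_truth[c("identity", "events")]
    raw <- sim
  } else {
    raw <- stage("read", read_tables(config$inputs))
    manifest$stages$read$records <- nrow(raw$respondents)
  }

  ds <- stage("validate", {
    d <- validate_dataset(raw$respondents, raw$rosters, raw$matches,
                          raw$attendance)
    if (nrow(d$violations) > 0)
      warning(sprintf("dataset has %d validation violations",
                      nrow(d$violations)), call. = FALSE)
    d
  })
  bundle$dataset <- ds
  manifest$stages$validate$violations <- nrow(ds$violations)

  map <- stage("resolve", resolve_alters(ds))
  set.seed(stream_seed(seed, "analysis"))
  bundle$dynamics <- stage("dynamics",
    cohort_dynamics(ds, retained_rule = retained_rule, ttest = ttest,
                    map = map))
  manifest$stages$dynamics$records <- nrow(bundle$dynamics$summaries)

  bundle$graph <- stage("structure", {
    g <- assemble_graph(ds, edge_kinds = edge_kinds, waves = waves,
                        map = map)
    g
  })
  bundle$metrics <- node_metrics(bundle$graph)
  bundle$structure_comparison <- group_structure_comparison(
    bundle$metrics, ds$respondents, ttest = ttest)
  manifest$stages$structure$records <- nrow(bundle$metrics)

  cmp <- stage("compare", {
    comp <- ego_composition(ds, wave = 1L, map = map)
    list(baseline = baseline_table(ds), composition = comp,
         odds_ratios = or_table(comp, direction = or_direction))
  })
  bundle$baseline <- cmp$baseline
  bundle$composition <- cmp$composition
  bundle$odds_ratios <- cmp$odds_ratios
  manifest$stages$compare$records <- nrow(cmp$composition)

  stage("report", {
    bundle$summary <- list(
      seed = seed,
      package_version = manifest$package_version,
      r_version = manifest$r_version,
      flags = manifest$flags,
      n_respondents = nrow(ds$respondents),
      group_counts = as.list(bundle$baseline$group_counts),
      group_share_pct = as.list(bundle$baseline$group_share_pct),
      dynamics_comparisons = bundle$dynamics$comparisons,
      structure_comparison = bundle$structure_comparison,
      odds_ratios = bundle$odds_ratios)
    bundle$summary$dynamics_comparisons[] <-
      lapply(bundle$summary$dynamics_comparisons, function(x)
        if (is.double(x)) signif(x, 6) else x)
    bundle$summary$structure_comparison[] <-
      lapply(bundle$summary$structure_comparison, function(x)
        if (is.double(x)) signif(x, 6) else x)
    bundle$summary$odds_ratios[] <-
      lapply(bundle$summary$odds_ratios, function(x)
        if (is.double(x)) signif(x, 6) else x)
    write_results(bundle, out)
  })
  write_manifest()
  invisible(bundle)
}
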