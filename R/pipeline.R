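#' Run the full simulate-classify-call pipeline
#'
#' Wires the stages end to end on a simulated genome: simulate, emit hits,
#' classify arm patterns, call inversions, reconcile simulated deletion-bin
#' records, enumerate the observed nonstandard pattern set per group and
#' test its single-genotype feasibility. All stage outputs are written side
#' by side as TSV and JSON with a frozen column order, together with a run
#' manifest sufficient to reproduce the run. All randomness flows from
#' `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [simulation_config()].
#' @param seed Integer seed for the whole run.
#' @param evalue_max,delta E-value threshold and secondary-hit window for
#'   [classify_arm_patterns()].
#' @param epsilon,strict Co-mapping tolerance and strict mode for
#'   [call_inversions()].
#' @param n_bins Number of simulated deletion-bin records to reconcile.
#'
#' @return Invisibly, a list with the in-memory stage results (`sim`,
#'   `hits`, `patterns`, `calls`, `report`, `reconciliation`,
#'   `feasibility`, `manifest`).
#' @export
run_pipeline <- function(out_dir, config = simulation_config(), seed = 1,
                         evalue_max = 1e-5, delta = 0.10, epsilon = 2,
                         strict = FALSE, n_bins = 50) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- simulate_genome(config, seed = seed)
  hits <- emit_hits(sim)
  patterns <- classify_arm_patterns(hits, evalue_max = evalue_max,
                                    delta = delta)
  calls <- suppressWarnings(
    call_inversions(patterns, map = sim$map, epsilon = epsilon,
                    strict = strict)
  )
  report <- report_table(calls)

  bins <- simulate_bin_data(sim, n = n_bins)
  arm_calls <- sim$truth |>
    filter(!is.na(.data$arm_observed)) |>
    select("gene", arm = "arm_observed")
  reconciliation <- reconcile_all(arm_calls, bins)

  observed_sets <- patterns |>
    as_tibble() |>
    filter(.data$classification == "nonstandard") |>
    distinct(.data$group, .data$triplet)
  feasibility <- observed_sets |>
    group_by(.data$group) |>
    summarise(patterns = list(sort(.data$triplet)), .groups = "drop") |>
    mutate(
      n_patterns = lengths(.data$patterns),
      feasible = purrr::map2_lgl(.data$patterns, .data$group,
                                 ~ feasibility_check(.x, .y)$feasible)
    )

  filter_counts <- attr(patterns, "summary")
  manifest <- list(
    subcommand = "pipeline",
    tool = "pericentr",
    version = as.character(packageVersion("pericentr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameters = list(evalue_max = evalue_max, delta = delta,
                      epsilon = epsilon, strict = strict, n_bins = n_bins),
    config = unclass(config),
    filter_counts = filter_counts,
    outputs = list(
      hits = "hits.tsv", patterns = "patterns.tsv", calls = "calls.tsv",
      report = "report.tsv", reconciliation = "reconciliation.tsv",
      feasibility = "feasibility.json", summary = "summary.json"
    )
  )

  write_tsv_frozen <- function(x, file) {
    readr::write_tsv(x, file.path(out_dir, file), progress = FALSE)
  }
  write_tsv_frozen(hits, "hits.tsv")
  write_tsv_frozen(as_tibble(patterns), "patterns.tsv")
  write_tsv_frozen(tidy(calls), "calls.tsv")
  write_tsv_frozen(report, "report.tsv")
  write_tsv_frozen(reconciliation, "reconciliation.tsv")
  jsonlite::write_json(
    list(
      feasibility = feasibility |>
        select("group", "n_patterns", "feasible", "patterns"),
      reconciliation_summary = as.list(attr(reconciliation, "summary"))
    ),
    file.path(out_dir, "feasibility.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  jsonlite::write_json(
    c(filter_counts, as.list(glance(calls))),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(sim = sim, hits = hits, patterns = patterns,
                 calls = calls, report = report,
                 reconciliation = reconciliation,
                 feasibility = feasibility, manifest = manifest))
}
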