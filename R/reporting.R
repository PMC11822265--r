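#' Deterministic base-case results for every strategy
#'
#' Runs the cohort-expectation oracle (no sampling) on each strategy of a
#' configuration: the exact expected discounted cost and QALYs of the
#' state-transition process at the base-case parameter values.
#'
#' @param config A validated `model_config`.
#' @return A data.frame: `strategy`, `expected_cost`, `expected_qaly`.
#' @export
run_base_case <- function(config) {
  validate_config(config)
  rows <- lapply(config$strategies, function(st) {
    e <- cohort_expectation(config, st$name)
    data.frame(strategy = st$name,
               expected_cost = e[["expected_cost"]],
               expected_qaly = e[["expected_qaly"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_plain_csv <- function(df, path) {
  utils::write.csv(format(df, trim = TRUE, scientific = FALSE,
                          justify = "none"),
                   path, row.names = FALSE, quote = FALSE)
  path
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_model_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Write the full set of PSA report files
#'
#' Emits, under `out_dir`:
#' \describe{
#'   \item{`cea_table.csv`}{the league table from [cea_table()]}
#'   \item{`frontier.csv`}{ICERs between successive undominated strategies}
#'   \item{`ceac.csv`}{acceptability curves, long format
#'     (`wtp`, `strategy`, `probability`)}
#'   \item{`nmb_curve.csv`}{mean NMB per strategy over the WTP grid}
#'   \item{`scatter.csv`}{per-iteration incremental (cost, QALY) pairs of
#'     every strategy against the cheapest}
#'   \item{`ellipses.csv`}{95% confidence-ellipse parameters per comparison}
#'   \item{`manifest.json`}{run metadata: config hash, seed, sizes, package
#'     version, timestamp and the list of files written}
#' }
#' CSV content is a pure function of (config, seed): re-running the same
#' manifest reproduces the data files byte for byte.
#'
#' @param psa A `psa_result`.
#' @param out_dir Output directory (created if missing).
#' @param wtp Willingness-to-pay for the league table (default: configured).
#' @param level Share level for the league table and acceptability curves,
#'   `"patient"` (default) or `"iteration"`.
#' @return Invisibly, the manifest as a list.
#' @export
write_psa_outputs <- function(psa, out_dir,
                              wtp = psa$config$settings$wtp,
                              level = c("patient", "iteration")) {
  level <- match.arg(level)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_plain_csv(df, p)
    paths <<- c(paths, name)
  }
  tab <- cea_table(psa, wtp = wtp, level = level)
  emit(as.data.frame(tab), "cea_table.csv")
  emit(attr(tab, "frontier"), "frontier.csv")
  cv <- ceac(psa, level = level)
  emit(cv, "ceac.csv")
  agg <- aggregate_psa(psa)
  nmb_rows <- do.call(rbind, lapply(psa$wtp_grid, function(w)
    data.frame(wtp = w, strategy = agg$strategy,
               nmb = nmb(agg$mean_cost, agg$mean_qaly, w))))
  emit(nmb_rows, "nmb_curve.csv")
  cheapest <- agg$strategy[which.min(agg$mean_cost)]
  others <- setdiff(agg$strategy, cheapest)
  scatter <- do.call(rbind, lapply(others, function(s) {
    ip <- incremental_pairs(psa, s, cheapest)
    data.frame(iteration = seq_len(nrow(ip)), strategy = s,
               comparator = cheapest, delta_cost = ip$delta_cost,
               delta_qaly = ip$delta_qaly)
  }))
  emit(scatter, "scatter.csv")
  ellipses <- do.call(rbind, lapply(others, function(s) {
    el <- confidence_ellipse(incremental_pairs(psa, s, cheapest))
    data.frame(strategy = s, comparator = cheapest,
               center_cost = el$center[[1]], center_qaly = el$center[[2]],
               semi_major = el$radii[1], semi_minor = el$radii[2],
               angle_rad = el$angle, level = el$level,
               degenerate = el$degenerate)
  }))
  emit(ellipses, "ellipses.csv")
  manifest <- list(
    config_hash = config_hash(psa$config),
    seed = psa$seed,
    n_iterations = psa$n_iterations,
    n_patients = psa$n_patients,
    wtp = wtp,
    share_level = level,
    package_version = as.character(utils::packageVersion("irctcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = paths
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
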