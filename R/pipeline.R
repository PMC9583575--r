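# End-to-end orchestration: configuration, the full pipeline run, and
# provenance-stamped outputs.

#' Pipeline configuration
#'
#' All analysis parameters with their standard defaults: SSN retention at
#' raw `p < 0.01`, hubs = top 20% of SSN degree, Hampel multiplier 3,
#' 10-nearest-neighbour imputation, probes removed above 10% missingness,
#' a 10,000 x 10,000 Monte Carlo null at `alpha = 0.05`, and a 60%
#' subtype-prevalence threshold.
#'
#' @param alpha_ssn SSN edge-retention p-value threshold.
#' @param hub_fraction Hub fraction of SSN degree.
#' @param hampel_k Hampel multiplier (MED +/- k * MAD).
#' @param knn_k Neighbours for beta-value imputation.
#' @param max_na_fraction Probe missingness tolerance.
#' @param mc_iterations,mc_edges_per_iter,mc_alpha Monte Carlo null
#'   parameters.
#' @param subtype_threshold Within-subtype edge-prevalence threshold.
#' @param seed Integer seed for all stochastic steps.
#' @return Object of class `pipeline_config` (validated list).
#' @export
pipeline_config <- function(alpha_ssn = 0.01, hub_fraction = 0.20,
                            hampel_k = 3, knn_k = 10,
                            max_na_fraction = 0.10,
                            mc_iterations = 10000, mc_edges_per_iter = 10000,
                            mc_alpha = 0.05, subtype_threshold = 0.60,
                            seed = 1) {
  assert_scalar_fraction(hub_fraction, "hub_fraction")
  assert_scalar_fraction(mc_alpha, "mc_alpha")
  assert_scalar_fraction(subtype_threshold, "subtype_threshold",
                         open_left = FALSE)
  if (alpha_ssn < 0 || alpha_ssn >= 1) abort("alpha_ssn must lie in [0, 1).")
  if (max_na_fraction < 0 || max_na_fraction > 1) {
    abort("max_na_fraction must lie in [0, 1].")
  }
  structure(list(alpha_ssn = alpha_ssn, hub_fraction = hub_fraction,
                 hampel_k = hampel_k, knn_k = knn_k,
                 max_na_fraction = max_na_fraction,
                 mc_iterations = mc_iterations,
                 mc_edges_per_iter = mc_edges_per_iter,
                 mc_alpha = mc_alpha,
                 subtype_threshold = subtype_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key: value` (or `key = value`); keys must be
#' [pipeline_config()] arguments. File values override defaults and are
#' themselves overridden by `...`.
#'
#' @param path Path to the config file, or `NULL` for defaults.
#' @param ... Direct overrides (highest precedence).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readr::read_lines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- regmatches(lines, regexec("^([A-Za-z_0-9]+)\\s*[:=]\\s*(.+)$", lines))
    for (m in kv) {
      if (length(m) == 3) vals[[m[2]]] <- as.numeric(m[3])
    }
  }
  vals <- modifyList(vals, list(...))
  bad <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(bad) > 0) {
    abort(sprintf("unknown configuration key(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' Run the full driver-module pipeline
#'
#' Executes every stage on files produced by [simulate_cohort()] or
#' equivalent user data: reference network, per-case-sample SSNs,
#' mutation/methylation profiles, per-sample driver modules, edge
#' frequencies, Monte Carlo cutoffs and cohort modules per driver type,
#' and (when labels are given) subtype modules. All outputs are written
#' under `out_dir` with a JSON provenance record (package version,
#' configuration, seed); a rerun with identical inputs, configuration and
#' seed is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param paths Named list of input paths: `expression`, `mutations`,
#'   `methylation`, `annotation`, `network`, optionally `labels`;
#'   plus `reference_ids` and `case_ids` character vectors.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory results (`ssns`,
#'   `modules`, `frequencies`, `cutoffs`, `cohort`, `subtype`,
#'   `provenance`).
#' @export
run_pipeline <- function(config, paths, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  expr <- stage("read_expression",
                read_expression(paths$expression, paths$reference_ids,
                                paths$case_ids))
  bg <- stage("read_network", read_edge_list(paths$network))
  ref_net <- stage("reference_network", build_reference_network(expr, bg))

  mut_raw <- stage("read_mutations", {
    df <- readr::read_tsv(paths$mutations,
                          col_types = readr::cols(
                            .default = readr::col_double(),
                            gene = readr::col_character()),
                          progress = FALSE)
    build_mutation_matrix(df, intersect(paths$case_ids, names(df)))
  })
  mt <- stage("methylation_profile", {
    beta_df <- readr::read_tsv(paths$methylation,
                               col_types = readr::cols(
                                 .default = readr::col_double(),
                                 probe_id = readr::col_character()),
                               progress = FALSE)
    ann <- read_probe_annotation(paths$annotation)
    build_methylation_profile(beta_df, ann,
                              max_na_fraction = config$max_na_fraction,
                              k = config$knn_k, hampel_k = config$hampel_k)
  })

  ssn_dir <- file.path(out_dir, "ssn")
  mod_dir <- file.path(out_dir, "modules")
  dir.create(ssn_dir, showWarnings = FALSE)
  dir.create(mod_dir, showWarnings = FALSE)
  ssns <- list()
  modules <- list(mutation = list(), methylation = list(), co = list())
  for (sid in paths$case_ids) {
    ssn <- stage(paste0("ssn:", sid),
                 build_ssn(expr, ref_net, sid, alpha = config$alpha_ssn))
    ssns[[sid]] <- ssn
    readr::write_tsv(as.data.frame(ssn), file.path(ssn_dir, paste0(sid, ".tsv")))
    mods <- stage(paste0("modules:", sid),
                  build_driver_modules(ssn, mut_raw, mt,
                                       hub_fraction = config$hub_fraction))
    for (ty in c("mutation", "methylation", "co")) {
      modules[[ty]][[sid]] <- mods[[ty]]
      write_module(mods[[ty]],
                   file.path(mod_dir, sprintf("%s_%s.tsv", sid, ty)))
    }
  }
  n_empty <- sum(vapply(modules$co, nrow, 0L) == 0)
  if (n_empty > 0) {
    inform(sprintf("run_pipeline: %d sample(s) have empty co-driver modules", n_empty))
  }

  frequencies <- list()
  cutoffs <- list()
  cohort <- list()
  for (ty in c("mutation", "methylation", "co")) {
    ft <- stage(paste0("frequencies:", ty),
                edge_frequencies(modules[[ty]], bg))
    frequencies[[ty]] <- ft
    cut <- stage(paste0("cutoff:", ty),
                 monte_carlo_cutoff(ft, iterations = config$mc_iterations,
                                    edges_per_iter = config$mc_edges_per_iter,
                                    alpha = config$mc_alpha,
                                    seed = config$seed))
    cutoffs[[ty]] <- cut
    cm <- cohort_module(ft, as.numeric(cut), driver_type = ty)
    cohort[[ty]] <- cm
    readr::write_tsv(as.data.frame(ft),
                     file.path(out_dir, sprintf("frequencies_%s.tsv", ty)))
    readr::write_tsv(as.data.frame(cm),
                     file.path(out_dir, sprintf("cohort_%s.tsv", ty)))
  }

  subtype <- NULL
  if (!is.null(paths$labels)) {
    labels <- read_subtype_labels(paths$labels, paths$case_ids)
    subtype <- stage("subtype_modules",
                     subtype_modules(modules$co, labels,
                                     threshold = config$subtype_threshold))
    for (st in names(subtype$modules)) {
      readr::write_tsv(as.data.frame(subtype$modules[[st]]),
                       file.path(out_dir, sprintf("subtype_%s.tsv", st)))
    }
    readr::write_tsv(as.data.frame(subtype$sizes),
                     file.path(out_dir, "subtype_sizes.tsv"))
  }

  provenance <- list(
    package = "ssdriver",
    version = as.character(utils::packageVersion("ssdriver")),
    config = unclass(config),
    cutoffs = lapply(cutoffs, as.numeric),
    n_case_samples = length(paths$case_ids),
    n_empty_co_modules = n_empty
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(ssns = ssns, modules = modules, frequencies = frequencies,
                 cutoffs = cutoffs, cohort = cohort, subtype = subtype,
                 provenance = provenance))
}
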