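# Cohort-level aggregation: edge occurrence frequencies across per-sample
# driver modules, a Monte Carlo null for the frequency cutoff, and
# subtype-level driver modules.

#' Edge occurrence frequencies across per-sample modules
#'
#' For every background edge, the fraction of samples whose driver module
#' contains it. Edges never seen in any module have frequency 0; module
#' edges outside the background universe are a contract breach and raise
#' an error.
#'
#' @param modules List of `driver_module`s (one per sample).
#' @param universe A [background_network()] (the testable edge universe).
#' @return Tibble of class `edge_frequency_table`: `gene_a`, `gene_b`,
#'   `count`, `frequency`; attribute `n_samples`.
#' @export
edge_frequencies <- function(modules, universe) {
  if (length(modules) == 0) abort("need at least one module.")
  ukey <- edge_key(universe$gene_a, universe$gene_b)
  counts <- integer(length(ukey))
  names(counts) <- ukey
  for (m in modules) {
    if (nrow(m) == 0) next
    mk <- edge_key(m$gene_a, m$gene_b)
    bad <- setdiff(mk, ukey)
    if (length(bad) > 0) {
      abort(sprintf("module (sample %s) contains %d edge(s) outside the background universe.",
                    attr(m, "sample_id"), length(bad)))
    }
    counts[mk] <- counts[mk] + 1L
  }
  n <- length(modules)
  out <- tibble(gene_a = universe$gene_a, gene_b = universe$gene_b,
                count = unname(counts),
                frequency = unname(counts) / n)
  out <- as_tibble(sort_edges(out))
  structure(out, class = c("edge_frequency_table", class(tibble())),
            n_samples = n)
}

#' Monte Carlo frequency cutoff
#'
#' Builds an empirical null for "how frequent can an edge be by chance":
#' in each iteration, `edges_per_iter` edges are drawn uniformly from the
#' background universe (with replacement by default) and the
#' `1 - alpha` empirical quantile (type-7) of their observed frequencies is
#' that iteration's cutoff. The returned cutoff is the mean of the
#' per-iteration cutoffs; edges above it are unusually frequent at level
#' `alpha`.
#'
#' @param freq_table An [edge_frequencies()] table over the full universe.
#' @param iterations Number of Monte Carlo iterations (default 10000).
#' @param edges_per_iter Edges sampled per iteration (default 10000).
#' @param alpha Upper tail mass (default 0.05).
#' @param seed Integer RNG seed (mandatory for reproducibility; default 1).
#' @param replace Sample with replacement (default `TRUE`; required when
#'   `edges_per_iter` exceeds the universe size).
#' @return Numeric cutoff with attributes `iterations`, `edges_per_iter`,
#'   `alpha`, `seed`, `replace` and `sd` (spread of per-iteration cutoffs).
#' @export
monte_carlo_cutoff <- function(freq_table, iterations = 10000,
                               edges_per_iter = 10000, alpha = 0.05,
                               seed = 1, replace = TRUE) {
  f <- freq_table$frequency
  if (length(f) == 0) abort("empty edge universe.")
  if (!replace && edges_per_iter > length(f)) {
    abort("edges_per_iter exceeds the universe size; use replace = TRUE.")
  }
  old <- .Random.seed_safe()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  cuts <- vapply(seq_len(iterations), function(i) {
    s <- f[sample.int(length(f), edges_per_iter, replace = replace)]
    unname(quantile(s, probs = 1 - alpha, type = 7))
  }, numeric(1))
  structure(mean(cuts), iterations = iterations,
            edges_per_iter = edges_per_iter, alpha = alpha, seed = seed,
            replace = replace, sd = stats::sd(cuts))
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Cohort-level driver module
#'
#' Retains the edges whose occurrence frequency is strictly greater than
#' the cutoff (typically the [monte_carlo_cutoff()] mean).
#'
#' @param freq_table An [edge_frequencies()] table.
#' @param cutoff Frequency cutoff in `[0, 1]`.
#' @param driver_type Label carried on the result.
#' @return Tibble of class `cohort_module` with columns `gene_a`,
#'   `gene_b`, `count`, `frequency`; attributes `cutoff`, `driver_type`,
#'   `n_samples`.
#' @export
cohort_module <- function(freq_table, cutoff,
                          driver_type = c("mutation", "methylation", "co")) {
  driver_type <- match.arg(driver_type)
  if (!is.numeric(cutoff) || cutoff < 0 || cutoff > 1) {
    abort("cutoff must lie in [0, 1].")
  }
  out <- freq_table[freq_table$frequency > cutoff, , drop = FALSE]
  out <- as_tibble(sort_edges(as.data.frame(out)))
  structure(out, class = c("cohort_module", class(tibble())),
            cutoff = as.numeric(cutoff), driver_type = driver_type,
            n_samples = attr(freq_table, "n_samples"))
}

#' Subtype-specific driver modules
#'
#' Per subtype, retains the edges present in strictly more than
#' `threshold` (default 60%) of that subtype's co-driver modules; then
#' derives the edges shared by all subtype modules and the edges specific
#' to exactly one subtype. Also reports per-sample module sizes by subtype
#' for downstream Kruskal-Wallis / Nemenyi comparisons.
#'
#' @param modules Named list of co-driver `driver_module`s, names = sample
#'   ids (or modules carrying `sample_id` attributes).
#' @param labels A [subtype_labels()] tibble; every labeled sample must
#'   have a module in `modules`. Subtypes with no samples are dropped with
#'   a warning.
#' @param threshold Within-subtype frequency threshold (strict >).
#' @return Object of class `subtype_modules`: list with `modules` (named
#'   list of per-subtype edge tibbles with `frequency`), `shared` (edge
#'   tibble), `specific` (edge tibble with a `subtype` column; pairwise
#'   disjoint by construction), and `sizes` (tibble `sample_id`,
#'   `subtype`, `n_edges`).
#' @export
subtype_modules <- function(modules, labels, threshold = 0.60) {
  assert_scalar_fraction(threshold, "threshold", open_left = FALSE)
  if (is.null(names(modules)) || any(!nzchar(names(modules)))) {
    names(modules) <- vapply(modules, function(m) attr(m, "sample_id"), "")
  }
  missing_m <- setdiff(labels$sample_id, names(modules))
  if (length(missing_m) > 0) {
    abort(sprintf("no module for labeled sample(s): %s",
                  paste(head(missing_m, 5), collapse = ", ")))
  }
  subtypes <- sort(unique(labels$subtype))
  per_subtype <- list()
  sizes <- list()
  for (st in subtypes) {
    ids <- labels$sample_id[labels$subtype == st]
    if (length(ids) == 0) {
      warn(sprintf("subtype '%s' has no samples; excluded.", st))
      next
    }
    keys <- unlist(lapply(modules[ids], function(m) {
      unique(edge_key(m$gene_a, m$gene_b))
    }))
    tab <- table(keys)
    freq <- as.numeric(tab) / length(ids)
    keep <- freq > threshold
    kk <- as.character(names(tab))[keep]
    parts <- strsplit(kk, "\r", fixed = TRUE)
    per_subtype[[st]] <- tibble(
      gene_a = vapply(parts, `[`, "", 1),
      gene_b = vapply(parts, `[`, "", 2),
      frequency = freq[keep]
    ) %>% sort_edges() %>% as_tibble()
    sizes[[st]] <- tibble(sample_id = ids, subtype = st,
                          n_edges = vapply(modules[ids], nrow, 0L))
  }
  if (length(per_subtype) == 0) abort("no subtype with samples.")
  keysets <- lapply(per_subtype, function(d) edge_key(d$gene_a, d$gene_b))
  shared_keys <- Reduce(intersect, keysets)
  all_keys <- unlist(keysets)
  key_tab <- table(all_keys)
  uniq_keys <- as.character(names(key_tab))[key_tab == 1]
  specific <- bind_rows(lapply(names(per_subtype), function(st) {
    d <- per_subtype[[st]]
    k <- edge_key(d$gene_a, d$gene_b)
    d <- d[k %in% uniq_keys, , drop = FALSE]
    if (nrow(d) > 0) d$subtype <- st
    d
  }))
  shared <- {
    parts <- strsplit(shared_keys, "\r", fixed = TRUE)
    as_tibble(sort_edges(tibble(
      gene_a = vapply(parts, `[`, "", 1),
      gene_b = vapply(parts, `[`, "", 2))))
  }
  structure(list(modules = per_subtype, shared = shared,
                 specific = as_tibble(specific),
                 sizes = bind_rows(sizes)),
            class = "subtype_modules", threshold = threshold)
}

#' @export
print.subtype_modules <- function(x, ...) {
  cat(sprintf("<subtype_modules> %d subtype(s), threshold > %g\n",
              length(x$modules), attr(x, "threshold")))
  for (st in names(x$modules)) {
    cat(sprintf("  %s: %d edge(s)\n", st, nrow(x$modules[[st]])))
  }
  cat(sprintf("  shared: %d, specific: %d\n", nrow(x$shared), nrow(x$specific)))
  invisible(x)
}
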