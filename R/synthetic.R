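# Deterministic synthetic-data generator with planted ground truth: a
# scale-free background network, reference/case expression with known
# edge correlations and planted per-sample correlation perturbations,
# Bernoulli mutation profiles, and Beta-distributed methylation with
# planted aberrations. Every generator draws from its own seed stream
# derived from the master seed, so adding one generator never perturbs
# the others' output.

#' Simulation configuration
#'
#' Holds every knob of the synthetic cohort. Defaults describe the study
#' conditions used throughout the package's validation: a 400-gene
#' universe, 100 reference and 50 case samples, a preferential-attachment
#' background with 2 edges per new node, latent edge correlation 0.6,
#' a 2% per-gene-per-sample mutation rate and Beta(10, 10) promoter
#' methylation (mid-methylated, so hyper- and hypo-aberrations are both
#' plantable).
#'
#' @param n_genes Number of genes (named `g0001`, ...).
#' @param n_reference,n_case Reference (normal) and case (tumor) sample
#'   counts.
#' @param attachment Edges added per node in the preferential-attachment
#'   background generator.
#' @param base_correlation Latent Gaussian correlation on background edges,
#'   in `(-1, 1)`. A positive-definite construction cannot give every edge
#'   of a degree-`d` hub correlation above `1/sqrt(d)`; see
#'   `hub_attenuation`.
#' @param hub_attenuation If `TRUE` (default), per-gene factor loadings are
#'   capped at `sqrt(0.9 / degree)` so the construction stays
#'   positive-definite on arbitrary scale-free graphs: degree-1 genes get
#'   exactly `base_correlation` on their edge, hub edges are attenuated.
#'   With `FALSE`, loadings are exactly `sqrt(base_correlation)` everywhere
#'   and an infeasible request (`degree x correlation >= 1`) raises an
#'   error suggesting a smaller value.
#' @param perturbed_edges Tibble `gene_a`, `gene_b`, `sample_id`: planted
#'   per-sample correlation perturbations. In the perturbed sample the
#'   edge's shared latent factor is replaced by opposite-sign extreme
#'   values (`+perturb_shift` for one endpoint, `-perturb_shift` for the
#'   other), so the pair decouples and the sample is a discordant outlier
#'   on that edge — the signature a single added sample must carry to move
#'   a correlation computed over n reference samples.
#' @param perturb_shift Magnitude (in latent standard deviations) of the
#'   planted perturbation (default 4).
#' @param mutation_rate Bernoulli rate of the mutation matrix.
#' @param planted_mutations Tibble `gene`, `sample_id`: forced 1 entries.
#' @param beta_shape1,beta_shape2 Beta parameters of baseline methylation.
#' @param probes_per_gene Promoter probes simulated per gene (one extra
#'   gene-body probe per gene is always added).
#' @param planted_outliers Tibble `gene`, `sample_id`, `direction`
#'   (`"hyper"` or `"hypo"`): planted methylation aberrations (promoter
#'   probes set to 0.98 / 0.02).
#' @param missing_fraction Fraction of beta entries set missing at random.
#' @param expression_log_mean,expression_log_sd Location/scale applied
#'   before exponentiating the latent Gaussian to FPKM-like values.
#' @param seed Master integer seed; fully determines all outputs.
#' @return Object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_genes = 400, n_reference = 100, n_case = 50,
                              attachment = 2, base_correlation = 0.6,
                              hub_attenuation = TRUE,
                              perturbed_edges = NULL, perturb_shift = 4,
                              mutation_rate = 0.02,
                              planted_mutations = NULL,
                              beta_shape1 = 10, beta_shape2 = 10,
                              probes_per_gene = 3,
                              planted_outliers = NULL,
                              missing_fraction = 0,
                              expression_log_mean = log(10),
                              expression_log_sd = 0.4,
                              seed = 1) {
  if (n_genes < 3) abort("need at least 3 genes.")
  if (n_reference < 3 || n_case < 1) abort("sample counts too small.")
  if (abs(base_correlation) >= 1) abort("base_correlation must lie in (-1, 1).")
  if (mutation_rate < 0 || mutation_rate > 1) abort("mutation_rate must lie in [0, 1].")
  if (beta_shape1 <= 0 || beta_shape2 <= 0) abort("Beta parameters must be positive.")
  if (missing_fraction < 0 || missing_fraction >= 1) abort("missing_fraction must lie in [0, 1).")
  if (seed %% 1 != 0) abort("seed must be an integer.")
  structure(list(
    n_genes = n_genes, n_reference = n_reference, n_case = n_case,
    attachment = attachment, base_correlation = base_correlation,
    hub_attenuation = hub_attenuation,
    perturbed_edges = perturbed_edges, perturb_shift = perturb_shift,
    mutation_rate = mutation_rate,
    planted_mutations = planted_mutations,
    beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
    probes_per_gene = probes_per_gene, planted_outliers = planted_outliers,
    missing_fraction = missing_fraction,
    expression_log_mean = expression_log_mean,
    expression_log_sd = expression_log_sd,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

sim_gene_ids <- function(config) sprintf("g%04d", seq_len(config$n_genes))
sim_ref_ids <- function(config) sprintf("N%03d", seq_len(config$n_reference))
sim_case_ids <- function(config) sprintf("T%03d", seq_len(config$n_case))

# Independent substreams: each generator seeds from master seed + offset.
with_sim_seed <- function(config, offset, code) {
  old <- .Random.seed_safe()
  on.exit(restore_seed(old), add = TRUE)
  set.seed((config$seed + offset) %% .Machine$integer.max)
  force(code)
}

#' Simulate a scale-free background network
#'
#' Barabasi-Albert preferential attachment over the configured gene
#' universe ([igraph::sample_pa()] with `m = attachment`): the first edge
#' joins the first two nodes, each later node attaches `m` edges, so for
#' `m = 2` and `n` nodes the graph has `1 + 2 (n - 2)` edges.
#'
#' @param config A [simulation_config()].
#' @return A [background_network()] over the simulated gene symbols.
#' @export
simulate_background <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  genes <- sim_gene_ids(config)
  g <- with_sim_seed(config, 101L, {
    igraph::sample_pa(config$n_genes, m = config$attachment,
                      directed = FALSE)
  })
  igraph::V(g)$name <- genes
  el <- igraph::as_edgelist(g)
  suppressMessages(background_network(
    data.frame(gene_a = el[, 1], gene_b = el[, 2])))
}

#' Simulate reference and case expression with planted perturbations
#'
#' Latent construction: each background edge carries an i.i.d.
#' standard-normal factor; gene `i` with per-gene loading `w_i` is
#' `w_i * sum(factors of incident edges) + sqrt(1 - d_i w_i^2) * noise`,
#' so the pair joined by an edge has latent correlation `w_i w_j` (equal to
#' `base_correlation` wherever the hub-attenuation cap is inactive) and
#' unconnected pairs 0 in expectation. For a planted perturbation of edge
#' `(a, b)` in case sample `s`, the edge's shared factor is replaced by
#' `+perturb_shift` for one endpoint and `-perturb_shift` for the other in
#' that sample only: the pair decouples and the sample is a discordant
#' outlier on the edge. Values are exponentiated
#' (`exp(mu + sigma z)`, log-normal marginals) to be FPKM-like; with the
#' default `sigma = 0.4` the observed-scale Pearson correlation is only
#' mildly attenuated relative to `r`. `transform = "gaussian"` returns the
#' latent scale directly (useful for calibration studies).
#'
#' @param config A [simulation_config()].
#' @param network A [background_network()] whose nodes are simulated genes
#'   (typically [simulate_background()], but any graph over the gene
#'   universe works, e.g. a perfect matching of independent pairs).
#' @param transform `"lognormal"` (default) or `"gaussian"`.
#' @return An [expression_set()] with `n_reference` reference and `n_case`
#'   case samples.
#' @export
simulate_expression <- function(config, network,
                                transform = c("lognormal", "gaussian")) {
  stopifnot(inherits(config, "simulation_config"))
  transform <- match.arg(transform)
  genes <- sim_gene_ids(config)
  extra <- setdiff(network_nodes(network), genes)
  if (length(extra) > 0) {
    abort("network contains nodes outside the configured gene universe.")
  }
  r <- config$base_correlation
  deg <- as.numeric(table(factor(c(network$gene_a, network$gene_b),
                                 levels = genes)))
  if (r != 0 && !config$hub_attenuation && max(deg) * abs(r) >= 1) {
    abort(sprintf(
      "correlation structure not positive-definite: max degree %d x r = %g >= 1; use a smaller base_correlation (or hub_attenuation = TRUE).",
      max(deg), r))
  }
  # per-gene loading on each incident edge factor
  w <- rep(sqrt(abs(r)), length(genes))
  if (config$hub_attenuation && r != 0) {
    w <- pmin(w, sqrt(0.9 / pmax(deg, 1)))
  }
  samples <- c(sim_ref_ids(config), sim_case_ids(config))
  S <- length(samples)
  E <- nrow(network)
  pe <- config$perturbed_edges
  z <- with_sim_seed(config, 102L, {
    fac <- if (E > 0) matrix(rnorm(E * S), E, S) else matrix(0, 0, S)
    eps <- matrix(rnorm(config$n_genes * S), config$n_genes, S,
                  dimnames = list(genes, samples))
    # per-sample replacement factors for perturbed edges
    fac_b <- fac
    if (!is.null(pe) && nrow(pe) > 0 && E > 0) {
      pk <- edge_key(pe$gene_a, pe$gene_b)
      ek <- edge_key(network$gene_a, network$gene_b)
      ei <- match(pk, ek)
      si <- match(pe$sample_id, samples)
      if (anyNA(ei)) abort("perturbed edge not present in the network.")
      if (anyNA(si)) abort("perturbed sample not among simulated samples.")
      fac[cbind(ei, si)] <- config$perturb_shift
      fac_b[cbind(ei, si)] <- -config$perturb_shift
    }
    zm <- matrix(0, config$n_genes, S, dimnames = list(genes, samples))
    if (E > 0 && r != 0) {
      ia <- match(network$gene_a, genes)
      ib <- match(network$gene_b, genes)
      for (e in seq_len(E)) {
        # gene_a (lexicographically smaller) uses the original factor;
        # gene_b uses the replacement stream (identical except where
        # perturbed), so a planted perturbation decouples the pair.
        zm[ia[e], ] <- zm[ia[e], ] + w[ia[e]] * fac[e, ]
        zm[ib[e], ] <- zm[ib[e], ] + sign(r) * w[ib[e]] * fac_b[e, ]
      }
    }
    scale_own <- sqrt(pmax(0, 1 - deg * w^2))
    zm + eps * scale_own
  })
  vals <- if (transform == "lognormal") {
    exp(config$expression_log_mean + config$expression_log_sd * z)
  } else {
    z
  }
  # construct directly: simulated values are complete by construction, and
  # the gaussian transform legitimately produces negative values
  structure(list(values = vals, reference_ids = sim_ref_ids(config),
                 case_ids = sim_case_ids(config)),
            class = "expression_set")
}

#' Simulate the binary mutation matrix
#'
#' I.i.d. Bernoulli(`mutation_rate`) entries over genes x case samples,
#' plus any forced `planted_mutations` entries set to 1.
#'
#' @param config A [simulation_config()].
#' @return A `mutation_matrix` (genes x case samples, 0/1).
#' @export
simulate_mutations <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  genes <- sim_gene_ids(config)
  cases <- sim_case_ids(config)
  m <- with_sim_seed(config, 103L, {
    matrix(rbinom(length(genes) * length(cases), 1, config$mutation_rate),
           length(genes), length(cases), dimnames = list(genes, cases))
  })
  pm <- config$planted_mutations
  if (!is.null(pm) && nrow(pm) > 0) {
    gi <- match(pm$gene, genes)
    si <- match(pm$sample_id, cases)
    if (anyNA(gi) || anyNA(si)) abort("planted mutation outside the simulated universe.")
    m[cbind(gi, si)] <- 1L
  }
  storage.mode(m) <- "integer"
  structure(m, class = c("mutation_matrix", "matrix", "array"))
}

#' Simulate the probe annotation table
#'
#' `probes_per_gene` promoter probes per gene (regions cycled over
#' TSS1500, TSS200, 5'UTR, 1stExon) plus one gene-body probe per gene.
#'
#' @param config A [simulation_config()].
#' @return A [probe_annotation()] tibble.
#' @export
simulate_probe_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  genes <- sim_gene_ids(config)
  regions <- promoter_regions()
  rows <- lapply(seq_along(genes), function(i) {
    k <- config$probes_per_gene
    tibble(
      probe_id = sprintf("cg%04d_%02d", i, seq_len(k + 1)),
      gene = genes[i],
      region = c(regions[((seq_len(k) - 1) %% length(regions)) + 1], "Body")
    )
  })
  probe_annotation(bind_rows(rows))
}

#' Simulate the probe beta matrix with planted aberrations
#'
#' Beta(`beta_shape1`, `beta_shape2`) values per probe and case sample.
#' Planted outliers set every promoter probe of the gene in that sample to
#' 0.98 (`"hyper"`) or 0.02 (`"hypo"`), far outside the Hampel band of the
#' baseline Beta. A `missing_fraction` of entries is then set `NA`
#' uniformly at random.
#'
#' @param config A [simulation_config()].
#' @param annotation A [simulate_probe_annotation()] (or compatible) table
#'   covering the simulated genes.
#' @return Numeric matrix, probes x case samples, values in `[0, 1]` or
#'   `NA`.
#' @export
simulate_methylation <- function(config, annotation) {
  stopifnot(inherits(config, "simulation_config"))
  cases <- sim_case_ids(config)
  probes <- unique(annotation$probe_id)
  m <- with_sim_seed(config, 104L, {
    mat <- matrix(rbeta(length(probes) * length(cases),
                        config$beta_shape1, config$beta_shape2),
                  length(probes), length(cases),
                  dimnames = list(probes, cases))
    po <- config$planted_outliers
    if (!is.null(po) && nrow(po) > 0) {
      for (i in seq_len(nrow(po))) {
        pr <- annotation$probe_id[annotation$gene == po$gene[i] & annotation$promoter]
        if (length(pr) == 0) abort("planted outlier gene has no promoter probe.")
        mat[pr, po$sample_id[i]] <-
          if (po$direction[i] == "hyper") 0.98 else 0.02
      }
    }
    if (config$missing_fraction > 0) {
      nmiss <- round(config$missing_fraction * length(mat))
      idx <- sample.int(length(mat), nmiss)
      mat[idx] <- NA_real_
    }
    mat
  })
  m
}

#' Write a complete synthetic cohort to disk
#'
#' Generates the full fixture set (expression, mutations, methylation,
#' annotation, background edge list, subtype labels, and a JSON record of
#' all planted signals) into a directory. All files are plain TSV/JSON and
#' the output is fully determined by `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @param n_subtypes Number of subtype labels assigned round-robin to case
#'   samples (0 = no label file).
#' @return Named list of file paths, invisibly.
#' @export
simulate_cohort <- function(config, dir, n_subtypes = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  net <- simulate_background(config)
  expr <- simulate_expression(config, net)
  mut <- simulate_mutations(config)
  ann <- simulate_probe_annotation(config)
  beta <- simulate_methylation(config, ann)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    mutations = file.path(dir, "mutations.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    network = file.path(dir, "network.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_matrix_tsv(expr$values, "gene", paths$expression)
  write_matrix_tsv(mut, "gene", paths$mutations)
  write_matrix_tsv(beta, "probe_id", paths$methylation)
  ann_out <- ann %>%
    group_by(.data$probe_id) %>%
    summarise(gene = paste(unique(.data$gene), collapse = ";"),
              region = .data$region[1], .groups = "drop")
  readr::write_tsv(ann_out, paths$annotation)
  readr::write_tsv(as.data.frame(net), paths$network)
  if (n_subtypes > 0) {
    paths$labels <- file.path(dir, "labels.tsv")
    lab <- tibble(sample_id = sim_case_ids(config),
                  subtype = sprintf("subtype%d",
                                    ((seq_len(config$n_case) - 1) %% n_subtypes) + 1))
    readr::write_tsv(lab, paths$labels)
  }
  truth <- list(
    seed = config$seed,
    reference_ids = sim_ref_ids(config),
    case_ids = sim_case_ids(config),
    perturbed_edges = config$perturbed_edges %||% list(),
    planted_mutations = config$planted_mutations %||% list(),
    planted_outliers = config$planted_outliers %||% list()
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(paths)
}

write_matrix_tsv <- function(m, id_col, path) {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  readr::write_tsv(df, path)
}
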