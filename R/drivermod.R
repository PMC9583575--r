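# Sample-specific driver modules: the subnetwork of the SSN reachable from
# mutated (or aberrantly methylated) seed genes within two steps, where
# every non-seed member must be a hub gene (top fraction of SSN degree).

new_driver_module <- function(edges, sample_id, driver_type, seeds,
                              hub_fraction = NULL) {
  edges <- as_tibble(sort_edges(as.data.frame(edges)[, c("gene_a", "gene_b")]))
  structure(edges,
            class = c("driver_module", class(tibble())),
            sample_id = as.character(sample_id),
            driver_type = as.character(driver_type),
            seeds = sort(as.character(seeds)),
            hub_fraction = hub_fraction)
}

#' Genes of a driver module
#' @param module A `driver_module`.
#' @return Sorted character vector of module genes (edge endpoint union).
#' @export
module_genes <- function(module) network_nodes(module)

#' @export
print.driver_module <- function(x, ...) {
  cat(sprintf("<driver_module> sample %s, type %s: %d edge(s), %d gene(s), %d seed(s)\n",
              attr(x, "sample_id"), attr(x, "driver_type"), nrow(x),
              length(module_genes(x)), length(attr(x, "seeds"))))
  NextMethod()
}

#' Hub genes of a sample-specific network
#'
#' Ranks the SSN's nodes by degree (computed from retained edges only) and
#' takes the top `hub_fraction` (default 20%). The threshold is the degree
#' at rank `ceiling(hub_fraction * n_nodes)`; all nodes with degree greater
#' than or equal to that threshold are hubs, so ties at the boundary are
#' included and the result is order-independent.
#'
#' @param ssn An [build_ssn()] result (or any edge table with `gene_a`,
#'   `gene_b`).
#' @param hub_fraction Fraction of nodes to call hubs, in `(0, 1]`.
#' @return Tibble of class `hub_set` with columns `gene`, `degree`,
#'   `is_hub`; attributes `degree_threshold` and `hub_fraction`. Empty SSN
#'   gives an empty table with a warning.
#' @export
hub_genes <- function(ssn, hub_fraction = 0.20) {
  assert_scalar_fraction(hub_fraction, "hub_fraction")
  if (nrow(ssn) == 0) {
    warn("empty SSN: no hub genes.")
    out <- tibble(gene = character(), degree = integer(), is_hub = logical())
    return(structure(out, class = c("hub_set", class(out)),
                     degree_threshold = NA_integer_,
                     hub_fraction = hub_fraction))
  }
  deg <- table(c(ssn$gene_a, ssn$gene_b))
  out <- tibble(gene = names(deg), degree = as.integer(deg)) %>%
    arrange(dplyr::desc(.data$degree), .data$gene)
  k <- ceiling(hub_fraction * nrow(out))
  thr <- out$degree[k]
  out$is_hub <- out$degree >= thr
  structure(out, class = c("hub_set", class(tibble())),
            degree_threshold = thr, hub_fraction = hub_fraction)
}

#' Two-order hub-constrained driver module
#'
#' Builds the per-sample driver module around seed genes (mutated or
#' aberrantly methylated in this sample) in the SSN, under two rules:
#' the module is restricted to the 2-order neighbourhood of the seeds, and
#' every non-seed member must be a hub gene. Concretely, the retained edges
#' are
#' \itemize{
#'   \item seed-to-neighbour edges `(s, u)` with `u` a hub, and
#'   \item neighbour-to-second-order edges `(u, w)` where `u` is a hub
#'     neighbour of some seed and `w` is a hub neighbour of `u`.
#' }
#' Seeds themselves are exempt from the hub requirement (altered genes
#' typically have low SSN degree). A non-hub first-order neighbour blocks
#' both its seed edge and any second-order extension through it.
#'
#' @param ssn An [build_ssn()] result.
#' @param seeds Character vector of seed genes for this sample; genes
#'   absent from the SSN are ignored.
#' @param hubs A [hub_genes()] result; computed from `ssn` with
#'   `hub_fraction` when omitted.
#' @param driver_type Label: `"mutation"`, `"methylation"` or `"co"`.
#' @param hub_fraction Used when `hubs` is omitted.
#' @return A `driver_module` tibble (canonical edges; attributes
#'   `sample_id`, `driver_type`, `seeds`, `hub_fraction`).
#' @export
two_order_module <- function(ssn, seeds, hubs = NULL,
                             driver_type = c("mutation", "methylation", "co"),
                             hub_fraction = 0.20) {
  driver_type <- match.arg(driver_type)
  sample_id <- attr(ssn, "sample_id") %||% NA_character_
  if (is.null(hubs)) hubs <- hub_genes(ssn, hub_fraction)
  hub_set <- hubs$gene[hubs$is_hub]
  nodes <- network_nodes(ssn)
  seeds <- sort(unique(as.character(seeds)))
  seeds_in <- intersect(seeds, nodes)
  if (length(seeds_in) == 0 || nrow(ssn) == 0) {
    if (length(seeds_in) == 0) warn("no seed gene present in the SSN: empty module.")
    return(new_driver_module(tibble(gene_a = character(), gene_b = character()),
                             sample_id, driver_type, seeds,
                             attr(hubs, "hub_fraction")))
  }
  ea <- ssn$gene_a
  eb <- ssn$gene_b
  is_seed_a <- ea %in% seeds_in
  is_seed_b <- eb %in% seeds_in
  is_hub_a <- ea %in% hub_set
  is_hub_b <- eb %in% hub_set
  # first-order edges: seed -- hub neighbour
  e1 <- (is_seed_a & is_hub_b) | (is_seed_b & is_hub_a)
  # hub first-order neighbours of seeds
  u <- unique(c(eb[is_seed_a & is_hub_b], ea[is_seed_b & is_hub_a]))
  # second-order edges: hub first-order neighbour -- hub
  in_u_a <- ea %in% u
  in_u_b <- eb %in% u
  e2 <- (in_u_a & is_hub_b) | (in_u_b & is_hub_a)
  keep <- e1 | e2
  new_driver_module(distinct(tibble(gene_a = ea[keep], gene_b = eb[keep])),
                    sample_id, driver_type, seeds,
                    attr(hubs, "hub_fraction"))
}

#' Co-driver module: union of mutation and methylation modules
#'
#' @param mutation_module,methylation_module `driver_module`s for the same
#'   sample.
#' @return A `driver_module` with `driver_type = "co"`, the canonical
#'   edge-set union and the seed-set union.
#' @export
co_driver_module <- function(mutation_module, methylation_module) {
  sa <- attr(mutation_module, "sample_id")
  sb <- attr(methylation_module, "sample_id")
  if (!identical(sa, sb)) {
    abort(sprintf("sample mismatch: '%s' vs '%s'.", sa, sb))
  }
  edges <- distinct(bind_rows(
    as_tibble(as.data.frame(mutation_module)[, c("gene_a", "gene_b")]),
    as_tibble(as.data.frame(methylation_module)[, c("gene_a", "gene_b")])
  ))
  new_driver_module(edges, sa, "co",
                    union(attr(mutation_module, "seeds"),
                          attr(methylation_module, "seeds")),
                    attr(mutation_module, "hub_fraction"))
}

#' Build the three driver modules of one sample
#'
#' Convenience wrapper: hub genes from the SSN, then the mutation-seeded
#' module, the methylation-seeded module and their co-driver union.
#'
#' @param ssn An [build_ssn()] result for one case sample.
#' @param mutation_matrix A [build_mutation_matrix()] result.
#' @param methylation_ternary A [hampel_ternary()] result.
#' @param hub_fraction Hub fraction (default 0.20).
#' @return Named list with elements `mutation`, `methylation`, `co`
#'   (`driver_module`s) and `hubs` (the [hub_genes()] table).
#' @export
build_driver_modules <- function(ssn, mutation_matrix, methylation_ternary,
                                 hub_fraction = 0.20) {
  sample_id <- attr(ssn, "sample_id")
  hubs <- hub_genes(ssn, hub_fraction)
  mut_seeds <- if (sample_id %in% colnames(mutation_matrix)) {
    profile_seeds(mutation_matrix, sample_id)
  } else character()
  met_seeds <- if (sample_id %in% colnames(methylation_ternary)) {
    profile_seeds(methylation_ternary, sample_id)
  } else character()
  m_mut <- suppressWarnings(
    two_order_module(ssn, mut_seeds, hubs, driver_type = "mutation"))
  m_met <- suppressWarnings(
    two_order_module(ssn, met_seeds, hubs, driver_type = "methylation"))
  list(mutation = m_mut, methylation = m_met,
       co = co_driver_module(m_mut, m_met), hubs = hubs)
}
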