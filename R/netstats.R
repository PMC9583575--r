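# Structural analytics on driver modules: centralities, Jaccard module
# similarity, and the rank tests used for group comparisons.

#' Gene centralities of a module
#'
#' Degree, shortest-path betweenness (unnormalized by default, so a 5-node
#' star's center scores (n-1)(n-2)/2 = 6) and eigenvector centrality.
#' Eigenvector centrality is computed per connected component (modules are
#' often disconnected) and normalized to unit maximum within each
#' component.
#'
#' @param module A `driver_module`, `ssn`, or any edge table with
#'   `gene_a`/`gene_b` columns.
#' @param classes Optional tibble with columns `gene`, `class` labelling
#'   genes (a gene may carry several labels, one row each); joined onto the
#'   result. See [gene_classes()].
#' @param normalized_betweenness If `TRUE`, betweenness is normalized by
#'   `(n-1)(n-2)/2`.
#' @return Tibble of class `centrality_table`: `gene`, `degree`,
#'   `betweenness`, `eigenvector` (and `class` when `classes` is given; a
#'   multi-labelled gene yields one row per label).
#' @export
centralities <- function(module, classes = NULL, normalized_betweenness = FALSE) {
  if (nrow(module) == 0) {
    out <- tibble(gene = character(), degree = integer(),
                  betweenness = numeric(), eigenvector = numeric())
    class(out) <- c("centrality_table", class(out))
    return(out)
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(module)[, c("gene_a", "gene_b")], directed = FALSE)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE,
                             normalized = normalized_betweenness)
  comp <- igraph::components(g)
  eig <- rep(NA_real_, igraph::vcount(g))
  names(eig) <- igraph::V(g)$name
  for (cc in seq_len(comp$no)) {
    vs <- which(comp$membership == cc)
    sub <- igraph::induced_subgraph(g, vs)
    if (igraph::vcount(sub) == 1) {
      ev <- setNames(1, igraph::V(sub)$name)
    } else {
      ev <- igraph::eigen_centrality(sub)$vector
    }
    eig[names(ev)] <- ev
  }
  out <- tibble(gene = names(deg), degree = as.integer(deg),
                betweenness = as.numeric(btw),
                eigenvector = as.numeric(eig[names(deg)])) %>%
    arrange(.data$gene)
  if (!is.null(classes)) {
    out <- left_join(out, classes, by = "gene")
    out$class[is.na(out$class)] <- "other"
  }
  class(out) <- c("centrality_table", class(tibble()))
  out
}

#' Gene class labels for centrality comparisons
#'
#' Labels module genes by their relation to the sample's alterations:
#' mutation seeds, methylation seeds, 1-order SSN neighbours of each seed
#' class, and `other`. A gene may carry several labels (one row per
#' label).
#'
#' @param module Edge table whose genes are to be labelled (typically the
#'   sample's co-driver module).
#' @param ssn The sample's SSN (neighbourhoods are taken here).
#' @param mutation_seeds,methylation_seeds Seed gene vectors for this
#'   sample.
#' @return Tibble with columns `gene`, `class`.
#' @export
gene_classes <- function(module, ssn, mutation_seeds, methylation_seeds) {
  genes <- module_genes(module)
  nb <- function(seeds) {
    s <- intersect(seeds, network_nodes(ssn))
    unique(c(ssn$gene_b[ssn$gene_a %in% s], ssn$gene_a[ssn$gene_b %in% s]))
  }
  lab <- bind_rows(
    tibble(gene = intersect(genes, mutation_seeds), class = "mutation_seed"),
    tibble(gene = intersect(genes, methylation_seeds), class = "methylation_seed"),
    tibble(gene = intersect(genes, setdiff(nb(mutation_seeds), mutation_seeds)),
           class = "mutation_neighbor"),
    tibble(gene = intersect(genes, setdiff(nb(methylation_seeds), methylation_seeds)),
           class = "methylation_neighbor")
  )
  rest <- setdiff(genes, lab$gene)
  bind_rows(lab, tibble(gene = rest,
                        class = rep("other", length(rest)))) %>%
    arrange(.data$gene, .data$class)
}

#' Jaccard similarity of two sets
#'
#' `|a n b| / |a u b|`; two empty sets score 0 by convention (warned).
#'
#' @param a,b Vectors treated as sets.
#' @return Similarity score in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) {
    warn("both sets empty: Jaccard similarity defined as 0.")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Similarity of a sample's mutation and methylation modules
#'
#' Jaccard similarity of the two modules' gene sets or canonical edge
#' sets.
#'
#' @param mutation_module,methylation_module `driver_module`s.
#' @param on `"edges"` or `"genes"`.
#' @return Similarity score in `[0, 1]`.
#' @export
module_similarity <- function(mutation_module, methylation_module,
                              on = c("edges", "genes")) {
  on <- match.arg(on)
  if (on == "edges") {
    jaccard(edge_key(mutation_module$gene_a, mutation_module$gene_b),
            edge_key(methylation_module$gene_a, methylation_module$gene_b))
  } else {
    jaccard(module_genes(mutation_module), module_genes(methylation_module))
  }
}

#' Rank-based group comparisons
#'
#' Delegates to the standard rank tests: two-group Wilcoxon rank sum with
#' continuity correction (one- or two-sided, paired or unpaired),
#' multi-group Kruskal-Wallis, and the Nemenyi all-pairs post-hoc (mean
#' ranks against the studentized-range distribution; no tie correction).
#'
#' @param data Data frame with one value column and one group column.
#' @param value,group Column names (strings).
#' @param method `"wilcoxon"`, `"kruskal"` or `"nemenyi"`.
#' @param ... Passed to [stats::wilcox.test()] (e.g. `alternative`,
#'   `paired`).
#' @return Tidy tibble: `method`, `statistic`, `p_value` (one row; for
#'   `"nemenyi"`, one row per group pair with `group1`, `group2`).
#' @export
compare_groups <- function(data, value, group,
                           method = c("wilcoxon", "kruskal", "nemenyi"), ...) {
  method <- match.arg(method)
  v <- data[[value]]
  gr <- factor(data[[group]])
  sizes <- table(gr)
  if (any(sizes < 2)) {
    abort(sprintf("every group needs at least 2 observations (smallest has %d).",
                  min(sizes)))
  }
  if (method == "wilcoxon") {
    if (nlevels(gr) != 2) abort("wilcoxon requires exactly 2 groups.")
    sp <- split(v, gr)
    ht <- wilcox.test(sp[[1]], sp[[2]], correct = TRUE, ...)
    tibble(method = "wilcoxon", statistic = unname(ht$statistic),
           p_value = ht$p.value)
  } else if (method == "kruskal") {
    ht <- kruskal.test(v, gr)
    tibble(method = "kruskal", statistic = unname(ht$statistic),
           p_value = ht$p.value)
  } else {
    nemenyi_test(v, gr)
  }
}

# Nemenyi all-pairs comparison after Kruskal-Wallis: |mean rank difference|
# referred to the studentized range distribution with infinite df,
# q = |Ri - Rj| / sqrt(N(N+1)/12 * (1/ni + 1/nj)) * sqrt(2).
nemenyi_test <- function(v, gr) {
  gr <- factor(gr)
  rk <- rank(v)
  N <- length(v)
  kgrp <- nlevels(gr)
  mean_rank <- tapply(rk, gr, mean)
  n <- tapply(rk, gr, length)
  pairs <- utils::combn(levels(gr), 2)
  res <- apply(pairs, 2L, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(N * (N + 1) / 12 * (1 / n[[i]] + 1 / n[[j]]))
    q <- abs(mean_rank[[i]] - mean_rank[[j]]) / se * sqrt(2)
    c(q = q, p = 1 - ptukey(q, nmeans = kgrp, df = Inf))
  })
  tibble(method = "nemenyi", group1 = pairs[1, ], group2 = pairs[2, ],
         statistic = res["q", ], p_value = res["p", ])
}
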