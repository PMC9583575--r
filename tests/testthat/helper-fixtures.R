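# Small in-code fixtures shared across test files.

# A 5-gene, 6-edge toy network used by the SSN oracle tests.
toy_network <- function() {
  suppressMessages(background_network(data.frame(
    gene_a = c("A", "A", "B", "B", "C", "D"),
    gene_b = c("B", "C", "C", "D", "E", "E")
  )))
}

# Deterministic toy expression: n_ref reference + n_case case samples over
# the given genes, i.i.d. lognormal (no planted structure).
toy_expression <- function(genes = LETTERS[1:5], n_ref = 20, n_case = 3,
                           seed = 42) {
  withr::with_seed(seed, {
    ref_ids <- sprintf("N%02d", seq_len(n_ref))
    case_ids <- sprintf("T%02d", seq_len(n_case))
    vals <- matrix(exp(rnorm(length(genes) * (n_ref + n_case), log(10), 0.4)),
                   length(genes), n_ref + n_case,
                   dimnames = list(genes, c(ref_ids, case_ids)))
    expression_set(data.frame(gene = genes, vals, check.names = FALSE),
                   ref_ids, case_ids)
  })
}

# A driver module built directly from an edge table (for cohort tests).
make_module <- function(edges, sample_id, driver_type = "co",
                        seeds = character()) {
  ssdriver:::new_driver_module(edges, sample_id, driver_type, seeds)
}

# Perfect-matching network over 2k genes from a simulation config: gene
# 2i-1 -- gene 2i. Independent pairs (no shared genes across edges).
matching_network <- function(n_genes) {
  ids <- sprintf("g%04d", seq_len(n_genes))
  suppressMessages(background_network(data.frame(
    gene_a = ids[seq(1, n_genes, by = 2)],
    gene_b = ids[seq(2, n_genes, by = 2)]
  )))
}

# Brute-force SSN for one sample: naive per-edge correlation loops plus the
# normal CDF, the independent oracle for build_ssn.
brute_force_ssn <- function(expr, bg, sample_id, alpha = 0.01) {
  refv <- expr$values[, expr$reference_ids, drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(bg))) {
    a <- bg$gene_a[i]; b <- bg$gene_b[i]
    if (!a %in% rownames(refv) || !b %in% rownames(refv)) next
    xa <- refv[a, ]; xb <- refv[b, ]
    if (sd(xa) == 0 || sd(xb) == 0) next
    pcc_n <- cor(xa, xb)
    if (abs(pcc_n) >= 1) next
    ya <- c(xa, expr$values[a, sample_id])
    yb <- c(xb, expr$values[b, sample_id])
    pcc_n1 <- cor(ya, yb)
    n <- length(xa)
    z <- (pcc_n1 - pcc_n) * (n - 1) / (1 - pcc_n^2)
    p <- 2 * (1 - pnorm(abs(z)))
    out[[length(out) + 1]] <- data.frame(
      gene_a = min(a, b), gene_b = max(a, b),
      pcc_n = pcc_n, pcc_n1 = pcc_n1, z = z, p = p)
  }
  df <- do.call(rbind, out)
  df[df$p < alpha, , drop = FALSE]
}

# Brute-force two-order module membership test: independently re-derives
# the retained edge set from the rule statement.
brute_force_module_edges <- function(ssn_edges, seeds, hubs) {
  adj <- list()
  add <- function(a, b) adj[[a]] <<- union(adj[[a]], b)
  for (i in seq_len(nrow(ssn_edges))) {
    add(ssn_edges$gene_a[i], ssn_edges$gene_b[i])
    add(ssn_edges$gene_b[i], ssn_edges$gene_a[i])
  }
  nodes <- names(adj)
  seeds <- intersect(seeds, nodes)
  keep <- logical(nrow(ssn_edges))
  for (i in seq_len(nrow(ssn_edges))) {
    a <- ssn_edges$gene_a[i]; b <- ssn_edges$gene_b[i]
    # seed--hub-neighbour edge
    for (pair in list(c(a, b), c(b, a))) {
      s <- pair[1]; u <- pair[2]
      if (s %in% seeds && u %in% hubs) keep[i] <- TRUE
      # hub-first-order-neighbour -- hub edge
      if (u %in% hubs && s %in% hubs) {
        # s must be a hub neighbour of some seed
        for (sd_ in seeds) {
          if (s %in% adj[[sd_]]) keep[i] <- TRUE
        }
      }
    }
  }
  ssn_edges[keep, c("gene_a", "gene_b"), drop = FALSE]
}

# Brute-force betweenness via all-pairs BFS path counting (unweighted,
# unnormalized, undirected).
brute_force_betweenness <- function(edges) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  adj <- lapply(setNames(nodes, nodes), function(v) {
    c(edges$gene_b[edges$gene_a == v], edges$gene_a[edges$gene_b == v])
  })
  btw <- setNames(numeric(length(nodes)), nodes)
  for (s in nodes) {
    # Brandes-style single-source accumulation
    dist <- setNames(rep(Inf, length(nodes)), nodes)
    sigma <- setNames(numeric(length(nodes)), nodes)
    preds <- lapply(setNames(nodes, nodes), function(v) character())
    dist[s] <- 0; sigma[s] <- 1
    queue <- s; order_ <- character()
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      order_ <- c(order_, v)
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- setNames(numeric(length(nodes)), nodes)
    for (w in rev(order_)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) btw[w] <- btw[w] + delta[w]
    }
  }
  btw / 2
}

# Random simple graph edge table over n nodes.
random_edges <- function(n_nodes, p = 0.3) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2])
}
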