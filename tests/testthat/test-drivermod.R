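# Helper: ssn-like edge table (class attributes not required by the
# module constructors beyond gene_a/gene_b).
ssn_edges <- function(...) {
  e <- data.frame(...)
  names(e) <- c("gene_a", "gene_b")
  structure(tibble::as_tibble(e), sample_id = "T01")
}

test_that("hub selection is rank-based with tie inclusion", {
  # star X--L1..L5 plus L1--L2: degrees X=5, L1=L2=2, L3=L4=L5=1
  edges <- ssn_edges(c("X", "X", "X", "X", "X", "L1"),
                     c("L1", "L2", "L3", "L4", "L5", "L2"))
  # fraction 0.15 of 6 nodes -> rank 1, unique top degree: X alone
  hs <- hub_genes(edges, 0.15)
  expect_equal(hs$gene[hs$is_hub], "X")
  expect_equal(attr(hs, "degree_threshold"), 5L)

  # fraction 0.34 -> rank 2, threshold degree 2: the degree-2 tie (L1, L2)
  # is fully included alongside X
  hs2 <- hub_genes(edges, 0.34)
  expect_setequal(hs2$gene[hs2$is_hub], c("X", "L1", "L2"))
  thr <- attr(hs2, "degree_threshold")
  expect_true(all(hs2$degree[hs2$is_hub] >= thr))
  expect_true(all(hs2$degree[!hs2$is_hub] < thr))

  # fraction 1: everyone is a hub
  hs3 <- hub_genes(edges, 1)
  expect_true(all(hs3$is_hub))

  expect_warning(h0 <- hub_genes(ssn_edges(character(), character())),
                 "empty")
  expect_equal(nrow(h0), 0L)
})

test_that("two-order rule: hub neighbours admit edges, non-hubs block", {
  # path s - u - w; hubs contain u and w
  path <- ssn_edges(c("s", "u"), c("u", "w"))
  hubs_uw <- tibble::tibble(gene = c("s", "u", "w"),
                            degree = c(1L, 2L, 1L),
                            is_hub = c(FALSE, TRUE, TRUE))
  m <- two_order_module(path, seeds = "s", hubs = hubs_uw,
                        driver_type = "mutation")
  expect_equal(nrow(m), 2L)

  # u not a hub: both orders blocked
  hubs_w <- tibble::tibble(gene = c("s", "u", "w"),
                           degree = c(1L, 2L, 1L),
                           is_hub = c(FALSE, FALSE, TRUE))
  m2 <- two_order_module(path, seeds = "s", hubs = hubs_w,
                         driver_type = "mutation")
  expect_equal(nrow(m2), 0L)

  # seed with no SSN presence: empty module with warning
  expect_warning(
    m3 <- two_order_module(path, seeds = "zz", hubs = hubs_uw,
                           driver_type = "methylation"),
    "no seed")
  expect_equal(nrow(m3), 0L)
  expect_equal(attr(m3, "driver_type"), "methylation")
})

test_that("module membership matches the brute-force rule on random toys", {
  withr::with_seed(99, {
    for (i in 1:100) {
      edges <- random_edges(20, p = 0.25)
      if (nrow(edges) == 0) next
      sed <- structure(tibble::as_tibble(edges), sample_id = "T01")
      nodes <- network_nodes(edges)
      seeds <- sample(nodes, min(3, length(nodes)))
      hs <- hub_genes(sed, 0.3)
      m <- suppressWarnings(
        two_order_module(sed, seeds, hs, driver_type = "mutation"))
      want <- brute_force_module_edges(edges, seeds, hs$gene[hs$is_hub])
      expect_setequal(paste(m$gene_a, m$gene_b),
                      unique(paste(pmin(want$gene_a, want$gene_b),
                                   pmax(want$gene_a, want$gene_b))))
    }
  })
})

test_that("every module gene lies within SSN distance 2 of a seed (BFS oracle)", {
  withr::with_seed(123, {
    for (i in 1:30) {
      edges <- random_edges(15, p = 0.3)
      if (nrow(edges) == 0) next
      sed <- structure(tibble::as_tibble(edges), sample_id = "T01")
      nodes <- network_nodes(edges)
      seeds <- sample(nodes, 2)
      m <- suppressWarnings(two_order_module(sed, seeds, hub_fraction = 0.4,
                                             driver_type = "mutation"))
      if (nrow(m) == 0) next
      g <- igraph::graph_from_data_frame(edges, directed = FALSE)
      d <- igraph::distances(g, v = intersect(seeds, nodes))
      mind <- apply(d, 2, min)
      expect_true(all(mind[module_genes(m)] <= 2))
      # edges subset of the SSN
      expect_true(all(paste(m$gene_a, m$gene_b) %in%
                        paste(pmin(edges$gene_a, edges$gene_b),
                              pmax(edges$gene_a, edges$gene_b))))
    }
  })
})

test_that("modules grow monotonically with hub_fraction", {
  withr::with_seed(7, {
    edges <- random_edges(25, p = 0.2)
    sed <- structure(tibble::as_tibble(edges), sample_id = "T01")
    seeds <- sample(network_nodes(edges), 3)
    fr <- c(0.1, 0.2, 0.4, 0.8, 1.0)
    mods <- lapply(fr, function(f) suppressWarnings(
      two_order_module(sed, seeds, hub_fraction = f,
                       driver_type = "mutation")))
    for (i in seq_len(length(fr) - 1)) {
      expect_true(all(paste(mods[[i]]$gene_a, mods[[i]]$gene_b) %in%
                        paste(mods[[i + 1]]$gene_a, mods[[i + 1]]$gene_b)))
    }
  })
})

test_that("co-driver module is the canonical edge union", {
  m1 <- make_module(data.frame(gene_a = c("A", "B", "C"),
                               gene_b = c("B", "C", "D")),
                    "T01", "mutation", seeds = "A")
  m2 <- make_module(data.frame(gene_a = c("B", "C", "D", "E"),
                               gene_b = c("C", "D", "E", "F")),
                    "T01", "methylation", seeds = "F")
  co <- co_driver_module(m1, m2)
  expect_equal(nrow(co), 5L)  # 3 + 4 with 2 overlapping
  expect_equal(attr(co, "driver_type"), "co")
  expect_setequal(attr(co, "seeds"), c("A", "F"))

  # idempotent union (same edge set, relabelled as a co module)
  co2 <- co_driver_module(m1, m1)
  expect_equal(co2$gene_a, m1$gene_a)
  expect_equal(co2$gene_b, m1$gene_b)

  # disjoint modules add up
  m3 <- make_module(data.frame(gene_a = c("X", "Y"), gene_b = c("Y", "Z")),
                    "T01", "methylation")
  expect_equal(nrow(co_driver_module(m1, m3)), 5L)

  m4 <- make_module(data.frame(gene_a = "A", gene_b = "B"), "T02", "methylation")
  expect_error(co_driver_module(m1, m4), "mismatch")
})

test_that("seed genes have lower module degree than their 1-order neighbours", {
  # planted-data tendency: seeds are low-degree, their admitted neighbours
  # are hubs by construction
  cfg <- simulation_config(n_genes = 150, n_reference = 60, n_case = 6,
                           base_correlation = 0.3, mutation_rate = 0.08,
                           attachment = 2, seed = 31)
  net <- simulate_background(cfg)
  expr <- simulate_expression(cfg, net)
  mut <- simulate_mutations(cfg)
  rn <- suppressMessages(build_reference_network(expr, net))
  seed_degs <- c(); nb_degs <- c()
  for (sid in expr$case_ids) {
    ssn <- build_ssn(expr, rn, sid, alpha = 0.05)
    if (nrow(ssn) == 0) next
    m <- suppressWarnings(two_order_module(
      ssn, profile_seeds(mut, sid), driver_type = "mutation"))
    if (nrow(m) == 0) next
    ct <- centralities(m)
    seeds <- intersect(attr(m, "seeds"), ct$gene)
    nbs <- setdiff(module_genes(m), seeds)
    seed_degs <- c(seed_degs, ct$degree[ct$gene %in% seeds])
    nb_degs <- c(nb_degs, ct$degree[ct$gene %in% nbs])
  }
  expect_gte(length(seed_degs), 3)
  expect_gte(length(nb_degs), 3)
  expect_lt(mean(seed_degs), mean(nb_degs))
})
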