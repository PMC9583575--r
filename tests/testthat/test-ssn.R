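test_that("pearson_cor matches hand-computed values and signals degeneracy", {
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(pearson_cor(c(1, 2, 3, 4), -c(1, 2, 3, 4)), -1)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(r <- pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))
  expect_error(pearson_cor(1:2, 1:3), "equal length")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("edge_statistic matches the normal-CDF oracle", {
  # pcc_n = 0, n = 101: null sd = (1 - 0)/100 = 0.01; delta = 0.02 -> z = 2
  s <- edge_statistic(0, 0.02, 101)
  expect_equal(s$delta, 0.02)
  expect_equal(s$z, 2)
  expect_equal(s$p, 2 * (1 - pnorm(2)), tolerance = 1e-12)
  # nonzero pcc_n: null sd = 0.36/100 = 0.0036; 0.0072/0.0036 = 2
  s2 <- edge_statistic(0.8, 0.8072, 101)
  expect_equal(s2$z, 2, tolerance = 1e-12)
  expect_equal(s2$p, s$p, tolerance = 1e-12)
  # null point
  s3 <- edge_statistic(0.5, 0.5, 50)
  expect_equal(s3$z, 0)
  expect_equal(s3$p, 1)
  expect_error(edge_statistic(1, 0.5, 50), "degenerate")
  expect_error(edge_statistic(0, 0.5, 2), "n >= 3")
})

test_that("reference network drops unmatched and degenerate edges", {
  expr <- toy_expression(genes = c("A", "B", "C", "D"))
  bg <- toy_network()  # includes gene E, absent from expression
  expect_message(rn <- build_reference_network(expr, bg), "dropped 2")
  expect_equal(nrow(rn), 4L)  # A-B, A-C, B-C, B-D survive
  expect_true(all(abs(rn$pcc_n) <= 1))
  expect_equal(attr(rn, "n_ref"), 20)

  # constant gene excluded
  expr2 <- toy_expression(genes = c("A", "B"))
  expr2$values["A", ] <- 5
  bg2 <- suppressMessages(background_network(
    data.frame(a = "A", b = "B")))
  expect_message(rn2 <- build_reference_network(expr2, bg2), "excluded 1")
  expect_equal(nrow(rn2), 0L)

  # fewer than 3 reference samples
  expr3 <- toy_expression(n_ref = 2)
  expect_error(build_reference_network(expr3, bg), "at least 3")
})

test_that("reference network recovers planted edge correlations", {
  cfg <- simulation_config(n_genes = 200, n_reference = 200, n_case = 2,
                           base_correlation = 0.6, seed = 11)
  net <- matching_network(200)
  expr <- simulate_expression(cfg, net)
  rn <- build_reference_network(expr, net)
  expect_equal(mean(rn$pcc_n), 0.6, tolerance = 0.1)

  cfg0 <- simulation_config(n_genes = 200, n_reference = 200, n_case = 2,
                            base_correlation = 0, seed = 12)
  expr0 <- simulate_expression(cfg0, net)
  rn0 <- build_reference_network(expr0, net)
  expect_lt(abs(mean(rn0$pcc_n)), 3 / sqrt(200))
})

test_that("build_ssn agrees with a brute-force oracle on the 5-gene toy", {
  bg <- toy_network()
  for (seed in 1:10) {
    expr <- toy_expression(genes = LETTERS[1:5], n_ref = 15, n_case = 2,
                           seed = seed)
    rn <- build_reference_network(expr, bg)
    for (sid in expr$case_ids) {
      got <- build_ssn(expr, rn, sid, alpha = 0.3)
      want <- brute_force_ssn(expr, bg, sid, alpha = 0.3)
      got_keys <- paste(got$gene_a, got$gene_b)
      want_keys <- if (is.null(want)) character() else
        paste(want$gene_a, want$gene_b)
      expect_setequal(got_keys, want_keys)
      if (length(got_keys) > 0) {
        ord <- match(got_keys, want_keys)
        expect_equal(got$p, want$p[ord], tolerance = 1e-10)
        expect_equal(got$pcc_n1, want$pcc_n1[ord], tolerance = 1e-10)
      }
    }
  }
})

test_that("SSN retention is monotone in alpha and empty at alpha = 0", {
  bg <- toy_network()
  expr <- toy_expression(n_ref = 15, n_case = 1, seed = 3)
  rn <- build_reference_network(expr, bg)
  sid <- expr$case_ids[1]
  alphas <- c(0, 0.01, 0.1, 0.5, 0.9)
  sizes <- vapply(alphas, function(a) nrow(build_ssn(expr, rn, sid, a)), 0L)
  expect_equal(sizes[1], 0L)
  expect_true(all(diff(sizes) >= 0))
  keys <- lapply(alphas, function(a) {
    s <- build_ssn(expr, rn, sid, a)
    paste(s$gene_a, s$gene_b)
  })
  for (i in seq_len(length(alphas) - 1)) {
    expect_true(all(keys[[i]] %in% keys[[i + 1]]))
  }
  expect_error(build_ssn(expr, rn, "nope"), "not found")
})

test_that("delta is null-calibrated: mean ~ 0, scale ~ (1-r^2)/(n-1)", {
  # matched pairs at three reference correlation levels; the added case
  # sample comes from the same distribution (pure null). The null scale
  # (standard deviation) of delta is (1 - pcc_n^2)/(n - 1).
  n_ref <- 120
  n_case <- 40
  for (r in c(0, 0.5, 0.8)) {
    cfg <- simulation_config(n_genes = 120, n_reference = n_ref,
                             n_case = n_case, base_correlation = r,
                             seed = 100 + round(100 * r))
    net <- matching_network(120)
    expr <- simulate_expression(cfg, net, transform = "gaussian")
    rn <- build_reference_network(expr, net)
    deltas <- unlist(lapply(expr$case_ids, function(sid) {
      build_ssn(expr, rn, sid, alpha = 1 - 1e-12, keep_all = TRUE)$delta
    }))
    expect_lt(abs(mean(deltas)), 3 * sd(deltas) / sqrt(length(deltas)))
    expected_sd <- mean((1 - rn$pcc_n^2) / (n_ref - 1))
    expect_equal(sd(deltas), expected_sd, tolerance = 0.15)
  }
})

test_that("case samples are processed independently of order", {
  bg <- toy_network()
  expr <- toy_expression(n_ref = 15, n_case = 3, seed = 5)
  rn <- build_reference_network(expr, bg)
  direct <- lapply(expr$case_ids, function(s) build_ssn(expr, rn, s, 0.2))
  reversed <- lapply(rev(expr$case_ids), function(s) build_ssn(expr, rn, s, 0.2))
  for (i in seq_along(direct)) {
    expect_equal(as.data.frame(direct[[i]]),
                 as.data.frame(reversed[[length(direct) + 1 - i]]))
  }
})

test_that("leave-one-out reference handling excludes the probed normal sample", {
  bg <- toy_network()
  expr <- toy_expression(n_ref = 16, n_case = 1, seed = 9)
  rn <- build_reference_network(expr, bg)
  sid <- expr$reference_ids[1]
  with_loo <- build_ssn(expr, rn, sid, alpha = 1 - 1e-12, keep_all = TRUE,
                        leave_one_out = TRUE)
  without <- build_ssn(expr, rn, sid, alpha = 1 - 1e-12, keep_all = TRUE)
  # without leave-one-out the sample is already in the reference: adding it
  # again changes nothing much, but the LOO reference excludes it, so the
  # two pcc_n columns must differ
  expect_false(isTRUE(all.equal(with_loo$pcc_n, without$pcc_n)))
  expect_equal(attr(with_loo, "n_ref"), 15)
})
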