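test_that("mutation matrix binarizes counts and fills absent genes", {
  calls <- data.frame(gene = c("A", "B"), T1 = c(3, 0), T2 = c(0, 1))
  m <- build_mutation_matrix(calls)
  expect_equal(unname(m["A", "T1"]), 1L)
  expect_equal(unname(m["A", "T2"]), 0L)
  expect_true(all(m %in% 0:1))

  m2 <- build_mutation_matrix(calls, genes = c("A", "B", "C"))
  expect_equal(unname(m2["C", ]), c(0L, 0L))

  expect_error(build_mutation_matrix(
    data.frame(gene = "A", T1 = -1)), "non-negative")
  expect_equal(profile_seeds(m, "T1"), "A")
})

test_that("probe filter uses a strict > max_na_fraction rule", {
  set.seed(1)
  beta <- matrix(runif(3 * 100), 3, 100,
                 dimnames = list(c("p1", "p2", "p3"), sprintf("s%03d", 1:100)))
  beta["p1", 1:11] <- NA  # 11% missing: removed
  beta["p2", 1:10] <- NA  # exactly 10%: kept
  out <- suppressMessages(filter_probes(beta, 0.10))
  expect_equal(rownames(out), c("p2", "p3"))
  expect_equal(attr(out, "n_removed"), 1L)
  # no missing values: identity
  full <- matrix(0.5, 2, 4, dimnames = list(c("a", "b"), letters[1:4]))
  expect_equal(unclass(filter_probes(full))[, ], full[, ])
})

test_that("knn imputation recovers exact neighbours and constant matrices", {
  # probe identical to a complete neighbour except one missing cell
  beta <- matrix(c(0.1, 0.2, 0.3, 0.4,
                   0.1, 0.2, 0.3, NA), 2, 4, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), letters[1:4]))
  out <- knn_impute(beta, k = 1)
  expect_equal(unname(out["p2", "d"]), 0.4)
  expect_false(anyNA(out))

  # all probes constant 0.5
  cb <- matrix(0.5, 4, 4, dimnames = list(paste0("p", 1:4), letters[1:4]))
  cb[2, 3] <- NA
  expect_equal(unique(as.vector(knn_impute(cb, k = 2))), 0.5)

  # fewer than k usable neighbours: row-mean fallback, with a note
  solo <- matrix(c(0.2, 0.4, NA), 1, 3,
                 dimnames = list("p1", letters[1:3]))
  expect_message(out2 <- knn_impute(solo, k = 10), "row mean")
  expect_equal(unname(out2["p1", "c"]), 0.3)
})

test_that("knn imputation beats column-mean imputation on masked entries", {
  # correlated probe rows: shared per-probe-cluster profile + noise
  set.seed(42)
  n_probes <- 60; n_samp <- 30
  cluster <- rep(1:6, each = 10)
  base <- matrix(runif(6 * n_samp, 0.2, 0.8), 6, n_samp)
  beta <- pmin(pmax(base[cluster, ] +
                      matrix(rnorm(n_probes * n_samp, 0, 0.02),
                             n_probes, n_samp), 0), 1)
  dimnames(beta) <- list(sprintf("p%02d", 1:n_probes),
                         sprintf("s%02d", 1:n_samp))
  mask <- cbind(sample(n_probes, 40, replace = TRUE),
                sample(n_samp, 40, replace = TRUE))
  mask <- mask[!duplicated(mask), , drop = FALSE]
  truth <- beta[mask]
  masked <- beta
  masked[mask] <- NA
  imputed <- knn_impute(masked, k = 5)
  rmse_knn <- sqrt(mean((imputed[mask] - truth)^2))
  colmean <- masked
  for (j in seq_len(n_samp)) {
    colmean[is.na(colmean[, j]), j] <- mean(masked[, j], na.rm = TRUE)
  }
  rmse_col <- sqrt(mean((colmean[mask] - truth)^2))
  expect_lt(rmse_knn, rmse_col)
})

test_that("promoter consolidation takes per-gene medians over promoter probes", {
  ann <- probe_annotation(data.frame(
    probe_id = c("c1", "c2", "c3", "c4", "c5", "c6"),
    gene = c("G1", "G1", "G1", "G2", "G2", "G3"),
    region = c("TSS200", "TSS1500", "1stExon", "5'UTR", "TSS200", "Body")))
  beta <- matrix(c(0.2, 0.4, 0.9,  0.2, 0.4,  0.7,
                   0.1, 0.3, 0.5,  0.6, 0.8,  0.1), 6, 2,
                 dimnames = list(paste0("c", 1:6), c("s1", "s2")))
  cons <- consolidate_promoter(beta, ann)
  expect_equal(unname(cons$values["G1", "s1"]), 0.4)   # odd-count median
  expect_equal(unname(cons$values["G2", "s1"]), 0.3)   # even-count median
  expect_false("G3" %in% rownames(cons$values))        # body-only gene absent
})

test_that("hampel ternary matches hand computation, incl. MAD = 0", {
  v <- matrix(c(0.2, 0.4, 0.5, 0.6, 0.95), 1,
              dimnames = list("G1", paste0("s", 1:5)))
  mt <- hampel_ternary(v)
  # MED 0.5, MAD 0.1, bounds (0.2, 0.8): only 0.95 flagged, 0.2 is NOT
  expect_equal(unname(unclass(mt)[1, ]), c(0L, 0L, 0L, 0L, 1L))

  v2 <- matrix(c(0.1, 0.1, 0.1, 0.1, 0.9), 1,
               dimnames = list("G1", paste0("s", 1:5)))
  mt2 <- hampel_ternary(v2)
  expect_equal(unname(unclass(mt2)[1, ]), c(0L, 0L, 0L, 0L, 1L))
  expect_equal(unname(attr(mt2, "mad")["G1"]), 0)

  v3 <- matrix(0.4, 2, 5, dimnames = list(c("G1", "G2"), paste0("s", 1:5)))
  expect_true(all(unclass(hampel_ternary(v3)) == 0L))
})

test_that("consolidate + hampel equals a naive per-gene reference on a toy", {
  set.seed(10)
  genes <- sprintf("G%02d", 1:10)
  ann <- probe_annotation(data.frame(
    probe_id = sprintf("c%02d", 1:30),
    gene = rep(genes, each = 3),
    region = rep(c("TSS200", "5'UTR", "Body"), 10)))
  beta <- matrix(rbeta(30 * 8, 5, 5), 30, 8,
                 dimnames = list(sprintf("c%02d", 1:30), sprintf("s%d", 1:8)))
  mt <- hampel_ternary(consolidate_promoter(beta, ann))
  # naive: per gene, promoter medians then literal Hampel rule
  for (g in genes) {
    probes <- ann$probe_id[ann$gene == g & ann$promoter]
    v <- apply(beta[probes, , drop = FALSE], 2, median)
    med <- median(v); mad_ <- median(abs(v - med))
    naive <- ifelse(v < med - 3 * mad_ - 1e-10, -1L,
                    ifelse(v > med + 3 * mad_ + 1e-10, 1L, 0L))
    expect_equal(unname(unclass(mt)[g, ]), unname(naive))
  }
})

test_that("flags are invariant to sample column order", {
  set.seed(3)
  v <- matrix(rbeta(5 * 12, 2, 2), 5, 12,
              dimnames = list(sprintf("G%d", 1:5), sprintf("s%02d", 1:12)))
  mt <- hampel_ternary(v)
  perm <- sample(12)
  mt_p <- hampel_ternary(v[, perm])
  expect_equal(unclass(mt_p)[, colnames(v)][, ], unclass(mt)[, ],
               ignore_attr = TRUE)
})

test_that("planted outliers flow through the full methylation profile", {
  outliers <- tibble::tibble(gene = c("g0001", "g0002"),
                             sample_id = c("T001", "T002"),
                             direction = c("hyper", "hypo"))
  cfg <- simulation_config(n_genes = 20, n_reference = 5, n_case = 10,
                           planted_outliers = outliers,
                           missing_fraction = 0.02, seed = 21)
  ann <- simulate_probe_annotation(cfg)
  beta <- simulate_methylation(cfg, ann)
  expect_true(all(beta >= 0 & beta <= 1, na.rm = TRUE))
  mt <- suppressMessages(build_methylation_profile(beta, ann))
  expect_equal(unname(unclass(mt)["g0001", "T001"]), 1L)
  expect_equal(unname(unclass(mt)["g0002", "T002"]), -1L)
})

test_that("hampel false-positive rate under pure Beta noise matches a resampling oracle", {
  # package path: flagged fraction over many genes of i.i.d. Beta noise
  withr::with_seed(71, {
    n_genes <- 400; n_samp <- 30
    v <- matrix(rbeta(n_genes * n_samp, 10, 10), n_genes, n_samp,
                dimnames = list(sprintf("G%03d", 1:n_genes),
                                sprintf("s%02d", 1:n_samp)))
    mt <- hampel_ternary(v)
    fp_pkg <- mean(unclass(mt) != 0L)

    # oracle: literal per-row rule applied to fresh draws of the same Beta
    flags <- replicate(400, {
      x <- rbeta(n_samp, 10, 10)
      med <- median(x); mad_ <- median(abs(x - med))
      mean(x < med - 3 * mad_ | x > med + 3 * mad_)
    })
    fp_oracle <- mean(flags)
    se <- sd(flags) / sqrt(length(flags)) + 
      sd(rowMeans(unclass(mt) != 0L)) / sqrt(n_genes)
    expect_lt(abs(fp_pkg - fp_oracle), 4 * se)
  })
})
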