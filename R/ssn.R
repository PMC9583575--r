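# Sample-specific network construction.
#
# The reference network weights every background edge with the Pearson
# correlation pcc_n over the n reference samples. Adding one case sample d
# and recomputing gives pcc_{n+1}; under the null (d drawn from the
# reference population) the difference
#     delta = pcc_{n+1} - pcc_n
# is approximately normal with mean 0 and variance (1 - pcc_n^2)/(n - 1)
# for large n, so each edge gets a two-tailed Z-test. Edges with p < alpha
# (default 0.01) form the sample-specific network (SSN) of d.
#
# Correlations are updated per edge from sufficient statistics (per-gene
# sums, sums of squares, per-edge cross-products), so a whole SSN costs
# O(|edges|) after an O(|edges| * n) precomputation shared by all samples.
#
# Null scale of delta: the influence function of the Pearson correlation
# at a standardized bivariate normal point (x, y) is
# IF = xy - rho (x^2 + y^2) / 2, with E[IF^2] = (1 - rho^2)^2, so adding
# one null sample shifts the correlation by IF/(n + 1) and
# sd(delta) = (1 - rho^2)/(n - 1) up to O(1/n^2). The literature often
# calls this quantity the "variance" of delta; it is the standard
# deviation, and the Z statistic divides by it directly — dividing by its
# square root would misscale the test by a factor sqrt(n) and drive the
# type-I error to zero.

#' Pearson correlation with degenerate-input signalling
#'
#' Standard product-moment correlation, with the degenerate cases the
#' network pipeline must handle made explicit: a constant vector has no
#' defined correlation and yields `NA` with a warning (the edge is then
#' excluded upstream rather than assigned a value).
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return Correlation in `[-1, 1]`, or `NA` for a constant input.
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  if (length(x) < 3) abort("need at least 3 observations.")
  if (anyNA(x) || anyNA(y)) abort("missing values are not allowed.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("constant vector: correlation undefined, returning NA.")
    return(NA_real_)
  }
  as.numeric(cor(x, y))
}

#' Differential-correlation edge statistic
#'
#' For an edge with reference correlation `pcc_n` (over `n` reference
#' samples) and perturbed correlation `pcc_n1` (over the same samples plus
#' one case sample), computes `delta = pcc_n1 - pcc_n`, the Z statistic
#' `delta / ((1 - pcc_n^2) / (n - 1))` and the two-tailed normal p-value
#' `2 * (1 - pnorm(|z|))`. Vectorized over edges.
#'
#' Under the null (the added sample drawn from the reference population),
#' `delta` is asymptotically normal with mean 0 and standard deviation
#' `(1 - pcc_n^2) / (n - 1)` — the influence of one added observation on a
#' Pearson correlation is O(1/n), and the influence-function second moment
#' at the bivariate normal is `(1 - rho^2)^2`. The statistic therefore
#' standardizes by that scale directly.
#'
#' @param pcc_n,pcc_n1 Numeric vectors of reference and perturbed
#'   correlations; `|pcc_n|` must be < 1 (degenerate-scale edges are
#'   excluded before testing).
#' @param n Reference sample count (>= 3).
#' @return Tibble with columns `delta`, `z`, `p`.
#' @examples
#' edge_statistic(0, 0.02, 101)       # null sd = 0.01, z = 2, p ~ 0.0455
#' edge_statistic(0.8, 0.8072, 101)   # null sd = 0.0036, z = 2
#' @export
edge_statistic <- function(pcc_n, pcc_n1, n) {
  if (n < 3) abort("need n >= 3 reference samples.")
  if (any(abs(pcc_n) >= 1)) {
    abort("|pcc_n| = 1: null scale is degenerate; exclude such edges before testing.")
  }
  delta <- pcc_n1 - pcc_n
  z <- delta * (n - 1) / (1 - pcc_n^2)
  tibble(delta = delta, z = z, p = 2 * pnorm(-abs(z)))
}

# Per-edge sufficient statistics over the reference samples. Returns NULL
# components for edges; used by both reference-network and SSN steps.
edge_suffstats <- function(values, edges) {
  n <- ncol(values)
  s1 <- rowSums(values)
  s2 <- rowSums(values^2)
  ia <- match(edges$gene_a, rownames(values))
  ib <- match(edges$gene_b, rownames(values))
  sab <- rowSums(values[ia, , drop = FALSE] * values[ib, , drop = FALSE])
  list(n = n, s1 = s1, s2 = s2, ia = ia, ib = ib, sab = sab)
}

pcc_from_suffstats <- function(st) {
  num <- st$n * st$sab - st$s1[st$ia] * st$s1[st$ib]
  va <- st$n * st$s2[st$ia] - st$s1[st$ia]^2
  vb <- st$n * st$s2[st$ib] - st$s1[st$ib]^2
  den <- sqrt(pmax(va, 0) * pmax(vb, 0))
  out <- ifelse(den > 0, num / den, NA_real_)
  pmin(1, pmax(-1, out))
}

#' Build the reference co-expression network
#'
#' Weights every background edge whose endpoints are present in the
#' expression data with the Pearson correlation over the reference samples.
#' Edges with a missing endpoint, a constant reference gene, or
#' `|pcc_n| = 1` (degenerate null variance) are excluded and counted.
#'
#' @param expr An [expression_set()] with at least 3 reference samples.
#' @param bg A [background_network()].
#' @return Tibble of class `reference_network` with columns `gene_a`,
#'   `gene_b`, `pcc_n`; attributes `n_ref`, `n_dropped_missing_gene`,
#'   `n_dropped_degenerate`, plus cached sufficient statistics used by
#'   [build_ssn()].
#' @export
build_reference_network <- function(expr, bg) {
  stopifnot(inherits(expr, "expression_set"))
  n_ref <- length(expr$reference_ids)
  if (n_ref < 3) abort("need at least 3 reference samples.")
  genes <- rownames(expr$values)
  keep <- bg$gene_a %in% genes & bg$gene_b %in% genes
  n_missing <- sum(!keep)
  edges <- as.data.frame(bg)[keep, c("gene_a", "gene_b")]
  if (nrow(edges) == 0) {
    abort("no background edge has both endpoints in the expression data.")
  }
  if (n_missing > 0) {
    inform(sprintf("build_reference_network: dropped %d edge(s) with endpoint(s) absent from expression data", n_missing))
  }
  refvals <- expr$values[, expr$reference_ids, drop = FALSE]
  st <- edge_suffstats(refvals, edges)
  pcc <- pcc_from_suffstats(st)
  degenerate <- is.na(pcc) | abs(pcc) >= 1
  if (any(degenerate)) {
    inform(sprintf("build_reference_network: excluded %d edge(s) with constant genes or |pcc_n| = 1", sum(degenerate)))
  }
  out <- as_tibble(edges[!degenerate, , drop = FALSE])
  out$pcc_n <- pcc[!degenerate]
  out <- sort_edges(out)
  st_kept <- edge_suffstats(refvals, out)
  structure(out,
            class = c("reference_network", class(as_tibble(out))),
            n_ref = n_ref,
            n_dropped_missing_gene = n_missing,
            n_dropped_degenerate = sum(degenerate),
            suffstats = st_kept,
            reference_ids = expr$reference_ids)
}

#' Build the sample-specific network of one case sample
#'
#' For every reference-network edge, recomputes the correlation over the
#' reference samples plus the given sample, forms the differential-
#' correlation Z statistic ([edge_statistic()]) and retains edges with
#' `p < alpha`. No multiple-testing correction is applied: the method
#' retains raw `p < 0.01` by default.
#'
#' @param expr The [expression_set()] used to build `ref_net`.
#' @param ref_net A [build_reference_network()] result.
#' @param sample_id A sample present in `expr` (normally a case sample; a
#'   reference sample is allowed for comparison analyses, see
#'   `leave_one_out`).
#' @param alpha Edge-retention significance level in `[0, 1)`; default 0.01.
#' @param keep_all If `TRUE`, return statistics for every testable edge
#'   with a logical `retained` column instead of only the retained edges.
#' @param leave_one_out If `TRUE` and `sample_id` is itself a reference
#'   sample, the reference statistics are recomputed without it before the
#'   sample is added back as the perturbing sample.
#' @return Tibble of class `ssn` with columns `gene_a`, `gene_b`, `pcc_n`,
#'   `pcc_n1`, `delta`, `z`, `p` (and `retained` when `keep_all = TRUE`);
#'   attributes `sample_id`, `alpha`, `n_ref`.
#' @export
build_ssn <- function(expr, ref_net, sample_id, alpha = 0.01,
                      keep_all = FALSE, leave_one_out = FALSE) {
  stopifnot(inherits(ref_net, "reference_network"))
  if (length(sample_id) != 1 || !sample_id %in% colnames(expr$values)) {
    abort(sprintf("sample '%s' not found in the expression data.",
                  as.character(sample_id)[1]))
  }
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1) {
    abort("alpha must lie in [0, 1).")
  }
  edges <- as.data.frame(ref_net)[, c("gene_a", "gene_b")]
  ref_ids <- attr(ref_net, "reference_ids")
  if (leave_one_out && sample_id %in% ref_ids) {
    refvals <- expr$values[, setdiff(ref_ids, sample_id), drop = FALSE]
    if (ncol(refvals) < 3) abort("fewer than 3 reference samples after leave-one-out.")
    st <- edge_suffstats(refvals, edges)
  } else {
    st <- attr(ref_net, "suffstats")
  }
  n <- st$n
  pcc_n <- pcc_from_suffstats(st)
  x <- expr$values[, sample_id]
  xa <- x[st$ia]
  xb <- x[st$ib]
  # update sufficient statistics with the one added sample
  num <- (n + 1) * (st$sab + xa * xb) -
    (st$s1[st$ia] + xa) * (st$s1[st$ib] + xb)
  va <- (n + 1) * (st$s2[st$ia] + xa^2) - (st$s1[st$ia] + xa)^2
  vb <- (n + 1) * (st$s2[st$ib] + xb^2) - (st$s1[st$ib] + xb)^2
  den <- sqrt(pmax(va, 0) * pmax(vb, 0))
  pcc_n1 <- pmin(1, pmax(-1, ifelse(den > 0, num / den, NA_real_)))
  ok <- !is.na(pcc_n1) & abs(pcc_n) < 1
  n_untestable <- sum(!ok)
  if (n_untestable > 0) {
    inform(sprintf("build_ssn: %d edge(s) untestable for sample %s (degenerate variance)",
                   n_untestable, sample_id))
  }
  stats <- edge_statistic(pcc_n[ok], pcc_n1[ok], n)
  out <- as_tibble(edges[ok, , drop = FALSE])
  out$pcc_n <- pcc_n[ok]
  out$pcc_n1 <- pcc_n1[ok]
  out <- dplyr::bind_cols(out, stats)
  out$retained <- out$p < alpha
  if (!keep_all) {
    out <- out[out$retained, , drop = FALSE]
    out$retained <- NULL
  }
  out <- sort_edges(out)
  structure(as_tibble(out),
            class = c("ssn", class(tibble())),
            sample_id = sample_id, alpha = alpha, n_ref = n,
            n_untestable = n_untestable)
}

#' @export
print.ssn <- function(x, ...) {
  cat(sprintf("<ssn> sample %s: %d edge(s), alpha = %g, n_ref = %d\n",
              attr(x, "sample_id"), nrow(x), attr(x, "alpha"), attr(x, "n_ref")))
  NextMethod()
}
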