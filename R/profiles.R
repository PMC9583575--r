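# Per-sample omics profiles: a binary somatic-mutation matrix and a ternary
# methylation-aberration matrix (Hampel filter on consolidated promoter
# beta values).

#' Build the binary somatic-mutation matrix
#'
#' Collapses a gene-by-sample table of nonsynonymous-mutation indicators or
#' counts to the binary profile M: `M[i, j] = 1` if gene i carries at least
#' one nonsynonymous mutation in sample j, else 0. Genes requested but
#' absent from the table get all-zero rows.
#'
#' @param calls Data frame (first column gene symbols, remaining columns
#'   samples) or a numeric matrix with gene rownames, holding non-negative
#'   indicator/count values.
#' @param case_samples Character vector of sample columns to keep; defaults
#'   to every sample column present.
#' @param genes Optional character vector fixing the gene universe of the
#'   output (missing genes become zero rows).
#' @return Integer 0/1 matrix of class `mutation_matrix`, genes in rows.
#' @export
build_mutation_matrix <- function(calls, case_samples = NULL, genes = NULL) {
  m <- as_gene_matrix(calls)
  if (is.null(case_samples)) case_samples <- colnames(m)
  missing_s <- setdiff(case_samples, colnames(m))
  if (length(missing_s) > 0) {
    abort(sprintf("sample(s) absent from mutation table: %s",
                  paste(head(missing_s, 5), collapse = ", ")))
  }
  m <- m[, case_samples, drop = FALSE]
  if (anyNA(m)) abort("mutation table contains missing values.")
  if (any(m < 0)) abort("mutation counts must be non-negative.")
  out <- matrix(0L, nrow = if (is.null(genes)) nrow(m) else length(genes),
                ncol = ncol(m),
                dimnames = list(if (is.null(genes)) rownames(m) else genes,
                                colnames(m)))
  common <- intersect(rownames(out), rownames(m))
  out[common, ] <- as.integer(m[common, , drop = FALSE] > 0)
  structure(out, class = c("mutation_matrix", "matrix", "array"))
}

as_gene_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("matrix input needs gene rownames.")
    return(x)
  }
  x <- as.data.frame(x)
  genes <- as.character(x[[1]])
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicated gene symbol(s): %s",
                  paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Remove probes with too many missing beta values
#'
#' Probes whose missing fraction across samples is strictly greater than
#' `max_na_fraction` are removed (the retention boundary is inclusive: a
#' probe missing in exactly 10% of samples is kept under the default).
#'
#' @param beta Numeric matrix, CpG probes in rows, samples in columns,
#'   values in `[0, 1]` or `NA`. A data frame with a probe-id first column
#'   is also accepted.
#' @param max_na_fraction Maximum tolerated missing fraction (default 0.10).
#' @return The filtered beta matrix; attribute `n_removed` counts dropped
#'   probes.
#' @export
filter_probes <- function(beta, max_na_fraction = 0.10) {
  beta <- as_beta_matrix(beta)
  na_frac <- rowMeans(is.na(beta))
  drop <- na_frac > max_na_fraction
  if (any(drop)) {
    inform(sprintf("filter_probes: removed %d probe(s) with > %g%% missing values",
                   sum(drop), 100 * max_na_fraction))
  }
  out <- beta[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}

as_beta_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else {
    x <- as.data.frame(x)
    m <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(x[[1]])
  }
  rng <- range(m, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) abort("beta values must lie in [0, 1].")
  m
}

#' k-nearest-neighbour imputation of missing beta values
#'
#' Each missing entry is replaced by the average of the `k` nearest probe
#' rows' values in that sample, nearness being Euclidean distance over the
#' samples co-observed between the two rows (root mean squared difference,
#' so rows with different numbers of co-observed samples are comparable).
#' Only rows observed in the target sample are candidate neighbours; when
#' fewer than `k` such rows exist (or no co-observed sample supports a
#' distance), the probe's own row mean is used and a note is emitted.
#' Imputed values are clipped to `[0, 1]`.
#'
#' @param beta Beta matrix (probes x samples) after [filter_probes()].
#' @param k Number of neighbours (default 10).
#' @return Complete beta matrix (no `NA`s).
#' @export
knn_impute <- function(beta, k = 10) {
  beta <- as_beta_matrix(beta)
  if (!anyNA(beta)) return(beta)
  obs <- !is.na(beta)
  filled <- beta
  n_fallback <- 0L
  rows_with_na <- which(rowSums(!obs) > 0)
  for (i in rows_with_na) {
    miss_cols <- which(!obs[i, ])
    # distance of row i to every other row over co-observed samples
    for (j in miss_cols) {
      cand <- which(obs[, j])
      cand <- setdiff(cand, i)
      d <- rep(NA_real_, length(cand))
      xi <- beta[i, ]
      oi <- obs[i, ]
      for (idx in seq_along(cand)) {
        r <- cand[idx]
        co <- oi & obs[r, ]
        if (any(co)) d[idx] <- sqrt(mean((xi[co] - beta[r, co])^2))
      }
      usable <- cand[!is.na(d)]
      d <- d[!is.na(d)]
      if (length(usable) >= k) {
        nb <- usable[order(d)][seq_len(k)]
        filled[i, j] <- mean(beta[nb, j])
      } else {
        filled[i, j] <- mean(beta[i, oi])
        n_fallback <- n_fallback + 1L
      }
    }
  }
  if (n_fallback > 0) {
    inform(sprintf("knn_impute: %d entr%s imputed by row mean (fewer than k=%d usable neighbours)",
                   n_fallback, if (n_fallback == 1) "y" else "ies", k))
  }
  # matrix first: pmax/pmin take attributes (dim, dimnames) from the
  # longest argument, a scalar first would strip them
  pmin(pmax(filled, 0), 1)
}

#' Consolidate promoter probes to one beta value per gene
#'
#' For each gene and sample, takes the median beta over the gene's CpG
#' probes annotated to a promoter region (TSS1500, TSS200, 5'UTR or
#' 1stExon). Genes without any promoter probe are absent from the output.
#' Multi-mapped probes contribute to every gene they annotate.
#'
#' @param beta Complete beta matrix (probes x samples).
#' @param annotation A [probe_annotation()] tibble.
#' @return Object of class `consolidated_methylation`: list with `values`
#'   (gene x sample matrix of medians), later augmented with per-gene
#'   `med`/`mad` by [hampel_ternary()].
#' @export
consolidate_promoter <- function(beta, annotation) {
  beta <- as_beta_matrix(beta)
  ann <- annotation %>%
    filter(.data$promoter, .data$probe_id %in% rownames(beta))
  if (nrow(ann) == 0) abort("no promoter probe in the annotation matches the beta matrix.")
  genes <- sort(unique(ann$gene))
  probes_by_gene <- split(ann$probe_id, ann$gene)
  vals <- t(vapply(genes, function(g) {
    sub <- beta[probes_by_gene[[g]], , drop = FALSE]
    apply(sub, 2L, median)
  }, numeric(ncol(beta))))
  rownames(vals) <- genes
  colnames(vals) <- colnames(beta)
  structure(list(values = vals), class = "consolidated_methylation")
}

#' @export
print.consolidated_methylation <- function(x, ...) {
  cat(sprintf("<consolidated_methylation> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Hampel-filter ternary methylation-aberration matrix
#'
#' Per gene, computes the median (MED) and the unscaled median absolute
#' deviation (MAD, no consistency constant) of the consolidated beta value
#' across samples, and flags each sample's value v as
#' hypomethylated (`-1`) when `v < MED - k * MAD`, hypermethylated (`+1`)
#' when `v > MED + k * MAD`, else `0`. Inequalities are strict; with
#' `MAD = 0` any deviation from the median is therefore flagged, and the
#' per-sample flagged fraction is reported so such degenerate genes are
#' visible. Comparisons carry a `1e-10` numerical tolerance so a value
#' sitting exactly on a bound is never flagged by rounding error.
#'
#' @param consolidated A [consolidate_promoter()] result (or a gene x
#'   sample numeric matrix).
#' @param k Aberration multiplier (default 3).
#' @return Integer matrix of class `methylation_ternary` with values in
#'   `{-1, 0, 1}`; attributes `med`, `mad` (per-gene vectors) and
#'   `flagged_fraction` (per-sample).
#' @examples
#' m <- matrix(c(0.2, 0.4, 0.5, 0.6, 0.95), 1,
#'             dimnames = list("G1", paste0("s", 1:5)))
#' hampel_ternary(m)  # only 0.95 flagged (+1): bounds are (0.2, 0.8), strict
#' @export
hampel_ternary <- function(consolidated, k = 3) {
  vals <- if (inherits(consolidated, "consolidated_methylation")) {
    consolidated$values
  } else {
    consolidated
  }
  if (anyNA(vals)) abort("consolidated matrix must be complete (impute first).")
  med <- apply(vals, 1L, median)
  mad_ <- apply(abs(vals - med), 1L, median)
  lower <- med - k * mad_
  upper <- med + k * mad_
  # strict inequalities with a small numerical tolerance, so a value that
  # sits exactly on a Hampel bound is never flagged by rounding error
  tol <- 1e-10
  mt <- matrix(0L, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  mt[vals < lower - tol] <- -1L
  mt[vals > upper + tol] <- 1L
  frac <- colMeans(mt != 0)
  structure(mt, class = c("methylation_ternary", "matrix", "array"),
            med = med, mad = mad_, k = k, flagged_fraction = frac)
}

#' Full methylation-profile pipeline
#'
#' [filter_probes()] then [knn_impute()] then [consolidate_promoter()] then
#' [hampel_ternary()], with the stated defaults.
#'
#' @inheritParams filter_probes
#' @inheritParams knn_impute
#' @inheritParams consolidate_promoter
#' @inheritParams hampel_ternary
#' @return A `methylation_ternary` matrix; the consolidated matrix is
#'   attached as attribute `consolidated`.
#' @export
build_methylation_profile <- function(beta, annotation, max_na_fraction = 0.10,
                                      k = 10, hampel_k = 3) {
  beta <- filter_probes(beta, max_na_fraction)
  beta <- knn_impute(beta, k = k)
  cons <- consolidate_promoter(beta, annotation)
  mt <- hampel_ternary(cons, k = hampel_k)
  attr(mt, "consolidated") <- cons
  mt
}

#' Seed genes of one sample from an omics profile
#'
#' @param profile A `mutation_matrix` (seeds are genes with `M = 1`) or a
#'   `methylation_ternary` matrix (seeds are genes with `MT != 0`).
#' @param sample_id A column of the profile.
#' @return Character vector of seed genes (sorted).
#' @export
profile_seeds <- function(profile, sample_id) {
  if (!sample_id %in% colnames(profile)) {
    abort(sprintf("sample '%s' not found in the profile.", sample_id))
  }
  v <- profile[, sample_id]
  sort(rownames(profile)[v != 0])
}
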