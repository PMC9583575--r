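#' Construct an expression set from a data frame
#'
#' Stores a gene-by-sample expression matrix together with the partition of
#' samples into a reference group (e.g. tumor-adjacent normal tissue) and a
#' case group (tumors). Gene identity is the bare symbol string,
#' case-sensitive; symbols must be pre-harmonized across omics inputs.
#'
#' Rows containing any missing, non-numeric or negative value are dropped
#' with a message; expression is never imputed.
#'
#' @param df Data frame whose first column holds gene symbols and remaining
#'   columns hold non-negative expression values (FPKM-like), one column per
#'   sample.
#' @param reference_ids,case_ids Character vectors of sample identifiers
#'   (column names of `df`) assigning samples to the reference and case
#'   groups. The two sets must be disjoint.
#' @return An object of class `expression_set`: a list with `values`
#'   (numeric matrix, genes in rows), `reference_ids` and `case_ids`.
#' @examples
#' df <- data.frame(gene = c("A", "B"), s1 = c(1, 2), s2 = c(2, 1),
#'                  s3 = c(5, 3), s4 = c(4, 4))
#' es <- expression_set(df, reference_ids = c("s1", "s2"),
#'                      case_ids = c("s3", "s4"))
#' dim(es$values)
#' @export
expression_set <- function(df, reference_ids, case_ids) {
  df <- as.data.frame(df)
  if (ncol(df) < 2) abort("expression table needs a gene column and at least one sample column.")
  genes <- as.character(df[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated gene symbol(s) in expression table: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  reference_ids <- as.character(reference_ids)
  case_ids <- as.character(case_ids)
  both <- intersect(reference_ids, case_ids)
  if (length(both) > 0) {
    abort(sprintf("sample(s) listed as both reference and case: %s",
                  paste(both, collapse = ", ")))
  }
  wanted <- c(reference_ids, case_ids)
  missing_cols <- setdiff(wanted, colnames(df)[-1])
  if (length(missing_cols) > 0) {
    abort(sprintf("sample column(s) not found in expression table: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  vals <- suppressWarnings(
    vapply(df[wanted], function(col) as.numeric(as.character(col)),
           numeric(nrow(df)))
  )
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(df))
  rownames(vals) <- genes
  colnames(vals) <- wanted
  bad <- apply(vals, 1L, function(r) anyNA(r) || any(r < 0))
  if (any(bad)) {
    inform(sprintf(
      "expression_set: dropped %d gene row(s) with missing or negative values (%s%s)",
      sum(bad), paste(head(genes[bad], 5), collapse = ", "),
      if (sum(bad) > 5) ", ..." else ""))
    vals <- vals[!bad, , drop = FALSE]
  }
  structure(
    list(values = vals, reference_ids = reference_ids, case_ids = case_ids),
    class = "expression_set"
  )
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set> %d genes x %d samples (%d reference, %d case)\n",
              nrow(x$values), ncol(x$values),
              length(x$reference_ids), length(x$case_ids)))
  invisible(x)
}

#' Read a gene-by-sample expression TSV
#'
#' Expects a tab-delimited file with a header row of sample identifiers and
#' gene symbols in the first column. See [expression_set()] for validation
#' rules.
#'
#' @param path Path to the TSV file.
#' @inheritParams expression_set
#' @return An `expression_set`.
#' @export
read_expression <- function(path, reference_ids, case_ids) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  expression_set(df, reference_ids, case_ids)
}

#' Construct a background interaction network
#'
#' Canonicalizes an undirected edge list over gene symbols (for instance
#' synthetic-lethality pairs): endpoints are stored in lexicographic order,
#' self-loops and duplicate edges are dropped and counted.
#'
#' @param df Data frame whose first two columns are gene symbols; extra
#'   columns are ignored.
#' @return A tibble of class `background_network` with columns `gene_a`,
#'   `gene_b` (canonical order), sorted; attributes `n_self_loops` and
#'   `n_duplicates` record what was dropped.
#' @examples
#' net <- background_network(data.frame(x = c("B", "A"), y = c("A", "C")))
#' nrow(net)
#' @export
background_network <- function(df) {
  df <- as.data.frame(df)
  if (nrow(df) == 0) abort("edge list is empty.")
  edges <- canonicalize_edges(
    data.frame(gene_a = df[[1]], gene_b = df[[2]])
  )
  n_self <- attr(edges, "n_self_loops")
  n_dup <- attr(edges, "n_duplicates")
  if (n_self + n_dup > 0) {
    inform(sprintf("background_network: dropped %d self-loop(s) and %d duplicate edge(s)",
                   n_self, n_dup))
  }
  out <- sort_edges(edges)
  out <- as_tibble(out)
  attr(out, "n_self_loops") <- n_self
  attr(out, "n_duplicates") <- n_dup
  class(out) <- c("background_network", class(out))
  out
}

#' Read a two-column edge-list TSV as a background network
#'
#' @param path Path to a tab-delimited file whose first two columns are gene
#'   symbols. A header line is detected and skipped when its first two
#'   fields are `gene_a`/`gene_b` (any case).
#' @return A `background_network` tibble; see [background_network()].
#' @export
read_edge_list <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 0) abort("edge list file is empty.")
  fields <- tolower(strsplit(first, "\t", fixed = TRUE)[[1]])
  has_header <- length(fields) >= 2 &&
    identical(fields[1:2], c("gene_a", "gene_b"))
  df <- readr::read_tsv(path, col_names = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        skip = if (has_header) 1 else 0, progress = FALSE)
  if (nrow(df) == 0) abort("edge list file is empty.")
  background_network(df)
}

#' Nodes of an edge table
#'
#' @param edges Data frame with `gene_a`, `gene_b` columns.
#' @return Sorted character vector of distinct endpoint genes.
#' @export
network_nodes <- function(edges) {
  sort(unique(c(edges$gene_a, edges$gene_b)))
}

# ---- driver-module serialization -------------------------------------------

#' Write a driver module to disk
#'
#' The on-disk format is a small header block of `# key: value` lines
#' (sample id, driver type, seed genes, parameters) followed by a
#' tab-delimited canonical edge list. Serialization is byte-stable:
#' `write_module()` then [read_module()] round-trips exactly.
#'
#' @param module A `driver_module` (see [two_order_module()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_module <- function(module, path) {
  stopifnot(inherits(module, "driver_module"))
  meta <- module_meta(module)
  hdr <- sprintf("# %s: %s", names(meta), unlist(meta))
  edges <- sort_edges(as.data.frame(module)[, c("gene_a", "gene_b")])
  lines <- c(hdr, "gene_a\tgene_b",
             if (nrow(edges) > 0) paste(edges$gene_a, edges$gene_b, sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

module_meta <- function(module) {
  list(
    sample_id = attr(module, "sample_id"),
    driver_type = attr(module, "driver_type"),
    seeds = paste(attr(module, "seeds"), collapse = ","),
    hub_fraction = format(attr(module, "hub_fraction") %||% NA, digits = 15)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a driver module written by [write_module()]
#'
#' @param path Path to a module file.
#' @return A `driver_module` tibble.
#' @export
read_module <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  if (length(hdr) == 0) abort("malformed module file: missing header block.")
  kv <- regmatches(hdr, regexec("^# ([^:]+): ?(.*)$", hdr))
  if (any(vapply(kv, length, 1L) != 3)) {
    abort("malformed module file: header lines must be '# key: value'.")
  }
  meta <- as.list(setNames(vapply(kv, `[`, "", 3), vapply(kv, `[`, "", 2)))
  for (key in c("sample_id", "driver_type")) {
    if (!key %in% names(meta)) {
      abort(sprintf("malformed module file: missing header key '%s'.", key))
    }
  }
  body <- lines[!startsWith(lines, "# ")]
  if (length(body) == 0 || body[1] != "gene_a\tgene_b") {
    abort("malformed module file: missing 'gene_a\\tgene_b' column line.")
  }
  body <- body[-1]
  body <- body[nzchar(body)]
  if (length(body) > 0) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    edges <- tibble(gene_a = vapply(parts, `[`, "", 1),
                    gene_b = vapply(parts, `[`, "", 2))
  } else {
    edges <- tibble(gene_a = character(), gene_b = character())
  }
  seeds <- meta[["seeds"]] %||% ""
  seeds <- if (is.na(seeds) || !nzchar(seeds)) character() else
    strsplit(seeds, ",", fixed = TRUE)[[1]]
  hf <- suppressWarnings(as.numeric(meta[["hub_fraction"]] %||% NA_character_))
  new_driver_module(edges,
                    sample_id = meta[["sample_id"]],
                    driver_type = meta[["driver_type"]],
                    seeds = seeds,
                    hub_fraction = if (length(hf) == 1 && !is.na(hf)) hf else NULL)
}

#' Read a probe annotation table
#'
#' Three-column TSV: probe id, gene symbol, genomic region label. Multi-gene
#' probes may list several symbols separated by `;`; they are expanded to
#' one row per gene and flagged.
#'
#' @param path Path to the annotation TSV (header: probe_id, gene, region).
#' @return A tibble with columns `probe_id`, `gene`, `region`, `promoter`
#'   (logical: region is one of TSS1500, TSS200, 5'UTR, 1stExon) and
#'   `multi_mapped`.
#' @export
read_probe_annotation <- function(path) {
  df <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  names(df)[1:3] <- c("probe_id", "gene", "region")
  probe_annotation(df)
}

#' @rdname read_probe_annotation
#' @param df Data frame with columns `probe_id`, `gene`, `region`.
#' @export
probe_annotation <- function(df) {
  df <- as_tibble(as.data.frame(df)[, c("probe_id", "gene", "region")])
  if (anyDuplicated(df$probe_id)) {
    abort("probe_id values must be unique in the annotation table.")
  }
  multi <- grepl(";", df$gene, fixed = TRUE)
  df <- df %>%
    mutate(multi_mapped = multi) %>%
    tidyr::separate_rows("gene", sep = ";") %>%
    filter(nzchar(.data$gene))
  df$promoter <- vapply(strsplit(df$region, ";", fixed = TRUE), function(r) {
    any(r %in% promoter_regions())
  }, logical(1))
  df
}

#' Promoter region vocabulary
#'
#' The HM450 annotation regions treated as promoter: 1500 bp and 200 bp
#' upstream of the transcription start site, the 5' UTR and the first exon.
#' @return Character vector of region labels.
#' @export
promoter_regions <- function() c("TSS1500", "TSS200", "5'UTR", "1stExon")

#' Read a sample-to-subtype label table
#'
#' @param path Two-column TSV (header `sample_id`, `subtype`).
#' @param case_ids Optional character vector; when given, every labeled
#'   sample must be one of these case samples.
#' @return Tibble with columns `sample_id`, `subtype`.
#' @export
read_subtype_labels <- function(path, case_ids = NULL) {
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  names(df)[1:2] <- c("sample_id", "subtype")
  subtype_labels(df, case_ids)
}

#' @rdname read_subtype_labels
#' @param df Data frame with columns `sample_id`, `subtype`.
#' @export
subtype_labels <- function(df, case_ids = NULL) {
  df <- as_tibble(as.data.frame(df)[, c("sample_id", "subtype")])
  if (any(!nzchar(df$subtype) | is.na(df$subtype))) {
    abort("subtype names must be non-empty.")
  }
  if (!is.null(case_ids)) {
    extra <- setdiff(df$sample_id, case_ids)
    if (length(extra) > 0) {
      abort(sprintf("labeled sample(s) not in the case set: %s",
                    paste(head(extra, 5), collapse = ", ")))
    }
  }
  df
}

#' Export an edge table as GraphML
#'
#' Thin wrapper around [igraph::write_graph()] for visualization tools.
#'
#' @param edges Data frame with `gene_a`, `gene_b` columns (e.g. a
#'   `driver_module` or SSN edge table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(edges, path) {
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges)[, c("gene_a", "gene_b")], directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
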