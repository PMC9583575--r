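# Shared internal helpers: edge canonicalization and light validation.

# Canonicalize an edge table: endpoints as character, lexicographic order
# within each row, self-loops and duplicates removed. Returns the edge
# tibble plus counts of what was dropped (as attributes "n_self_loops",
# "n_duplicates").
canonicalize_edges <- function(df, a = "gene_a", b = "gene_b") {
  ga <- as.character(df[[a]])
  gb <- as.character(df[[b]])
  lo <- pmin(ga, gb)
  hi <- pmax(ga, gb)
  self <- lo == hi
  lo <- lo[!self]
  hi <- hi[!self]
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  out <- tibble(gene_a = lo[!dup], gene_b = hi[!dup])
  attr(out, "n_self_loops") <- sum(self)
  attr(out, "n_duplicates") <- sum(dup)
  out
}

edge_key <- function(gene_a, gene_b) {
  paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = "\r")
}

# Consistent sort order for deterministic, byte-stable edge output.
sort_edges <- function(df) {
  df[order(df$gene_a, df$gene_b), , drop = FALSE]
}

assert_scalar_fraction <- function(x, name, open_left = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  lo_ok <- if (open_left) x > 0 else x >= 0
  if (!lo_ok || x > 1) {
    abort(sprintf("`%s` must lie in %s0, 1].", name,
                  if (open_left) "(" else "["))
  }
  invisible(x)
}
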