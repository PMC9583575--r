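# broom-style tidiers for the package's result objects.

#' @rdname ssdriver_tidiers
#' @param x An `ssn`.
#' @param ... Unused.
#' @export
tidy.ssn <- function(x, ...) {
  out <- as_tibble(as.data.frame(x))
  out$sample_id <- attr(x, "sample_id")
  dplyr::relocate(out, "sample_id")
}

#' Tidiers for sample-specific network results
#'
#' `tidy()` returns the per-edge (or per-gene) records as a plain tibble;
#' `glance()` returns a one-row summary.
#'
#' @name ssdriver_tidiers
#' @param x A result object (`ssn`, `driver_module`, `cohort_module`,
#'   `hub_set`).
#' @param ... Unused.
#' @export
glance.ssn <- function(x, ...) {
  tibble(sample_id = attr(x, "sample_id"),
         n_edges = nrow(x),
         n_genes = length(network_nodes(x)),
         alpha = attr(x, "alpha"),
         n_ref = attr(x, "n_ref"))
}

#' @rdname ssdriver_tidiers
#' @export
tidy.driver_module <- function(x, ...) {
  out <- as_tibble(as.data.frame(x))
  out$sample_id <- attr(x, "sample_id")
  out$driver_type <- attr(x, "driver_type")
  dplyr::relocate(out, "sample_id", "driver_type")
}

#' @rdname ssdriver_tidiers
#' @export
glance.driver_module <- function(x, ...) {
  tibble(sample_id = attr(x, "sample_id"),
         driver_type = attr(x, "driver_type"),
         n_edges = nrow(x),
         n_genes = length(module_genes(x)),
         n_seeds = length(attr(x, "seeds")))
}

#' @rdname ssdriver_tidiers
#' @export
tidy.cohort_module <- function(x, ...) as_tibble(as.data.frame(x))

#' @rdname ssdriver_tidiers
#' @export
glance.cohort_module <- function(x, ...) {
  tibble(driver_type = attr(x, "driver_type"),
         n_edges = nrow(x),
         n_genes = length(network_nodes(x)),
         cutoff = attr(x, "cutoff"),
         n_samples = attr(x, "n_samples"))
}

#' @rdname ssdriver_tidiers
#' @export
glance.hub_set <- function(x, ...) {
  tibble(n_nodes = nrow(x),
         n_hubs = sum(x$is_hub),
         degree_threshold = attr(x, "degree_threshold"),
         hub_fraction = attr(x, "hub_fraction"))
}
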