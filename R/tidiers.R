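#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn build_network Tidy the family-by-class edge table.
#' @param x A `vh_network`.
#' @param ... Unused.
#' @export
tidy.vh_network <- function(x, ...) x$edges

#' @describeIn build_network One-row network summary (numbers of linked
#'   virus families, host classes, network edges, and distinct virus-host
#'   pairs).
#' @export
glance.vh_network <- function(x, ...) {
  tibble(
    n_virus_families = n_distinct(x$edges$virus_family),
    n_host_classes = n_distinct(x$edges$host_class),
    n_edges = nrow(x$edges),
    n_pairs = sum(x$edges$weight)
  )
}

#' @describeIn classify_traits Long per-genome, per-pathway completeness
#'   table.
#' @param x A `trait_profiles` object.
#' @param ... Unused.
#' @export
tidy.trait_profiles <- function(x, ...) attr(x, "completeness")

#' @describeIn classify_traits One-row community summary (genome count and
#'   per-flag counts).
#' @export
glance.trait_profiles <- function(x, ...) {
  s <- trait_summary(x)
  out <- as_tibble(as.list(setNames(s$n, paste0("n_", s$flag))))
  bind_cols(tibble(n_genomes = nrow(x)), out)
}

#' @describeIn summarize_abundance One-row summary of an abundance table
#'   (rank, denominator, taxa count, percentage covered by rows).
#' @param x An `abund_table`.
#' @param ... Unused.
#' @export
glance.abund_table <- function(x, ...) {
  tibble(
    rank = attr(x, "rank"),
    denominator = attr(x, "denominator"),
    n_taxa = nrow(x),
    percent_resolved = sum(x$rel_abundance)
  )
}
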