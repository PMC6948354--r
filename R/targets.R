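#' Standardize raw target protein names to official gene symbols
#'
#' Maps the `raw_name` of every component-target record to an official
#' (human) gene symbol through a mapping table, mirroring the manual
#' UniProt-style standardization step. Unmapped raw names are returned
#' separately, never silently dropped. Mapped `(component_id, symbol)` pairs
#' are deduplicated (two raw names resolving to the same symbol for one
#' component collapse to a single edge).
#'
#' @param edges `data.frame` with columns `component_id`, `raw_name` and
#'   optionally `evidence`.
#' @param mapping `data.frame` with columns `raw_name`, `symbol`. A raw name
#'   mapping to two different symbols is an error.
#' @return A list with `mapped` (deduplicated edges: `component_id`,
#'   `symbol`, `evidence`), `unmapped` (records whose raw name has no mapping
#'   row), `total_raw` (input record count) and `total_mapped` (mapped record
#'   count before pair deduplication, so
#'   `total_mapped + nrow(unmapped) == total_raw`).
#' @export
standardize_symbols <- function(edges, mapping) {
  stopifnot(all(c("component_id", "raw_name") %in% names(edges)))
  stopifnot(all(c("raw_name", "symbol") %in% names(mapping)))
  if (nrow(mapping) == 0) stop("mapping table is empty", call. = FALSE)
  mapping$symbol <- toupper(trimws(mapping$symbol))
  if (any(mapping$symbol == "" | grepl("\\s", mapping$symbol))) {
    stop("mapping table contains an empty or whitespace-containing symbol",
         call. = FALSE)
  }
  conflict <- tapply(mapping$symbol, mapping$raw_name,
                     function(s) length(unique(s)) > 1)
  if (any(conflict)) {
    stop("conflicting mappings for raw name(s): ",
         paste(names(conflict)[conflict], collapse = ", "), call. = FALSE)
  }
  mapping <- mapping[!duplicated(mapping$raw_name), , drop = FALSE]
  if (!"evidence" %in% names(edges)) edges$evidence <- "predicted"
  idx <- match(edges$raw_name, mapping$raw_name)
  hit <- !is.na(idx)
  mapped <- data.frame(component_id = edges$component_id[hit],
                       symbol = mapping$symbol[idx[hit]],
                       evidence = edges$evidence[hit],
                       stringsAsFactors = FALSE)
  total_mapped <- nrow(mapped)
  mapped <- mapped[!duplicated(paste(mapped$component_id, mapped$symbol,
                                     sep = "\r")), , drop = FALSE]
  rownames(mapped) <- NULL
  unmapped <- edges[!hit, c("component_id", "raw_name"), drop = FALSE]
  rownames(unmapped) <- NULL
  list(mapped = mapped, unmapped = unmapped,
       total_raw = nrow(edges), total_mapped = total_mapped)
}

#' Assemble per-herb and union target statistics
#'
#' Attributes each mapped component-target record to every herb its component
#' belongs to (a multi-herb component contributes the same record to each of
#' its herbs) and collects the global symbol union.
#'
#' @param mapped `data.frame` of mapped edges (`component_id`, `symbol`).
#' @param components Component `data.frame`; every edge's component must be
#'   present.
#' @param total_raw Optional raw record count (pre-standardization) carried
#'   into the report; defaults to `nrow(mapped)`.
#' @return An object of class `netpharm_assembly`: a list with `total_raw`,
#'   `total_mapped` (number of mapped records), `per_herb_counts` (named
#'   integer vector) and `union_targets` (sorted unique symbols).
#' @export
assemble_targets <- function(mapped, components, total_raw = NULL) {
  stopifnot(all(c("component_id", "symbol") %in% names(mapped)))
  unknown <- setdiff(mapped$component_id, components$component_id)
  if (length(unknown) > 0) {
    stop("edge references unknown component(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  herbs_of <- component_herbs(components)
  herb_levels <- sort(unique(unlist(herbs_of, use.names = FALSE)))
  counts <- setNames(integer(length(herb_levels)), herb_levels)
  if (nrow(mapped) > 0) {
    rec_herbs <- unlist(herbs_of[mapped$component_id], use.names = FALSE)
    tab <- table(rec_herbs)
    counts[names(tab)] <- as.integer(tab)
  }
  out <- list(total_raw = if (is.null(total_raw)) nrow(mapped) else total_raw,
              total_mapped = nrow(mapped),
              per_herb_counts = counts,
              union_targets = sort(unique(mapped$symbol)))
  stopifnot(out$total_mapped <= out$total_raw)
  class(out) <- "netpharm_assembly"
  out
}

#' @export
print.netpharm_assembly <- function(x, ...) {
  cat("Target assembly:", x$total_mapped, "mapped records of", x$total_raw,
      "raw;", length(x$union_targets), "unique targets\n")
  cat("Per-herb mapped records:\n")
  print(x$per_herb_counts)
  invisible(x)
}

#' Intersect herb targets with disease gene sets
#'
#' Computes the Venn overlap of the herb target union with the two disease
#' gene sets and their combined set, and extracts the putative therapeutic
#' targets as the intersection of the herb union with the combined set — the
#' seed set for the downstream PPI screen. The single-disease intersections
#' are descriptive statistics only.
#'
#' @param union_targets Character vector of unique herb target symbols.
#' @param af,osahs,combined Character vectors of disease gene symbols; the
#'   combined set is the operative disease list.
#' @return An object of class `netpharm_venn`: a list with `herb_af`,
#'   `herb_osahs`, `herb_both` (intersection cardinalities, where `herb_both`
#'   is the triple intersection with both single-disease sets) and
#'   `putative_targets` (sorted symbols).
#' @export
intersect_disease <- function(union_targets, af, osahs, combined) {
  union_targets <- unique(toupper(union_targets))
  af <- unique(toupper(af)); osahs <- unique(toupper(osahs))
  combined <- unique(toupper(combined))
  if (length(combined) == 0) {
    stop("combined disease gene set is empty: nothing to screen", call. = FALSE)
  }
  putative <- sort(intersect(union_targets, combined))
  if (length(putative) == 0) {
    stop("no herb target intersects the combined disease set; ",
         "downstream screening is undefined on an empty seed set",
         call. = FALSE)
  }
  out <- list(herb_af = length(intersect(union_targets, af)),
              herb_osahs = length(intersect(union_targets, osahs)),
              herb_both = length(intersect(intersect(union_targets, af), osahs)),
              putative_targets = putative)
  class(out) <- "netpharm_venn"
  out
}

#' @export
print.netpharm_venn <- function(x, ...) {
  cat("Disease intersection: herb∩AF =", x$herb_af,
      "| herb∩OSAHS =", x$herb_osahs,
      "| triple =", x$herb_both, "\n")
  cat("Putative therapeutic targets (herb ∩ combined):",
      length(x$putative_targets), "\n")
  invisible(x)
}
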