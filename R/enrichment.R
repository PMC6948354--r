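#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of observing at
#' least `k` annotated genes in a query of size `n` drawn from a universe of
#' `N` genes of which `K` carry the annotation. This is the standard
#' over-representation statistic. Computed through the stable tail routine of
#' [stats::phyper()]; vectorized over its arguments.
#'
#' @param N Universe size.
#' @param K Annotated genes in the universe.
#' @param n Query size.
#' @param k Overlap count.
#' @return Numeric vector of upper-tail probabilities in (0, 1].
#' @export
hypergeom_upper <- function(N, K, n, k) {
  bad <- !(K >= 0 & K <= N & n >= 0 & n <= N & k >= 0 & k <= pmin(K, n))
  if (any(bad | !is.finite(N) | !is.finite(K) | !is.finite(n) | !is.finite(k))) {
    stop("require 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(K, n)",
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard BH step-up with clamping at 1; output order matches input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis of a gene set
#'
#' Tests each annotation term for enrichment of `query` genes with the
#' upper-tail hypergeometric statistic. The gene universe defaults to the
#' union of all genes in the supplied collection (an explicit background can
#' be given); the query is intersected with the universe before testing.
#' Only terms overlapping the query (`k >= 1`) are emitted, and only those
#' enter the FDR family. FDR is controlled per category (BP, MF, CC, pathway
#' separately). Significance follows the conventional cutoffs: GO categories
#' by `fdr < fdr_go`, pathway terms by raw `p_value < p_pathway`. The rich
#' factor `k / K` is the enrichment dot-plot x-axis.
#'
#' @param query Character vector of gene symbols.
#' @param terms List of annotation terms (see [read_gmt()]).
#' @param universe Optional explicit background gene list.
#' @param fdr_go FDR cutoff for GO categories (default 0.01).
#' @param p_pathway Raw p-value cutoff for the pathway category (default 0.05).
#' @return A `data.frame` of class `netpharm_enrichment`, one row per tested
#'   term, sorted by ascending p within category: `term_id`, `term_name`,
#'   `category`, `k`, `K`, `n`, `N`, `p_value`, `fdr`, `rich_factor`,
#'   `significant`, `overlap_genes` (`;`-separated).
#' @export
enrich <- function(query, terms, universe = NULL, fdr_go = 0.01,
                   p_pathway = 0.05) {
  if (length(terms) == 0) stop("no annotation terms supplied", call. = FALSE)
  query <- unique(toupper(query))
  all_genes <- sort(unique(toupper(unlist(lapply(terms, `[[`, "genes"),
                                          use.names = FALSE))))
  universe <- if (is.null(universe)) all_genes
              else sort(unique(toupper(universe)))
  query <- intersect(query, universe)
  if (length(query) == 0) {
    stop("query has no gene in the universe", call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(terms, function(tm) {
    genes <- intersect(unique(toupper(tm$genes)), universe)
    K <- length(genes)
    ov <- intersect(genes, query)
    k <- length(ov)
    if (k == 0) return(NULL)
    data.frame(term_id = tm$term_id, term_name = tm$term_name,
               category = tm$category, k = k, K = K, n = n, N = N,
               p_value = hypergeom_upper(N, K, n, k),
               rich_factor = k / K,
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    stop("no term overlaps the query", call. = FALSE)
  }
  rows$fdr <- NA_real_
  for (cg in unique(rows$category)) {
    sel <- rows$category == cg
    rows$fdr[sel] <- bh_fdr(rows$p_value[sel])
  }
  rows$significant <- ifelse(rows$category == "pathway",
                             rows$p_value < p_pathway,
                             rows$fdr < fdr_go)
  rows <- rows[order(rows$category, rows$p_value, rows$term_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows <- rows[, c("term_id", "term_name", "category", "k", "K", "n", "N",
                   "p_value", "fdr", "rich_factor", "significant",
                   "overlap_genes")]
  class(rows) <- c("netpharm_enrichment", "data.frame")
  rows
}

#' Enrichment dot plot
#'
#' Plots rich factor against term for the significant rows of an enrichment
#' table (all rows if none is significant), point size scaled by the overlap
#' count and color by p-value — the conventional pathway-enrichment display.
#'
#' @param x A `netpharm_enrichment` table.
#' @param category Restrict to one category (e.g. `"pathway"`); default all.
#' @param top Maximum number of terms plotted (smallest p first).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_enrichment <- function(x, category = NULL, top = 20, ...) {
  df <- as.data.frame(x)
  if (!is.null(category)) df <- df[df$category %in% category, , drop = FALSE]
  if (any(df$significant)) df <- df[df$significant, , drop = FALSE]
  df <- df[order(df$p_value), , drop = FALSE]
  df <- utils::head(df, top)
  if (nrow(df) == 0) stop("nothing to plot", call. = FALSE)
  df <- df[order(df$rich_factor), , drop = FALSE]
  pal <- grDevices::colorRampPalette(c("red", "blue"))(100)
  pcol <- pal[pmin(100, pmax(1, ceiling(100 * df$p_value / max(df$p_value))))]
  oldpar <- graphics::par(mar = c(5, 12, 2, 2)); on.exit(graphics::par(oldpar))
  graphics::plot(df$rich_factor, seq_len(nrow(df)), yaxt = "n",
                 xlab = "Rich factor", ylab = "",
                 cex = 0.8 + 2 * df$k / max(df$k), pch = 19, col = pcol, ...)
  graphics::axis(2, at = seq_len(nrow(df)), labels = df$term_name, las = 2,
                 cex.axis = 0.7)
  invisible(df)
}
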