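#' Default parameters of the synthetic study generator
#'
#' The defaults emulate the scale of a six-herb liver-regulating formula
#' study: 265 raw components of which roughly 94 survive the ADME screen
#' (OB drawn uniformly on 5-60 percent, DL from a right-skewed Beta(2, 6.5),
#' cutoffs 30 / 0.18, 8 literature-rescued components), heavy-tailed
#' component-target out-degrees with three planted promiscuous components
#' (164 / 104 / 50 targets, quercetin-like), a 182-gene target union, a
#' 232-gene combined disease set overlapping the union in exactly 38 genes,
#' an 88-node PPI graph with a planted 6-clique wired densely into the
#' periphery so it dominates degree, betweenness and closeness, and
#' annotation collections with planted enriched terms over-sampling the
#' putative target set.
#'
#' @return Named list of generator parameters.
#' @export
study_params <- function() {
  list(
    n_herbs = 6L,
    n_components = 265L,
    ob_range = c(5, 60),         # percent
    dl_shape = c(2, 6.5),        # Beta shape parameters for drug-likeness
    ob_min = 30, dl_min = 0.18,
    n_rescued = 8L,
    second_herb_prob = 0.02,
    n_targets = 182L,
    promiscuous_counts = c(164L, 104L, 50L),
    mean_targets = 18, size_targets = 0.7,  # negative-binomial out-degree
    n_unmapped = 6L,
    n_combined = 232L, overlap = 38L,
    n_af = 120L, af_overlap = 50L,
    n_osahs = 150L, osahs_overlap = 75L,
    ppi_extra = 50L,             # first-shell neighbor genes beyond putative
    core_size = 6L,
    core_attach = 0.6,           # planted-core attachment probability
    pa_m = 3L, pa_power = 1.1,   # preferential-attachment background
    score_range = c(0.15, 0.99), core_score_range = c(0.7, 0.99),
    planted_per_cat = 2L, null_per_cat = 28L,
    term_size_range = c(15L, 30L), planted_overlap = 12L,
    n_filler_genes = 150L
  )
}

# internal: herb frequency weights loosely matching a multi-herb formula in
# which one herb contributes the majority of characterized components
herb_weights <- function(n) {
  w <- c(9, 8, 51, 10, 14, 6)
  if (n <= 6) w[seq_len(n)] else c(w, rep(5, n - 6))
}

#' Generate a complete ground-truthed synthetic study
#'
#' Produces every input the pipeline reads — component table, rescue list,
#' raw-name mapping, component-target edges, disease gene lists, PPI edge
#' table, annotation collections — together with a `truth` record describing
#' exactly what was planted (promiscuous components, core genes, enriched
#' terms, all parameters and the seed). The same seed yields a byte-identical
#' fixture. Set overlaps (herb-disease intersections) are constructed
#' exactly, not sampled, so set-logic checks are deterministic.
#'
#' @param seed Integer RNG seed.
#' @param params Parameter list; see [study_params()]. Partial lists are
#'   merged over the defaults.
#' @return An object of class `netpharm_study`: a list with `components`,
#'   `rescue_ids`, `mapping`, `edges`, `disease` (`af`, `osahs`, `combined`),
#'   `ppi`, `annotations`, and `truth`.
#' @export
generate_study <- function(seed = 1, params = list()) {
  p <- utils::modifyList(study_params(), params)
  stopifnot(p$n_herbs >= 2, p$n_components >= 10, p$n_targets >= 20)
  if (p$overlap > min(p$n_targets, p$n_combined)) {
    stop("infeasible overlap: larger than one of the intersected sets",
         call. = FALSE)
  }
  if (p$af_overlap > p$n_af || p$af_overlap > p$n_targets ||
      p$osahs_overlap > p$n_osahs || p$osahs_overlap > p$n_targets) {
    stop("infeasible single-disease overlap", call. = FALSE)
  }
  if (p$core_size > p$overlap) {
    stop("planted core cannot exceed the putative set", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  herbs <- HERB_CODES[seq_len(p$n_herbs)]

  ## -- components ----------------------------------------------------------
  ids <- sprintf("C%04d", seq_len(p$n_components))
  primary <- sample(herbs, p$n_components, replace = TRUE,
                    prob = herb_weights(p$n_herbs))
  herb_field <- primary
  dual <- which(runif(p$n_components) < p$second_herb_prob)
  for (i in dual) {
    extra <- sample(setdiff(herbs, primary[i]), 1)
    herb_field[i] <- paste(sort(c(primary[i], extra)), collapse = ";")
  }
  ob <- round(runif(p$n_components, p$ob_range[1], p$ob_range[2]), 2)
  dl <- round(rbeta(p$n_components, p$dl_shape[1], p$dl_shape[2]), 3)
  components <- data.frame(
    component_id = ids,
    name = sprintf("compound_%04d", seq_len(p$n_components)),
    herbs = herb_field, ob = ob, dl = dl, rescued = FALSE,
    source = "synthetic", stringsAsFactors = FALSE)

  passes <- ob >= p$ob_min & dl >= p$dl_min
  failing <- ids[!passes]
  rescue_ids <- sort(sample(failing, min(p$n_rescued, length(failing))))
  active_ids <- sort(union(ids[passes], rescue_ids))

  ## -- gene universes ------------------------------------------------------
  union_targets <- sprintf("TG%04d", seq_len(p$n_targets))
  disease_only <- sprintf("DG%04d", seq_len(p$n_combined - p$overlap))
  fillers <- sprintf("FG%04d", seq_len(p$n_filler_genes))
  putative <- sort(sample(union_targets, p$overlap))
  combined <- sort(c(putative, disease_only))
  af <- sort(c(sample(union_targets, p$af_overlap),
               sample(c(disease_only, fillers), p$n_af - p$af_overlap)))
  osahs <- sort(c(sample(union_targets, p$osahs_overlap),
                  sample(c(disease_only, fillers), p$n_osahs - p$osahs_overlap)))

  ## -- component-target edges (raw names, heavy-tailed out-degree) ---------
  n_active <- length(active_ids)
  counts <- 1L + rnbinom(n_active, size = p$size_targets, mu = p$mean_targets)
  counts <- pmin(counts, p$n_targets)
  prom <- sample(seq_len(n_active), length(p$promiscuous_counts))
  counts[prom] <- pmin(p$promiscuous_counts, p$n_targets)
  pairs <- lapply(seq_len(n_active), function(i) {
    cbind(active_ids[i], sample(union_targets, counts[i]))
  })
  pairs <- do.call(rbind, pairs)
  # guarantee the union covers every target gene
  missing <- setdiff(union_targets, pairs[, 2])
  if (length(missing) > 0) {
    pairs <- rbind(pairs, cbind(sample(active_ids, length(missing),
                                       replace = TRUE), missing))
  }
  pairs <- pairs[!duplicated(paste(pairs[, 1], pairs[, 2])), , drop = FALSE]
  raw_of <- function(sym) paste0(tolower(sym), "_protein")
  edges <- data.frame(component_id = pairs[, 1],
                      raw_name = raw_of(pairs[, 2]),
                      evidence = sample(c("validated", "predicted"),
                                        nrow(pairs), replace = TRUE,
                                        prob = c(0.3, 0.7)),
                      stringsAsFactors = FALSE)
  # a few records whose raw protein name has no mapping row
  unmapped_raw <- sprintf("uncharacterized_protein_%02d", seq_len(p$n_unmapped))
  if (p$n_unmapped > 0) {
    edges <- rbind(edges, data.frame(
      component_id = sample(active_ids, p$n_unmapped, replace = TRUE),
      raw_name = unmapped_raw, evidence = "predicted",
      stringsAsFactors = FALSE))
  }
  ord <- order(edges$component_id, edges$raw_name)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  mapping <- data.frame(raw_name = raw_of(union_targets),
                        symbol = union_targets, stringsAsFactors = FALSE)

  ## -- PPI graph with a planted, densely wired core ------------------------
  core <- sort(sample(putative, p$core_size))
  neighbors <- sprintf("NB%03d", seq_len(p$ppi_extra))
  nodes <- c(putative, neighbors)
  n_nodes <- length(nodes)
  bg <- igraph::sample_pa(n_nodes, power = p$pa_power, m = p$pa_m,
                          directed = FALSE)
  igraph::V(bg)$name <- sample(nodes)   # detach PA hubs from node identity
  el <- igraph::as_edgelist(bg)
  non_core <- setdiff(nodes, core)
  # clique on the core plus probabilistic attachment to the periphery
  cl <- t(utils::combn(core, 2))
  att <- do.call(rbind, lapply(core, function(cg) {
    hit <- non_core[runif(length(non_core)) < p$core_attach]
    if (length(hit) == 0) NULL else cbind(cg, hit)
  }))
  el <- rbind(el, cl, att)
  lo <- pmin(el[, 1], el[, 2]); hi <- pmax(el[, 1], el[, 2])
  keep <- !duplicated(paste(lo, hi)) & lo != hi
  lo <- lo[keep]; hi <- hi[keep]
  core_touch <- lo %in% core | hi %in% core
  score <- ifelse(core_touch,
                  runif(length(lo), p$core_score_range[1], p$core_score_range[2]),
                  runif(length(lo), p$score_range[1], p$score_range[2]))
  ppi <- data.frame(gene_a = lo, gene_b = hi,
                    combined_score = round(score, 3),
                    stringsAsFactors = FALSE)
  ppi <- ppi[order(ppi$gene_a, ppi$gene_b), , drop = FALSE]
  rownames(ppi) <- NULL

  ## -- annotation collections with planted enrichment ----------------------
  ann_universe <- c(union_targets, disease_only, fillers)
  categories <- c("BP", "MF", "CC", "pathway")
  annotations <- list()
  planted_ids <- character()
  for (cg in categories) {
    for (j in seq_len(p$planted_per_cat)) {
      size <- sample(p$term_size_range[1]:p$term_size_range[2], 1)
      hit <- sample(putative, min(p$planted_overlap, size))
      rest <- sample(setdiff(ann_universe, hit), size - length(hit))
      id <- sprintf("%s_PLANT%02d", cg, j)
      planted_ids <- c(planted_ids, id)
      annotations[[length(annotations) + 1]] <-
        list(term_id = id, term_name = sprintf("planted %s term %d", cg, j),
             category = cg, genes = sort(c(hit, rest)))
    }
    for (j in seq_len(p$null_per_cat)) {
      size <- sample(p$term_size_range[1]:p$term_size_range[2], 1)
      annotations[[length(annotations) + 1]] <-
        list(term_id = sprintf("%s_NULL%02d", cg, j),
             term_name = sprintf("null %s term %d", cg, j),
             category = cg, genes = sort(sample(ann_universe, size)))
    }
  }

  truth <- list(
    seed = seed, params = p,
    active_ids = active_ids, rescue_ids = rescue_ids,
    promiscuous = setNames(as.integer(counts[prom]), active_ids[prom]),
    union_targets = union_targets, putative_targets = putative,
    planted_core = core, ppi_nodes = sort(nodes),
    planted_terms = sort(planted_ids), unmapped_raw = unmapped_raw)

  out <- list(components = components, rescue_ids = rescue_ids,
              mapping = mapping, edges = edges,
              disease = list(af = af, osahs = osahs, combined = combined),
              ppi = ppi, annotations = annotations, truth = truth)
  class(out) <- "netpharm_study"
  out
}

#' @export
print.netpharm_study <- function(x, ...) {
  cat("Synthetic network-pharmacology study (seed", x$truth$seed, ")\n")
  cat(sprintf("  %d components (%d active incl. %d rescued), %d target records\n",
              nrow(x$components), length(x$truth$active_ids),
              length(x$rescue_ids), nrow(x$edges)))
  cat(sprintf("  %d-gene target union, %d-gene combined disease set, overlap %d\n",
              length(x$truth$union_targets), length(x$disease$combined),
              length(x$truth$putative_targets)))
  cat(sprintf("  PPI: %d nodes / %d edges, planted core: %s\n",
              length(x$truth$ppi_nodes), nrow(x$ppi),
              paste(x$truth$planted_core, collapse = ", ")))
  cat(sprintf("  %d annotation terms (%d planted)\n",
              length(x$annotations), length(x$truth$planted_terms)))
  invisible(x)
}

#' Write a synthetic study fixture to disk
#'
#' Emits every input file the pipeline reads, in its canonical plain-text
#' format, plus `truth.json`.
#'
#' @param study A `netpharm_study` from [generate_study()].
#' @param dir Output directory (created if absent).
#' @return Named list of file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "netpharm_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(dir, f)
  tsv <- function(df, f) {
    utils::write.table(df, path(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path(f)
  }
  files <- list(
    components = tsv(study$components, "components.tsv"),
    mapping = tsv(study$mapping, "mapping.tsv"),
    targets = tsv(study$edges, "component_targets.tsv"),
    ppi = tsv(study$ppi, "ppi.tsv"))
  writeLines(study$rescue_ids, path("rescue.txt"))
  files$rescue <- path("rescue.txt")
  for (nm in c("af", "osahs", "combined")) {
    f <- paste0(nm, ".txt")
    writeLines(study$disease[[nm]], path(f))
    files[[nm]] <- path(f)
  }
  gmt_files <- c(BP = "go_bp.gmt", MF = "go_mf.gmt", CC = "go_cc.gmt",
                 pathway = "pathways.gmt")
  for (cg in names(gmt_files)) {
    terms <- Filter(function(tm) tm$category == cg, study$annotations)
    lines <- vapply(terms, function(tm) {
      paste(c(tm$term_id, tm$term_name, tm$genes), collapse = "\t")
    }, character(1))
    writeLines(lines, path(gmt_files[[cg]]))
    files[[paste0("gmt_", tolower(cg))]] <- path(gmt_files[[cg]])
  }
  jsonlite::write_json(study$truth, path("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  files$truth <- path("truth.json")
  invisible(files)
}
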