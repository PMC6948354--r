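#' Default pipeline thresholds
#' @return Named list of analysis parameters with their conventional values.
#' @export
pipeline_params <- function() {
  list(ob_min = 30, dl_min = 0.18, score_min = 0.4, strict_hub = FALSE,
       fdr_go = 0.01, p_pathway = 0.05, disease_label = "AF_OSAHS")
}

#' Run the full network-pharmacology pipeline
#'
#' Executes the stages in fixed order: ADME filter of components, symbol
#' standardization, target assembly, disease intersection, construction of
#' the component-target / disease-mapping / target-pathway networks, PPI
#' topology screen, and GO/pathway over-representation analysis. All
#' intermediates are written under `out_dir` together with a machine-readable
#' `report.json` echoing the thresholds actually applied and the counts of
#' every stage.
#'
#' @param config Either a path to a YAML file or a list. Recognized keys:
#'   `inputs` (paths: `components`, `mapping`, `targets`, `rescue`, `af`,
#'   `osahs`, `combined`, `ppi`, `gmt_bp`, `gmt_mf`, `gmt_cc`,
#'   `gmt_pathway`), `params` (see [pipeline_params()]) and, alternatively to
#'   `inputs`, `simulate` (a list with `seed` and optional generator
#'   `params`, see [generate_study()]).
#' @param out_dir Artifact directory; defaults to `config$out_dir` or a
#'   temporary directory.
#' @param overrides Named list merged over `config$params` (mirrors
#'   command-line flag overrides).
#' @return An object of class `netpharm_run`: a list with the per-stage
#'   results (`filter`, `assembly`, `venn`, `networks`, `screen`,
#'   `enrichment`), the merged `params`, the `report` list and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, overrides = list()) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  params <- utils::modifyList(pipeline_params(), config$params %||% list())
  params <- utils::modifyList(params, overrides)
  if (is.null(out_dir)) out_dir <- config$out_dir %||% tempfile("netpharm_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ## -- inputs --------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    study <- generate_study(seed = sim$seed %||% 1,
                            params = sim$params %||% list())
    components <- study$components
    rescue_ids <- study$rescue_ids
    mapping <- study$mapping
    raw_edges <- study$edges
    af <- study$disease$af; osahs <- study$disease$osahs
    combined <- study$disease$combined
    terms <- study$annotations
    ppi_edges <- study$ppi
    # apply the same confidence filter a file-based run would
    ppi_edges <- ppi_edges[ppi_edges$combined_score >= params$score_min, ,
                           drop = FALSE]
  } else {
    inp <- config$inputs
    required <- c("components", "mapping", "targets", "af", "osahs",
                  "combined", "ppi")
    missing <- setdiff(required, names(inp))
    if (length(missing) > 0) {
      stop("config$inputs missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    absent <- unlist(inp)[!file.exists(unlist(inp))]
    if (length(absent) > 0) {
      stop("input file(s) not found: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    components <- read_component_table(inp$components)
    rescue_ids <- if (!is.null(inp$rescue)) read_gene_list(inp$rescue)
                  else character()
    mapping <- read_mapping_table(inp$mapping)
    raw_edges <- read_target_table(inp$targets)
    af <- read_gene_list(inp$af)
    osahs <- read_gene_list(inp$osahs)
    combined <- read_gene_list(inp$combined)
    ppi_edges <- read_interaction_table(inp$ppi, score_min = params$score_min)
    terms <- list()
    for (cg in c("BP", "MF", "CC", "pathway")) {
      key <- paste0("gmt_", tolower(cg))
      if (!is.null(inp[[key]])) {
        terms <- c(terms, read_gmt(inp[[key]], category = cg))
      }
    }
  }

  ## -- stages --------------------------------------------------------------
  filt <- filter_components(components, ob_min = params$ob_min,
                            dl_min = params$dl_min, rescue_ids = rescue_ids)
  active <- filt$active
  raw_edges <- raw_edges[raw_edges$component_id %in% active$component_id, ,
                         drop = FALSE]
  std <- standardize_symbols(raw_edges, mapping)
  assembly <- assemble_targets(std$mapped, active, total_raw = std$total_raw)
  venn <- intersect_disease(assembly$union_targets, af, osahs, combined)

  ct_net <- build_component_target_network(active, std$mapped)
  dm_net <- build_disease_mapping_network(active, std$mapped,
                                          venn$putative_targets, combined,
                                          disease_label = params$disease_label)
  ppi_graph <- graph_from_interactions(ppi_edges)
  screen <- median_screen(ppi_graph, strict_hub = params$strict_hub)
  enr <- if (length(terms) > 0) {
    enrich(venn$putative_targets, terms, fdr_go = params$fdr_go,
           p_pathway = params$p_pathway)
  } else NULL
  tp_net <- if (!is.null(enr)) {
    sig_pw <- enr$term_id[enr$category == "pathway" & enr$significant]
    build_target_pathway_network(
      active, std$mapped, venn$putative_targets,
      Filter(function(tm) tm$term_id %in% sig_pw, terms))
  } else NULL

  ## -- artifacts -----------------------------------------------------------
  tsv <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(active, "active_components.tsv")
  tsv(std$mapped, "mapped_targets.tsv")
  tsv(std$unmapped, "unmapped_targets.tsv")
  tsv(screen$centrality, "centrality.tsv")
  if (!is.null(enr)) tsv(as.data.frame(enr), "enrichment.tsv")
  write_network(ct_net, file.path(out_dir, "component_target.sif"))
  write_network(dm_net, file.path(out_dir, "disease_mapping.graphml"),
                format = "graphml")
  if (igraph::vcount(ppi_graph) > 0) {
    write_network(ppi_graph, file.path(out_dir, "ppi.graphml"),
                  format = "graphml")
  }
  if (!is.null(tp_net) && igraph::vcount(tp_net) > 0) {
    write_network(tp_net, file.path(out_dir, "target_pathway.graphml"),
                  format = "graphml")
  }

  sig_counts <- if (is.null(enr)) NULL else {
    tab <- table(enr$category[enr$significant])
    setNames(as.integer(tab), names(tab))
  }
  report <- list(
    params = params,
    components = filt$report,
    targets = list(total_raw = std$total_raw, total_mapped = std$total_mapped,
                   unmapped = nrow(std$unmapped),
                   union_targets = length(assembly$union_targets),
                   per_herb = as.list(assembly$per_herb_counts)),
    venn = list(herb_af = venn$herb_af, herb_osahs = venn$herb_osahs,
                herb_both = venn$herb_both,
                putative = length(venn$putative_targets)),
    networks = list(component_target = count_network(ct_net),
                    disease_mapping = count_network(dm_net),
                    ppi = count_network(ppi_graph)),
    screen = list(hub_nodes = screen$hub_nodes,
                  core_targets = screen$core_targets,
                  thresholds = screen$thresholds),
    enrichment = list(tested = if (is.null(enr)) 0L else nrow(enr),
                      significant_per_category = as.list(sig_counts %||% list())),
    version = as.character(utils::packageVersion("netpharm")))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  out <- list(filter = filt, assembly = assembly, venn = venn,
              networks = list(component_target = ct_net,
                              disease_mapping = dm_net, ppi = ppi_graph,
                              target_pathway = tp_net),
              screen = screen, enrichment = enr, params = params,
              report = report, out_dir = out_dir)
  class(out) <- "netpharm_run"
  out
}

#' @export
print.netpharm_run <- function(x, ...) {
  r <- x$report
  cat("netpharm pipeline run ->", x$out_dir, "\n")
  cat(sprintf("  components: %d raw -> %d active (%d rescued)\n",
              r$components$input, r$components$kept, r$components$rescued))
  cat(sprintf("  targets: %d raw records, %d mapped, %d unique; %d unmapped\n",
              r$targets$total_raw, r$targets$total_mapped,
              r$targets$union_targets, r$targets$unmapped))
  cat(sprintf("  disease intersection: AF %d | OSAHS %d | putative %d\n",
              r$venn$herb_af, r$venn$herb_osahs, r$venn$putative))
  cat(sprintf("  networks: CT %d/%d, disease-mapping %d/%d, PPI %d/%d (nodes/edges)\n",
              r$networks$component_target$nodes, r$networks$component_target$edges,
              r$networks$disease_mapping$nodes, r$networks$disease_mapping$edges,
              r$networks$ppi$nodes, r$networks$ppi$edges))
  cat(sprintf("  screen: %d hub -> %d core [%s]\n",
              length(r$screen$hub_nodes), length(r$screen$core_targets),
              paste(r$screen$core_targets, collapse = ", ")))
  if (!is.null(x$enrichment)) {
    sig <- r$enrichment$significant_per_category
    cat(sprintf("  enrichment: %d terms tested; significant: %s\n",
                r$enrichment$tested,
                paste(names(sig), unlist(sig), sep = "=", collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.netpharm_run <- function(object, ...) {
  print(object)
  cat("\nStage-1/2 screen thresholds:\n")
  utils::str(object$screen$thresholds, give.head = FALSE)
  invisible(object$report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
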