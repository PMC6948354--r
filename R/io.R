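#' @keywords internal
HERB_CODES <- c("SZR", "GS", "YHS", "XHC", "JL", "ML")

# internal: read a delimited table with a header and check required columns
read_table_checked <- function(path, required, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

# internal: coerce a column to numeric, reporting 1-based file line numbers
# (header is line 1) for values that fail to parse
numeric_column <- function(x, col, allow_na = rep(FALSE, length(x))) {
  raw <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(raw))
  blank <- is.na(raw) | raw == "" | toupper(raw) == "NA"
  bad <- is.na(out) & !blank
  if (any(bad)) {
    stop("non-numeric value in column '", col, "' at line ",
         which(bad)[1] + 1L, ": '", raw[which(bad)[1]], "'", call. = FALSE)
  }
  if (any(blank & !allow_na)) {
    stop("missing value in column '", col, "' at line ",
         which(blank & !allow_na)[1] + 1L, call. = FALSE)
  }
  out
}

#' Read a herb component table
#'
#' Reads a delimited table of herb components with ADME parameters. Required
#' columns: `component_id`, `name`, `herbs` (one or more herb codes separated
#' by `;`), `ob` (oral bioavailability, percent) and `dl` (drug-likeness, in
#' \[0, 1\]). Optional columns: `rescued` (logical: literature-supported
#' despite failing the ADME cutoffs) and `source`. Rows with a missing OB or
#' DL are rejected unless their `rescued` flag is set.
#'
#' @param path Path to the table.
#' @param sep Field separator; tab by default, use `","` for CSV.
#' @return A `data.frame` with columns `component_id`, `name`, `herbs`
#'   (`;`-separated codes), `ob`, `dl`, `rescued`, `source`.
#' @export
read_component_table <- function(path, sep = "\t") {
  df <- read_table_checked(path, c("component_id", "name", "herbs", "ob", "dl"),
                           sep = sep)
  if (nrow(df) == 0) {
    return(data.frame(component_id = character(), name = character(),
                      herbs = character(), ob = numeric(), dl = numeric(),
                      rescued = logical(), source = character(),
                      stringsAsFactors = FALSE))
  }
  rescued <- if ("rescued" %in% names(df)) {
    tolower(trimws(as.character(df$rescued))) %in% c("true", "t", "1", "yes")
  } else rep(FALSE, nrow(df))
  ob <- numeric_column(df$ob, "ob", allow_na = rescued)
  dl <- numeric_column(df$dl, "dl", allow_na = rescued)
  id <- trimws(as.character(df$component_id))
  herbs <- trimws(as.character(df$herbs))
  if (anyDuplicated(id)) {
    stop("duplicate component_id: ", id[duplicated(id)][1], call. = FALSE)
  }
  if (any(herbs == "")) {
    stop("empty herbs field at line ", which(herbs == "")[1] + 1L, call. = FALSE)
  }
  ok_ob <- is.na(ob) | (is.finite(ob) & ob >= 0)
  ok_dl <- is.na(dl) | (is.finite(dl) & dl >= 0 & dl <= 1)
  if (!all(ok_ob)) stop("ob must be finite and >= 0 (line ",
                        which(!ok_ob)[1] + 1L, ")", call. = FALSE)
  if (!all(ok_dl)) stop("dl must lie in [0, 1] (line ",
                        which(!ok_dl)[1] + 1L, ")", call. = FALSE)
  data.frame(component_id = id, name = as.character(df$name), herbs = herbs,
             ob = ob, dl = dl, rescued = rescued,
             source = if ("source" %in% names(df)) as.character(df$source) else "",
             stringsAsFactors = FALSE)
}

#' Split the `herbs` field of a component table into a list of herb codes
#' @param components A component `data.frame` (see [read_component_table()]).
#' @return A named list of character vectors, one per component.
#' @export
component_herbs <- function(components) {
  out <- lapply(strsplit(components$herbs, ";", fixed = TRUE),
                function(h) unique(trimws(h[trimws(h) != ""])))
  names(out) <- components$component_id
  out
}

#' Read a GMT annotation collection
#'
#' Standard tab-delimited gene-set format: one term per line, fields are term
#' id, description, then member genes. Gene symbols are uppercased and
#' duplicates within a line collapsed.
#'
#' @param path Path to a `.gmt` file.
#' @param category Annotation category for every term in this file: one of
#'   `"BP"`, `"MF"`, `"CC"`, `"pathway"`.
#' @return A list of terms; each term is a list with `term_id`, `term_name`,
#'   `category`, and `genes` (character vector).
#' @export
read_gmt <- function(path, category = c("BP", "MF", "CC", "pathway")) {
  category <- match.arg(category)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields",
           call. = FALSE)
    }
    genes <- unique(toupper(trimws(fields[-(1:2)])))
    genes <- genes[genes != ""]
    if (length(genes) == 0) {
      stop("GMT line ", i, " has no genes", call. = FALSE)
    }
    out[[i]] <- list(term_id = fields[1], term_name = fields[2],
                     category = category, genes = genes)
  }
  out
}

#' Read a protein-protein interaction edge table
#'
#' Required columns: `gene_a`, `gene_b`, `combined_score` (interaction
#' confidence in \[0, 1\]). Edges below `score_min` are dropped, self-loops
#' are dropped with a warning, and duplicate unordered pairs are collapsed
#' keeping the maximum combined score.
#'
#' @param path Path to the edge table.
#' @param score_min Minimum combined score to retain an edge.
#' @param sep Field separator.
#' @return A `data.frame` with columns `gene_a`, `gene_b`, `combined_score`;
#'   symbols uppercased, one row per unordered pair.
#' @export
read_interaction_table <- function(path, score_min = 0.4, sep = "\t") {
  stopifnot(is.numeric(score_min), score_min >= 0, score_min <= 1)
  df <- read_table_checked(path, c("gene_a", "gene_b", "combined_score"),
                           sep = sep)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      combined_score = numeric(), stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(empty)
  score <- numeric_column(df$combined_score, "combined_score")
  if (any(score < 0 | score > 1)) {
    stop("combined_score outside [0, 1] at line ",
         which(score < 0 | score > 1)[1] + 1L, call. = FALSE)
  }
  a <- toupper(trimws(as.character(df$gene_a)))
  b <- toupper(trimws(as.character(df$gene_b)))
  if (any(a == "" | b == "")) {
    stop("empty gene symbol at line ", which(a == "" | b == "")[1] + 1L,
         call. = FALSE)
  }
  loop <- a == b
  if (any(loop)) {
    warning(sum(loop), " self-loop edge(s) dropped", call. = FALSE)
    a <- a[!loop]; b <- b[!loop]; score <- score[!loop]
  }
  keep <- score >= score_min
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  if (length(a) == 0) return(empty)
  # canonical unordered orientation, then max-collapse duplicates
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  score <- tapply(score, key, max)
  pairs <- do.call(rbind, strsplit(names(score), "\r", fixed = TRUE))
  out <- data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                    combined_score = as.numeric(score),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Read a gene list (one symbol per line)
#' @param path Path to a plain-text file, one gene symbol per line.
#' @return Character vector of unique, uppercased symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- toupper(trimws(readLines(path, warn = FALSE)))
  unique(x[x != ""])
}

#' Read a raw-name to gene-symbol mapping table
#' @param path Path to a table with columns `raw_name` and `symbol`.
#' @param sep Field separator.
#' @return A `data.frame` with columns `raw_name`, `symbol`.
#' @export
read_mapping_table <- function(path, sep = "\t") {
  df <- read_table_checked(path, c("raw_name", "symbol"), sep = sep)
  data.frame(raw_name = trimws(as.character(df$raw_name)),
             symbol = toupper(trimws(as.character(df$symbol))),
             stringsAsFactors = FALSE)
}

#' Read a component-target edge table (raw protein names)
#' @param path Path to a table with columns `component_id`, `raw_name` and an
#'   optional `evidence` column (`validated` or `predicted`).
#' @param sep Field separator.
#' @return A `data.frame` with columns `component_id`, `raw_name`, `evidence`.
#' @export
read_target_table <- function(path, sep = "\t") {
  df <- read_table_checked(path, c("component_id", "raw_name"), sep = sep)
  data.frame(component_id = trimws(as.character(df$component_id)),
             raw_name = trimws(as.character(df$raw_name)),
             evidence = if ("evidence" %in% names(df))
               as.character(df$evidence) else "predicted",
             stringsAsFactors = FALSE)
}

#' Build an igraph PPI graph from an interaction edge table
#' @param edges A `data.frame` from [read_interaction_table()].
#' @return An undirected simple `igraph` graph with edge attribute
#'   `combined_score`.
#' @export
graph_from_interactions <- function(edges) {
  stopifnot(all(c("gene_a", "gene_b", "combined_score") %in% names(edges)))
  igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b", "combined_score")], directed = FALSE)
}

#' Export a network to SIF or GraphML
#'
#' SIF (`source<TAB>interaction<TAB>target`) is the plain Cytoscape exchange
#' format; isolated nodes are written as single-field lines. GraphML
#' round-trips node attributes (e.g. `type`).
#'
#' @param graph A nonempty `igraph` graph with named vertices.
#' @param path Output path.
#' @param format `"sif"` or `"graphml"`.
#' @param interaction Relation label used in SIF output.
#' @export
write_network <- function(graph, path, format = c("sif", "graphml"),
                          interaction = "pp") {
  format <- match.arg(format)
  if (igraph::vcount(graph) == 0) stop("refusing to write an empty graph",
                                       call. = FALSE)
  if (is.null(igraph::V(graph)$name)) {
    stop("graph vertices must be named", call. = FALSE)
  }
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(graph, names = TRUE)
  lines <- if (nrow(el) > 0) paste(el[, 1], interaction, el[, 2], sep = "\t")
           else character()
  iso <- setdiff(igraph::V(graph)$name, c(el[, 1], el[, 2]))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Read a network written by [write_network()]
#' @param path Path to a `.sif` or `.graphml` file.
#' @param format `"sif"` or `"graphml"`.
#' @return An undirected `igraph` graph.
#' @export
read_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(igraph::as_undirected(g, mode = "collapse"))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  edges <- Filter(function(f) length(f) >= 3, fields)
  nodes <- unlist(lapply(fields, function(f) f[c(1, if (length(f) >= 3) seq(3, length(f)))]),
                  use.names = FALSE)
  el <- do.call(rbind, lapply(edges, function(f) {
    cbind(f[1], f[seq(3, length(f))])
  }))
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(unique(nodes))
  if (!is.null(el) && nrow(el) > 0) {
    g <- igraph::add_edges(g, t(el))
  }
  igraph::simplify(g)
}
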