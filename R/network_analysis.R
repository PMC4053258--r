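# Interaction-network analysis of called genes: induced subgraph, largest
# connected component and degree-based hub extraction, on a user-supplied
# undirected edge list (SIF or two-column TSV). Backed by igraph.

#' Read an interaction edge list
#'
#' Accepts SIF (`node relation node`, whitespace separated) or a two-column
#' TSV; an optional third/relation column is kept as an edge attribute for
#' reporting only. The graph is undirected and simple: duplicate edges are
#' merged and self-loops dropped (their count is reported in a message).
#'
#' @param path edge-list file.
#' @return an undirected simple [igraph::igraph] graph.
#' @examples
#' # a small synthetic example network around apoptosis-pathway hubs
#' sif <- system.file("extdata", "example_interactions.sif",
#'                    package = "trailscreen")
#' g <- read_edge_list(sif)
#' hub_nodes(g, min_degree = 7)
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop_validation(paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_validation("empty edge list")
  fields <- strsplit(trimws(lines), "[\t ]+")
  bad <- which(vapply(fields, length, integer(1)) < 2L)
  if (length(bad))
    stop_validation("malformed edge-list line", bad)
  from <- vapply(fields, `[`, character(1), 1L)
  nfield <- vapply(fields, length, integer(1))
  # SIF puts the relation in the middle field; plain TSV has none
  to <- ifelse(nfield >= 3L,
               vapply(fields, `[`, character(1), 3L),
               vapply(fields, `[`, character(1), 2L))
  relation <- ifelse(nfield >= 3L,
                     vapply(fields, `[`, character(1), 2L), NA_character_)
  edges <- data.frame(from = from, to = to, relation = relation,
                      stringsAsFactors = FALSE)
  n_loops <- sum(edges$from == edges$to)
  if (n_loops) message(sprintf("dropped %d self-loop(s)", n_loops))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(relation = "first"))
}

#' Induced subgraph on a set of hit genes
#'
#' @param graph an undirected interaction graph.
#' @param hit_genes character vector of gene identifiers.
#' @return list with `subgraph` (induced igraph on the mapped hits) and
#'   `unmapped` (hit genes absent from the graph).
#' @export
hit_subgraph <- function(graph, hit_genes) {
  hit_genes <- unique(hit_genes)
  present <- intersect(hit_genes, igraph::V(graph)$name)
  list(subgraph = igraph::induced_subgraph(graph, present),
       unmapped = setdiff(hit_genes, present))
}

#' Nodes of the largest connected component
#'
#' Ties in component size are broken by the lexicographically smallest
#' member, so the result is deterministic regardless of input order.
#'
#' @param graph an igraph graph with at least one node.
#' @return sorted character vector of node names.
#' @export
largest_component <- function(graph) {
  if (igraph::vcount(graph) == 0L) stop_validation("empty graph")
  comp <- igraph::components(graph)
  members <- split(igraph::V(graph)$name, comp$membership)
  members <- lapply(members, sort)
  sizes <- vapply(members, length, integer(1))
  biggest <- members[sizes == max(sizes)]
  firsts <- vapply(biggest, `[`, character(1), 1L)
  biggest[[order(firsts)[1L]]]
}

#' Hub nodes by degree
#'
#' Reports every node together with its degree (count of distinct neighbors
#' in the given graph), whether it lies in the largest connected component,
#' and whether it qualifies as a hub (degree at or above `min_degree`;
#' default 7).
#'
#' @param graph the (sub)graph to analyze.
#' @param min_degree hub threshold (default 7).
#' @param corroboration optional data.frame from [corroborate_calls()] to
#'   merge in by gene_id.
#' @return data.frame gene_id, degree, in_largest_component, is_hub
#'   (plus corroboration columns when supplied), sorted by decreasing degree
#'   then gene_id.
#' @export
hub_nodes <- function(graph, min_degree = 7L, corroboration = NULL) {
  if (igraph::vcount(graph) == 0L)
    return(data.frame(gene_id = character(), degree = integer(),
                      in_largest_component = logical(),
                      is_hub = logical()))
  deg <- igraph::degree(graph, loops = FALSE)
  lcc <- largest_component(graph)
  out <- data.frame(gene_id = names(deg), degree = as.integer(deg),
                    in_largest_component = names(deg) %in% lcc,
                    is_hub = as.integer(deg) >= min_degree,
                    stringsAsFactors = FALSE)
  if (!is.null(corroboration))
    out <- merge(out, corroboration, by = "gene_id", all.x = TRUE,
                 sort = FALSE)
  out <- out[order(-out$degree, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a graph as SIF
#'
#' @param graph igraph graph.
#' @param path output path.
#' @param relation relation label for edges lacking one (default `"pp"`).
#' @return `path`, invisibly.
#' @export
write_sif <- function(graph, path, relation = "pp") {
  el <- igraph::as_edgelist(graph)
  rel <- if ("relation" %in% igraph::edge_attr_names(graph)) {
    r <- igraph::E(graph)$relation
    ifelse(is.na(r), relation, r)
  } else rep(relation, nrow(el))
  lines <- if (nrow(el)) paste(el[, 1L], rel, el[, 2L], sep = "\t")
  else character()
  isolated <- setdiff(igraph::V(graph)$name, c(el))
  writeLines(c(lines, isolated), path)
  invisible(path)
}
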