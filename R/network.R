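#' Assemble condition-specific co-expression networks from PCIT results
#'
#' One undirected network per condition: nodes are the shared PCIT node set
#' with a gene/TF role taken from the catalog, edges are the significant
#' pairs weighted by their correlation. No self-loops, no duplicate edges.
#'
#' @param p_ref,p_alt `pcit_result`s for the reference and alternate
#'   condition; must share the same node ids.
#' @param tfs character vector of TF ids for role assignment.
#' @param conditions length-2 character vector of condition labels.
#' @return list of two `condition_network`s (reference first), each a list
#'   with `nodes` (data frame: id, role), `edges` (data frame: node_a,
#'   node_b, weight) and `condition`.
#' @export
build_networks <- function(p_ref, p_alt, tfs = character(),
                           conditions = c("reference", "alternate")) {
  stopifnot(inherits(p_ref, "pcit_result"), inherits(p_alt, "pcit_result"))
  if (!identical(p_ref$node_ids, p_alt$node_ids)) {
    stop("PCIT results have mismatched node sets")
  }
  mk <- function(p, lbl) {
    e <- pcit_edges(p)
    structure(list(
      nodes = data.frame(id = p$node_ids,
                         role = ifelse(p$node_ids %in% tfs, "TF", "gene"),
                         stringsAsFactors = FALSE),
      edges = data.frame(node_a = e$node_a, node_b = e$node_b,
                         weight = e$correlation, stringsAsFactors = FALSE),
      condition = lbl
    ), class = "condition_network")
  }
  stats::setNames(list(mk(p_ref, conditions[1]), mk(p_alt, conditions[2])),
                  conditions)
}

#' @export
print.condition_network <- function(x, ...) {
  cat(sprintf("<condition_network> '%s': %d nodes (%d TFs), %d edges\n",
              x$condition, nrow(x$nodes), sum(x$nodes$role == "TF"),
              nrow(x$edges)))
  invisible(x)
}

# Named degree vector over all nodes of the network (isolated nodes -> 0).
network_degrees <- function(net) {
  stopifnot(inherits(net, "condition_network"))
  deg <- stats::setNames(integer(nrow(net$nodes)), net$nodes$id)
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$node_a, net$edges$node_b))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Table of transcription factors with high regulatory impact
#'
#' Joins the RIF scores with each TF's degree ("frequency of appearance") in
#' the two condition networks. `freq_diff = freq_ref - freq_alt`: a positive
#' difference marks a TF wired mainly in the reference condition. By default
#' rows are restricted to RIF-significant TFs and sorted by `freq_diff`
#' descending.
#'
#' @param net_ref,net_alt `condition_network`s for reference and alternate.
#' @param rif a `rif_table` from [rif_scores()].
#' @param significant_only keep only RIF-significant TFs (default TRUE).
#' @return data frame of class `hri_table` with columns `TF`, `avgexpr`,
#'   `RIF1`, `RIF2`, `freq_ref`, `freq_alt`, `freq_diff`.
#' @export
hri_table <- function(net_ref, net_alt, rif, significant_only = TRUE) {
  stopifnot(inherits(rif, "rif_table"))
  deg_ref <- network_degrees(net_ref)
  deg_alt <- network_degrees(net_alt)
  rows <- if (significant_only) rif[rif$sig1 | rif$sig2, , drop = FALSE] else rif
  get_deg <- function(deg, ids) {
    out <- deg[ids]
    out[is.na(out)] <- 0L          # TF absent from the network => degree 0
    unname(out)
  }
  out <- data.frame(
    TF = rows$TF,
    avgexpr = rows$avgexpr,
    RIF1 = rows$RIF1,
    RIF2 = rows$RIF2,
    freq_ref = get_deg(deg_ref, rows$TF),
    freq_alt = get_deg(deg_alt, rows$TF),
    stringsAsFactors = FALSE
  )
  out$freq_diff <- out$freq_ref - out$freq_alt
  out <- out[order(-out$freq_diff, out$TF), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hri_table", "data.frame")
  out
}

#' Targets of a transcription factor in a network
#'
#' @param net a `condition_network`.
#' @param tf a node id present in the network.
#' @return sorted character vector of the TF's neighbors.
#' @export
tf_targets <- function(net, tf) {
  stopifnot(inherits(net, "condition_network"))
  if (!tf %in% net$nodes$id) stop("unknown node id: ", tf)
  e <- net$edges
  sort(unique(c(e$node_b[e$node_a == tf], e$node_a[e$node_b == tf])))
}

#' Average local clustering coefficient
#'
#' Mean over all nodes of the local clustering coefficient (realized
#' triangles among a node's neighbors divided by possible neighbor pairs);
#' nodes of degree < 2 contribute 0. Returns a value in `[0, 1]`.
#'
#' @param net a `condition_network`.
#' @return a single number.
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "condition_network"))
  ids <- net$nodes$id
  n <- length(ids)
  if (n == 0) stop("network has no nodes")
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (nrow(net$edges)) {
    ia <- match(net$edges$node_a, ids)
    ib <- match(net$edges$node_b, ids)
    adj[cbind(ia, ib)] <- TRUE
    adj[cbind(ib, ia)] <- TRUE
  }
  local <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ])
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb, drop = FALSE]) / 2
    links / (k * (k - 1) / 2)
  }, numeric(1))
  mean(local)
}

#' Average clustering coefficient as a percentage
#'
#' @inheritParams clustering_coefficient
#' @return `100 * clustering_coefficient(net)`.
#' @export
clustering_coefficient_pct <- function(net) 100 * clustering_coefficient(net)

#' Degree distribution of a network
#'
#' @param net a `condition_network`.
#' @return named integer vector mapping degree to node count; counts sum to
#'   the number of nodes.
#' @export
degree_histogram <- function(net) {
  deg <- network_degrees(net)
  tab <- table(deg)
  stats::setNames(as.integer(tab), names(tab))
}

#' Write a network edge list as TSV
#'
#' Columns: node_a, interaction (constant `"cor"`), node_b, weight,
#' condition.
#'
#' @param net a `condition_network`.
#' @param path output file.
#' @export
write_edges_tsv <- function(net, path) {
  stopifnot(inherits(net, "condition_network"))
  n_e <- nrow(net$edges)
  df <- data.frame(node_a = net$edges$node_a,
                   interaction = rep_len("cor", n_e),
                   node_b = net$edges$node_b, weight = net$edges$weight,
                   condition = rep_len(net$condition, n_e),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network in Simple Interaction Format
#'
#' One `node_a cor node_b` line per edge; isolated nodes are written as bare
#' single-node lines so the full node set round-trips.
#'
#' @param net a `condition_network`.
#' @param path output file.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "condition_network"))
  lines <- character(0)
  if (nrow(net$edges)) {
    lines <- sprintf("%s\tcor\t%s", net$edges$node_a, net$edges$node_b)
  }
  isolated <- setdiff(net$nodes$id, c(net$edges$node_a, net$edges$node_b))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Convert a condition network to an igraph object
#'
#' @param net a `condition_network`.
#' @return an undirected [igraph::igraph] graph with a `role` vertex
#'   attribute and a `weight` edge attribute.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "condition_network"))
  igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$node_a, to = net$edges$node_b,
                   weight = net$edges$weight, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = net$nodes
  )
}

#' Write a network as GraphML
#'
#' @param net a `condition_network`.
#' @param path output file.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
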