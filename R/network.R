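#' Assemble the kinship network
#'
#' Nodes are accessions; edges are typed: \code{po_oriented}
#' (parent -> offspring, from accepted trios), \code{po_unoriented}
#' (parent-offspring pairs never resolved in a trio) and
#' \code{full_sib}. A pair carries at most one edge; trio evidence
#' upgrades an unoriented parent-offspring edge to an oriented one. A
#' trio referencing a pair absent from the pairwise calls adds the edge
#' anyway, with a warning (trio evidence dominates).
#'
#' @param pair_calls an \code{\link{ibd_all_pairs}} result (or a
#'   data.frame with \code{a}, \code{b}, \code{call}).
#' @param accepted_trios data.frame with \code{p1}, \code{p2}, \code{f}
#'   (e.g. \code{search_trios()$accepted}).
#' @param full_sibs data.frame with \code{a}, \code{b}.
#' @param ancestry optional numeric matrix of ancestry proportions
#'   (rownames = accession ids), attached as vertex attributes
#'   \code{anc_<component>}.
#' @return an \pkg{igraph} directed graph; edge attribute \code{type}
#'   holds the edge type (direction is meaningful only for
#'   \code{po_oriented} edges: parent to offspring).
#' @export
build_kinship_graph <- function(pair_calls, accepted_trios = NULL,
                                full_sibs = NULL, ancestry = NULL) {
  po <- pair_calls[pair_calls$call == "parent_offspring", c("a", "b"),
                   drop = FALSE]
  edges <- data.frame(from = character(0), to = character(0),
                      type = character(0))
  pkey <- function(x, y) paste(pmin(x, y), pmax(x, y))
  oriented <- data.frame(from = character(0), to = character(0))
  if (!is.null(accepted_trios) && nrow(accepted_trios)) {
    oriented <- unique(rbind(
      data.frame(from = accepted_trios$p1, to = accepted_trios$f),
      data.frame(from = accepted_trios$p2, to = accepted_trios$f)))
    missing_pairs <- setdiff(pkey(oriented$from, oriented$to), pkey(po$a, po$b))
    if (length(missing_pairs))
      warning("trio-derived parent-offspring pair(s) absent from pairwise calls: ",
              paste(missing_pairs, collapse = "; "))
    edges <- rbind(edges, data.frame(oriented, type = "po_oriented"))
  }
  if (nrow(po)) {
    un <- po[!(pkey(po$a, po$b) %in% pkey(oriented$from, oriented$to)), ,
             drop = FALSE]
    if (nrow(un))
      edges <- rbind(edges, data.frame(from = un$a, to = un$b,
                                       type = "po_unoriented"))
  }
  if (!is.null(full_sibs) && nrow(full_sibs))
    edges <- rbind(edges, data.frame(from = full_sibs$a, to = full_sibs$b,
                                     type = "full_sib"))
  nodes <- unique(c(pair_calls$a, pair_calls$b, edges$from, edges$to))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  if (!is.null(ancestry)) {
    for (comp in colnames(ancestry)) {
      v <- ancestry[match(nodes, rownames(ancestry)), comp]
      g <- igraph::set_vertex_attr(g, paste0("anc_", comp), value = v)
    }
  }
  g
}

#' Descent group of a founder set
#'
#' All accessions connected to any founder through a chain of
#' parent-offspring edges (oriented or not, followed in either
#' direction), excluding the founders themselves. Full-sib edges are not
#' followed (full sibs of a descendant are connected through their
#' shared parents anyway when those are in the graph).
#'
#' @param graph a \code{\link{build_kinship_graph}} result.
#' @param founders character vector of founder ids.
#' @return character vector of descent-group member ids.
#' @export
descent_group <- function(graph, founders) {
  absent <- setdiff(founders, igraph::V(graph)$name)
  if (length(absent)) stop("unknown founder(s): ", paste(absent, collapse = ", "))
  keep <- igraph::E(graph)[igraph::E(graph)$type %in%
                           c("po_oriented", "po_unoriented")]
  sub <- igraph::subgraph_from_edges(graph, keep, delete.vertices = FALSE)
  reach <- unique(unlist(lapply(founders, function(fd)
    igraph::subcomponent(sub, fd, mode = "all")$name)))
  setdiff(reach, founders)
}

#' Export the kinship network
#'
#' Edge types travel as attributes in every format; the TSV edge list
#' (\code{from}, \code{to}, \code{type}) is the canonical plain-text
#' form and round-trips through \code{\link{read_kinship_graph}}.
#'
#' @param graph a \code{\link{build_kinship_graph}} result.
#' @param path output file.
#' @param format \code{"graphml"}, \code{"dot"} or \code{"tsv"}
#'   (default from the file extension, falling back to tsv).
#' @return \code{path}, invisibly.
#' @export
export_graph <- function(graph, path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("graphml", "dot", "gv", "tsv")) ext else "tsv"
    if (format == "gv") format <- "dot"
  }
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else if (format == "dot") {
    igraph::write_graph(graph, path, format = "dot")
  } else if (format == "tsv") {
    el <- igraph::as_data_frame(graph, what = "edges")
    data.table::fwrite(el[, c("from", "to", "type")], path, sep = "\t")
  } else stop("unknown format: ", format)
  invisible(path)
}

#' Read a kinship network from a TSV edge list or GraphML file
#' @param path file written by \code{\link{export_graph}}.
#' @return an \pkg{igraph} graph.
#' @export
read_kinship_graph <- function(path) {
  if (tolower(tools::file_ext(path)) == "graphml")
    return(igraph::read_graph(path, format = "graphml"))
  el <- data.table::fread(path, data.table = FALSE)
  igraph::graph_from_data_frame(el, directed = TRUE)
}
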