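#' Gene regulation network
#'
#' A directed labeled multigraph: nodes are normalized gene names, arcs are
#' `(agent, target, label)` triples with labels from the closed six-type
#' vocabulary (effect types `Activation`, `Inhibition`, `Requirement`,
#' `Regulation`; mechanism types `Binding`, `Transcription`). Several labels
#' may connect the same ordered gene pair; duplicate triples collapse to one
#' arc. Self-loops (autoregulation) are kept with a warning.
#'
#' @param arcs data.frame with character columns `agent`, `label`, `target`
#'   (may be empty).
#' @param nodes optional character vector of gene names; arc endpoints are
#'   always included.
#' @param check if `TRUE`, reject labels outside the six-type vocabulary
#'   (disabled internally for shape-transformed networks).
#' @return An object of class `grn_network`.
#' @export
grn_network <- function(arcs = NULL, nodes = character(), check = TRUE) {
  if (is.null(arcs) || nrow(arcs) == 0L) {
    arcs <- data.frame(agent = character(), label = character(),
                       target = character(), stringsAsFactors = FALSE)
  } else {
    arcs <- data.frame(agent = as.character(arcs$agent),
                       label = as.character(arcs$label),
                       target = as.character(arcs$target),
                       stringsAsFactors = FALSE)
    if (check && !all(arcs$label %in% GRN_INTERACTION_LABELS)) {
      bad <- setdiff(arcs$label, GRN_INTERACTION_LABELS)
      bt_stop("unknown interaction label '%s'", bad[1L],
              class = "bteval_label_error")
    }
    if (any(!nzchar(arcs$agent)) || any(!nzchar(arcs$target))) {
      bt_stop("empty gene name in arc list", class = "bteval_label_error")
    }
    arcs <- unique(arcs)
    if (any(arcs$agent == arcs$target)) {
      warning("network contains self-loop arc(s) (autoregulation)",
              call. = FALSE)
    }
    arcs <- arcs[order(arcs$agent, arcs$target, arcs$label), , drop = FALSE]
    rownames(arcs) <- NULL
  }
  nodes <- sort(unique(c(as.character(nodes), arcs$agent, arcs$target)))
  structure(list(nodes = nodes, arcs = arcs), class = "grn_network")
}

#' @export
print.grn_network <- function(x, ...) {
  cat(sprintf("<grn_network: %d node(s), %d arc(s)>\n", length(x$nodes),
              nrow(x$arcs)))
  if (nrow(x$arcs)) print(utils::head(x$arcs, 10))
  invisible(x)
}

arc_keys <- function(net) {
  if (nrow(net$arcs) == 0L) return(character())
  paste(net$arcs$agent, net$arcs$label, net$arcs$target, sep = "\r")
}

#' Read / write a network as a TSV arc list
#'
#' The submission format is one arc per line: `agent<TAB>label<TAB>target`.
#'
#' @param path file path.
#' @param net a [grn_network()].
#' @return `read_arc_list` returns a [grn_network()].
#' @export
read_arc_list <- function(path) {
  if (length(readLines(path, warn = FALSE)) == 0L) return(grn_network())
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("agent", "label", "target"),
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  grn_network(df)
}

#' @rdname read_arc_list
#' @export
write_arc_list <- function(net, path) {
  utils::write.table(net$arcs[, c("agent", "label", "target")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' @param net a [grn_network()].
#' @param path output path.
#' @export
write_graphml <- function(net, path) {
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$arcs)) {
    edges <- rbind(match(net$arcs$agent, net$nodes),
                   match(net$arcs$target, net$nodes))
    g <- igraph::add_edges(g, as.vector(edges), label = net$arcs$label)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Import a network from GraphML
#'
#' @param path GraphML file with a `label` edge attribute.
#' @return A [grn_network()].
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::V(g)$name
  if (igraph::ecount(g) == 0L) return(grn_network(nodes = nodes))
  el <- igraph::as_edgelist(g, names = TRUE)
  grn_network(data.frame(agent = el[, 1L],
                         label = igraph::E(g)$label,
                         target = el[, 2L], stringsAsFactors = FALSE),
              nodes = nodes)
}
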