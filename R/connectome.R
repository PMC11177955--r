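#' Construct a connectome (simple directed graph over named ROIs)
#'
#' A connectome is a simple digraph: unique node labels, no self-loops, no
#' duplicate arcs. Undirected anatomical edge lists are expanded to reciprocal
#' arc pairs at construction time, so every downstream algorithm operates on
#' digraphs.
#'
#' @param arcs a data frame with columns `from` and `to` (character). For
#'   `directed = FALSE` each row is an undirected edge and both orientations
#'   are added.
#' @param nodes optional character vector of node labels; defaults to
#'   first-appearance order in `arcs`. Isolated nodes must be declared here.
#' @param directed logical; is the input edge list directed?
#' @return an object of class `connectome` with fields `nodes` (ordered
#'   labels), `arcs` (tibble `from`, `to`) and `directed_input`.
#' @examples
#' g <- connectome(data.frame(from = "A", to = "B"), directed = FALSE)
#' n_arcs(g)  # 2: A->B and B->A
#' @export
connectome <- function(arcs, nodes = NULL, directed = TRUE) {
  arcs <- tibble::as_tibble(arcs)
  if (!all(c("from", "to") %in% names(arcs))) {
    stop("`arcs` must have columns `from` and `to`", call. = FALSE)
  }
  arcs$from <- as.character(arcs$from)
  arcs$to <- as.character(arcs$to)
  bad <- !nzchar(arcs$from) | !nzchar(arcs$to) | is.na(arcs$from) | is.na(arcs$to)
  if (any(bad)) {
    stop("blank or missing node label in edge row(s) ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  loops <- arcs$from == arcs$to
  if (any(loops)) {
    stop("self-loop in edge row(s) ", paste(which(loops), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(arcs$from, arcs$to, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate edge row(s) ", paste(which(duplicated(key)), collapse = ", "),
         call. = FALSE)
  }
  if (!directed) {
    arcs <- dplyr::bind_rows(arcs[c("from", "to")],
                             tibble::tibble(from = arcs$to, to = arcs$from))
    arcs <- dplyr::distinct(arcs)
  }
  seen <- unique(c(rbind(arcs$from, arcs$to)))
  if (is.null(nodes)) {
    nodes <- seen
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node labels", call. = FALSE)
    unknown <- setdiff(seen, nodes)
    if (length(unknown)) {
      stop("arc endpoint(s) not declared as nodes: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  arcs <- arcs[order(match(arcs$from, nodes), match(arcs$to, nodes)), c("from", "to")]
  structure(list(nodes = nodes, arcs = arcs, directed_input = directed),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d nodes, %d arcs (%s input)\n",
              n_nodes(x), n_arcs(x),
              if (x$directed_input) "directed" else "undirected"))
  cat("nodes:", paste(x$nodes, collapse = ", "), "\n")
  invisible(x)
}

#' Number of nodes / arcs of a connectome
#' @param g a `connectome`
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_arcs <- function(g) nrow(g$arcs)

stopifnot_connectome <- function(g) {
  if (!inherits(g, "connectome")) stop("expected a `connectome`", call. = FALSE)
  invisible(g)
}

#' Adjacency matrix of a connectome
#'
#' @param g a `connectome`
#' @return a 0/1 integer matrix with `A[i, j] = 1` iff arc i -> j exists.
#' @export
adjacency_matrix <- function(g) {
  stopifnot_connectome(g)
  n <- n_nodes(g)
  a <- matrix(0L, n, n, dimnames = list(g$nodes, g$nodes))
  a[cbind(match(g$arcs$from, g$nodes), match(g$arcs$to, g$nodes))] <- 1L
  a
}

#' Convert a connectome to an igraph object
#' @param g a `connectome`
#' @export
as_igraph <- function(g) {
  stopifnot_connectome(g)
  igraph::graph_from_data_frame(g$arcs, directed = TRUE,
                                vertices = data.frame(name = g$nodes))
}

#' Ordered node pairs with no arc (the non-edges E^C)
#'
#' Returns every ordered pair (i, j), i != j, for which the arc i -> j is
#' absent; these are the candidate arc additions of the edit program.
#' The count always satisfies `nrow == n(n-1) - m`.
#'
#' @param g a `connectome`
#' @return a tibble with columns `from`, `to`
#' @export
non_edges <- function(g) {
  stopifnot_connectome(g)
  all_pairs <- expand.grid(to = g$nodes, from = g$nodes,
                           stringsAsFactors = FALSE)[, c("from", "to")]
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  present <- paste(g$arcs$from, g$arcs$to, sep = "\r")
  keep <- !(paste(all_pairs$from, all_pairs$to, sep = "\r") %in% present)
  out <- tibble::as_tibble(all_pairs[keep, ])
  out[order(match(out$from, g$nodes), match(out$to, g$nodes)), ]
}

#' In-neighbour lists of a connectome
#' @param g a `connectome`
#' @return named list: for each node, the character vector of its in-neighbours
#'   (sources of arcs ending at the node), in node order.
#' @export
in_neighbours <- function(g) {
  stopifnot_connectome(g)
  out <- lapply(g$nodes, function(v) g$arcs$from[g$arcs$to == v])
  names(out) <- g$nodes
  out
}

#' Read an edge list from TSV
#'
#' The file must be tab-separated with a header naming columns `source` and
#' `target`; an optional `tract` annotation column is carried along but
#' ignored by all algorithms.
#'
#' @param path path to the TSV file
#' @param directed logical; if `FALSE`, each row is an undirected edge and is
#'   expanded into a reciprocal arc pair.
#' @return a `connectome`
#' @export
load_edge_list <- function(path, directed = TRUE) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!all(c("source", "target") %in% names(df))) {
    stop("edge list must have columns `source` and `target`", call. = FALSE)
  }
  connectome(data.frame(from = df$source, to = df$target), directed = directed)
}

#' Write a connectome as a TSV edge list
#'
#' For connectomes built from undirected input, each reciprocal arc pair is
#' written once; round-tripping with [load_edge_list()] recovers the same arc
#' set.
#'
#' @param g a `connectome`
#' @param path output path
#' @export
write_edge_list <- function(g, path) {
  stopifnot_connectome(g)
  df <- tibble::tibble(source = g$arcs$from, target = g$arcs$to)
  if (!g$directed_input) {
    keep <- match(df$source, g$nodes) < match(df$target, g$nodes) |
      !paste(df$target, df$source) %in% paste(df$source, df$target)
    df <- df[match(df$source, g$nodes) < match(df$target, g$nodes), ]
  }
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Induced subgraph after removing / adding arcs
#'
#' @param g a `connectome`
#' @param remove data frame of arcs (`from`, `to`) to delete
#' @param add data frame of arcs to insert
#' @return a `connectome` over the same node set
#' @export
edit_arcs <- function(g, remove = NULL, add = NULL) {
  stopifnot_connectome(g)
  arcs <- g$arcs
  if (!is.null(remove) && nrow(remove)) {
    drop <- paste(arcs$from, arcs$to) %in% paste(remove$from, remove$to)
    arcs <- arcs[!drop, ]
  }
  if (!is.null(add) && nrow(add)) {
    arcs <- dplyr::bind_rows(arcs, tibble::as_tibble(add)[, c("from", "to")])
  }
  connectome(arcs, nodes = g$nodes, directed = TRUE)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.connectome <- function(x, ...) x$arcs
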