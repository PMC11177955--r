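#' Cluster PLV of a node set
#'
#' The Cluster PLV of a candidate synchronization clique is the arithmetic
#' mean of its `N(N-1)/2` pairwise PLV entries; it measures the strength of
#' within-cluster synchronization and ranks the clique hierarchy.
#'
#' @param m a `plv_matrix`
#' @param members character vector of at least two ROI labels
#' @return the mean pairwise PLV
#' @export
cluster_plv <- function(m, members) {
  if (!inherits(m, "plv_matrix")) stop("expected a `plv_matrix`", call. = FALSE)
  unknown <- setdiff(members, m$roi_labels)
  if (length(unknown)) stop("unknown ROI label(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  if (length(members) < 2L) stop("need at least 2 members", call. = FALSE)
  sub <- m$values[members, members]
  mean(sub[upper.tri(sub)])
}

# does `members` satisfy the cluster-synchronization clique condition?
# mean intra-pair PLV >= every PLV from a member to an outside node, with
# sigma read from the full matrix. Cliques spanning every node have an empty
# boundary set, which leaves the condition undefined; they are not acceptable.
cs_condition <- function(m, members) {
  outside <- setdiff(m$roi_labels, members)
  if (!length(outside)) return(FALSE)
  cluster_plv(m, members) >= max(m$values[members, outside]) - 1e-12
}

#' Detect cluster-synchronization cliques by percolation
#'
#' Implements the percolation procedure on a complete synchronization matrix:
#' distinct PLV weights are processed in decreasing order (equal weights enter
#' as one batch); after each batch, every newly formed maximal clique of the
#' accumulated graph is tested against the cluster-synchronization condition
#' -- the mean intra-clique PLV must be at least the largest PLV from any
#' member to any non-member, with boundary values read from the full matrix.
#' An accepted clique is frozen but may still grow: a later accepted clique
#' that strictly contains one or more accepted cliques supersedes them,
#' whereas a candidate that would steal only part of a frozen clique is
#' rejected. Percolation stops when the accepted cliques cover every node
#' (further weights can no longer form new cliques among unfrozen nodes) or
#' when the weights are exhausted. The final hierarchy is the accepted pool
#' ordered by decreasing Cluster PLV, then decreasing size, then smallest
#' member label.
#'
#' @param m a `plv_matrix` over at least 3 ROIs
#' @return an object of class `cs_result`: list with `cliques` (list of
#'   `members` + `cluster_plv`, in rank order), `interclique_links` (tibble of
#'   the strongest PLV entry between each pair of finalized cliques),
#'   `unassigned` (nodes in no clique).
#' @export
detect_cs <- function(m) {
  if (!inherits(m, "plv_matrix")) stop("expected a `plv_matrix`", call. = FALSE)
  labs <- m$roi_labels
  n <- length(labs)
  if (n < 3L) stop("need at least 3 ROIs", call. = FALSE)
  ut <- which(upper.tri(m$values), arr.ind = TRUE)
  edges <- tibble::tibble(a = labs[ut[, 1L]], b = labs[ut[, 2L]],
                          w = m$values[ut])
  weights <- sort(unique(edges$w), decreasing = TRUE)
  accepted <- list()     # named by member-key; kept pairwise disjoint
  tested <- character(0) # each clique is judged once, at its formation batch
  added <- edges[0, ]
  for (w in weights) {
    added <- dplyr::bind_rows(added, edges[edges$w == w, ])
    gr <- igraph::graph_from_data_frame(added[, c("a", "b")], directed = FALSE,
                                        vertices = data.frame(name = labs))
    cliques <- lapply(igraph::max_cliques(gr, min = 2L),
                      function(cl) sort(igraph::V(gr)$name[cl]))
    cliques <- cliques[lengths(cliques) < n]
    if (length(cliques)) {
      ord <- order(-vapply(cliques, function(mem) cluster_plv(m, mem), 0),
                   -lengths(cliques),
                   vapply(cliques, `[`, "", 1L))
      for (members in cliques[ord]) {
        key <- paste(members, collapse = "\r")
        if (key %in% tested) next
        tested <- c(tested, key)
        if (!cs_condition(m, members)) next
        overlapping <- names(accepted)[vapply(accepted, function(c2)
          any(c2 %in% members), TRUE)]
        subsumed <- vapply(overlapping, function(k2)
          all(accepted[[k2]] %in% members), TRUE)
        if (length(overlapping) && !all(subsumed)) next  # would break a frozen clique
        for (k2 in overlapping) accepted[[k2]] <- NULL   # growth / merger by superset
        accepted[[key]] <- members
      }
    }
    if (length(setdiff(labs, unlist(accepted))) == 0L) break
  }
  final <- lapply(accepted, function(mem) {
    list(members = mem, cluster_plv = cluster_plv(m, mem))
  })
  ord <- order(-vapply(final, `[[`, 0, "cluster_plv"),
               -lengths(lapply(final, `[[`, "members")),
               vapply(final, function(x) x$members[1L], ""))
  final <- unname(final[ord])
  taken <- unlist(lapply(final, `[[`, "members"))
  inter <- list()
  if (length(final) >= 2L) {
    for (i in seq_len(length(final) - 1L)) {
      for (j in seq.int(i + 1L, length(final))) {
        sub <- m$values[final[[i]]$members, final[[j]]$members, drop = FALSE]
        top <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
        inter[[length(inter) + 1L]] <- tibble::tibble(
          node_a = final[[i]]$members[top[1L]],
          node_b = final[[j]]$members[top[2L]],
          plv = max(sub))
      }
    }
  }
  inter <- if (length(inter)) dplyr::arrange(dplyr::bind_rows(inter),
                                             dplyr::desc(.data$plv)) else
    tibble::tibble(node_a = character(), node_b = character(), plv = numeric())
  structure(list(cliques = final,
                 interclique_links = inter,
                 unassigned = setdiff(labs, taken),
                 roi_labels = labs),
            class = "cs_result")
}

#' @export
print.cs_result <- function(x, ...) {
  cat(sprintf("<cs_result> %d clique(s), %d unassigned node(s)\n",
              length(x$cliques), length(x$unassigned)))
  for (i in seq_along(x$cliques)) {
    cl <- x$cliques[[i]]
    cat(sprintf("  %d. {%s}  Cluster PLV = %.3f\n", i,
                paste(cl$members, collapse = ", "), cl$cluster_plv))
  }
  if (length(x$unassigned)) {
    cat("  unassigned:", paste(x$unassigned, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.cs_result <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$cliques), function(i) {
    tibble::tibble(rank = i, node = x$cliques[[i]]$members,
                   cluster_plv = x$cliques[[i]]$cluster_plv,
                   size = length(x$cliques[[i]]$members))
  }))
}

#' @export
glance.cs_result <- function(x, ...) {
  tibble::tibble(n_cliques = length(x$cliques),
                 n_assigned = length(x$roi_labels) - length(x$unassigned),
                 n_unassigned = length(x$unassigned),
                 top_cluster_plv = if (length(x$cliques))
                   x$cliques[[1L]]$cluster_plv else NA_real_)
}

#' @export
autoplot.cs_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$rank),
                                   y = .data$cluster_plv)) +
    ggplot2::geom_col(ggplot2::aes(fill = factor(.data$rank)),
                      width = 0.7, show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$node),
                       position = ggplot2::position_stack(vjust = 0.5),
                       size = 2.8, check_overlap = TRUE) +
    ggplot2::labs(x = "clique rank", y = "Cluster PLV") +
    ggplot2::theme_minimal()
}

#' Serialize / read a CS result as JSON
#' @param r a `cs_result`
#' @param path output path
#' @export
write_cs_result <- function(r, path) {
  jsonlite::write_json(list(
    cliques = lapply(r$cliques, function(cl)
      list(members = cl$members, cluster_plv = cl$cluster_plv)),
    interclique_links = r$interclique_links,
    unassigned = r$unassigned,
    rank_order = vapply(r$cliques, function(cl)
      paste(cl$members, collapse = "+"), "")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Convert a CS result into a node coloring
#'
#' Each finalized clique becomes one colour class; every unassigned node
#' becomes its own singleton class. The result is the target coloring fed to
#' the structural edit program.
#'
#' @param r a `cs_result`
#' @param nodes the full node label set to colour
#' @return a `roi_coloring`
#' @export
cs_to_coloring <- function(r, nodes) {
  members <- unlist(lapply(r$cliques, `[[`, "members"))
  if (!all(members %in% nodes)) stop("clique members outside node set", call. = FALSE)
  classes <- lapply(r$cliques, `[[`, "members")
  singletons <- setdiff(nodes, members)
  classes <- c(classes, as.list(singletons))
  roi_coloring(classes)
}
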