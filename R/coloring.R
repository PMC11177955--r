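#' Construct a node coloring (partition of ROI labels)
#'
#' A coloring partitions a node set into disjoint, non-empty colour classes.
#' Classes are stored in canonical order: decreasing size, ties broken by the
#' lexicographically smallest member label. The same container holds target
#' colorings from cluster synchronization, fiber partitions, and orbit
#' partitions.
#'
#' @param classes a list of character vectors (one per class), optionally named
#' @return an object of class `roi_coloring`
#' @export
roi_coloring <- function(classes) {
  if (!length(classes)) stop("coloring must have at least one class", call. = FALSE)
  classes <- lapply(classes, function(x) sort(as.character(x)))
  if (any(lengths(classes) == 0)) stop("empty colour class", call. = FALSE)
  all_nodes <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(all_nodes)) {
    stop("node(s) assigned to more than one colour: ",
         paste(unique(all_nodes[duplicated(all_nodes)]), collapse = ", "),
         call. = FALSE)
  }
  ord <- order(-lengths(classes), vapply(classes, `[`, "", 1L))
  classes <- classes[ord]
  if (is.null(names(classes)) || any(!nzchar(names(classes)))) {
    names(classes) <- paste0("c", seq_along(classes))
  }
  structure(list(classes = classes), class = "roi_coloring")
}

#' @export
print.roi_coloring <- function(x, ...) {
  cat(sprintf("<roi_coloring> %d classes over %d nodes\n",
              n_classes(x), length(unlist(x$classes))))
  for (nm in names(x$classes)) {
    cat(" ", nm, ": {", paste(x$classes[[nm]], collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}

#' Number of classes of a coloring
#' @param c a `roi_coloring`
#' @export
n_classes <- function(c) length(c$classes)

#' Class membership as a named vector
#' @param c a `roi_coloring`
#' @return named character vector mapping node label to class name
#' @export
membership <- function(c) {
  out <- rep(names(c$classes), lengths(c$classes))
  names(out) <- unlist(c$classes, use.names = FALSE)
  out
}

#' @export
tidy.roi_coloring <- function(x, ...) {
  tibble::tibble(node = unlist(x$classes, use.names = FALSE),
                 class = rep(names(x$classes), lengths(x$classes)))
}

#' Do two colorings induce the same partition?
#'
#' Compares the partitions up to class relabeling.
#' @param a,b `roi_coloring` objects
#' @export
same_partition <- function(a, b) {
  key <- function(x) {
    unname(sort(vapply(x$classes, function(cl) paste(cl, collapse = "\r"), "")))
  }
  identical(key(a), key(b))
}

#' Check that a coloring partitions a connectome's node set
#'
#' @param c a `roi_coloring`
#' @param g a `connectome`
#' @return invisibly `c`; errors when the coloring references unknown nodes or
#'   fails to cover the graph.
#' @export
bind_coloring <- function(c, g) {
  stopifnot_connectome(g)
  nodes <- unlist(c$classes, use.names = FALSE)
  extra <- setdiff(nodes, g$nodes)
  if (length(extra)) {
    stop("coloring references unknown node(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(g$nodes, nodes)
  if (length(missing)) {
    stop("coloring does not cover node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(c)
}

#' Read a coloring from JSON or two-column TSV
#'
#' JSON files map colour name to a list of node labels. TSV files have a
#' header `node<TAB>color`.
#'
#' @param path file path (`.json`, or anything else treated as TSV)
#' @return a `roi_coloring`
#' @export
load_coloring <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    classes <- lapply(raw, as.character)
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    if (!all(c("node", "color") %in% names(df))) {
      stop("coloring TSV must have columns `node` and `color`", call. = FALSE)
    }
    classes <- split(df$node, df$color)
  }
  roi_coloring(classes)
}

#' Write a coloring to JSON
#' @param c a `roi_coloring`
#' @param path output path
#' @export
write_coloring <- function(c, path) {
  jsonlite::write_json(c$classes, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
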