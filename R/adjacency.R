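#' District adjacency graphs
#'
#' Areal models in this package need to know which districts border which.
#' A `zi_graph` stores a symmetric, binary (0/1) neighbourhood structure:
#' a node per district, an edge per unordered pair of adjacent districts,
#' and the per-node neighbour count \eqn{m_i = \sum_{i \sim i'} \omega_{ii'}}.
#'
#' @param neighbors named list; element `i` holds the character vector of
#'   node names adjacent to node `i`. Missing reciprocal entries are added
#'   (symmetrisation) with a warning.
#' @return an object of class `zi_graph` with elements `nodes` (character),
#'   `nb` (list of integer neighbour indices), `m` (integer neighbour counts)
#'   and `edges` (two-column integer matrix, one row per unordered edge).
#' @export
as_zi_graph <- function(neighbors) {
  if (is.null(names(neighbors)) || any(!nzchar(names(neighbors)))) {
    stop("`neighbors` must be a fully named list (one element per node)")
  }
  nodes <- names(neighbors)
  all_named <- unique(unlist(neighbors, use.names = FALSE))
  unknown <- setdiff(all_named, nodes)
  if (length(unknown) > 0) {
    stop("neighbor list names unknown node(s): ", paste(unknown, collapse = ", "))
  }
  n <- length(nodes)
  nb <- lapply(neighbors, function(v) sort(match(unique(v), nodes)))
  # symmetrise
  asym <- FALSE
  for (i in seq_len(n)) {
    for (j in nb[[i]]) {
      if (j == i) stop("self-adjacency (loop) at node ", nodes[i])
      if (!(i %in% nb[[j]])) {
        nb[[j]] <- sort(c(nb[[j]], i))
        asym <- TRUE
      }
    }
  }
  if (asym) warning("adjacency input was asymmetric; symmetrised")
  m <- vapply(nb, length, integer(1))
  if (any(m == 0)) {
    warning("isolated node(s) with no neighbors: ",
            paste(nodes[m == 0], collapse = ", "))
  }
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    js <- nb[[i]][nb[[i]] > i]
    if (length(js) == 0) NULL else cbind(i, js)
  }))
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
  dimnames(edges) <- list(NULL, c("i", "j"))
  structure(
    list(nodes = nodes, nb = unname(nb), m = unname(m), edges = edges),
    class = "zi_graph"
  )
}

#' @export
print.zi_graph <- function(x, ...) {
  cat("<zi_graph> ", length(x$nodes), " districts, ", nrow(x$edges),
      " edges; neighbour counts ", min(x$m), "-", max(x$m), "\n", sep = "")
  invisible(x)
}

#' Number of districts in a graph
#' @param graph a `zi_graph`
#' @return integer
#' @export
n_districts <- function(graph) length(graph$nodes)

#' Binary adjacency matrix of a graph
#'
#' @param graph a `zi_graph`
#' @param sparse return a `Matrix::sparseMatrix` instead of a base matrix
#' @return symmetric 0/1 matrix with zero diagonal, dimnames = node names
#' @export
adjacency_matrix <- function(graph, sparse = FALSE) {
  n <- length(graph$nodes)
  if (sparse) {
    e <- graph$edges
    W <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                              x = 1, dims = c(n, n),
                              dimnames = list(graph$nodes, graph$nodes))
    return(W)
  }
  W <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges) > 0) {
    W[graph$edges] <- 1
    W[graph$edges[, 2:1, drop = FALSE]] <- 1
  }
  W
}

#' Graph Laplacian D - W
#' @param graph a `zi_graph`
#' @return symmetric matrix `diag(m) - W`
#' @export
graph_laplacian <- function(graph) {
  diag(graph$m, n_districts(graph)) - adjacency_matrix(graph)
}

#' Is the graph connected?
#' @param graph a `zi_graph`
#' @return logical
#' @export
is_connected <- function(graph) {
  n <- n_districts(graph)
  if (n == 0) return(TRUE)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack) > 0) {
    i <- stack[[1L]]
    stack <- stack[-1L]
    for (j in graph$nb[[i]]) {
      if (!seen[j]) {
        seen[j] <- TRUE
        stack <- c(stack, j)
      }
    }
  }
  all(seen)
}

#' Rook-adjacency lattice graph
#'
#' Regular `rows` x `cols` grid of districts where each cell is adjacent to
#' its horizontal and vertical neighbours. Used as a stand-in district map in
#' simulation studies; real analyses supply their own neighbour list.
#'
#' @param rows,cols positive integers
#' @return a `zi_graph` with `rows * cols` nodes named `d001`, `d002`, ...
#'   (row-major order) and `2*rows*cols - rows - cols` edges
#' @export
make_lattice_graph <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  n <- rows * cols
  idx <- function(r, c) (r - 1L) * cols + c
  nodes <- sprintf("d%03d", seq_len(n))
  nbs <- vector("list", n)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      i <- idx(r, c)
      js <- c(if (r > 1) idx(r - 1L, c), if (r < rows) idx(r + 1L, c),
              if (c > 1) idx(r, c - 1L), if (c < cols) idx(r, c + 1L))
      nbs[[i]] <- nodes[js]
    }
  }
  names(nbs) <- nodes
  as_zi_graph(nbs)
}

#' Read a neighbour-list file
#'
#' Plain-text format: one line per district, `node: neighbor neighbor ...`.
#' Every node must have its own line (possibly with no neighbours listed);
#' neighbours naming a node without a line of its own are an error.
#' Asymmetric listings are symmetrised with a warning and isolated nodes are
#' flagged.
#'
#' @param path file path
#' @return a `zi_graph`
#' @export
read_adjacency <- function(path) {
  if (!file.exists(path)) stop("adjacency file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("adjacency file is empty: ", path)
  parts <- strsplit(lines, ":", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 1
  nodes <- trimws(vapply(parts, `[[`, character(1), 1))
  if (anyDuplicated(nodes)) {
    stop("duplicate node line(s): ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  nbs <- lapply(parts, function(p) {
    if (length(p) < 2) return(character(0))
    v <- strsplit(trimws(p[[2]]), "[[:space:]]+")[[1]]
    v[nzchar(v)]
  })
  names(nbs) <- nodes
  unknown <- setdiff(unique(unlist(nbs)), nodes)
  if (length(unknown) > 0) {
    stop("adjacency file names unknown node(s): ", paste(unknown, collapse = ", "))
  }
  as_zi_graph(nbs)
}

#' Write a neighbour-list file
#' @param graph a `zi_graph`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_adjacency <- function(graph, path) {
  lines <- vapply(seq_along(graph$nodes), function(i) {
    paste0(graph$nodes[i], ": ",
           paste(graph$nodes[graph$nb[[i]]], collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
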