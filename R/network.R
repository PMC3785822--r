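#' Undirected interaction network
#'
#' A simple undirected graph on units `1..n_units` (1-based internally;
#' edge-list files use 0-based ids, see [write_edge_list()]). Self-loops and
#' parallel edges are rejected at construction.
#'
#' @param edges Two-column integer matrix of unit-id pairs (1-based).
#' @param n_units Number of units; defaults to the largest id present.
#' @return An object of class `interaction_network` with fields `n_units`,
#'   `edges` (canonicalized, smaller id first, ordered), `degrees`,
#'   `adjacency` (list of neighbour-id vectors).
#' @export
interaction_network <- function(edges, n_units = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (is.null(n_units)) n_units <- if (nrow(edges)) max(edges) else 0L
  n_units <- as.integer(n_units)
  if (nrow(edges)) {
    if (any(edges < 1L) || any(edges > n_units))
      stop("edge endpoints must be unit ids in 1..n_units")
    if (any(edges[, 1] == edges[, 2]))
      stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    key <- (edges[, 1] - 1) * as.double(n_units) + edges[, 2]
    if (anyDuplicated(key)) stop("parallel edges are not allowed")
    edges <- edges[order(key), , drop = FALSE]
  }
  degrees <- tabulate(c(edges[, 1], edges[, 2]), nbins = n_units)
  adjacency <- vector("list", n_units)
  if (nrow(edges)) {
    ends <- c(edges[, 2], edges[, 1])
    adjacency <- split(ends, factor(c(edges[, 1], edges[, 2]),
                                    levels = seq_len(n_units)))
    adjacency <- lapply(adjacency, as.integer)
  } else {
    adjacency <- rep(list(integer(0)), n_units)
  }
  structure(list(n_units = n_units, edges = edges,
                 degrees = as.integer(degrees), adjacency = adjacency),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d units, %d edges, degrees %d..%d\n",
              x$n_units, nrow(x$edges), min(x$degrees), max(x$degrees)))
  invisible(x)
}

#' Degree lookup
#' @param network An [interaction_network()].
#' @param units Unit ids (1-based); defaults to all.
#' @return Integer degrees.
#' @export
degree_of <- function(network, units = seq_len(network$n_units)) {
  network$degrees[units]
}

#' Validate network invariants by recount
#'
#' Recounts degrees from the edge set and re-checks simplicity. Stops on any
#' violation; used by tests and after graph repair.
#' @param network An [interaction_network()].
#' @return `TRUE` invisibly.
#' @export
validate_network <- function(network) {
  e <- network$edges
  if (any(e[, 1] == e[, 2])) stop("self-loop present")
  key <- (e[, 1] - 1) * as.double(network$n_units) + e[, 2]
  if (anyDuplicated(key)) stop("parallel edge present")
  recount <- tabulate(c(e[, 1], e[, 2]), nbins = network$n_units)
  if (!identical(as.integer(recount), network$degrees))
    stop("stored degrees do not match edge incidence")
  if (sum(recount) %% 2L != 0L) stop("odd total degree")
  invisible(TRUE)
}

#' Configuration-model graph with an exact degree sequence
#'
#' Realizes the given degree sequence as a simple undirected graph by stub
#' matching followed by double-edge-swap repair of self-loops and parallel
#' edges. Rejection of whole defective graphs is avoided because it is
#' infeasible for heavy-tailed sequences; instead each defective edge is
#' repeatedly swapped against a uniformly chosen partner edge until the graph
#' is simple. The resulting degree sequence equals the input exactly.
#'
#' @param degrees Integer degree per unit; the sum must be even and the
#'   maximum degree less than the number of units.
#' @param max_retries Number of fresh stub matchings attempted before giving
#'   up (each matching gets a bounded swap budget).
#' @return An [interaction_network()]; the number of repair swaps performed
#'   is recorded in the `"repair_swaps"` attribute and the number of stub
#'   matchings in `"matchings"`.
#' @export
build_configuration_graph <- function(degrees, max_retries = 100L) {
  degrees <- as.integer(degrees)
  n <- length(degrees)
  if (n < 2L) stop("need at least two units")
  if (any(degrees < 0L)) stop("degrees must be nonnegative")
  if (sum(degrees) %% 2L != 0L)
    stop("odd degree sum: no graph realizes this sequence")
  if (max(degrees) >= n)
    stop("maximum degree must be < number of units for a simple graph")
  if (!igraph::is_graphical(degrees))
    stop(sprintf("degree sequence is not graphical (n = %d, max = %d)",
                 n, max(degrees)))
  stubs <- rep.int(seq_len(n), degrees)
  for (attempt in seq_len(max_retries)) {
    res <- .stub_match_and_repair(stubs, n)
    if (!is.null(res)) {
      net <- interaction_network(res$edges, n_units = n)
      if (!identical(net$degrees, degrees))
        stop("internal error: repaired graph degree sequence mismatch")
      attr(net, "repair_swaps") <- res$swaps
      attr(net, "matchings") <- attempt
      return(net)
    }
  }
  stop(sprintf(
    "configuration-model repair failed after %d matchings for sequence with n = %d, sum = %d, max = %d",
    max_retries, n, sum(degrees), max(degrees)))
}

# One stub matching plus bounded double-edge-swap repair. Returns NULL if the
# swap budget is exhausted before the graph is simple.
.stub_match_and_repair <- function(stubs, n) {
  perm <- sample(stubs)
  m <- length(perm) %/% 2L
  if (m == 0L) return(list(edges = matrix(integer(0), ncol = 2), swaps = 0L))
  a <- perm[seq.int(1L, 2L * m, 2L)]
  b <- perm[seq.int(2L, 2L * m, 2L)]
  edges <- cbind(pmin(a, b), pmax(a, b))
  keys <- (edges[, 1] - 1) * as.double(n) + edges[, 2]
  swaps <- 0L
  budget <- 200L * m + 10000L
  repeat {
    bad <- which(edges[, 1] == edges[, 2] | duplicated(keys))
    if (!length(bad)) return(list(edges = edges, swaps = swaps))
    d <- bad[1L]
    repaired <- FALSE
    for (try in seq_len(200L)) {
      budget <- budget - 1L
      if (budget <= 0L) return(NULL)
      f <- sample.int(m, 1L)
      if (f == d) next
      # swap the second endpoints of edges d and f
      n1 <- c(edges[d, 1], edges[f, 2]); n1 <- c(min(n1), max(n1))
      n2 <- c(edges[f, 1], edges[d, 2]); n2 <- c(min(n2), max(n2))
      if (n1[1] == n1[2] || n2[1] == n2[2]) next
      k1 <- (n1[1] - 1) * as.double(n) + n1[2]
      k2 <- (n2[1] - 1) * as.double(n) + n2[2]
      if (k1 == k2) next
      other <- keys[-c(d, f)]
      if (k1 %in% other || k2 %in% other) next
      edges[d, ] <- n1; edges[f, ] <- n2
      keys[d] <- k1; keys[f] <- k2
      swaps <- swaps + 1L
      repaired <- TRUE
      break
    }
    if (!repaired) return(NULL)
  }
}

#' Convert to an igraph object
#' @param network An [interaction_network()].
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_edgelist(network$edges, directed = FALSE)
}

#' Read / write an edge-list file
#'
#' Two whitespace-separated 0-based integer columns, one undirected edge per
#' line, no header, smaller id first. Internal unit ids are 1-based; the file
#' format is 0-based for stable interchange with other tools.
#'
#' @param network An [interaction_network()].
#' @param path File path.
#' @param n_units Number of units when reading (defaults to max id + 1).
#' @return `write_edge_list` returns `path` invisibly; `read_edge_list`
#'   returns an [interaction_network()].
#' @export
write_edge_list <- function(network, path) {
  e <- network$edges - 1L
  utils::write.table(e, path, row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, n_units = NULL) {
  e <- as.matrix(utils::read.table(path, header = FALSE,
                                   colClasses = "integer"))
  if (ncol(e) != 2L) stop("edge-list file must have exactly two columns")
  interaction_network(e + 1L, n_units = n_units)
}
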