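#' Toy networks for exact-oracle work
#'
#' Small named graphs used throughout the test suite and by
#' [cmd_make_fixtures()]: a star (one hub plus leaves), a path, a triangle
#' and a small Erdos-Renyi-type random simple graph (resampled until no unit
#' is isolated).
#'
#' @param n_leaves Number of leaves of the star (hub is unit 1).
#' @return An [interaction_network()].
#' @export
make_star_network <- function(n_leaves = 5L) {
  interaction_network(cbind(1L, seq_len(n_leaves) + 1L),
                      n_units = n_leaves + 1L)
}

#' @rdname make_star_network
#' @param n_units Number of units of the path.
#' @export
make_path_network <- function(n_units = 5L) {
  stopifnot(n_units >= 2L)
  interaction_network(cbind(seq_len(n_units - 1L), seq_len(n_units - 1L) + 1L),
                      n_units = n_units)
}

#' @rdname make_star_network
#' @export
make_triangle_network <- function() {
  interaction_network(rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L)), n_units = 3L)
}

#' @rdname make_star_network
#' @param n Number of units of the random graph.
#' @param p_edge Independent edge probability.
#' @export
make_random_network <- function(n = 8L, p_edge = 0.4) {
  pairs <- t(utils::combn(n, 2L))
  repeat {
    keep <- stats::runif(nrow(pairs)) < p_edge
    net <- interaction_network(pairs[keep, , drop = FALSE], n_units = n)
    if (all(net$degrees >= 1L)) return(net)
  }
}

#' Standard fixture set
#'
#' @return Named list of the four toy networks used by the oracle-equivalence
#'   checks: `star6`, `path5`, `triangle`, `random8` (the random graph uses
#'   the current RNG stream).
#' @export
fixture_networks <- function() {
  list(star6 = make_star_network(5L),
       path5 = make_path_network(5L),
       triangle = make_triangle_network(),
       random8 = make_random_network(8L, 0.4))
}
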