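#' Discrete degree distribution
#'
#' A probability table `p(k)` over integer node degrees. The same container
#' holds excess degree distributions `q(m)` (which may have mass at `m = 0`),
#' distinguished by `kind`.
#'
#' @param support Integer degrees with positive probability. Must be distinct;
#'   at least 1 for `kind = "degree"`, at least 0 for `kind = "excess"`.
#' @param probs Probabilities per degree; must be nonnegative and sum to 1
#'   within `1e-12`.
#' @param gamma Optional power-law exponent recorded as provenance when the
#'   table was built from `p(k) ~ k^-gamma`.
#' @param kind `"degree"` for an ordinary degree distribution, `"excess"` for
#'   the distribution of additional edges seen by following a random edge.
#' @return An object of class `degree_distribution` with fields `support`,
#'   `probs`, `gamma`, `k_min`, `k_max`, `kind`.
#' @seealso [power_law_distribution()], [excess_degree_distribution()]
#' @export
degree_distribution <- function(support, probs, gamma = NULL,
                                kind = c("degree", "excess")) {
  kind <- match.arg(kind)
  if (length(support) != length(probs) || length(support) == 0L)
    stop("support and probs must be non-empty and of equal length")
  if (any(support != round(support)))
    stop("support must contain integers")
  support <- as.integer(round(support))
  if (anyDuplicated(support)) stop("support values must be distinct")
  min_k <- if (kind == "degree") 1L else 0L
  if (any(support < min_k))
    stop(sprintf("all support values must be >= %d for kind '%s'", min_k, kind))
  if (any(probs < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(probs) - 1) > 1e-12)
    stop("probabilities must sum to 1 within 1e-12")
  ord <- order(support)
  structure(
    list(support = support[ord], probs = as.numeric(probs)[ord],
         gamma = gamma, k_min = min(support), k_max = max(support),
         kind = kind),
    class = "degree_distribution"
  )
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf("<degree_distribution (%s)> support %d..%d, %d atoms",
              x$kind, x$k_min, x$k_max, length(x$support)))
  if (!is.null(x$gamma)) cat(sprintf(", gamma = %g", x$gamma))
  cat("\n")
  invisible(x)
}

#' Truncated power-law degree distribution
#'
#' Builds the normalized table `p(k) ~ k^-gamma` on `k_min..k_max`, the
#' degree law of the heavy-tailed ensembles studied here.
#'
#' @param gamma Power-law exponent, `> 0`.
#' @param k_min,k_max Inclusive integer degree bounds, `1 <= k_min <= k_max`.
#' @return A [degree_distribution()].
#' @export
power_law_distribution <- function(gamma, k_min = 1L, k_max) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma > 0)
  if (k_min < 1 || k_min > k_max) stop("need 1 <= k_min <= k_max")
  k <- seq.int(k_min, k_max)
  w <- k^(-gamma)
  degree_distribution(k, w / sum(w), gamma = gamma)
}

#' Mean of a degree distribution
#' @param p A [degree_distribution()].
#' @return The expected degree `sum(k * p(k))`.
#' @export
mean_degree <- function(p) {
  stopifnot(inherits(p, "degree_distribution"))
  sum(p$support * p$probs)
}

#' Excess degree distribution
#'
#' Distribution `q(m) = (m + 1) p(m + 1) / <k>` of the number of edges of a
#' node reached by following a random edge, besides the edge it was reached
#' by. This is the weight with which neighbour degrees enter every
#' edge-averaged quantity on a configuration-model (locally tree-like)
#' network, because neighbour degrees are size-biased and do not depend on
#' the degree of the unit itself.
#'
#' @param p A [degree_distribution()] of kind `"degree"` with positive mean.
#' @return A [degree_distribution()] of kind `"excess"` with support
#'   `p$support - 1`.
#' @export
excess_degree_distribution <- function(p) {
  stopifnot(inherits(p, "degree_distribution"))
  if (p$kind != "degree") stop("p must be an ordinary degree distribution")
  kbar <- mean_degree(p)
  if (kbar <= 0) stop("degree distribution has zero mean degree")
  q <- p$support * p$probs / kbar
  degree_distribution(p$support - 1L, q / sum(q), gamma = p$gamma,
                      kind = "excess")
}

#' Sample a power-law degree sequence
#'
#' Draws `n` i.i.d. degrees from the normalized `k^-gamma` table on
#' `[k_min, k_max]`. If the total is odd (no graph exists, by the handshake
#' lemma), the last entry is resampled until the total is even; the number of
#' resampling draws is recorded in the `"odd_sum_resamples"` attribute so run
#' logs can report the adjustment.
#'
#' @param n Number of units, `>= 2`.
#' @param gamma Power-law exponent, `> 0`.
#' @param k_min Minimum degree (default 1).
#' @param k_max Maximum degree; defaults to `floor(sqrt(n))`, which keeps the
#'   maximum degree sublinear in the network size as the locally-tree-like
#'   assumption requires. Must satisfy `k_max < n`.
#' @return Integer vector of length `n` with even sum, with attributes
#'   `gamma`, `k_min`, `k_max`, `odd_sum_resamples`.
#' @export
sample_power_law_degrees <- function(n, gamma, k_min = 1L, k_max = NULL) {
  if (length(n) != 1L || !is.numeric(n) || n != round(n))
    stop("n must be a single integer")
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  if (is.null(k_max)) k_max <- max(k_min, floor(sqrt(n)))
  if (k_max >= n) stop("k_max must be < n for a simple graph to exist")
  p <- power_law_distribution(gamma, k_min, k_max)
  degs <- sample(p$support, n, replace = TRUE, prob = p$probs)
  resamples <- 0L
  if (length(p$support) == 1L && sum(degs) %% 2L == 1L)
    stop("degree sum is odd and cannot be repaired: single-atom support")
  while (sum(degs) %% 2L == 1L) {
    degs[n] <- sample(p$support, 1L, prob = p$probs)
    resamples <- resamples + 1L
    if (resamples > 10000L)
      stop("could not repair odd degree sum by resampling")
  }
  structure(as.integer(degs), gamma = gamma, k_min = as.integer(k_min),
            k_max = as.integer(k_max), odd_sum_resamples = resamples)
}

#' Read / write a degree-distribution table
#'
#' Two-column CSV with header `k,probability`.
#'
#' @param p A [degree_distribution()].
#' @param path File path.
#' @return `write_degree_distribution` returns `path` invisibly;
#'   `read_degree_distribution` returns a [degree_distribution()].
#' @export
write_degree_distribution <- function(p, path) {
  stopifnot(inherits(p, "degree_distribution"))
  utils::write.csv(data.frame(k = p$support, probability = p$probs),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_degree_distribution
#' @export
read_degree_distribution <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("k", "probability") %in% names(d)))
    stop("degree-distribution file must have columns 'k' and 'probability'")
  pr <- d$probability / sum(d$probability)
  degree_distribution(d$k, pr)
}
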