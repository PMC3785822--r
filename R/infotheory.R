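#' Discrete probability distribution over labelled outcomes
#'
#' @param outcomes Finite label set (character, integer, ...).
#' @param probs Probabilities, nonnegative and summing to 1 within `1e-12`.
#' @return Object of class `discrete_distribution`.
#' @export
discrete_distribution <- function(outcomes, probs) {
  if (length(outcomes) != length(probs) || length(outcomes) == 0L)
    stop("outcomes and probs must be non-empty and of equal length")
  if (anyDuplicated(outcomes)) stop("outcomes must be distinct")
  if (any(probs < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(probs) - 1) > 1e-12)
    stop("probabilities must sum to 1 within 1e-12")
  structure(list(outcomes = outcomes, probs = as.numeric(probs)),
            class = "discrete_distribution")
}

#' Joint distribution over outcome pairs
#'
#' @param probs Matrix of pair probabilities, rows indexing X outcomes and
#'   columns Y outcomes; nonnegative, summing to 1 within `1e-12`.
#' @param outcomes_x,outcomes_y Optional outcome labels (default dimnames or
#'   integer indices).
#' @return Object of class `joint_distribution`.
#' @export
joint_distribution <- function(probs, outcomes_x = NULL, outcomes_y = NULL) {
  probs <- as.matrix(probs)
  if (any(probs < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(probs) - 1) > 1e-12)
    stop("probabilities must sum to 1 within 1e-12")
  if (is.null(outcomes_x)) outcomes_x <- rownames(probs) %||% seq_len(nrow(probs))
  if (is.null(outcomes_y)) outcomes_y <- colnames(probs) %||% seq_len(ncol(probs))
  structure(list(probs = unname(probs), outcomes_x = outcomes_x,
                 outcomes_y = outcomes_y),
            class = "joint_distribution")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -sum(p log2 p) with 0 log 0 = 0, for a bare probability vector/matrix.
.entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# binary entropy in bits
.h2 <- function(p) {
  out <- numeric(length(p))
  ok <- p > 0 & p < 1
  out[ok] <- -p[ok] * log2(p[ok]) - (1 - p[ok]) * log2(1 - p[ok])
  out
}

#' Shannon entropy in bits
#'
#' `H = -sum_i p_i log2 p_i`, the number of yes/no questions needed to pin
#' down an outcome; `0 * log 0` is taken as 0.
#'
#' @param d A [discrete_distribution()], a [joint_distribution()] (entropy of
#'   the pair), or a bare probability vector summing to 1 within `1e-12`.
#' @return Entropy in bits.
#' @export
entropy <- function(d) {
  if (inherits(d, "discrete_distribution")) return(.entropy_bits(d$probs))
  if (inherits(d, "joint_distribution")) return(.entropy_bits(d$probs))
  if (is.numeric(d)) {
    if (any(d < 0) || abs(sum(d) - 1) > 1e-12)
      stop("probabilities must be nonnegative and sum to 1 within 1e-12")
    return(.entropy_bits(d))
  }
  stop("unsupported input to entropy()")
}

#' Marginals of a joint distribution
#' @param j A [joint_distribution()].
#' @return List with `x` and `y` [discrete_distribution()]s.
#' @export
marginals <- function(j) {
  stopifnot(inherits(j, "joint_distribution"))
  px <- rowSums(j$probs); py <- colSums(j$probs)
  list(x = discrete_distribution(j$outcomes_x, px / sum(px)),
       y = discrete_distribution(j$outcomes_y, py / sum(py)))
}

#' Mutual information in bits
#'
#' `I(X;Y) = H(X) + H(Y) - H(X,Y) = H(X) - H(X|Y)`; symmetric and
#' nonnegative.
#'
#' @param j A [joint_distribution()] or a nonnegative matrix summing to 1
#'   within `1e-12`.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(j) {
  p <- if (inherits(j, "joint_distribution")) j$probs else as.matrix(j)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
    stop("probabilities must be nonnegative and sum to 1 within 1e-12")
  .entropy_bits(rowSums(p)) + .entropy_bits(colSums(p)) - .entropy_bits(p)
}

#' Plug-in entropy and mutual-information estimates
#'
#' Maximum-likelihood (plug-in) estimates from empirical frequencies of two
#' aligned label sequences, with an optional Miller-Madow small-sample
#' correction (`+ (K - 1) / (2 n ln 2)` bits per entropy term, `K` the number
#' of observed outcomes). Corrections are never applied silently: the choice
#' is echoed in the result together with `n`, so callers can judge bias.
#'
#' @param samples_x,samples_y Equal-length aligned label sequences,
#'   length `>= 1`.
#' @param correction `"none"` (raw plug-in) or `"miller-madow"`.
#' @return List with `entropy_x_bits`, `entropy_y_bits`, `mi_bits`, `n`,
#'   `correction`.
#' @export
plugin_estimates <- function(samples_x, samples_y,
                             correction = c("none", "miller-madow")) {
  correction <- match.arg(correction)
  n <- length(samples_x)
  if (n == 0L) stop("empty input")
  if (length(samples_y) != n)
    stop("samples_x and samples_y must have equal length")
  tab <- table(samples_x, samples_y)
  p <- tab / n
  hx <- .entropy_bits(rowSums(p))
  hy <- .entropy_bits(colSums(p))
  hxy <- .entropy_bits(p)
  if (correction == "miller-madow") {
    kx <- sum(rowSums(tab) > 0); ky <- sum(colSums(tab) > 0); kxy <- sum(tab > 0)
    mm <- function(k) (k - 1) / (2 * n * log(2))
    hx <- hx + mm(kx); hy <- hy + mm(ky); hxy <- hxy + mm(kxy)
  }
  list(entropy_x_bits = hx, entropy_y_bits = hy,
       mi_bits = hx + hy - hxy, n = n, correction = correction)
}
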