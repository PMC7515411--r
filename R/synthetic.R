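#' Synthetic distributions with known information structure
#'
#' Generators for the benchmark configurations used throughout: product
#' (independent) laws, fully redundant copies, the Borromean XOR triple,
#' and seeded Dirichlet-random laws for fuzzing the algebraic identity
#' suites.
#'
#' @name synthetic
NULL

#' @describeIn synthetic Product law of `n` independent variables sharing
#'   one marginal (uniform by default).  Every mutual information of two or
#'   more variables is 0 and the total free energy is 0.
#' @param n Number of variables.
#' @param cardinality Alphabet size per variable.
#' @param marginal Optional probability vector (length `cardinality`)
#'   shared by all variables; uniform when `NULL`.
#' @export
gen_independent <- function(n, cardinality = 2, marginal = NULL) {
  N <- as.integer(cardinality)
  if (is.null(marginal)) marginal <- rep(1 / N, N)
  if (length(marginal) != N || any(marginal < 0) ||
      abs(sum(marginal) - 1) > 1e-9) {
    stop("`marginal` must be a probability vector of length `cardinality`",
         call. = FALSE)
  }
  p <- Reduce(function(a, b) outer(a, b), rep(list(as.numeric(marginal)), n))
  joint_dist(as.numeric(p), cardinalities = rep(N, n))
}

#' @describeIn synthetic `n` fully redundant variables: all equal with
#'   probability 1, mass `marginal[x]` on the diagonal state `(x, ..., x)`.
#'   Every `Hk` and every `Ik` equals the base entropy `H1`.
#' @export
gen_redundant <- function(n, marginal = c(0.5, 0.5)) {
  N <- length(marginal)
  if (any(marginal < 0) || abs(sum(marginal) - 1) > 1e-9) {
    stop("`marginal` must be a probability vector", call. = FALSE)
  }
  p <- array(0, dim = rep(N, n))
  idx <- matrix(rep(seq_len(N), n), ncol = n)
  p[idx] <- as.numeric(marginal)
  joint_dist(p, cardinalities = rep(N, n))
}

#' @describeIn synthetic The Borromean three-bit configuration: probability
#'   1/4 on each of the states 000, 011, 101, 110 (the XOR constraint).
#'   Marginals are uniform, every pair is independent (`I2 = 0`), and
#'   `I3 = -1` bit: the canonical synergy / information-negativity example.
#' @export
gen_borromean <- function() {
  p <- array(0, dim = c(2, 2, 2))
  # states with even parity: 000, 011, 101, 110 (codes are 0-based)
  p[1, 1, 1] <- p[1, 2, 2] <- p[2, 1, 2] <- p[2, 2, 1] <- 1 / 4
  joint_dist(p)
}

#' @describeIn synthetic Strictly positive random joint law with entries
#'   drawn from a symmetric Dirichlet; reproducible by `seed`.
#' @param concentration Dirichlet concentration parameter (> 0); large
#'   values give near-uniform laws.
#' @param seed Integer seed.
#' @export
gen_random_dirichlet <- function(n, cardinality = 2, concentration = 1,
                                 seed = NULL) {
  stopifnot(concentration > 0)
  N <- as.integer(cardinality)
  size <- N^n
  draw <- function() {
    g <- stats::rgamma(size, shape = concentration, rate = 1)
    g / sum(g)
  }
  p <- if (is.null(seed)) draw() else with_seed(seed, draw())
  joint_dist(p, cardinalities = rep(N, n))
}

#' @describeIn synthetic Tensor product of independent blocks: the joint
#'   law under which the blocks are mutually independent while each keeps
#'   its internal dependences.  Variables are re-indexed consecutively in
#'   the order given.  Used to plant known modules inside noise.
#' @param ... [joint_dist] blocks.
#' @export
block_product <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1L && is.list(blocks[[1]]) &&
      !inherits(blocks[[1]], "joint_dist")) {
    blocks <- blocks[[1]]
  }
  stopifnot(all(vapply(blocks, inherits, logical(1), "joint_dist")))
  p <- Reduce(function(a, b) outer(a, b),
              lapply(blocks, function(jd) jd$prob))
  cards <- unlist(lapply(blocks, function(jd) jd$vars$cardinality))
  joint_dist(as.numeric(p), cardinalities = cards)
}

#' Draw an i.i.d. sample matrix from a joint distribution
#'
#' `m` independent draws from the joint law, returned as a tibble of
#' 0-based integer codes (one column per variable) ready for
#' [empirical_joint()] / [info_structure()].
#'
#' @param joint A [joint_dist].
#' @param m Number of rows to draw.
#' @param seed Integer seed (recorded as an attribute).
#' @return A tibble of integer codes with attributes `cardinalities` and
#'   `seed`.
#' @examples
#' sample_matrix(gen_borromean(), 5, seed = 42)
#' @export
sample_matrix <- function(joint, m, seed = NULL) {
  stopifnot(inherits(joint, "joint_dist"), m >= 1)
  g <- state_grid(joint$vars$cardinality)
  draw <- function() {
    sample.int(nrow(g), size = m, replace = TRUE,
               prob = as.numeric(joint$prob))
  }
  rows <- if (is.null(seed)) draw() else with_seed(seed, draw())
  out <- tibble::as_tibble(as.data.frame(g[rows, , drop = FALSE]))
  colnames(out) <- joint$vars$name
  rownames(out) <- NULL
  attr(out, "cardinalities") <- joint$vars$cardinality
  attr(out, "seed") <- seed
  out
}
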