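#' Joint probability distributions over finite product alphabets
#'
#' A `joint_dist` stores a probability table over the product alphabet of a
#' set of discrete variables.  Probabilities are held as a dense numeric
#' array whose j-th dimension runs over the alphabet of the j-th variable;
#' state codes are 0-based in all user-facing input and output (state
#' `"0,1,1"` is the first letter of variable 1, second of variables 2 and 3).
#'
#' @param prob Numeric vector or array of non-negative probabilities summing
#'   to 1.  Its length must equal the product of the cardinalities.
#' @param cardinalities Integer vector of alphabet sizes, one per variable.
#'   Defaults to `dim(prob)` when `prob` is an array.
#' @param indices Integer identifiers for the variables (1-based, unique).
#'   Defaults to `seq_along(cardinalities)`.
#' @param names Optional character labels for the variables.
#'
#' @return An object of class `joint_dist` with fields `prob` (array) and
#'   `vars` (tibble with columns `index`, `cardinality`, `name`).
#' @examples
#' # a fair coin pair
#' joint_dist(rep(1 / 4, 4), cardinalities = c(2, 2))
#' @export
joint_dist <- function(prob, cardinalities = NULL, indices = NULL, names = NULL) {
  if (is.null(cardinalities)) {
    if (is.null(dim(prob))) {
      stop("`cardinalities` must be given when `prob` has no dim attribute",
           call. = FALSE)
    }
    cardinalities <- dim(prob)
  }
  cardinalities <- as.integer(cardinalities)
  if (any(cardinalities < 1L)) {
    stop("every cardinality must be >= 1", call. = FALSE)
  }
  n <- length(cardinalities)
  if (is.null(indices)) indices <- seq_len(n)
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("variable indices must be unique", call. = FALSE)
  if (is.null(names)) names <- paste0("X", indices)
  p <- as.numeric(prob)
  if (length(p) != prod(cardinalities)) {
    stop("length(prob) must equal prod(cardinalities)", call. = FALSE)
  }
  if (any(p < -1e-12)) stop("probabilities must be non-negative", call. = FALSE)
  p[p < 0] <- 0
  s <- sum(p)
  if (abs(s - 1) > 1e-9) {
    stop("probabilities must sum to 1 (got ", format(s), ")", call. = FALSE)
  }
  if (n > 0L) dim(p) <- cardinalities
  structure(
    list(
      prob = p,
      vars = tibble::tibble(index = indices, cardinality = cardinalities,
                            name = as.character(names))
    ),
    class = "joint_dist"
  )
}

#' The unit (empty) distribution
#'
#' The identity element of the lattice of joint variables: zero variables,
#' a single state of probability one.  `entropy()` of it is 0 bits.
#' @return A `joint_dist` over zero variables.
#' @export
unit_dist <- function() {
  structure(
    list(prob = 1,
         vars = tibble::tibble(index = integer(), cardinality = integer(),
                               name = character())),
    class = "joint_dist"
  )
}

#' @export
print.joint_dist <- function(x, ...) {
  n <- nrow(x$vars)
  cat("<joint_dist> ", n, " variable(s), ",
      if (n > 0L) prod(x$vars$cardinality) else 1L, " joint state(s)\n", sep = "")
  if (n > 0L) {
    cat("  cardinalities: ", paste(x$vars$cardinality, collapse = " x "),
        "  (", paste(x$vars$name, collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

n_vars <- function(jd) nrow(jd$vars)

# positions (array margins) of the given variable indices, ascending
var_positions <- function(jd, subset) {
  pos <- match(sort(as.integer(subset)), jd$vars$index)
  if (anyNA(pos)) {
    stop("subset contains variable indices absent from the distribution",
         call. = FALSE)
  }
  pos
}

#' Marginalize a joint distribution onto a variable subset
#'
#' Sums out every variable not in `subset`.  Variables keep their original
#' indices; the result's variable order is ascending index.
#'
#' @param joint A [joint_dist].
#' @param subset Integer vector of variable indices to keep.  The empty
#'   subset yields [unit_dist()].
#' @return A [joint_dist] over `subset`.
#' @examples
#' marginalize(gen_borromean(), 1)      # a fair coin
#' @export
marginalize <- function(joint, subset) {
  stopifnot(inherits(joint, "joint_dist"))
  subset <- unique(as.integer(subset))
  if (length(subset) == 0L) return(unit_dist())
  pos <- var_positions(joint, subset)
  if (length(pos) == n_vars(joint)) {
    keep <- joint$vars[pos, , drop = FALSE]
    p <- if (identical(pos, seq_len(n_vars(joint)))) joint$prob else
      aperm(joint$prob, pos)
    return(joint_dist(p, cardinalities = keep$cardinality,
                      indices = keep$index, names = keep$name))
  }
  p <- apply(joint$prob, pos, sum)
  keep <- joint$vars[pos, , drop = FALSE]
  joint_dist(p, cardinalities = keep$cardinality,
             indices = keep$index, names = keep$name)
}

#' Empirical (plug-in) joint distribution of a coded data matrix
#'
#' Counts joint states over the rows of an integer-coded matrix: the
#' maximum-likelihood ("naive") estimator.  No pseudocounts and no bias
#' correction are applied; unobserved states get probability zero.
#'
#' @param data A data frame / tibble (or matrix) of integer codes in
#'   `0..Nj-1`, one row per sample, one column per variable — typically the
#'   output of [bin_data()] or [sample_matrix()].  Rows containing `NA` are
#'   dropped listwise with a message.
#' @param subset Integer vector of variable (column) indices; empty subset
#'   returns [unit_dist()].
#' @param cardinalities Optional integer vector of alphabet sizes for the
#'   *selected* columns; defaults to the `cardinalities` attribute of
#'   `data`, else `max(code) + 1` per column.
#' @return A [joint_dist] over `subset`.
#' @examples
#' x <- tibble::tibble(a = c(0, 0, 1, 1), b = c(0, 0, 1, 1))
#' empirical_joint(x, c(1, 2))
#' @export
empirical_joint <- function(data, subset = NULL, cardinalities = NULL) {
  m0 <- as.data.frame(data)
  if (is.null(subset)) subset <- seq_len(ncol(m0))
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) == 0L) return(unit_dist())
  if (any(subset < 1L | subset > ncol(m0))) {
    stop("subset refers to columns outside the data matrix", call. = FALSE)
  }
  all_cards <- attr(data, "cardinalities")
  keep <- stats::complete.cases(m0)
  if (!all(keep)) {
    message("dropping ", sum(!keep), " row(s) with missing values")
    m0 <- m0[keep, , drop = FALSE]
  }
  if (nrow(m0) == 0L) stop("no complete rows to estimate from", call. = FALSE)
  cols <- m0[, subset, drop = FALSE]
  if (is.null(cardinalities)) {
    cardinalities <- if (!is.null(all_cards)) all_cards[subset] else
      vapply(cols, function(v) as.integer(max(v)) + 1L, integer(1))
  }
  cardinalities <- as.integer(cardinalities)
  for (j in seq_along(subset)) {
    v <- cols[[j]]
    if (any(v < 0L | v >= cardinalities[j])) {
      stop("codes in column ", subset[j], " fall outside 0..",
           cardinalities[j] - 1L, call. = FALSE)
    }
  }
  fs <- lapply(seq_along(subset), function(j) {
    factor(cols[[j]], levels = 0:(cardinalities[j] - 1L))
  })
  counts <- table(fs)
  nms <- colnames(m0)[subset]
  jd <- joint_dist(as.numeric(counts) / nrow(m0),
                   cardinalities = cardinalities, indices = subset,
                   names = if (is.null(nms)) paste0("X", subset) else nms)
  attr(jd, "m") <- nrow(m0)
  jd
}

#' Gibbs distribution from a table of state energies
#'
#' Builds the distribution `p(state) = 2^(-beta * E(state)) / Z` with
#' energies in bits and a dimensionless inverse temperature `beta`
#' (physical constants are absorbed into the unit convention).
#'
#' @param energies Numeric array of state energies in bits; its `dim` gives
#'   the product alphabet.  `+Inf` entries get probability zero.
#' @param beta Positive inverse temperature.
#' @inheritParams joint_dist
#' @return A [joint_dist].
#' @examples
#' gibbs_distribution(array(c(0, 1), 2), beta = 1)  # probs 2/3, 1/3
#' @export
gibbs_distribution <- function(energies, beta = 1, cardinalities = NULL,
                               indices = NULL, names = NULL) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta > 0)
  if (is.null(cardinalities)) cardinalities <- dim(energies)
  if (is.null(cardinalities)) cardinalities <- length(energies)
  e <- as.numeric(energies)
  if (any(is.na(e))) stop("energies must be finite or +Inf", call. = FALSE)
  w <- 2^(-beta * e)
  z <- sum(w)
  if (!is.finite(z) || z <= 0) {
    stop("partition function is not positive and finite", call. = FALSE)
  }
  joint_dist(w / z, cardinalities = cardinalities, indices = indices,
             names = names)
}

# ---- state keys ------------------------------------------------------------

# all joint states as a 0-based integer matrix, rows in array order
state_grid <- function(cardinalities) {
  if (length(cardinalities) == 0L) return(matrix(integer(), 1, 0))
  as.matrix(expand.grid(lapply(cardinalities, function(N) 0:(N - 1L)),
                        KEEP.OUT.ATTRS = FALSE))
}

#' Tidy a joint distribution into a state-by-probability table
#'
#' @param x A [joint_dist].
#' @param ... Unused.
#' @return A tibble with one 0-based code column per variable (named after
#'   the variables), a `state` key (comma-joined codes) and `prob`.
#' @export
tidy.joint_dist <- function(x, ...) {
  g <- state_grid(x$vars$cardinality)
  out <- tibble::as_tibble(as.data.frame(g))
  if (ncol(out) > 0) colnames(out) <- x$vars$name
  out$state <- apply(g, 1, paste, collapse = ",")
  out$prob <- as.numeric(x$prob)
  out
}
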