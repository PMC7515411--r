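#' @rdname entropy
#' @export
xlog2x_sum <- function(p) {
  # -sum p log2 p with the 0 log 0 := 0 convention
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Shannon joint entropy (bits)
#'
#' `entropy()` computes the Shannon-Gibbs entropy of a joint distribution,
#' `-sum(p * log2(p))` with `0 * log2(0) := 0`, in bits.  `xlog2x_sum()` is
#' the bare summation on a probability vector.
#'
#' @param joint A [joint_dist], or an [info_structure] when `subset` is
#'   given.
#' @param subset Optional integer vector of variable indices: the entropy
#'   of the marginal on `subset`.
#' @return Entropy in bits, in `[0, log2(prod Nj)]`.
#' @examples
#' entropy(gen_borromean())             # 2 bits
#' entropy(gen_borromean(), subset = 1) # 1 bit
#' @export
entropy <- function(joint, subset = NULL) {
  if (inherits(joint, "info_structure")) {
    return(structure_value(joint, subset, "H"))
  }
  stopifnot(inherits(joint, "joint_dist"))
  if (!is.null(subset)) joint <- marginalize(joint, subset)
  xlog2x_sum(as.numeric(joint$prob))
}

#' Kullback-Leibler divergence (bits)
#'
#' `D(p || q) = sum p log2(p / q)`, non-negative, zero iff `p == q`.
#' Returns `Inf` when `p` puts mass where `q` does not.
#'
#' @param p,q [joint_dist] objects over identical product alphabets.
#' @return Divergence in bits (possibly `Inf`).
#' @export
kl_divergence <- function(p, q) {
  stopifnot(inherits(p, "joint_dist"), inherits(q, "joint_dist"))
  if (!identical(p$vars$cardinality, q$vars$cardinality)) {
    stop("`p` and `q` must share the same product alphabet", call. = FALSE)
  }
  pp <- as.numeric(p$prob)
  qq <- as.numeric(q$prob)
  pos <- pp > 0
  if (any(qq[pos] == 0)) return(Inf)
  sum(pp[pos] * log2(pp[pos] / qq[pos]))
}

# all non-empty subsets of an index vector, as a list
# (combn is indexed by position so scalar idx is not expanded to seq_len)
nonempty_subsets <- function(idx) {
  pos <- unlist(lapply(seq_along(idx), function(k) {
    utils::combn(seq_along(idx), k, simplify = FALSE)
  }), recursive = FALSE)
  lapply(pos, function(p) idx[p])
}

#' Multivariate mutual information / co-information (bits)
#'
#' The k-mutual information of a set of variables, computed by
#' inclusion-exclusion over subset entropies:
#' `I(S) = sum over non-empty T in S of (-1)^(|T|-1) H(T)`.
#' `I` of a single variable is its entropy; for three or more variables the
#' value can be negative (synergy).  The empty subset gives 0.
#'
#' @param joint A [joint_dist] or an [info_structure].
#' @param subset Integer vector of variable indices.
#' @return Mutual information in bits.
#' @examples
#' mutual_information(gen_borromean(), c(1, 2, 3))  # -1 bit
#' @export
mutual_information <- function(joint, subset) {
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) == 0L) return(0)
  if (inherits(joint, "info_structure")) {
    return(structure_value(joint, subset, "I"))
  }
  stopifnot(inherits(joint, "joint_dist"))
  val <- 0
  for (T in nonempty_subsets(subset)) {
    val <- val + (-1)^(length(T) - 1) * entropy(joint, T)
  }
  val
}

#' Total correlation / total free energy (bits)
#'
#' `C(S) = sum of marginal entropies - joint entropy`, Watanabe's total
#' correlation.  It equals the Kullback-Leibler divergence between the
#' joint law and the product of its marginals, so it is non-negative, and
#' it is the total free energy `G` of [energy_decomposition()].
#'
#' @inheritParams mutual_information
#' @return Total correlation in bits (`>= 0`).
#' @export
total_correlation <- function(joint, subset = NULL) {
  if (inherits(joint, "joint_dist") && is.null(subset)) {
    subset <- joint$vars$index
  }
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) < 2L) {
    stop("total correlation needs at least two variables", call. = FALSE)
  }
  sum(vapply(subset, function(i) entropy(joint, i), numeric(1))) -
    entropy(joint, subset)
}

#' Conditional entropy H(A | B) in bits
#'
#' `H(A | B) = H(A, B) - H(B)`, non-negative; with `given` empty this is
#' the plain joint entropy of `target`.
#'
#' @inheritParams mutual_information
#' @param target,given Disjoint integer vectors of variable indices.
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(joint, target, given = integer(0)) {
  target <- sort(unique(as.integer(target)))
  given <- sort(unique(as.integer(given)))
  if (length(intersect(target, given)) > 0L) {
    stop("`target` and `given` must be disjoint", call. = FALSE)
  }
  entropy(joint, union(target, given)) - entropy(joint, given)
}

#' Conditional mutual information Y.I(A) in bits
#'
#' The k-mutual information among the variables of `vars`, conditioned on
#' the joint variable `given`:
#' `Y.I(A1; ...; Ak) = sum over non-empty T of (-1)^(|T|-1) H(A_T | Y)`.
#' For `|vars| = 1` this is the conditional entropy; for `|vars| = 2` it is
#' the classic conditional mutual information, always non-negative; for
#' three or more it can be negative.  Via the chain rule it equals
#' `I(vars) - I(vars + given)` when `given` is a single variable.
#'
#' @inheritParams mutual_information
#' @param vars Integer vector of variable indices (each its own argument).
#' @param given Integer vector, the conditioning joint variable (disjoint
#'   from `vars`).
#' @return Conditional mutual information in bits.
#' @examples
#' conditional_mutual_information(gen_borromean(), c(1, 2), given = 3) # 1 bit
#' @export
conditional_mutual_information <- function(joint, vars, given = integer(0)) {
  vars <- sort(unique(as.integer(vars)))
  given <- sort(unique(as.integer(given)))
  if (length(vars) == 0L) return(0)
  if (length(intersect(vars, given)) > 0L) {
    stop("`vars` and `given` must be disjoint", call. = FALSE)
  }
  group_cmi(joint, as.list(vars), given)
}

# conditional k-mutual information of variable *groups* (each group a joint
# variable), the general form used by the coboundary operators
group_cmi <- function(joint, groups, given = integer(0)) {
  k <- length(groups)
  if (k == 0L) return(0)
  val <- 0
  for (Tm in nonempty_subsets(seq_len(k))) {
    s <- sort(unique(c(unlist(groups[Tm]), given)))
    val <- val + (-1)^(length(Tm) - 1) * entropy(joint, s)
  }
  if (length(given) > 0L) val <- val - entropy(joint, given)
  val
}

#' Pseudo k-volume Vk = Hk - Ik (bits)
#'
#' A symmetric non-negative function of a variable set; for pairs it is
#' Shannon's information pseudo-metric `H(X delta Y) = H(X,Y) - I(X;Y)`,
#' and for a single variable it is 0.
#'
#' @inheritParams mutual_information
#' @return `H(subset) - I(subset)` in bits.
#' @export
pseudo_volume <- function(joint, subset) {
  entropy(joint, subset) - mutual_information(joint, subset)
}

#' Elementary (extensive) state energies in bits
#'
#' For each joint state, the energy `E(state) = -sum_j log2 p_j(x_j)` where
#' `p_j` is the j-th marginal: the unique assignment satisfying the
#' additivity axiom `E(x_i, x_j) = E(x_i) + E(x_j)`.  States with a
#' zero-probability marginal coordinate get `+Inf`; by the `0 log 0 := 0`
#' convention these never contribute to the internal energy because their
#' joint probability is also zero.
#'
#' @param joint A [joint_dist].
#' @return An object of class `energy_table`: the numeric array of energies
#'   (same shape as the probability table) with attribute `vars`.
#' @examples
#' elementary_energies(gen_borromean())  # 3 bits for every state
#' @export
elementary_energies <- function(joint) {
  stopifnot(inherits(joint, "joint_dist"))
  n <- n_vars(joint)
  if (n == 0L) {
    return(structure(array(0, dim = 1), vars = joint$vars,
                     class = "energy_table"))
  }
  marg <- lapply(joint$vars$index, function(i) {
    as.numeric(marginalize(joint, i)$prob)
  })
  g <- state_grid(joint$vars$cardinality)
  e <- numeric(nrow(g))
  for (j in seq_len(n)) {
    pj <- marg[[j]][g[, j] + 1L]
    e <- e - log2(pj)  # -log2(0) = +Inf for impossible coordinates
  }
  dim(e) <- joint$vars$cardinality
  structure(e, vars = joint$vars, class = "energy_table")
}

#' @export
tidy.energy_table <- function(x, ...) {
  vars <- attr(x, "vars")
  g <- state_grid(vars$cardinality)
  tibble::tibble(
    state = apply(g, 1, paste, collapse = ","),
    energy = as.numeric(x)
  )
}

#' @export
print.energy_table <- function(x, ...) {
  cat("<energy_table> ", length(x), " state energies (bits)\n", sep = "")
  print(tidy.energy_table(x))
  invisible(x)
}

#' Internal energy / free energy decomposition H = U - G
#'
#' Splits the joint entropy of a variable set into the internal energy
#' `U = sum of marginal entropies` and the total free energy
#' `G = sum over degrees i >= 2 of (-1)^i sum_{|T| = i} I(T)`, which equals
#' the total correlation.  The identity `H = U - G` holds algebraically
#' (inclusion-exclusion), so the returned row always satisfies it to
#' floating precision; `G >= 0` always.
#'
#' @inheritParams mutual_information
#' @return A one-row tibble with columns `U`, `G`, `H` (bits) and `n_vars`.
#' @examples
#' energy_decomposition(gen_borromean())  # U = 3, G = 1, H = 2
#' @export
energy_decomposition <- function(joint, subset = NULL) {
  if (is.null(subset)) {
    subset <- if (inherits(joint, "info_structure")) joint$var_index else
      joint$vars$index
  }
  subset <- sort(unique(as.integer(subset)))
  U <- sum(vapply(subset, function(i) entropy(joint, i), numeric(1)))
  H <- entropy(joint, subset)
  G <- 0
  if (length(subset) >= 2L) {
    for (i in 2:length(subset)) {
      for (T in utils::combn(subset, i, simplify = FALSE)) {
        G <- G + (-1)^i * mutual_information(joint, T)
      }
    }
  }
  tibble::tibble(n_vars = length(subset), U = U, G = G, H = H)
}

#' Finite information rate r = Hk / k
#'
#' @param Hk Joint entropy in bits.
#' @param k Number of variables (degree), `>= 1`.
#' @return Bits per variable.
#' @export
information_rate <- function(Hk, k) {
  if (any(k < 1)) stop("`k` must be >= 1", call. = FALSE)
  Hk / k
}
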