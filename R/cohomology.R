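#' Information cochain of the mutual-information family
#'
#' A degree-k cochain assigns a number in bits to a tuple of k disjoint
#' variable groups (each group acting as a single joint variable).  The
#' standard family used throughout is the k-mutual information
#' `F(A1; ...; Ak) = I(A1; ...; Ak)` — which for a single argument is the
#' joint entropy — with the conditioning action
#' `Y.F(A1; ...; Ak) = I(A1; ...; Ak | Y)`.
#'
#' @param joint A [joint_dist] (or [info_structure] covering all needed
#'   joins).
#' @param groups List of disjoint integer vectors (the tuple of arguments).
#' @param given Integer vector: the conditioning joint variable.
#' @return Value in bits.
#' @export
info_cochain <- function(joint, groups, given = integer(0)) {
  groups <- lapply(groups, function(g) sort(unique(as.integer(g))))
  flat <- unlist(groups)
  if (anyDuplicated(flat)) {
    stop("cochain argument groups must be disjoint", call. = FALSE)
  }
  if (length(intersect(flat, given)) > 0L) {
    stop("conditioning variable overlaps the arguments", call. = FALSE)
  }
  group_cmi(joint, groups, given = as.integer(given))
}

#' Hochschild-type coboundary operators on information cochains
#'
#' Evaluates the three coboundary operators on a degree-k cochain `F` at a
#' tuple of `k + 1` disjoint variable groups, numerically from a joint
#' distribution.  Writing `F_i` for `F` applied with the adjacent pair
#' `(X_i, X_{i+1})` joined into one group:
#'
#' * left action: `X1.F(X2; ...; X_{k+1}) + sum_i (-1)^i F_i
#'   + (-1)^(k+1) F(X1; ...; Xk)`
#' * topological (trivial action): same with the first term unconditioned
#' * symmetric: left form, but with the last term conditioned on `X_{k+1}`
#'
#' In low degrees these reproduce the information functions: the
#' topological 1-coboundary of `H` is `I2`, the left 2-coboundary of `I2`
#' is `-I3`, the topological 3-coboundary of `I3` is `I4`, and the
#' topological/symmetric even-degree and left odd-degree coboundaries
#' vanish identically.
#'
#' @inheritParams info_cochain
#' @param args List of `k + 1` disjoint integer vectors (variable groups).
#' @param action `"left"`, `"topological"` or `"symmetric"`.
#' @param F Cochain evaluator `function(joint, groups, given)`; defaults to
#'   [info_cochain()].
#' @return The coboundary value in bits.
#' @examples
#' # topological 1-coboundary of H is the mutual information
#' coboundary(gen_borromean(), list(1, 2), action = "topological")
#' @export
coboundary <- function(joint, args,
                       action = c("left", "topological", "symmetric"),
                       F = info_cochain) {
  action <- match.arg(action)
  args <- lapply(args, function(g) sort(unique(as.integer(g))))
  if (anyDuplicated(unlist(args))) {
    stop("argument groups must be disjoint", call. = FALSE)
  }
  k <- length(args) - 1L
  if (k < 1L) stop("need at least two argument groups", call. = FALSE)
  val <- if (action == "topological") {
    F(joint, args[-1])
  } else {
    F(joint, args[-1], given = args[[1]])
  }
  for (i in seq_len(k)) {
    joined <- args
    joined[[i]] <- sort(c(args[[i]], args[[i + 1]]))
    joined[[i + 1]] <- NULL
    val <- val + (-1)^i * F(joint, joined)
  }
  last <- if (action == "symmetric") {
    F(joint, args[-(k + 1L)], given = args[[k + 1L]])
  } else {
    F(joint, args[-(k + 1L)])
  }
  val + (-1)^(k + 1L) * last
}

#' Verify the low-degree coboundary identities numerically
#'
#' Evaluates, on a given distribution, the identities tying the three
#' coboundary operators to the information functions: the left
#' 1-coboundary of `H` vanishes (the chain rule), the topological and
#' symmetric 1-coboundaries give `I2` and `-I2`, the left 2-coboundary
#' gives `-I3` while the topological and symmetric 2-coboundaries vanish,
#' the left 3-coboundary vanishes while the topological and symmetric
#' 3-coboundaries give `I4` and `-I4`, and (with five or more variables)
#' the left 4-coboundary gives `-I5` with vanishing topological and
#' symmetric 4-coboundaries.  These hold algebraically for every
#' distribution, so residuals measure only floating-point error.
#'
#' @param joint A [joint_dist]; at least 2 variables, all identities need
#'   at least 4 (degree-4 checks need 5).
#' @param tol Pass threshold on the absolute residual.
#' @param vars Optional integer vector naming which variables to use as the
#'   singleton argument groups (defaults to the first five).
#' @return A tibble with columns `identity`, `degree`, `action`, `value`,
#'   `expected`, `residual`, `pass`, plus attribute `partial` when fewer
#'   than 4 variables limited the checks.
#' @examples
#' verify_identities(gen_random_dirichlet(4, seed = 1))
#' @export
verify_identities <- function(joint, tol = 1e-9, vars = NULL) {
  idx <- if (inherits(joint, "joint_dist")) joint$vars$index else
    joint$var_index
  if (is.null(vars)) vars <- utils::head(sort(idx), 5L)
  n <- length(vars)
  if (n < 2L) stop("need at least two variables", call. = FALSE)
  g <- as.list(vars)
  Ik <- function(k) mutual_information(joint, vars[seq_len(k)])
  rows <- list()
  add <- function(identity, degree, action, value, expected) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      identity = identity, degree = degree, action = action,
      value = value, expected = expected,
      residual = abs(value - expected)
    )
  }
  a2 <- g[1:2]
  add("d1_left_null (chain rule)", 1L, "left",
      coboundary(joint, a2, "left"), 0)
  add("dt1 = I2", 1L, "topological",
      coboundary(joint, a2, "topological"), Ik(2))
  add("dstar1 = -I2", 1L, "symmetric",
      coboundary(joint, a2, "symmetric"), -Ik(2))
  if (n >= 3L) {
    a3 <- g[1:3]
    add("d2 = -I3", 2L, "left", coboundary(joint, a3, "left"), -Ik(3))
    add("dt2 null", 2L, "topological",
        coboundary(joint, a3, "topological"), 0)
    add("dstar2 null", 2L, "symmetric",
        coboundary(joint, a3, "symmetric"), 0)
  }
  if (n >= 4L) {
    a4 <- g[1:4]
    add("d3 null", 3L, "left", coboundary(joint, a4, "left"), 0)
    add("dt3 = I4", 3L, "topological",
        coboundary(joint, a4, "topological"), Ik(4))
    add("dstar3 = -I4", 3L, "symmetric",
        coboundary(joint, a4, "symmetric"), -Ik(4))
  }
  if (n >= 5L) {
    a5 <- g[1:5]
    add("d4 = -I5", 4L, "left", coboundary(joint, a5, "left"), -Ik(5))
    add("dt4 null", 4L, "topological",
        coboundary(joint, a5, "topological"), 0)
    add("dstar4 null", 4L, "symmetric",
        coboundary(joint, a5, "symmetric"), 0)
  }
  out <- dplyr::bind_rows(rows)
  out$pass <- out$residual <= tol
  attr(out, "partial") <- n < 4L
  out
}
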