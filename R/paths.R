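#' Profile of a single information or entropy path
#'
#' An information (or entropy) path follows an ordering of variables up the
#' simplicial lattice; its value at step `j` is `I` (or `H`) of the first
#' `j` variables.  Successive differences of the profile are, by the chain
#' rules, minus the conditional mutual information
#' `-X_k.I(X_1; ...; X_{k-1})` for information paths and the conditional
#' entropy `(X_1, ..., X_{k-1}).H(X_k)` for entropy paths — so entropy
#' profiles can never decrease (the topological second law), while
#' information profiles can rise after degree 3, marking a critical point.
#'
#' @param structure An [info_structure] (or a [joint_dist], computed on the
#'   fly).
#' @param order Integer vector of distinct variable indices, the path.
#' @param kind `"information"` or `"entropy"`.
#' @return An object of class `info_path`: list with `order`, `kind`,
#'   `profile`, `derivative`, `first_critical_dimension` (info paths only;
#'   `NA` when the profile never rises) and `stop_reason`.
#' @examples
#' path_profile(info_structure(gen_borromean()), c(1, 2, 3))
#' @export
path_profile <- function(structure, order,
                         kind = c("information", "entropy")) {
  kind <- match.arg(kind)
  order <- as.integer(order)
  if (anyDuplicated(order)) stop("`order` has repeated indices", call. = FALSE)
  fn <- if (kind == "entropy") entropy else mutual_information
  profile <- vapply(seq_along(order), function(j) {
    fn(structure, order[seq_len(j)])
  }, numeric(1))
  deriv <- diff(profile)
  p <- structure(
    list(order = order, kind = kind, profile = profile, derivative = deriv,
         first_critical_dimension = NA_integer_, stop_reason = NA_character_),
    class = "info_path"
  )
  if (kind == "information") {
    p$first_critical_dimension <- first_critical_dimension(p)
  }
  p
}

#' @export
print.info_path <- function(x, ...) {
  cat("<info_path> ", x$kind, " path ",
      paste(x$order, collapse = " -> "), "\n  profile (bits): ",
      paste(format(x$profile, digits = 4), collapse = ", "), "\n", sep = "")
  if (!is.na(x$first_critical_dimension)) {
    cat("  first critical dimension: ", x$first_critical_dimension, "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
tidy.info_path <- function(x, ...) {
  tibble::tibble(
    step = seq_along(x$order),
    variable = x$order,
    degree = seq_along(x$order),
    value = x$profile,
    derivative = c(NA_real_, x$derivative)
  )
}

#' First informational critical dimension of a path
#'
#' The degree of the first local minimum of an information path profile:
#' the first `k` after which the profile strictly rises, i.e. the
#' conditional information of the next step turns negative.  Since
#' conditional pairwise information is non-negative, the smallest possible
#' value is 3; `NA` when the profile never rises.
#'
#' @param path An information-kind [info_path] (or a bare numeric profile).
#' @param tol Absolute tolerance on the rise.
#' @return Integer degree `>= 3`, or `NA`.
#' @export
first_critical_dimension <- function(path, tol = 1e-10) {
  profile <- if (inherits(path, "info_path")) {
    if (path$kind != "information") {
      stop("critical dimensions are defined for information paths only",
           call. = FALSE)
    }
    path$profile
  } else {
    as.numeric(path)
  }
  rises <- which(diff(profile) > tol)
  if (length(rises) == 0L) return(NA_integer_)
  k <- as.integer(rises[1])
  # conditional pairwise information is non-negative, so a genuine first
  # minimum can never sit below degree 3
  stopifnot(k >= 3L)
  k
}

#' Enumerate information paths of a variable set
#'
#' All `k!` orderings of a k-set (Theorem: paths are in bijection with the
#' symmetric group), or a seeded sample of `cap` orderings when `k!`
#' exceeds `cap`.
#'
#' @inheritParams path_profile
#' @param subset Integer vector of variable indices; defaults to all.
#' @param cap Maximum number of paths to return.
#' @param seed Seed for the sampled regime.
#' @return A tibble with columns `path_id`, `order` (list), `profile`
#'   (list), `critical_dimension` and attribute `sampled` (logical).
#' @examples
#' enumerate_paths(info_structure(gen_borromean()))
#' @export
enumerate_paths <- function(structure, subset = NULL,
                            kind = c("information", "entropy"),
                            cap = 5000L, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(subset)) {
    subset <- if (inherits(structure, "info_structure")) structure$var_index
      else structure$vars$index
  }
  subset <- sort(unique(as.integer(subset)))
  k <- length(subset)
  nperm <- factorial(k)
  sampled <- nperm > cap
  orders <- if (!sampled) {
    permutations_of(subset)
  } else {
    warning("k! = ", nperm, " exceeds cap = ", cap,
            "; returning a seeded sample of orderings", call. = FALSE)
    with_seed(seed, replicate(cap, sample(subset), simplify = FALSE))
  }
  paths <- lapply(orders, function(o) path_profile(structure, o, kind))
  out <- tibble::tibble(
    path_id = seq_along(paths),
    order = lapply(paths, `[[`, "order"),
    profile = lapply(paths, `[[`, "profile"),
    critical_dimension = vapply(paths, `[[`, integer(1),
                                "first_critical_dimension")
  )
  attr(out, "sampled") <- sampled
  attr(out, "kind") <- kind
  if (sampled) attr(out, "seed") <- seed
  out
}

# all permutations of a vector, deterministic (lexicographic) order
permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  unlist(lapply(seq_along(v), function(i) {
    lapply(permutations_of(v[-i]), function(rest) c(v[i], rest))
  }), recursive = FALSE)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Audit the second law on entropy paths
#'
#' Every entropy path profile must be non-decreasing (conditional entropy
#' is non-negative); for valid distributions any violation can only be a
#' floating-point artifact.  The audit walks a set of entropy paths and
#' reports the largest observed decrease.
#'
#' @inheritParams enumerate_paths
#' @param tol Decreases larger than this flag an internal inconsistency.
#' @return A list with `n_paths`, `max_violation` (bits, `>= 0`) and
#'   `pass`.
#' @export
second_law_audit <- function(structure, subset = NULL, cap = 5000L,
                             seed = 1L, tol = 1e-10) {
  paths <- enumerate_paths(structure, subset, kind = "entropy",
                           cap = cap, seed = seed)
  worst <- 0
  for (pr in paths$profile) {
    d <- diff(pr)
    if (length(d) > 0L) worst <- max(worst, -min(d, 0))
  }
  list(n_paths = nrow(paths), max_violation = worst, pass = worst <= tol)
}
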