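#' Maximal positive information paths (facets)
#'
#' A positive information path is an ordering of variables whose
#' information profile strictly decreases: each added variable keeps a
#' strictly positive conditional information with the path so far.  A
#' maximal positive path cannot be extended.  Extension stops either at
#' conditional independence (conditional information within `tol` of zero)
#' or at negativity (the profile would rise: a critical point).
#'
#' A variable *set* counts as positive when at least one of its orderings
#' is a positive path; the facets returned are the maximal such sets, with
#' subsets of other facets pruned.  The search is a depth-first walk with
#' branch pruning (a prefix that stops is never extended), which visits far
#' fewer than the `k!` orderings of the exhaustive definition while
#' returning the same sets.
#'
#' @param structure An [info_structure] computed to `kmax` at least the
#'   longest positive path (facets hitting `kmax` are flagged truncated).
#' @param tol Strict-positivity threshold on conditional information
#'   (bits).
#' @param strict If `FALSE`, ties (conditional information equal to zero
#'   within `tol`) also extend, for exploratory use.
#' @return A tibble with columns `facet` (list of sorted integer vectors),
#'   `key`, `size`, `witness` (list: one positive ordering), `stop_reason`
#'   (`"negativity"`, `"conditional-independence"` or `"exhausted"`) and
#'   `truncated`.  Sorted by key for determinism.
#' @examples
#' st <- info_structure(block_product(gen_borromean(), gen_independent(1)))
#' maximal_positive_paths(st)
#' @export
maximal_positive_paths <- function(structure, tol = 1e-10, strict = TRUE) {
  vars <- structure$var_index
  kmax <- structure$kmax
  # positive_sets: key -> list(set, witness, stop_reason, truncated)
  found <- new.env(parent = emptyenv())
  extendable <- function(value_prev, value_new) {
    if (strict) value_prev - value_new > tol else value_prev - value_new > -tol
  }
  record <- function(set, witness, reason, truncated) {
    key <- subset_key(set)
    if (is.null(found[[key]])) {
      found[[key]] <- list(set = sort(set), witness = witness,
                           stop_reason = reason, truncated = truncated)
    }
  }
  # depth-first over ordered prefixes; a set already known positive is not
  # re-entered through another ordering unless it can still grow (we allow
  # re-entry: different orderings may have different extensions? no --
  # extension tests depend only on the set, so one visit per set suffices)
  visited <- new.env(parent = emptyenv())
  walk <- function(set, ord, value) {
    key <- subset_key(set)
    if (!is.null(visited[[key]])) return(invisible())
    visited[[key]] <- TRUE
    if (length(set) >= kmax) {
      record(set, ord, "exhausted", truncated = kmax < structure$n)
      return(invisible())
    }
    rest <- setdiff(vars, set)
    reasons <- character(0)
    grew <- FALSE
    for (x in rest) {
      new_val <- mutual_information(structure, c(set, x))
      if (extendable(value, new_val)) {
        grew <- TRUE
        walk(c(set, x), c(ord, x), new_val)
      } else {
        reasons <- c(reasons,
                     if (value - new_val < -tol) "negativity"
                     else "conditional-independence")
      }
    }
    if (!grew) {
      reason <- if ("negativity" %in% reasons) "negativity" else
        "conditional-independence"
      record(set, ord, reason, truncated = FALSE)
    }
    invisible()
  }
  for (x in vars) {
    walk(x, x, mutual_information(structure, x))
  }
  sets <- as.list(found)
  keys <- sort(names(sets))
  # containment pruning: drop any positive set contained in another
  all_sets <- lapply(keys, function(k) sets[[k]]$set)
  maximal <- vapply(seq_along(all_sets), function(i) {
    !any(vapply(seq_along(all_sets), function(j) {
      j != i && length(all_sets[[i]]) < length(all_sets[[j]]) &&
        all(all_sets[[i]] %in% all_sets[[j]])
    }, logical(1)))
  }, logical(1))
  keep <- keys[maximal]
  tibble::tibble(
    facet = lapply(keep, function(k) sets[[k]]$set),
    key = keep,
    size = vapply(keep, function(k) length(sets[[k]]$set), integer(1),
                  USE.NAMES = FALSE),
    witness = lapply(keep, function(k) sets[[k]]$witness),
    stop_reason = vapply(keep, function(k) sets[[k]]$stop_reason,
                         character(1), USE.NAMES = FALSE),
    truncated = vapply(keep, function(k) sets[[k]]$truncated, logical(1),
                       USE.NAMES = FALSE)
  )
}

#' Build the minimum free energy complex from its facets
#'
#' The complex generated by downward closure of a facet list: every subset
#' of a facet is a face.  Reports the face vector (counts per geometric
#' dimension, vertices at dimension 0), the Euler characteristic
#' `chi = sum (-1)^dim count(dim)`, the dimension in both conventions
#' (variable count of the largest facet, and geometric `size - 1`), and —
#' when an [info_structure] is supplied — the minimum free energy
#' characteristic `H+ = sum over faces of (-1)^(size - 1) I(face)`.
#'
#' @param facets A list of integer vectors, or the tibble returned by
#'   [maximal_positive_paths()].
#' @param structure Optional [info_structure] for `h_plus`.
#' @return An object of class `mfe_complex`.
#' @examples
#' mfe_complex(list(c(1, 2, 3), c(1, 4), c(2, 4), c(3, 4)))
#' @export
mfe_complex <- function(facets, structure = NULL) {
  if (is.data.frame(facets)) facets <- facets$facet
  facets <- lapply(facets, function(s) sort(unique(as.integer(s))))
  if (length(facets) == 0L) stop("`facets` must be non-empty", call. = FALSE)
  if (!is.null(structure)) {
    bad <- setdiff(unlist(facets), structure$var_index)
    if (length(bad) > 0L) {
      stop("facet variable(s) ", paste(bad, collapse = ", "),
           " unknown to the structure", call. = FALSE)
    }
  }
  # drop facets contained in other facets
  keep <- vapply(seq_along(facets), function(i) {
    !any(vapply(seq_along(facets), function(j) {
      j != i && (length(facets[[i]]) < length(facets[[j]]) ||
                 (length(facets[[i]]) == length(facets[[j]]) && j < i &&
                  identical(facets[[i]], facets[[j]]))) &&
        all(facets[[i]] %in% facets[[j]])
    }, logical(1)))
  }, logical(1))
  facets <- facets[keep]
  # downward closure
  faces <- new.env(parent = emptyenv())
  for (f in facets) {
    for (s in nonempty_subsets(f)) faces[[subset_key(s)]] <- s
  }
  face_list <- as.list(faces)
  face_list <- face_list[sort(names(face_list))]
  sizes <- vapply(face_list, length, integer(1))
  dmax <- max(sizes)
  face_vector <- vapply(seq_len(dmax), function(k) sum(sizes == k),
                        integer(1))
  euler <- sum((-1)^(seq_len(dmax) - 1) * face_vector)
  h_plus <- NA_real_
  if (!is.null(structure)) {
    h_plus <- sum(vapply(face_list, function(s) {
      (-1)^(length(s) - 1) * mutual_information(structure, s)
    }, numeric(1)))
  }
  structure(
    list(
      facets = facets,
      faces = unname(face_list),
      face_vector = face_vector,
      dimension = dmax,               # variable-count (critical-dimension)
      geometric_dimension = dmax - 1L,
      euler_characteristic = as.integer(euler),
      h_plus = h_plus
    ),
    class = "mfe_complex"
  )
}

#' Extract the minimum free energy complex of a structure
#'
#' Convenience wrapper: runs [maximal_positive_paths()] and closes the
#' resulting facets into an [mfe_complex()], carrying the structure so the
#' minimum free energy characteristic is filled in.
#'
#' @inheritParams maximal_positive_paths
#' @return An `mfe_complex`.
#' @export
minimum_free_energy_complex <- function(structure, tol = 1e-10,
                                        strict = TRUE) {
  mfe_complex(maximal_positive_paths(structure, tol = tol, strict = strict),
              structure = structure)
}

#' @export
print.mfe_complex <- function(x, ...) {
  cat("<mfe_complex> ", length(x$facets), " facet(s), dimension ",
      x$dimension, " (geometric ", x$geometric_dimension, ")\n", sep = "")
  cat("  face vector: (", paste(x$face_vector, collapse = ", "),
      ")  chi = ", x$euler_characteristic, "\n", sep = "")
  if (!is.na(x$h_plus)) {
    cat("  minimum free energy characteristic H+ = ", format(x$h_plus),
        " bits\n", sep = "")
  }
  cat("  facets: ", paste(vapply(x$facets, subset_key, character(1)),
                          collapse = " | "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.mfe_complex <- function(x, ...) {
  tibble::tibble(
    key = vapply(x$faces, subset_key, character(1)),
    size = vapply(x$faces, length, integer(1)),
    dim = vapply(x$faces, length, integer(1)) - 1L,
    is_facet = vapply(x$faces, function(f) {
      any(vapply(x$facets, function(g) identical(f, g), logical(1)))
    }, logical(1))
  )
}

#' @export
glance.mfe_complex <- function(x, ...) {
  tibble::tibble(
    n_facets = length(x$facets),
    n_faces = length(x$faces),
    dimension = x$dimension,
    geometric_dimension = x$geometric_dimension,
    euler_characteristic = x$euler_characteristic,
    h_plus = x$h_plus
  )
}
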