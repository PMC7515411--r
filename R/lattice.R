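#' Enumerate the simplicial lattice of variable subsets
#'
#' All non-empty subsets of `n` variables up to size `kmax`, in a
#' deterministic order: grouped by degree, lexicographic within degree.
#' The count at degree `k` is `choose(n, k)`.
#'
#' @param n Number of variables; a scalar `n` means indices `1..n`, while
#'   an integer vector of length `> 1` names the variable indices
#'   themselves.
#' @param kmax Maximum subset size, `1 <= kmax <= n`.
#' @return A tibble with columns `key` (sorted comma-joined 1-based
#'   indices), `degree`, and `vars` (list of integer vectors).
#' @examples
#' enumerate_subsets(4, 2)
#' @export
enumerate_subsets <- function(n, kmax = NULL) {
  idx <- if (length(n) == 1L) seq_len(n) else sort(as.integer(n))
  enumerate_index_subsets(idx, kmax)
}

# subset enumeration over an explicit index vector (any length)
enumerate_index_subsets <- function(idx, kmax = NULL) {
  if (is.null(kmax)) kmax <- length(idx)
  if (kmax < 1L || kmax > length(idx)) {
    stop("`kmax` must lie in 1..", length(idx), call. = FALSE)
  }
  rows <- lapply(seq_len(kmax), function(k) {
    subs <- lapply(utils::combn(seq_along(idx), k, simplify = FALSE),
                   function(p) idx[p])
    tibble::tibble(
      key = vapply(subs, subset_key, character(1)),
      degree = k,
      vars = subs
    )
  })
  dplyr::bind_rows(rows)
}

subset_key <- function(s) paste(sort(as.integer(s)), collapse = ",")

#' Compute the simplicial information structure
#'
#' Evaluates the joint entropy `H(S)` and the multivariate mutual
#' information `I(S)` for every non-empty variable subset `S` of size at
#' most `kmax`.  Entropies come from the empirical joint of each subset
#' (plug-in estimate) when `x` is a coded data matrix, or from
#' marginalization when `x` is a [joint_dist]; informations follow by
#' inclusion-exclusion over the cached subset entropies.
#'
#' The number of evaluations is `sum over k of choose(n, k)`; computation
#' refuses to start above `max_subsets` (default `2^21`) unless
#' `force = TRUE`.
#'
#' @param x A [joint_dist] or an integer-coded data frame / tibble (rows =
#'   samples) as produced by [bin_data()] or [sample_matrix()].
#' @param kmax Maximum degree (defaults to the number of variables).
#' @param max_subsets Complexity cap on the subset count.
#' @param force Proceed even above the cap.
#' @return An object of class `info_structure`: a list with `subsets`
#'   (tibble `key`, `degree`, `vars`, `H`, `I`), `n`, `kmax`, `m` (sample
#'   count, `NA` for exact distributions) and `var_index`.
#' @examples
#' info_structure(gen_borromean())
#' @export
info_structure <- function(x, kmax = NULL, max_subsets = 2^21, force = FALSE) {
  from_data <- !inherits(x, "joint_dist")
  if (from_data) {
    df <- tibble::as_tibble(x)
    var_index <- seq_len(ncol(df))
    m <- nrow(df)
  } else {
    var_index <- x$vars$index
    m <- attr(x, "m") %||% NA_integer_
  }
  n <- length(var_index)
  if (is.null(kmax)) kmax <- n
  subs <- enumerate_index_subsets(var_index, kmax)
  if (nrow(subs) > max_subsets && !force) {
    stop("structure would require ", nrow(subs), " subset evaluations ",
         "(cap ", max_subsets, "); raise `max_subsets` or set force = TRUE",
         call. = FALSE)
  }
  H <- numeric(nrow(subs))
  if (from_data) {
    cards <- attr(x, "cardinalities")
    if (is.null(cards)) {
      cards <- vapply(df, function(v) as.integer(max(v)) + 1L, integer(1))
    }
    for (i in seq_len(nrow(subs))) {
      s <- subs$vars[[i]]
      jd <- empirical_joint(df, s, cardinalities = cards[s])
      H[i] <- entropy(jd)
    }
  } else {
    for (i in seq_len(nrow(subs))) {
      H[i] <- entropy(x, subs$vars[[i]])
    }
  }
  names(H) <- subs$key
  # I by inclusion-exclusion over cached subset entropies
  I <- numeric(nrow(subs))
  for (i in seq_len(nrow(subs))) {
    s <- subs$vars[[i]]
    acc <- 0
    for (T in nonempty_subsets(s)) {
      acc <- acc + (-1)^(length(T) - 1) * H[[subset_key(T)]]
    }
    I[i] <- acc
  }
  subs$H <- unname(H)
  subs$I <- I
  structure(
    list(subsets = subs, n = n, kmax = kmax, m = m, var_index = var_index),
    class = "info_structure"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

structure_value <- function(st, subset, what = c("H", "I")) {
  what <- match.arg(what)
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) == 0L) return(0)
  key <- subset_key(subset)
  i <- match(key, st$subsets$key)
  if (is.na(i)) {
    stop("subset {", key, "} is not in the computed structure (kmax = ",
         st$kmax, ")", call. = FALSE)
  }
  st$subsets[[what]][i]
}

#' @export
print.info_structure <- function(x, ...) {
  cat("<info_structure> n = ", x$n, ", kmax = ", x$kmax,
      if (!is.na(x$m)) paste0(", estimated from m = ", x$m, " samples"),
      "\n", sep = "")
  cat("  ", nrow(x$subsets), " subsets; H(max degree) = ",
      format(max(x$subsets$H[x$subsets$degree == x$kmax])), " bits\n", sep = "")
  invisible(x)
}

#' @export
tidy.info_structure <- function(x, ...) {
  dplyr::select(x$subsets, "key", "degree", "H", "I")
}

#' @export
glance.info_structure <- function(x, ...) {
  ed <- if (x$kmax == x$n) energy_decomposition(x) else
    tibble::tibble(n_vars = x$n, U = NA_real_, G = NA_real_, H = NA_real_)
  tibble::tibble(
    n = x$n, kmax = x$kmax, n_subsets = nrow(x$subsets), m = x$m,
    U = ed$U, G = ed$G, H = ed$H
  )
}

#' Entropy / information landscape with degeneracy counts
#'
#' Groups the per-degree values of an [info_structure] into a landscape:
#' for each degree `k`, the distinct values (within an absolute grouping
#' tolerance) and the number of k-subsets attaining each.  Degeneracies at
#' degree `k` always sum to `choose(n, k)`.
#'
#' @param structure An [info_structure].
#' @param kind `"information"` or `"entropy"`.
#' @param tol Absolute tolerance for grouping near-equal values.
#' @return A tibble of class `info_landscape` with columns `degree`,
#'   `value` (bits) and `count`.
#' @examples
#' landscape(info_structure(gen_borromean()), "information")
#' @export
landscape <- function(structure, kind = c("information", "entropy"),
                      tol = 1e-9) {
  kind <- match.arg(kind)
  col <- if (kind == "entropy") "H" else "I"
  out <- structure$subsets |>
    dplyr::group_by(.data$degree) |>
    dplyr::reframe(group_values(.data[[col]], tol))
  out <- tibble::new_tibble(out, kind = kind, n = structure$n,
                            class = "info_landscape")
  out
}

# cluster a numeric vector by absolute tolerance, return value/count pairs
group_values <- function(v, tol) {
  o <- order(v)
  sv <- v[o]
  grp <- cumsum(c(1, diff(sv) > tol))
  tibble::tibble(
    value = as.numeric(tapply(sv, grp, mean)),
    count = as.integer(tapply(sv, grp, length))
  )
}

#' @export
autoplot.info_landscape <- function(object, ...) {
  kind <- attr(object, "kind")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$degree, y = .data$value,
                               colour = .data$count)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c(name = "degeneracy") +
    ggplot2::scale_x_continuous(breaks = unique(object$degree)) +
    ggplot2::labs(
      x = "degree k",
      y = if (kind == "entropy") "H[k] (bits)" else "I[k] (bits)",
      title = paste0(kind, " landscape")
    ) +
    ggplot2::theme_minimal()
}

#' Mean entropy and information paths
#'
#' The per-degree averages `<Hk>` and `<Ik>` over all `choose(n, k)`
#' k-subsets: the homogeneous (mean-field) summary of the structure.  The
#' homogeneous internal energy is `n <I1>`, the homogeneous free energy is
#' the alternating sum of `choose(n, i) <Ii>` for `i >= 2`, and the mean
#' path obeys `H = U - G` like any single path.  The first degree at which
#' `<Ik>` rises again (a local minimum of the mean information path) is
#' reported as the homogeneous critical dimension.
#'
#' @param structure An [info_structure].
#' @param tol Tolerance for detecting a strict rise of `<Ik>`.
#' @return A tibble of class `mean_path` with columns `degree`, `H_mean`,
#'   `I_mean`, and attributes `U_hom`, `G_hom`, `H_hom`,
#'   `critical_dimension` (NA when the mean path never rises).
#' @examples
#' mean_paths(info_structure(gen_borromean()))
#' @export
mean_paths <- function(structure, tol = 1e-10) {
  av <- structure$subsets |>
    dplyr::group_by(.data$degree) |>
    dplyr::summarise(H_mean = mean(.data$H), I_mean = mean(.data$I))
  n <- structure$n
  ks <- av$degree
  U_hom <- n * av$I_mean[ks == 1]
  G_hom <- 0
  for (i in ks[ks >= 2]) {
    G_hom <- G_hom + (-1)^i * choose(n, i) * av$I_mean[ks == i]
  }
  # first local minimum of <Ik>: a strict drop into k followed by a strict
  # rise, or a strict drop into the terminal degree
  crit <- NA_integer_
  im <- av$I_mean
  for (j in seq_along(im)[-1]) {
    if (ks[j] >= 3 && im[j] < im[j - 1] - tol &&
        (j == length(im) || im[j + 1] > im[j] + tol)) {
      crit <- as.integer(ks[j])
      break
    }
  }
  tibble::new_tibble(av, U_hom = U_hom, G_hom = G_hom,
                     H_hom = max(av$H_mean[ks == max(ks)]),
                     critical_dimension = crit, n = n,
                     class = "mean_path")
}

#' @export
autoplot.mean_path <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("H_mean", "I_mean"),
                              names_to = "kind", values_to = "bits")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$degree, y = .data$bits,
                                     colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_discrete(labels = c("<Hk>", "<Ik>"), name = NULL) +
    ggplot2::labs(x = "degree k", y = "bits", title = "mean information path") +
    ggplot2::theme_minimal()
}
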