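# Independent brute-force oracles, written against raw probability arrays
# with base R only -- deliberately not sharing code paths with the package.

# marginal array over array-margin positions `keep` (ascending)
oracle_marginal <- function(p, keep) {
  if (length(keep) == length(dim(p))) return(p)
  apply(p, keep, sum)
}

oracle_H <- function(p) {
  q <- as.numeric(p)
  q <- q[q > 0]
  -sum(q * log2(q))
}

# direct state-sum for the k-mutual information (alternating product of
# subset marginals inside the log), positions are array margins
oracle_Ik_statesum <- function(p, pos) {
  dims <- dim(p)
  grid <- as.matrix(expand.grid(lapply(dims, seq_len)))
  subsets <- list()
  for (k in seq_along(pos)) {
    cmb <- combn(seq_along(pos), k)
    for (j in seq_len(ncol(cmb))) subsets <- c(subsets, list(pos[cmb[, j]]))
  }
  total <- 0
  pv <- as.numeric(p)
  for (r in seq_len(nrow(grid))) {
    px <- pv[r]
    if (px == 0) next
    logterm <- 0
    for (T in subsets) {
      mT <- oracle_marginal(p, T)
      coord <- grid[r, T, drop = TRUE]
      pT <- if (length(T) == 1L) mT[coord] else mT[matrix(coord, 1)]
      logterm <- logterm + (-1)^(length(T) - 1) * log2(pT)
    }
    total <- total - px * logterm
  }
  total
}

# direct conditional mutual information of two margins given a third set,
# state by state (weighted sum of per-slice mutual informations)
oracle_cmi2_statesum <- function(p, a, b, given) {
  dims <- dim(p)
  gvals <- expand.grid(lapply(dims[given], seq_len))
  total <- 0
  grid <- as.matrix(expand.grid(lapply(dims, seq_len)))
  pv <- as.numeric(p)
  for (r in seq_len(nrow(gvals))) {
    sel <- rep(TRUE, nrow(grid))
    for (j in seq_along(given)) {
      sel <- sel & grid[, given[j]] == gvals[r, j]
    }
    py <- sum(pv[sel])
    if (py == 0) next
    slice <- pv[sel] / py
    sg <- grid[sel, , drop = FALSE]
    # mutual information of margins a, b inside the slice
    key_a <- apply(sg[, a, drop = FALSE], 1, paste, collapse = ",")
    key_b <- apply(sg[, b, drop = FALSE], 1, paste, collapse = ",")
    key_ab <- paste(key_a, key_b, sep = "|")
    pa <- tapply(slice, key_a, sum)
    pb <- tapply(slice, key_b, sum)
    pab <- tapply(slice, key_ab, sum)
    mi <- 0
    for (s in names(pab)) {
      if (pab[[s]] == 0) next
      parts <- strsplit(s, "|", fixed = TRUE)[[1]]
      mi <- mi + pab[[s]] *
        log2(pab[[s]] / (pa[[parts[1]]] * pb[[parts[2]]]))
    }
    total <- total + py * mi
  }
  total
}

# exhaustive-permutation facet oracle: a set is positive when some ordering
# of it has a strictly decreasing information profile; return the maximal
# positive sets (sorted keys)
oracle_facets_exhaustive <- function(st, tol = 1e-10) {
  vars <- st$var_index
  n <- length(vars)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  positive <- character(0)
  pos_sets <- list()
  for (k in seq_len(st$kmax)) {
    cmb <- combn(n, k)
    for (j in seq_len(ncol(cmb))) {
      s <- vars[cmb[, j]]
      ok <- FALSE
      for (o in perms(s)) {
        prof <- vapply(seq_along(o), function(l) {
          mutual_information(st, o[seq_len(l)])
        }, numeric(1))
        if (all(diff(prof) < -tol)) { ok <- TRUE; break }
      }
      if (length(s) == 1L) ok <- TRUE  # single vertices are trivially positive
      if (ok) {
        positive <- c(positive, paste(sort(s), collapse = ","))
        pos_sets <- c(pos_sets, list(sort(s)))
      }
    }
  }
  maximal <- vapply(seq_along(pos_sets), function(i) {
    !any(vapply(seq_along(pos_sets), function(j) {
      j != i && length(pos_sets[[i]]) < length(pos_sets[[j]]) &&
        all(pos_sets[[i]] %in% pos_sets[[j]])
    }, logical(1)))
  }, logical(1))
  sort(positive[maximal])
}

# independent downward-closure checker for a complex
oracle_is_closed <- function(cx) {
  keys <- vapply(cx$faces, function(f) paste(sort(f), collapse = ","),
                 character(1))
  for (f in cx$faces) {
    if (length(f) == 1L) next
    for (i in seq_along(f)) {
      sub <- paste(sort(f[-i]), collapse = ",")
      if (!(sub %in% keys)) return(FALSE)
    }
  }
  TRUE
}

# seeded random joint distributions for property loops
random_joints <- function(n_dists, nvar, card = 2, seed0 = 100) {
  lapply(seq_len(n_dists), function(i) {
    gen_random_dirichlet(nvar, cardinality = card, seed = seed0 + i)
  })
}
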