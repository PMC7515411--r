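#' Read a samples-by-variables matrix from TSV/CSV
#'
#' Expects a header row of variable names and numeric cells.  The
#' delimiter is auto-detected from the first line (tab beats comma) unless
#' forced.
#'
#' @param path File path.
#' @param delim Optional delimiter override (`"\t"` or `","`).
#' @return A tibble of numeric columns.
#' @export
read_data_matrix <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.delim(path, sep = delim, header = TRUE,
                          check.names = FALSE)
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("non-numeric cells in ", path, call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Serialize / deserialize joint distributions as JSON
#'
#' The on-disk format lists the variables (1-based `index`, `cardinality`,
#' optional `name`) and the non-zero probabilities keyed by comma-joined
#' 0-based state codes, e.g. `{"0,1,1": 0.25}`.
#'
#' @param joint A [joint_dist].
#' @param path Output / input file path.
#' @return `write_joint_json()` returns `path` invisibly;
#'   `read_joint_json()` returns a [joint_dist].
#' @export
write_joint_json <- function(joint, path) {
  stopifnot(inherits(joint, "joint_dist"))
  td <- tidy.joint_dist(joint)
  nz <- td[td$prob > 0, ]
  obj <- list(
    variables = lapply(seq_len(nrow(joint$vars)), function(i) {
      list(index = joint$vars$index[i],
           cardinality = joint$vars$cardinality[i],
           name = joint$vars$name[i])
    }),
    probs = as.list(stats::setNames(nz$prob, nz$state))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_joint_json
#' @export
read_joint_json <- function(path) {
  obj <- jsonlite::read_json(path)
  vars <- obj$variables
  cards <- vapply(vars, function(v) as.integer(v$cardinality), integer(1))
  idx <- vapply(vars, function(v) as.integer(v$index), integer(1))
  nms <- vapply(vars, function(v) v$name %||% paste0("X", v$index),
                character(1))
  p <- array(0, dim = cards)
  g <- state_grid(cards)
  keys <- apply(g, 1, paste, collapse = ",")
  for (k in names(obj$probs)) {
    i <- match(k, keys)
    if (is.na(i)) stop("state key '", k, "' outside the product alphabet",
                       call. = FALSE)
    p[i] <- as.numeric(obj$probs[[k]])
  }
  joint_dist(p, cardinalities = cards, indices = idx, names = nms)
}

#' Run the full analysis pipeline
#'
#' From a coded (or raw, to-be-binned) data matrix or an explicit joint
#' distribution to one results bundle: the simplicial information
#' structure, both landscapes, the mean paths, the energy decomposition,
#' the minimum free energy complex and the coboundary identity report.
#'
#' @param input A file path (TSV/CSV matrix or joint-distribution JSON), a
#'   data frame, or a [joint_dist].
#' @param bins Alphabet size for binning raw data (ignored for integer
#'   codes and joint distributions).
#' @param strategy Binning strategy, see [bin_data()].
#' @param kmax Maximum degree, default all variables.
#' @param tol Positivity / grouping tolerance in bits.
#' @param path_cap Cap on enumerated paths for the second-law audit.
#' @param seed Seed recorded in the bundle and used for any sampling.
#' @param out Optional path: write the bundle as JSON.
#' @return A list (invisibly when `out` is given) with elements `config`,
#'   `structure`, `landscape_entropy`, `landscape_information`,
#'   `mean_path`, `energy`, `facets`, `complex`, `cohomology`,
#'   `second_law`.
#' @export
run_pipeline <- function(input, bins = 8, strategy = "quantile",
                         kmax = NULL, tol = 1e-10, path_cap = 5000L,
                         seed = 1L, out = NULL) {
  joint <- NULL
  data <- NULL
  if (inherits(input, "joint_dist")) {
    joint <- input
  } else if (is.character(input)) {
    if (grepl("\\.json$", input, ignore.case = TRUE)) {
      joint <- read_joint_json(input)
    } else {
      data <- read_data_matrix(input)
    }
  } else {
    data <- tibble::as_tibble(input)
  }
  if (!is.null(data)) {
    coded <- bin_data(data, bins = bins, strategy = strategy)
    st <- info_structure(coded, kmax = kmax)
    joint <- empirical_joint(coded,
                             cardinalities = attr(coded, "cardinalities"))
  } else {
    st <- info_structure(joint, kmax = kmax)
  }
  facets <- maximal_positive_paths(st, tol = tol)
  cplx <- mfe_complex(facets, structure = st)
  coh <- tryCatch(verify_identities(joint, tol = max(tol, 1e-9)),
                  error = function(e) NULL)
  bundle <- list(
    config = list(bins = bins, strategy = strategy, kmax = st$kmax,
                  tol = tol, path_cap = path_cap, seed = seed),
    structure = tidy.info_structure(st),
    landscape_entropy = tibble::as_tibble(landscape(st, "entropy")),
    landscape_information = tibble::as_tibble(landscape(st, "information")),
    mean_path = tibble::as_tibble(mean_paths(st)),
    energy = energy_decomposition(st),
    facets = facets[, c("key", "size", "stop_reason", "truncated")],
    complex = glance.mfe_complex(cplx),
    cohomology = coh,
    second_law = second_law_audit(st, cap = path_cap, seed = seed, tol = 1e-9)
  )
  if (!is.null(out)) {
    jsonlite::write_json(bundle, out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
    return(invisible(bundle))
  }
  bundle
}
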