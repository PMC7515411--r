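#' Discretize a real-valued matrix into integer codes
#'
#' Maps each column of a samples-by-variables table onto an N-letter
#' alphabet (the "graining"), either by equal-width bins over the observed
#' range or by sample quantiles.  The default is quantile binning, which
#' spreads the finite sample as evenly as possible over the alphabet and so
#' makes the most of the marginal entropy budget.
#'
#' Quantile boundaries that coincide (columns with heavy ties) are collapsed
#' with a warning, so the effective alphabet of a column can be smaller than
#' requested.  Columns that are already integer-coded with fewer than `bins`
#' distinct values pass through unchanged under either strategy.
#'
#' @param raw A data frame / tibble or matrix of numeric values, one row per
#'   sample.  Rows with missing values are dropped listwise with a message.
#' @param bins Positive integer alphabet size, or one per column.
#' @param strategy `"quantile"` (default) or `"equal-width"`.
#' @return A tibble of integer codes in `0..bins-1`, with attributes
#'   `cardinalities` (integer per column) and `breaks` (list of numeric
#'   boundary vectors, for reporting).
#' @examples
#' bin_data(data.frame(x = c(0.1, 0.2, 0.9, 1.0)), bins = 2,
#'          strategy = "equal-width")
#' @export
bin_data <- function(raw, bins = 8, strategy = c("quantile", "equal-width")) {
  strategy <- match.arg(strategy)
  df <- as.data.frame(raw)
  if (nrow(df) < 1L) stop("`raw` must have at least one row", call. = FALSE)
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("all columns must be numeric", call. = FALSE)
  }
  keep <- stats::complete.cases(df)
  if (!all(keep)) {
    message("dropping ", sum(!keep), " row(s) with missing values")
    df <- df[keep, , drop = FALSE]
    if (nrow(df) == 0L) stop("no complete rows left after dropping missing values",
                             call. = FALSE)
  }
  bins <- as.integer(bins)
  if (length(bins) == 1L) bins <- rep(bins, ncol(df))
  if (length(bins) != ncol(df) || any(bins < 1L)) {
    stop("`bins` must be a positive integer, one overall or one per column",
         call. = FALSE)
  }
  breaks <- vector("list", ncol(df))
  cards <- integer(ncol(df))
  out <- df
  for (j in seq_len(ncol(df))) {
    v <- df[[j]]
    nb <- bins[j]
    already_coded <- all(v == floor(v)) && min(v) >= 0 && max(v) <= nb - 1L
    if (nb == 1L) {
      out[[j]] <- rep(0L, length(v))
      breaks[[j]] <- range(v)
      cards[j] <- 1L
      next
    }
    if (already_coded) {
      out[[j]] <- as.integer(v)
      breaks[[j]] <- numeric(0)
      cards[j] <- nb
      next
    }
    if (strategy == "equal-width") {
      rng <- range(v)
      if (rng[1] == rng[2]) {
        out[[j]] <- rep(0L, length(v))
        breaks[[j]] <- rng
        cards[j] <- 1L
        next
      }
      br <- seq(rng[1], rng[2], length.out = nb + 1L)
    } else {
      br <- stats::quantile(v, probs = seq(0, 1, length.out = nb + 1L),
                            names = FALSE, type = 7)
      ubr <- unique(br)
      if (length(ubr) < length(br)) {
        warning("column ", j, ": duplicate quantile boundaries collapsed (",
                length(ubr) - 1L, " effective bin(s) of ", nb, " requested)",
                call. = FALSE)
        br <- ubr
      }
      if (length(br) < 2L) {
        out[[j]] <- rep(0L, length(v))
        breaks[[j]] <- br
        cards[j] <- 1L
        next
      }
    }
    codes <- findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE) - 1L
    out[[j]] <- as.integer(codes)
    breaks[[j]] <- br
    cards[j] <- length(br) - 1L
  }
  res <- tibble::as_tibble(out)
  attr(res, "cardinalities") <- cards
  attr(res, "breaks") <- breaks
  res
}
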