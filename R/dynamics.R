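# Gaussian smoothing of a series with kernel truncated at 4*sigma and
# reflected boundaries.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  n <- length(x)
  half <- min(max(1L, ceiling(4 * sigma)), n - 1L)
  kern <- dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  padded <- c(rev(x[seq_len(half) + 1L]), x, rev(x[n - seq_len(half)]))
  as.vector(stats::filter(padded, kern, sides = 2L))[half + seq_len(n)]
}

#' Sliding-window expression extrema along the cell order
#'
#' Slides a window of `n_window` consecutive cells across the cell
#' ordering and reports the windows with the maximum and minimum mean
#' expression, with their center positions (index into the ordered
#' cells). Ties pick the first window.
#'
#' @param expr_row Numeric expression vector (one gene across cells).
#' @param order Per-cell order used to sort the cells.
#' @param n_window Window width in cells (default 20).
#' @return List with `max_mean`, `min_mean`, `max_pos`, `min_pos`
#'   (positions are window centers on the ordered axis).
#' @export
window_extrema <- function(expr_row, order, n_window = 20L) {
  n <- length(expr_row)
  if (length(order) != n)
    stop("'order' must align with 'expr_row'", call. = FALSE)
  if (n < n_window)
    stop(sprintf("need at least %d cells for the %d-cell window",
                 n_window, n_window), call. = FALSE)
  x <- expr_row[base::order(order)]
  cs <- c(0, cumsum(x))
  means <- (cs[(n_window + 1L):(n + 1L)] - cs[seq_len(n - n_window + 1L)]) /
    n_window
  imax <- which.max(means)
  imin <- which.min(means)
  center <- function(i) i + (n_window - 1) / 2
  list(max_mean = means[imax], min_mean = means[imin],
       max_pos = center(imax), min_pos = center(imin))
}

#' Select dynamically varying genes
#'
#' A gene is called dynamic when the spread between its maximum and
#' minimum sliding-window mean expression along the cell order reaches
#' `min_delta` (on the normalized expression scale). The window
#' computation is [window_extrema()]; `min_delta` is an explicit knob
#' with no canonical value — tune it to the planted effect size or
#' expected dynamic range of the data.
#'
#' @param expr Normalized genes x cells matrix.
#' @param order Per-cell order (named or aligned to columns).
#' @param min_delta Minimum max-minus-min window-mean difference
#'   (default 2).
#' @param n_window Window width in cells (default 20).
#' @return Data.frame (gene, delta, max_pos, min_pos) of selected genes,
#'   sorted by decreasing delta.
#' @export
select_dynamic_genes <- function(expr, order, min_delta = 2,
                                 n_window = 20L) {
  x <- as_expr_matrix(expr)
  if (!is.null(names(order))) order <- order[colnames(x)]
  res <- lapply(seq_len(nrow(x)), function(gi)
    window_extrema(x[gi, ], order, n_window))
  delta <- vapply(res, function(r) r$max_mean - r$min_mean, numeric(1L))
  keep <- delta >= min_delta
  out <- data.frame(gene = rownames(x)[keep], delta = delta[keep],
                    max_pos = vapply(res[keep], `[[`, numeric(1L), "max_pos"),
                    min_pos = vapply(res[keep], `[[`, numeric(1L), "min_pos"),
                    stringsAsFactors = FALSE)
  out[base::order(-out$delta), , drop = FALSE]
}

#' Detect retained expression inflection points
#'
#' Each gene's expression across the ordered cells is Gaussian-smoothed
#' (width sigma = `sigma_frac` of the trajectory length) and the
#' derivative d_k is computed by central differences. The positions of
#' maximally increasing and maximally decreasing expression (argmax and
#' argmin of d_k) are the candidates; the gene's inflection point is
#' the dominant one — the extremum of largest absolute derivative —
#' so each gene contributes (at most) one turn-on or turn-off event,
#' which is what the inflection *density* counts. The point is retained
#' only if it stands out from the gene's typical fluctuation:
#' max(|d_k|) / median(|d_k|) > Q. The ratio uses absolute derivatives
#' — a turn-off gene's defining derivative is negative, so a signed
#' ratio would never retain it. Flat genes (median |d_k| = 0) retain
#' nothing. The test is invariant to positive rescaling of the gene.
#'
#' @param expr Normalized genes x cells matrix (or one row).
#' @param order Per-cell order used to sort cells.
#' @param Q Retention threshold on the derivative ratio (default 3).
#' @param sigma_frac Smoothing width as a fraction of the trajectory
#'   length (default 0.01).
#' @return Data.frame of class `inflection_set`: gene, position (index
#'   on the ordered axis), order_position (order value at that cell),
#'   sign (+1 turn-on, -1 turn-off), derivative, ratio. Attribute
#'   `sigma` records the smoothing width in index units.
#' @export
detect_inflections <- function(expr, order, Q = 3, sigma_frac = 0.01) {
  x <- as_expr_matrix(expr)
  if (!is.null(names(order)) && !is.null(colnames(x)))
    order <- order[colnames(x)]
  n <- ncol(x)
  sigma <- sigma_frac * n
  ord_idx <- base::order(order)
  ord_sorted <- order[ord_idx]
  rows <- vector("list", nrow(x))
  for (gi in seq_len(nrow(x))) {
    sm <- gaussian_smooth(x[gi, ord_idx], sigma)
    d <- c(sm[2L] - sm[1L],
           (sm[3:n] - sm[1:(n - 2L)]) / 2,
           sm[n] - sm[n - 1L])
    med <- median(abs(d))
    if (med == 0) next
    cand <- c(which.max(d), which.min(d))
    dominant <- cand[which.max(abs(d[cand]))]
    ratio <- abs(d[dominant]) / med
    if (ratio <= Q) next
    rows[[gi]] <- data.frame(gene = rownames(x)[gi],
                             position = dominant,
                             order_position = ord_sorted[dominant],
                             sign = if (d[dominant] > 0) 1L else -1L,
                             derivative = d[dominant],
                             ratio = ratio,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), position = numeric(),
                      order_position = numeric(), sign = integer(),
                      derivative = numeric(), ratio = numeric())
  rownames(out) <- NULL
  attr(out, "sigma") <- sigma
  class(out) <- c("inflection_set", "data.frame")
  out
}

#' Density of inflection points over the cell ordering
#'
#' Gaussian kernel density of the retained inflection positions,
#' evaluated on a grid of `n_cells` points along the ordered axis and
#' scaled so that its integral equals the number of points. Regions of
#' coordinated transcriptional change (stage transitions) appear as
#' density peaks; stable states as valleys.
#'
#' @param points An [detect_inflections()] result (or a numeric vector
#'   of positions in index units).
#' @param n_cells Number of cells (grid length).
#' @param bandwidth Kernel standard deviation in index units; defaults
#'   to the smoothing sigma of the inflection set (or 1% of `n_cells`).
#' @return Data.frame (position, density) of length `n_cells`.
#' @export
inflection_density <- function(points, n_cells, bandwidth = NULL) {
  pos <- if (is.data.frame(points)) points$position else as.numeric(points)
  if (is.null(bandwidth))
    bandwidth <- if (!is.null(attr(points, "sigma"))) attr(points, "sigma")
                 else 0.01 * n_cells
  grid <- seq_len(n_cells)
  if (!length(pos)) {
    warning("no inflection points; returning a zero profile",
            call. = FALSE)
    return(data.frame(position = grid, density = rep(0, n_cells)))
  }
  dens <- rowSums(vapply(pos, function(p) dnorm(grid, mean = p,
                                                sd = bandwidth),
                         numeric(n_cells)))
  data.frame(position = grid, density = dens)
}
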