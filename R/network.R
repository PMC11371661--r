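#' Build a functional connectivity matrix from regional time series
#'
#' Computes the pairwise Pearson correlation between region-averaged BOLD
#' time courses. By default the absolute value is taken (the absolute-FC
#' convention), so weights lie in \[0, 1\]; set `absolute = FALSE` to keep
#' signed correlations. The diagonal is zeroed.
#'
#' @param ts a [timeseries_matrix()] (regions x time).
#' @param absolute take `abs()` of the correlations (default `TRUE`).
#' @return a functional [connectivity_matrix()].
#' @export
build_fc <- function(ts, absolute = TRUE) {
  if (!inherits(ts, "timeseries_matrix"))
    ts <- timeseries_matrix(as.matrix(ts))
  const <- attr(ts, "constant_regions")
  if (length(const))
    stop("constant time series for region(s): ",
         paste(const, collapse = ", "), call. = FALSE)
  r <- stats::cor(t(unclass(ts)))
  if (absolute) r <- abs(r)
  diag(r) <- 0
  # cor() can stray past 1 by rounding; clip before validation
  r[r > 1] <- 1; r[r < -1] <- -1
  connectivity_matrix(r, kind = "functional",
                      region_labels = rownames(ts))
}

#' Symmetrize a directed structural connectivity matrix
#'
#' Probabilistic tractography gives a direction-dependent connection
#' probability from seed region i to target region j; an undirected edge
#' weight is obtained by averaging the two directions:
#' `out_ij = (w_ij + w_ji) / 2`. The diagonal is zeroed.
#'
#' @param w square nonnegative numeric matrix (possibly asymmetric), e.g. as
#'   returned by `read_matrix(..., symmetric = FALSE)`.
#' @param region_labels optional labels (default: dimnames of `w`).
#' @return a structural [connectivity_matrix()].
#' @export
symmetrize_sc <- function(w, region_labels = NULL) {
  if (!is.matrix(w) || nrow(w) != ncol(w))
    stop("'w' must be a square matrix", call. = FALSE)
  if (any(!is.finite(w))) stop("non-finite entries in 'w'", call. = FALSE)
  if (any(w < 0)) stop("structural weights must be nonnegative", call. = FALSE)
  out <- (w + t(w)) / 2
  diag(out) <- 0
  connectivity_matrix(out, kind = "structural", region_labels = region_labels)
}

#' Proportional sparsity-threshold series
#'
#' The analysis is repeated over a series of network densities to avoid the
#' bias of a single threshold. The default sweeps sparsity (fraction of
#' strongest edges retained) from 8% to 60% in 2% steps: 27 levels.
#'
#' @param from,to,by sparsity range and step, all in (0, 1].
#' @param values explicit sparsity values (overrides `from/to/by`).
#' @return numeric vector of class `"threshold_scheme"`, strictly increasing.
#' @export
threshold_scheme <- function(from = 0.08, to = 0.60, by = 0.02, values = NULL) {
  s <- if (!is.null(values)) as.numeric(values) else seq(from, to, by = by)
  if (!length(s) || any(!is.finite(s)) || any(s <= 0) || any(s > 1))
    stop("sparsity values must lie in (0, 1]", call. = FALSE)
  if (is.unsorted(s, strictly = TRUE))
    stop("sparsity values must be strictly increasing", call. = FALSE)
  structure(s, class = "threshold_scheme")
}

# round half away from zero (matches common connectome-toolbox behaviour;
# base round() is round-half-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# deterministic total order over upper-triangle edges: decreasing weight,
# ties broken by ascending (row, col). Returns a 3-col matrix (i, j, w)
# sorted by that order.
edge_order <- function(m) {
  n <- nrow(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[ut]
  o <- order(-w, ut[, 1L], ut[, 2L])
  cbind(i = ut[o, 1L], j = ut[o, 2L], w = w[o])
}

#' Threshold a connectivity matrix to a target sparsity
#'
#' Retains exactly `k = round(s * n(n-1)/2)` upper-triangle edges with the
#' largest weights (rounding half away from zero); all other edges are set
#' to zero. Ties at the cut are broken deterministically by ascending
#' (row, column) index, so for `s1 < s2` the retained set at `s1` is always
#' a subset of the set at `s2`.
#'
#' @param c a [connectivity_matrix()] (or symmetric numeric matrix).
#' @param s sparsity fraction in (0, 1].
#' @return an object of class `"sparse_network"`: the thresholded symmetric
#'   matrix with attributes `sparsity`, `k` (retained edge count) and
#'   `edges` (k x 2 index matrix of retained upper-triangle edges).
#' @export
threshold_proportional <- function(c, s) {
  if (length(s) != 1L || !is.finite(s) || s <= 0 || s > 1)
    stop("sparsity must be a single value in (0, 1]", call. = FALSE)
  m <- unclass(c)
  n <- nrow(m)
  E <- n * (n - 1) / 2
  k <- as.integer(round_half_away(s * E))
  if (k < 1L)
    stop(sprintf("sparsity %g retains zero edges at n = %d", s, n),
         call. = FALSE)
  eo <- edge_order(m)
  keep <- eo[seq_len(k), , drop = FALSE]
  out <- matrix(0, n, n, dimnames = dimnames(m))
  out[keep[, 1:2, drop = FALSE]] <- keep[, 3L]
  out[keep[, 2:1, drop = FALSE]] <- keep[, 3L]
  structure(out, sparsity = s, k = k,
            edges = keep[, 1:2, drop = FALSE],
            kind = attr(c, "kind"),
            class = c("sparse_network", "matrix"))
}

#' @export
print.sparse_network <- function(x, ...) {
  cat(sprintf("<sparse_network> %d regions, sparsity %.3f (%d edges)\n",
              nrow(x), attr(x, "sparsity"), attr(x, "k")))
  invisible(x)
}

#' Retained upper-triangle edges of a sparse network
#' @param net a `"sparse_network"`.
#' @return k x 2 integer matrix of (row, col) indices, row < col.
#' @export
retained_edges <- function(net) attr(net, "edges")
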