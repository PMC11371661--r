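#' SC-FC coupling over an explicit edge set
#'
#' The coupling statistic: the functional weights of the given retained
#' edges are reshaped to a vector, the structural weights of the *same*
#' edges to another, and the Pearson correlation between the two is
#' returned. Structural zeros are kept as-is (no structural-edge filtering).
#'
#' Undefined results are returned as `NA` with an attribute `code`:
#' `"too_few_edges"` when fewer than 3 edges are supplied, and
#' `"zero_variance"` when either vector is constant.
#'
#' @param fc_sparse a thresholded functional network
#'   ([threshold_proportional()]).
#' @param sc the structural [connectivity_matrix()] on the same regions.
#' @param edges m x 2 index matrix of upper-triangle edges (row < col),
#'   a subset of `retained_edges(fc_sparse)`; defaults to all retained
#'   edges.
#' @return Pearson r in \[-1, 1\], or `NA` with attribute `code`; attribute
#'   `n_edges` carries the edge count used.
#' @export
couple_edges <- function(fc_sparse, sc, edges = retained_edges(fc_sparse)) {
  if (!is.matrix(edges)) edges <- matrix(edges, ncol = 2L)
  m <- nrow(edges)
  if (m < 3L)
    return(structure(NA_real_, code = "too_few_edges", n_edges = m))
  fcv <- unclass(fc_sparse)[edges]
  scv <- unclass(sc)[edges]
  if (stats::var(fcv) < .Machine$double.eps ||
      stats::var(scv) < .Machine$double.eps)
    return(structure(NA_real_, code = "zero_variance", n_edges = m))
  structure(stats::cor(fcv, scv), code = "ok", n_edges = m)
}

#' Whole-brain SC-FC coupling at one sparsity threshold
#'
#' [couple_edges()] over all edges retained in the sparse functional
#' network: one coupling value per subject per threshold.
#'
#' @inheritParams couple_edges
#' @return Pearson r (see [couple_edges()] for undefined markers).
#' @export
whole_brain_coupling <- function(fc_sparse, sc) {
  couple_edges(fc_sparse, sc)
}

#' Modular SC-FC coupling at one sparsity threshold
#'
#' Restricts the coupling statistic to retained edges with *both* endpoints
#' inside one functional module; between-module edges are excluded.
#'
#' @inheritParams couple_edges
#' @param partition a [module_partition()] over the network's regions.
#' @param module_name one of `partition$module_names`.
#' @return Pearson r (NA with `code` when fewer than 3 within-module edges
#'   survive the threshold, or on zero variance).
#' @export
modular_coupling <- function(fc_sparse, sc, partition, module_name) {
  if (!module_name %in% partition$module_names)
    stop("unknown module: ", module_name, call. = FALSE)
  labs <- region_labels(fc_sparse)
  check_partition_regions(partition, labs)
  memb <- partition$module[labs]
  e <- retained_edges(fc_sparse)
  inside <- memb[e[, 1L]] == module_name & memb[e[, 2L]] == module_name
  couple_edges(fc_sparse, sc, e[inside, , drop = FALSE])
}

#' Multilevel SC-FC coupling profile across the sparsity series
#'
#' For each sparsity threshold, thresholds the functional network and
#' computes the whole-brain coupling plus one coupling per functional
#' module, then summarizes each scope across thresholds by the
#' range-normalized (threshold-averaged) AUC.
#'
#' @param fc functional [connectivity_matrix()].
#' @param sc structural [connectivity_matrix()] on the same regions.
#' @param partition a [module_partition()]; `NULL` for whole-brain only.
#' @param scheme a [threshold_scheme()].
#' @param subject optional subject identifier carried in the result.
#' @return object of class `"coupling_profile"`: list with `sparsity`,
#'   `scopes`, matrices `r`, `n_edges`, `code` (scopes x thresholds), and
#'   named vector `auc` (NA where more than 10% of thresholds are
#'   undefined; see [auc_summary()]).
#' @export
coupling_profile <- function(fc, sc, partition = NULL,
                             scheme = threshold_scheme(), subject = NA) {
  labs <- region_labels(fc)
  if (!identical(labs, region_labels(sc)))
    stop("FC and SC region labels disagree", call. = FALSE)
  scopes <- "whole_brain"
  memb <- NULL
  if (!is.null(partition)) {
    check_partition_regions(partition, labs)
    scopes <- c(scopes, partition$module_names)
    memb <- partition$module[labs]
  }
  ns <- length(scheme)
  r <- matrix(NA_real_, length(scopes), ns,
              dimnames = list(scopes, sprintf("s%.2f", as.numeric(scheme))))
  ne <- matrix(0L, length(scopes), ns, dimnames = dimnames(r))
  code <- matrix("ok", length(scopes), ns, dimnames = dimnames(r))

  # one global edge ordering; each threshold is a prefix of it
  m <- unclass(fc)
  eo <- edge_order(m)
  E <- nrow(eo)
  scm <- unclass(sc)
  edge_module <- if (!is.null(memb)) {
    mi <- memb[eo[, 1L]]
    ifelse(mi == memb[eo[, 2L]], mi, NA_character_)
  }
  fcv_all <- eo[, 3L]
  scv_all <- scm[eo[, 1:2, drop = FALSE]]

  couple_vec <- function(fcv, scv) {
    m <- length(fcv)
    if (m < 3L) return(list(NA_real_, "too_few_edges", m))
    if (stats::var(fcv) < .Machine$double.eps ||
        stats::var(scv) < .Machine$double.eps)
      return(list(NA_real_, "zero_variance", m))
    list(stats::cor(fcv, scv), "ok", m)
  }
  for (t in seq_len(ns)) {
    k <- as.integer(round_half_away(scheme[t] * E))
    if (k < 1L) stop("sparsity retains zero edges", call. = FALSE)
    idx <- seq_len(k)
    res <- couple_vec(fcv_all[idx], scv_all[idx])
    r[1L, t] <- res[[1L]]; code[1L, t] <- res[[2L]]; ne[1L, t] <- res[[3L]]
    if (!is.null(memb)) {
      em <- edge_module[idx]
      for (mo in partition$module_names) {
        sel <- which(!is.na(em) & em == mo)
        res <- couple_vec(fcv_all[idx][sel], scv_all[idx][sel])
        row <- match(mo, scopes)
        r[row, t] <- res[[1L]]; code[row, t] <- res[[2L]]
        ne[row, t] <- res[[3L]]
      }
    }
  }
  auc <- apply(r, 1L, auc_summary, scheme = scheme)
  structure(list(subject = subject, sparsity = as.numeric(scheme),
                 scopes = scopes, r = r, n_edges = ne, code = code,
                 auc = auc),
            class = "coupling_profile")
}

#' @export
print.coupling_profile <- function(x, ...) {
  cat(sprintf("<coupling_profile> %s%d thresholds (%.2f-%.2f), %d scope(s)\n",
              if (!is.na(x$subject)) paste0("subject ", x$subject, ", ") else "",
              length(x$sparsity), min(x$sparsity), max(x$sparsity),
              length(x$scopes)))
  cat("  AUC (threshold-averaged coupling):\n")
  for (s in x$scopes)
    cat(sprintf("    %-20s %s\n", s,
                ifelse(is.na(x$auc[[s]]), "undefined",
                       sprintf("%.4f", x$auc[[s]]))))
  invisible(x)
}

#' @export
plot.coupling_profile <- function(x, ...) {
  graphics::matplot(x$sparsity, t(x$r), type = "b", pch = 16, lty = 1,
                    xlab = "sparsity", ylab = "SC-FC coupling (r)", ...)
  graphics::legend("bottomright", legend = x$scopes, col = seq_along(x$scopes),
                   lty = 1, pch = 16, cex = 0.8, bty = "n")
  invisible(x)
}

#' Threshold-averaged area under the curve
#'
#' Summarizes a per-threshold metric series by its trapezoidal integral
#' over sparsity divided by the sparsity range, so the summary shares the
#' metric's scale (a constant series summarizes to that constant). Up to
#' 10% of points may be undefined (`NA`); they are filled by linear
#' interpolation between defined neighbours (constant extension at the
#' ends). With fewer than 2 defined points, or more than 10% undefined,
#' the AUC is `NA`.
#'
#' @param values numeric vector, one value per threshold (NA = undefined).
#' @param scheme matching [threshold_scheme()] (or numeric sparsity vector).
#' @return single numeric value, or `NA`.
#' @export
auc_summary <- function(values, scheme) {
  s <- as.numeric(scheme)
  if (length(values) != length(s))
    stop("'values' and 'scheme' lengths differ", call. = FALSE)
  if (length(s) == 1L)  # degenerate scheme: AUC is the value itself
    return(if (is.finite(values)) values else NA_real_)
  def <- is.finite(values)
  if (sum(def) < 2L || mean(!def) > 0.10) return(NA_real_)
  if (!all(def))
    values <- stats::approx(s[def], values[def], xout = s, rule = 2)$y
  dx <- diff(s)
  integral <- sum(dx * (values[-1L] + values[-length(values)]) / 2)
  integral / (s[length(s)] - s[1L])
}
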