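#' Convert network weights to path lengths
#'
#' Weighted graph metrics travel along edge *lengths*. Weights are first
#' normalized to (0, 1\] by dividing by the largest weight in the network
#' (so efficiencies are bounded by 1 and comparable across subjects), then
#' inverted: `length = 1 / normalized_weight` on retained edges, `+Inf`
#' elsewhere.
#'
#' @param net a `"sparse_network"` (or symmetric nonnegative matrix).
#' @return n x n matrix of lengths (`Inf` where no edge; diagonal `Inf`,
#'   by convention distances to self are 0 regardless).
#' @export
edge_lengths <- function(net) {
  w <- normalized_weights(net)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- Inf
  len
}

normalized_weights <- function(net) {
  w <- unclass(net)
  if (any(w < 0))
    stop("topology metrics need nonnegative weights (absolute FC)",
         call. = FALSE)
  mx <- max(w)
  if (mx <= 0) stop("all-zero network", call. = FALSE)
  w / mx
}

#' All-pairs shortest path distances of a weighted network
#'
#' Dijkstra single-source shortest paths from every node over the edge
#' lengths of [edge_lengths()]. `d[i, i] = 0`; disconnected pairs are
#' `Inf`.
#'
#' @inheritParams edge_lengths
#' @return n x n symmetric distance matrix.
#' @export
all_pairs_shortest <- function(net) {
  w <- normalized_weights(net)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$weight <- 1 / igraph::E(g)$weight
  d <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(d) <- dimnames(unclass(net))
  d
}

# mean of 1/d over ordered pairs i != j (disconnected pairs contribute 0)
inv_distance_mean <- function(d) {
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  n <- nrow(d)
  if (n < 2L) return(0)
  sum(inv) / (n * (n - 1))
}

#' Global efficiency of a weighted network
#'
#' Mean inverse shortest-path distance over all ordered node pairs;
#' disconnected pairs contribute 0. Under max-normalized weights the value
#' lies in \[0, 1\], reaching 1 on a complete unit-weight graph.
#'
#' @inheritParams edge_lengths
#' @return scalar in \[0, 1\].
#' @export
global_efficiency <- function(net) {
  inv_distance_mean(all_pairs_shortest(net))
}

#' Nodal efficiency
#'
#' For node i, the mean of `1/d(i, j)` over all other nodes j: how
#' efficiently the node reaches the rest of the network. An isolated node
#' has efficiency 0.
#'
#' @inheritParams edge_lengths
#' @param node a node index or region label, or `NULL` for all nodes.
#' @return numeric vector (named when the network carries labels), or a
#'   single value when `node` is given.
#' @export
nodal_efficiency <- function(net, node = NULL) {
  d <- all_pairs_shortest(net)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  en <- rowSums(inv) / (nrow(d) - 1L)
  if (is.null(node)) return(en)
  if (is.character(node)) {
    if (!node %in% rownames(d)) stop("unknown node: ", node, call. = FALSE)
    return(en[[node]])
  }
  if (node < 1L || node > length(en)) stop("unknown node: ", node, call. = FALSE)
  en[[node]]
}

#' Local efficiency of a weighted network
#'
#' Mean, over nodes, of the global efficiency of the subgraph induced by
#' each node's neighbours (edges and weights retained from the parent
#' network, no renormalization). Nodes with fewer than 2 neighbours
#' contribute 0.
#'
#' @inheritParams edge_lengths
#' @return scalar in \[0, 1\].
#' @export
local_efficiency <- function(net) {
  w <- normalized_weights(net)
  n <- nrow(w)
  eloc <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2L) return(0)
    sub <- w[nb, nb, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    if (igraph::ecount(g) == 0L) return(0)
    igraph::E(g)$weight <- 1 / igraph::E(g)$weight
    inv_distance_mean(igraph::distances(g, algorithm = "dijkstra"))
  }, 0)
  mean(eloc)
}

#' Characteristic path length
#'
#' Default (`"harmonic"`): `Lp = 1 / Eglob`, the harmonic-mean convention,
#' which stays finite and monotone on partially disconnected sparse
#' networks; undefined (`NA`) when the network has no connected pair.
#' Alternative (`"arithmetic"`): the arithmetic mean of the finite
#' off-diagonal distances.
#'
#' @inheritParams edge_lengths
#' @param convention `"harmonic"` (default) or `"arithmetic"`.
#' @return scalar >= 1 when defined, else `NA`.
#' @export
char_path_length <- function(net, convention = c("harmonic", "arithmetic")) {
  convention <- match.arg(convention)
  d <- all_pairs_shortest(net)
  if (convention == "harmonic") {
    eg <- inv_distance_mean(d)
    if (eg <= 0) return(NA_real_)
    return(1 / eg)
  }
  off <- d[row(d) != col(d)]
  off <- off[is.finite(off)]
  if (!length(off)) return(NA_real_)
  mean(off)
}

# all metrics from one distance computation
topology_metrics <- function(net, lp_convention = "harmonic") {
  d <- all_pairs_shortest(net)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  n <- nrow(d)
  enodal <- rowSums(inv) / (n - 1L)
  eglob <- sum(inv) / (n * (n - 1L))
  lp <- if (lp_convention == "harmonic") {
    if (eglob > 0) 1 / eglob else NA_real_
  } else {
    off <- d[row(d) != col(d)]
    off <- off[is.finite(off)]
    if (length(off)) mean(off) else NA_real_
  }
  list(Lp = lp, Eglob = eglob, Eloc = local_efficiency(net), Enodal = enodal)
}

#' Functional-network topology profile across the sparsity series
#'
#' Thresholds the functional network at each sparsity level and computes
#' the weighted global metrics (characteristic path length Lp, global
#' efficiency Eglob, local efficiency Eloc) and per-region nodal efficiency,
#' then summarizes each metric across thresholds with the range-normalized
#' AUC of [auc_summary()].
#'
#' @param fc functional [connectivity_matrix()] (nonnegative weights; use
#'   the absolute-FC convention).
#' @param scheme a [threshold_scheme()].
#' @param lp_convention passed to [char_path_length()].
#' @param subject optional subject identifier.
#' @return object of class `"topology_profile"`: `sparsity`; `global`
#'   (3 x T matrix, rows Lp/Eglob/Eloc); `enodal` (n x T matrix); `auc`
#'   (named vector for the global metrics); `enodal_auc` (per region);
#'   `lp_convention`.
#' @export
topology_profile <- function(fc, scheme = threshold_scheme(),
                             lp_convention = c("harmonic", "arithmetic"),
                             subject = NA) {
  lp_convention <- match.arg(lp_convention)
  s <- as.numeric(scheme)
  n <- nrow(fc)
  glob <- matrix(NA_real_, 3L, length(s),
                 dimnames = list(c("Lp", "Eglob", "Eloc"),
                                 sprintf("s%.2f", s)))
  enod <- matrix(NA_real_, n, length(s),
                 dimnames = list(region_labels(fc), sprintf("s%.2f", s)))
  for (t in seq_along(s)) {
    net <- threshold_proportional(fc, s[t])
    mt <- topology_metrics(net, lp_convention)
    glob[, t] <- c(mt$Lp, mt$Eglob, mt$Eloc)
    enod[, t] <- mt$Enodal
  }
  structure(list(subject = subject, sparsity = s, global = glob,
                 enodal = enod,
                 auc = apply(glob, 1L, auc_summary, scheme = scheme),
                 enodal_auc = apply(enod, 1L, auc_summary, scheme = scheme),
                 lp_convention = lp_convention),
            class = "topology_profile")
}

#' @export
print.topology_profile <- function(x, ...) {
  cat(sprintf("<topology_profile> %s%d thresholds (%.2f-%.2f), %d regions, Lp convention: %s\n",
              if (!is.na(x$subject)) paste0("subject ", x$subject, ", ") else "",
              length(x$sparsity), min(x$sparsity), max(x$sparsity),
              nrow(x$enodal), x$lp_convention))
  cat(sprintf("  AUC: Lp = %.4f, Eglob = %.4f, Eloc = %.4f\n",
              x$auc[["Lp"]], x$auc[["Eglob"]], x$auc[["Eloc"]]))
  invisible(x)
}

#' @export
plot.topology_profile <- function(x, ...) {
  graphics::matplot(x$sparsity, t(x$global), type = "b", pch = 16, lty = 1,
                    xlab = "sparsity", ylab = "metric value", ...)
  graphics::legend("topright", legend = rownames(x$global),
                   col = 1:3, lty = 1, pch = 16, cex = 0.8, bty = "n")
  invisible(x)
}
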