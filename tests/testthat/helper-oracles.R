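# Independent brute-force oracles, kept deliberately naive: they share no
# code with the package implementation.

# random symmetric zero-diagonal weight matrix with distinct weights
random_symmetric <- function(n, labels = paste0("R", seq_len(n)),
                             nonneg = TRUE) {
  w <- matrix(0, n, n)
  vals <- stats::runif(n * (n - 1) / 2)
  if (!nonneg) vals <- vals - 0.5
  w[upper.tri(w)] <- vals
  w <- w + t(w)
  dimnames(w) <- list(labels, labels)
  w
}

# Pearson correlation from the raw covariance formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - sum(x) / n) * (y - sum(y) / n))
  sxx <- sum((x - sum(x) / n)^2)
  syy <- sum((y - sum(y) / n)^2)
  sxy / sqrt(sxx * syy)
}

# sort-and-cut proportional thresholding oracle
threshold_oracle <- function(m, s) {
  n <- nrow(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[ut]
  k <- floor(s * n * (n - 1) / 2 + 0.5)
  o <- order(-w, ut[, 1], ut[, 2])
  keep <- o[seq_len(k)]
  out <- matrix(0, n, n, dimnames = dimnames(m))
  out[ut[keep, , drop = FALSE]] <- w[keep]
  out + t(out)
}

# Floyd-Warshall all-pairs shortest paths on a length matrix
floyd_warshall <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# brute-force weighted efficiency metrics from first principles
topology_oracle <- function(w) {
  wn <- w / max(w)
  len <- ifelse(wn > 0, 1 / wn, Inf)
  d <- floyd_warshall(len)
  n <- nrow(w)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  eglob <- sum(inv) / (n * (n - 1))
  enodal <- rowSums(inv) / (n - 1)
  eloc_i <- sapply(seq_len(n), function(i) {
    nb <- which(wn[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- wn[nb, nb, drop = FALSE]
    lens <- ifelse(sub > 0, 1 / sub, Inf)
    ds <- floyd_warshall(lens)
    m <- length(nb)
    invs <- 1 / ds
    diag(invs) <- 0
    invs[is.infinite(ds)] <- 0
    sum(invs) / (m * (m - 1))
  })
  list(Eglob = eglob, Enodal = enodal, Eloc = mean(eloc_i),
       Lp = if (eglob > 0) 1 / eglob else NA_real_, d = d)
}

# Benjamini-Hochberg step-up computed literally from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest down
  for (i in seq(m - 1, 1)) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# small deterministic partition over n regions split into two modules
toy_partition <- function(n, labels = paste0("R", seq_len(n))) {
  half <- ceiling(n / 2)
  module_partition(stats::setNames(
    c(rep("A", half), rep("B", n - half)), labels))
}

std_covariates <- function(cohort)
  cohort[, c("head_motion", "age", "sex", "education")]
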