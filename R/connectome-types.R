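#' Construct a validated connectivity matrix
#'
#' A connectivity matrix is a square, symmetric, zero-diagonal matrix of
#' finite connection weights between brain regions, with region labels on
#' both dimensions. Functional (FC) matrices hold inter-regional time-series
#' correlations (absolute-value convention gives weights in \[0, 1\]; the
#' signed convention allows \[-1, 1\]). Structural (SC) matrices hold
#' nonnegative tractography connection probabilities (any nonnegative scale
#' is accepted: the coupling statistic is invariant to positive affine
#' rescaling of SC).
#'
#' @param weights numeric n x n matrix, n >= 3.
#' @param kind either `"functional"` or `"structural"`.
#' @param region_labels character vector of region identifiers; defaults to
#'   the matrix dimnames, or `R1..Rn` when absent.
#' @param tol symmetry tolerance. Matrices asymmetric beyond `tol` are
#'   rejected; use [symmetrize_sc()] for raw directed tractography output.
#' @return a matrix of class `"connectivity_matrix"` with attribute `kind`.
#' @seealso [read_matrix()], [symmetrize_sc()], [build_fc()]
#' @export
connectivity_matrix <- function(weights, kind = c("functional", "structural"),
                                region_labels = NULL, tol = 1e-9) {
  kind <- match.arg(kind)
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("'weights' must be a numeric matrix", call. = FALSE)
  n <- nrow(weights)
  if (n != ncol(weights))
    stop(sprintf("connectivity matrix must be square, got %d x %d",
                 nrow(weights), ncol(weights)), call. = FALSE)
  if (n < 3L)
    stop("connectivity matrix needs at least 3 regions", call. = FALSE)
  if (anyNA(weights))
    stop("connectivity matrix contains NA; networks must be complete",
         call. = FALSE)
  if (any(!is.finite(weights)))
    stop("connectivity matrix contains non-finite weights", call. = FALSE)
  if (max(abs(weights - t(weights))) > tol)
    stop(sprintf("matrix asymmetric beyond tolerance %g; symmetrize first",
                 tol), call. = FALSE)
  if (any(diag(weights) != 0))
    stop("diagonal must be exactly zero", call. = FALSE)
  if (kind == "structural" && any(weights < 0))
    stop("structural weights must be nonnegative", call. = FALSE)
  if (kind == "functional" && any(weights < -1 | weights > 1))
    stop("functional weights must lie in [-1, 1]", call. = FALSE)

  if (is.null(region_labels)) {
    region_labels <- rownames(weights)
    if (is.null(region_labels)) region_labels <- paste0("R", seq_len(n))
  }
  if (length(region_labels) != n || anyDuplicated(region_labels))
    stop("region labels must be unique and match the matrix dimension",
         call. = FALSE)
  weights <- (weights + t(weights)) / 2  # exact symmetry after tolerance check
  dimnames(weights) <- list(region_labels, region_labels)
  structure(weights, kind = kind, class = c("connectivity_matrix", "matrix"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s, %d regions\n",
              attr(x, "kind"), nrow(x)))
  w <- x[upper.tri(x)]
  cat(sprintf("  weights: min %.4g, median %.4g, max %.4g\n",
              min(w), stats::median(w), max(w)))
  invisible(x)
}

#' Region labels of a connectome object
#' @param x a connectivity matrix, time-series matrix or module partition.
#' @return character vector of region identifiers.
#' @export
region_labels <- function(x) {
  if (inherits(x, "module_partition")) return(names(x$module))
  rn <- rownames(x)
  if (is.null(rn)) stop("object carries no region labels", call. = FALSE)
  rn
}

#' Construct a regional BOLD time-series matrix
#'
#' Holds one region per row and one time point per column, in arbitrary
#' BOLD-like units. Regions with (near) zero temporal variance are flagged,
#' since they cannot enter a correlation-based functional network.
#'
#' @param samples numeric n_regions x T matrix, T >= 3.
#' @param region_labels character vector; defaults to rownames or `R1..Rn`.
#' @param sampling_interval repetition time in seconds (metadata only).
#' @return matrix of class `"timeseries_matrix"`; attribute
#'   `constant_regions` lists zero-variance regions (empty when none).
#' @export
timeseries_matrix <- function(samples, region_labels = NULL,
                              sampling_interval = NA_real_) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("'samples' must be a numeric matrix", call. = FALSE)
  if (ncol(samples) < 3L)
    stop("time series needs at least 3 time points", call. = FALSE)
  if (any(!is.finite(samples)))
    stop("time series contains non-finite values", call. = FALSE)
  if (is.null(region_labels)) {
    region_labels <- rownames(samples)
    if (is.null(region_labels)) region_labels <- paste0("R", seq_len(nrow(samples)))
  }
  if (length(region_labels) != nrow(samples) || anyDuplicated(region_labels))
    stop("region labels must be unique, one per row", call. = FALSE)
  rownames(samples) <- region_labels
  v <- apply(samples, 1L, stats::var)
  structure(samples,
            sampling_interval = sampling_interval,
            constant_regions = region_labels[v < .Machine$double.eps],
            class = c("timeseries_matrix", "matrix"))
}

#' Construct a module partition
#'
#' Assigns every region to exactly one named functional module. The analysis
#' keeps a fixed partition across all subjects and groups so that modular
#' coupling values are comparable.
#'
#' @param module named character vector: `names()` are region labels, values
#'   are module names.
#' @param module_names optional ordered module names; defaults to order of
#'   first appearance.
#' @return object of class `"module_partition"` with elements `module`
#'   (named character) and `module_names`.
#' @seealso [default_partition()] for the shipped five-module division.
#' @export
module_partition <- function(module, module_names = NULL) {
  if (is.null(names(module)) || anyDuplicated(names(module)))
    stop("'module' must be named by unique region labels", call. = FALSE)
  if (anyNA(module) || any(!nzchar(module)))
    stop("every region must be assigned a nonempty module name", call. = FALSE)
  if (is.null(module_names)) module_names <- unique(unname(module))
  missing_mod <- setdiff(module_names, module)
  if (length(missing_mod))
    stop("empty module(s): ", paste(missing_mod, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(module, module_names)
  if (length(extra))
    stop("module(s) not in declared order: ", paste(extra, collapse = ", "),
         call. = FALSE)
  structure(list(module = module, module_names = module_names),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  sizes <- table(factor(x$module, levels = x$module_names))
  cat(sprintf("<module_partition> %d regions, %d modules\n",
              length(x$module), length(x$module_names)))
  for (m in x$module_names) cat(sprintf("  %s: %d regions\n", m, sizes[[m]]))
  invisible(x)
}

# check that a partition covers exactly the given regions
check_partition_regions <- function(partition, regions) {
  missing_r <- setdiff(regions, names(partition$module))
  if (length(missing_r))
    stop("regions without module assignment: ",
         paste(missing_r, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(partition$module), regions)
  if (length(unknown))
    stop("partition assigns unknown regions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Construct a cohort table
#'
#' Per-subject phenotype table: group membership, the four nuisance
#' covariates used throughout the inference layer (age, sex, education,
#' head motion as mean framewise displacement), cognitive scores, and
#' optional binary clinical markers. Cognitive scores may be missing (NA)
#' and are excluded pairwise downstream; covariates must be complete.
#'
#' @param df data.frame with at least columns `id` and `group`.
#' @param groups ordered character vector of allowed group labels (first is
#'   treated as most affected, last as reference/control downstream).
#' @param covariates character vector of covariate column names.
#' @param scores character vector of cognitive-score column names.
#' @return `df` with class `"cohort_table"` and attributes `groups`,
#'   `covariates`, `scores`; `group` becomes a factor with the declared
#'   level order and `sex` (when present) is validated as a 0/1 code.
#' @export
cohort_table <- function(df,
                         groups = c("CSVD-s", "CSVD-m", "HC"),
                         covariates = c("age", "sex", "education", "head_motion"),
                         scores = intersect(c("MoCA", "AVLT", "SCWT", "SDMT", "TMT"),
                                            names(df))) {
  if (!is.data.frame(df)) stop("'df' must be a data.frame", call. = FALSE)
  need <- c("id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate subject id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(as.character(df$group)), groups)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  df$group <- factor(as.character(df$group), levels = groups)
  for (cv in intersect(covariates, names(df))) {
    if (!is.numeric(df[[cv]]))
      stop(sprintf("covariate '%s' must be numeric", cv), call. = FALSE)
    if (any(!is.finite(df[[cv]])))
      stop(sprintf("covariate '%s' has missing or non-finite values", cv),
           call. = FALSE)
  }
  if ("sex" %in% names(df) && !all(df$sex %in% c(0, 1)))
    stop("'sex' must be coded 0/1", call. = FALSE)
  for (sc in scores) {
    if (!sc %in% names(df)) next
    if (!is.numeric(df[[sc]]))
      stop(sprintf("score '%s' must be numeric (NA allowed)", sc), call. = FALSE)
  }
  structure(df, groups = groups, covariates = covariates, scores = scores,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects in %d groups (%s)\n",
              nrow(x), nlevels(x$group),
              paste(sprintf("%s: %d", levels(x$group), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}
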