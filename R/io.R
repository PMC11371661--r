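#' Read a connectivity matrix from a delimited text file
#'
#' File dialect: tab-delimited numeric square matrix. An optional header row
#' prefixed with `#` carries region labels; alternatively (or additionally)
#' a non-numeric first column carries row labels. Matrices must be complete:
#' any `NA` cell is a hard error. Asymmetric structural matrices are *not*
#' silently fixed here; pass them through [symmetrize_sc()].
#'
#' @param path file path.
#' @param kind `"functional"` or `"structural"`.
#' @param regions optional character vector giving the canonical region
#'   order (typically the partition file's order); the matrix is permuted to
#'   it on load so labels can never silently misalign.
#' @param symmetric if `FALSE` the raw (possibly directed) matrix is
#'   returned unvalidated, for feeding into [symmetrize_sc()].
#' @return a [connectivity_matrix()] (or a plain labelled matrix when
#'   `symmetric = FALSE`).
#' @export
read_matrix <- function(path, kind = c("functional", "structural"),
                        regions = NULL, symmetric = TRUE) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: ", path, call. = FALSE)
  labels <- NULL
  if (startsWith(lines[1L], "#")) {
    labels <- strsplit(trimws(sub("^#", "", lines[1L])), "\t", fixed = TRUE)[[1L]]
    lines <- lines[-1L]
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncell <- lengths(cells)
  if (length(unique(ncell)) != 1L)
    stop("ragged rows in matrix file: ", path, call. = FALSE)
  first_col <- vapply(cells, `[[`, "", 1L)
  # a first column is a label column only when non-numeric and not "NA"
  has_row_labels <- any(is.na(suppressWarnings(as.numeric(first_col))) &
                          first_col != "NA")
  if (has_row_labels) {
    row_labels <- first_col
    cells <- lapply(cells, `[`, -1L)
    if (is.null(labels)) labels <- row_labels
    if (!identical(row_labels, labels))
      stop("row labels disagree with header labels in ", path, call. = FALSE)
  }
  nr <- length(cells)
  nc <- length(cells[[1L]])
  if (nr != nc)
    stop(sprintf("matrix in '%s' is not square: %d rows x %d columns",
                 path, nr, nc), call. = FALSE)
  w <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    bad <- which(is.na(v) & cells[[i]] != "NA")
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column %d of '%s': '%s'",
                   i, bad[1L], path, cells[[i]][bad[1L]]), call. = FALSE)
    w[i, ] <- v
  }
  if (anyNA(w))
    stop("matrix in '", path, "' contains NA; networks must be complete",
         call. = FALSE)
  if (any(!is.finite(w)))
    stop("matrix in '", path, "' contains non-finite values", call. = FALSE)
  if (!is.null(labels)) dimnames(w) <- list(labels, labels)
  if (!is.null(regions)) {
    if (is.null(labels))
      stop("canonical region order requested but '", path,
           "' carries no labels", call. = FALSE)
    check_labels_permutation(labels, regions, path)
    w <- w[regions, regions, drop = FALSE]
  }
  if (!symmetric) return(w)
  connectivity_matrix(w, kind = kind)
}

check_labels_permutation <- function(labels, regions, path) {
  miss <- setdiff(regions, labels)
  extra <- setdiff(labels, regions)
  if (length(miss) || length(extra))
    stop("region labels of '", path, "' do not match the canonical set",
         if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}

#' Write a connectivity (or any labelled square) matrix as TSV
#'
#' Mirrors the [read_matrix()] dialect: a `#`-prefixed label header followed
#' by tab-delimited rows. Values are written with 12 significant digits so a
#' write/read round trip is an identity at that precision.
#'
#' @param x matrix with region dimnames.
#' @param path destination file.
#' @param digits significant digits (default 12).
#' @export
write_matrix <- function(x, path, digits = 12L) {
  labels <- rownames(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(labels))
    writeLines(paste0("#", paste(labels, collapse = "\t")), con)
  body <- apply(x, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a regional time-series matrix (regions x time) from TSV
#'
#' Same dialect as [read_matrix()] but rectangular: one region per row, one
#' time point per column.
#'
#' @inheritParams read_matrix
#' @param sampling_interval repetition time in seconds (metadata).
#' @return a [timeseries_matrix()].
#' @export
read_timeseries <- function(path, regions = NULL, sampling_interval = NA_real_) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  labels <- NULL
  if (startsWith(lines[1L], "#")) {
    # header names time points; row labels carry regions
    lines <- lines[-1L]
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  first_col <- vapply(cells, `[[`, "", 1L)
  if (anyNA(suppressWarnings(as.numeric(first_col)))) {
    labels <- first_col
    cells <- lapply(cells, `[`, -1L)
  }
  s <- do.call(rbind, lapply(cells, function(r) as.numeric(r)))
  if (anyNA(s)) stop("time-series file '", path, "' has non-numeric cells",
                     call. = FALSE)
  if (!is.null(labels)) rownames(s) <- labels
  if (!is.null(regions)) {
    if (is.null(labels))
      stop("canonical region order requested but '", path,
           "' carries no labels", call. = FALSE)
    check_labels_permutation(labels, regions, path)
    s <- s[regions, , drop = FALSE]
  }
  timeseries_matrix(s, sampling_interval = sampling_interval)
}

#' Write a regional time-series matrix as TSV
#' @inheritParams write_matrix
#' @export
write_timeseries <- function(x, path, digits = 12L) {
  con <- file(path, "w")
  on.exit(close(con))
  labels <- rownames(x)
  body <- vapply(seq_len(nrow(x)), function(i) {
    row <- paste(formatC(x[i, ], digits = digits, format = "g"),
                 collapse = "\t")
    if (!is.null(labels)) paste(labels[i], row, sep = "\t") else row
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Read a region-to-module partition from a two-column TSV
#'
#' @param path two-column tab-delimited file: region label, module name. A
#'   `#`-prefixed header line is skipped.
#' @param regions optional region set the partition must cover exactly.
#' @return a [module_partition()]; module order follows first appearance.
#' @export
read_partition <- function(path, regions = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(cells) != 2L))
    stop("partition file '", path, "' must have exactly two columns",
         call. = FALSE)
  reg <- vapply(cells, `[[`, "", 1L)
  mod <- vapply(cells, `[[`, "", 2L)
  dup <- duplicated(reg)
  if (any(dup)) {
    conflict <- unique(reg[dup][mod[dup] != mod[match(reg[dup], reg)]])
    if (length(conflict))
      stop("conflicting module assignment for region(s): ",
           paste(conflict, collapse = ", "), call. = FALSE)
    keep <- !dup
    reg <- reg[keep]; mod <- mod[keep]
  }
  p <- module_partition(stats::setNames(mod, reg))
  if (!is.null(regions)) check_partition_regions(p, regions)
  p
}

#' Write a module partition as a two-column TSV
#' @param x a [module_partition()].
#' @param path destination file.
#' @export
write_partition <- function(x, path) {
  writeLines(c("#region\tmodule",
               paste(names(x$module), x$module, sep = "\t")), path)
  invisible(path)
}

#' The shipped five-module functional division of the 90-region AAL atlas
#'
#' Returns the default partition of the 90 AAL cortical/subcortical regions
#' into five resting-state functional modules: auditory/motor (20 regions),
#' vision (14), attention (18), default-mode network (18) and
#' limbic/subcortical (20). This is a documented approximation of the
#' standard five-module resting-state division used in modular coupling
#' analyses; replace it with a study-specific table via [read_partition()]
#' whenever one is available.
#'
#' @return a [module_partition()] over the 90 AAL region abbreviations
#'   (`.L`/`.R` suffixed).
#' @export
default_partition <- function() {
  read_partition(system.file("extdata", "aal90_modules.tsv",
                             package = "scfcoupling", mustWork = TRUE))
}

#' Published three-group CSVD cohort summaries
#'
#' Group-level summary statistics (per-group n, mean, sd for continuous
#' characteristics; positive counts for binary clinical markers) of a
#' published cerebral small vessel disease cohort: severe burden (CSVD-s,
#' n = 54), mild burden (CSVD-m, n = 106) and healthy controls (HC,
#' n = 79). Shipped as a worked example for the summary-statistic ANOVA
#' ([anova_oneway_summary()]) and chi-square ([chi_square_independence()])
#' re-analyses; binary markers scored only within the patient groups have
#' `NA` in the HC columns.
#'
#' @return data.frame with columns `variable`, `type`, and per-group
#'   `*_n`, `*_mean`, `*_sd`, `*_count`.
#' @export
reference_cohort_summaries <- function() {
  utils::read.delim(
    system.file("extdata", "csvd_cohort_summaries.tsv",
                package = "scfcoupling", mustWork = TRUE),
    sep = "\t", comment.char = "#", check.names = FALSE)
}

#' Read a cohort table from TSV
#'
#' Expects a header row naming at least `id` and `group`; covariate and
#' score columns are read as numeric, with `NA` allowed only in scores.
#'
#' @param path tab-delimited file with header.
#' @inheritParams cohort_table
#' @return a [cohort_table()].
#' @export
read_cohort <- function(path, groups = c("CSVD-s", "CSVD-m", "HC"),
                        covariates = c("age", "sex", "education", "head_motion"),
                        scores = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(scores))
    scores <- setdiff(names(df), c("id", "group", covariates))
  scores <- intersect(scores, names(df))
  cohort_table(df, groups = groups, covariates = covariates, scores = scores)
}

#' Write a cohort table as TSV
#' @param x a [cohort_table()] (or plain data.frame).
#' @param path destination file.
#' @export
write_cohort <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
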