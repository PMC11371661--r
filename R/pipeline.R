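# table-style formatting: p-values to 3 decimals with a "<0.001" floor,
# percentages rounded half away from zero to 1 decimal
format_p <- function(p) {
  ifelse(is.na(p), "-",
         ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}
format_pct <- function(count, n) {
  sprintf("%d (%.1f%%)", count, round_half_away(1000 * count / n) / 10)
}
format_mean_sd <- function(m, s) sprintf("%.2f ± %.2f", m, s)

# 32-bit FNV-1a hash of a deparsed object, for run metadata
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256), in double arithmetic
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    # h * 16777619 mod 2^32 without double-precision overflow
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Pipeline run configuration
#'
#' @param simulate a [sim_config()] to generate the cohort, or `NULL` to
#'   read it from `input_dir`.
#' @param input_dir directory laid out as by [write_synthetic_cohort()]
#'   (`cohort.tsv`, `partition.tsv`, `<id>_sc.tsv`, `<id>_fc.tsv`).
#' @param scheme a [threshold_scheme()].
#' @param absolute FC sign convention for [build_fc()] (recorded in
#'   metadata; matrices read from disk are used as-is).
#' @param lp_convention characteristic-path-length convention, see
#'   [char_path_length()].
#' @param covariates covariate column names for the adjusted analyses.
#' @param metrics which per-subject profiles to compute.
#' @param out_dir directory for the output tables, or `NULL` to skip
#'   writing.
#' @param seed integer seed (overrides the simulation config's seed so one
#'   flag controls the whole run).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(simulate = NULL, input_dir = NULL,
                       scheme = threshold_scheme(),
                       absolute = TRUE,
                       lp_convention = c("harmonic", "arithmetic"),
                       covariates = c("head_motion", "age", "sex", "education"),
                       metrics = c("coupling", "topology"),
                       out_dir = NULL, seed = 1L) {
  if (is.null(simulate) && is.null(input_dir))
    stop("either 'simulate' or 'input_dir' is required", call. = FALSE)
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  structure(list(simulate = simulate, input_dir = input_dir,
                 scheme = scheme, absolute = absolute,
                 lp_convention = match.arg(lp_convention),
                 covariates = covariates,
                 metrics = match.arg(metrics, several.ok = TRUE),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

read_cohort_dir <- function(dir) {
  cohort_path <- file.path(dir, "cohort.tsv")
  if (!file.exists(cohort_path))
    stop("missing cohort.tsv in ", dir, call. = FALSE)
  first <- readLines(cohort_path, n = 1L)
  groups <- NULL  # accept whatever group set the file declares
  df <- utils::read.delim(cohort_path, sep = "\t", check.names = FALSE)
  groups <- unique(as.character(df$group))
  cohort <- cohort_table(df, groups = groups)
  partition <- read_partition(file.path(dir, "partition.tsv"))
  regions <- names(partition$module)
  subjects <- lapply(cohort$id, function(id) {
    scp <- file.path(dir, paste0(id, "_sc.tsv"))
    fcp <- file.path(dir, paste0(id, "_fc.tsv"))
    if (!file.exists(scp) || !file.exists(fcp))
      stop("missing matrix file(s) for subject ", id, call. = FALSE)
    list(id = id,
         group = as.character(cohort$group[cohort$id == id]),
         sc = read_matrix(scp, "structural", regions = regions),
         fc = read_matrix(fcp, "functional", regions = regions))
  })
  list(subjects = subjects, cohort = cohort, partition = partition)
}

#' Run the full SC-FC coupling analysis chain
#'
#' simulate (or load) -> threshold series -> coupling + topology profiles
#' -> covariate-adjusted group statistics and brain-cognition correlations.
#' Deterministic given the seed; all report tables are returned and
#' (optionally) written as TSV with a metadata header.
#'
#' @param config a [run_config()].
#' @return object of class `"scfc_report"` with elements `demographics`
#'   (Table-1 analog), `group_comparison` (coupling/topology AUC ANCOVA
#'   table), `correlations` (per-group partial correlations with raw p and
#'   BH q), `curves` (per-threshold group mean/sd of every metric),
#'   `coupling_auc`/`topology_auc` (per-subject AUC tables) and `metadata`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- config$seed
    cohort_data <- generate_cohort(sim)
    subjects <- cohort_data$subjects
    cohort <- cohort_data$cohort
    partition <- sim$partition
  } else {
    cohort_data <- read_cohort_dir(config$input_dir)
    subjects <- cohort_data$subjects
    cohort <- cohort_data$cohort
    partition <- cohort_data$partition
  }
  scheme <- config$scheme
  scopes <- c("whole_brain", partition$module_names)
  groups <- levels(cohort$group)
  covs <- intersect(config$covariates, names(cohort))

  coupling_auc <- NULL
  coupling_curves <- NULL
  if ("coupling" %in% config$metrics) {
    profs <- lapply(subjects, function(s)
      coupling_profile(s$fc, s$sc, partition, scheme, subject = s$id))
    coupling_auc <- data.frame(id = vapply(profs, function(p) p$subject, ""),
                               check.names = FALSE)
    for (sc in scopes)
      coupling_auc[[sc]] <- vapply(profs, function(p) p$auc[[sc]], 0)
    coupling_curves <- curves_table(
      lapply(profs, function(p) p$r), scopes, scheme, cohort, "coupling")
  }

  topology_auc <- NULL
  topo_curves <- NULL
  enodal_auc <- NULL
  if ("topology" %in% config$metrics) {
    tprofs <- lapply(subjects, function(s)
      topology_profile(s$fc, scheme, config$lp_convention, subject = s$id))
    topology_auc <- data.frame(id = vapply(tprofs, function(p) p$subject, ""))
    for (m in c("Lp", "Eglob", "Eloc"))
      topology_auc[[m]] <- vapply(tprofs, function(p) p$auc[[m]], 0)
    enodal_auc <- t(vapply(tprofs, function(p) p$enodal_auc,
                           numeric(nrow(tprofs[[1]]$enodal))))
    rownames(enodal_auc) <- topology_auc$id
    topo_curves <- curves_table(
      lapply(tprofs, function(p) p$global), c("Lp", "Eglob", "Eloc"),
      scheme, cohort, "topology")
  }

  demographics <- make_demographics_table(cohort)

  metric_tab <- metric_table(coupling_auc, topology_auc, cohort)
  group_comparison <- NULL
  correlations <- NULL
  if (nlevels(cohort$group) >= 2L && ncol(metric_tab) > 0L) {
    group_comparison <- comparison_table(metric_tab, cohort, covs)
    correlations <- correlation_table(metric_tab, cohort, covs)
  }

  metadata <- list(
    seed = config$seed,
    config_hash = config_hash(unclass(config)[setdiff(names(config),
                                                      "out_dir")]),
    n_subjects = nrow(cohort), groups = groups,
    n_regions = length(partition$module),
    thresholds = as.numeric(scheme),
    absolute_fc = config$absolute, lp_convention = config$lp_convention,
    covariates = covs,
    package_version = as.character(utils::packageVersion("scfcoupling")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  report <- structure(list(demographics = demographics,
                           group_comparison = group_comparison,
                           correlations = correlations,
                           curves = rbind(coupling_curves, topo_curves),
                           coupling_auc = coupling_auc,
                           topology_auc = topology_auc,
                           enodal_auc = enodal_auc,
                           cohort = cohort,
                           metadata = metadata),
                      class = "scfc_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# per-threshold group mean/sd long table for a list of per-subject
# scope x threshold matrices
curves_table <- function(mats, scopes, scheme, cohort, family) {
  s <- as.numeric(scheme)
  out <- list()
  for (g in levels(cohort$group)) {
    idx <- which(cohort$group == g)
    for (sc in scopes) {
      vals <- t(vapply(mats[idx], function(m) m[sc, ], numeric(length(s))))
      out[[paste(g, sc)]] <- data.frame(
        family = family, metric = sc, group = g, sparsity = s,
        mean = colMeans(vals, na.rm = TRUE),
        sd = apply(vals, 2L, stats::sd, na.rm = TRUE))
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

metric_table <- function(coupling_auc, topology_auc, cohort) {
  out <- data.frame(row.names = seq_len(nrow(cohort)))
  if (!is.null(coupling_auc)) {
    stopifnot(identical(coupling_auc$id, cohort$id))
    for (sc in setdiff(names(coupling_auc), "id"))
      out[[paste0("coupling_", sc)]] <- coupling_auc[[sc]]
  }
  if (!is.null(topology_auc)) {
    stopifnot(identical(topology_auc$id, cohort$id))
    for (m in setdiff(names(topology_auc), "id"))
      out[[m]] <- topology_auc[[m]]
  }
  out
}

comparison_table <- function(metric_tab, cohort, covs) {
  covd <- if (length(covs)) cohort[, covs, drop = FALSE] else NULL
  groups <- levels(cohort$group)
  pairs <- utils::combn(groups, 2L)
  rows <- lapply(names(metric_tab), function(m) {
    y <- metric_tab[[m]]
    fit <- ancova_group_test(y, cohort$group, covd)
    row <- data.frame(metric = m)
    for (g in groups) {
      idx <- cohort$group == g
      row[[g]] <- format_mean_sd(mean(y[idx], na.rm = TRUE),
                                 stats::sd(y[idx], na.rm = TRUE))
    }
    row$F <- fit$F
    row$p <- fit$p
    for (k in seq_len(ncol(pairs))) {
      lbl <- paste(pairs[1L, k], "vs", pairs[2L, k])
      row[[lbl]] <- if (is.finite(fit$p) && fit$p < 0.05)
        format_p(fit$posthoc$p[pairs[1L, k], pairs[2L, k]]) else "-"
    }
    row
  })
  do.call(rbind, rows)
}

correlation_table <- function(metric_tab, cohort, covs) {
  scores <- intersect(attr(cohort, "scores"), names(cohort))
  if (!length(scores)) return(NULL)
  covd <- if (length(covs)) cohort[, covs, drop = FALSE] else NULL
  out <- list()
  for (g in levels(cohort$group)) {
    idx <- which(cohort$group == g)
    rows <- list()
    for (m in names(metric_tab)) for (sc in scores) {
      pc <- tryCatch(
        partial_correlation(metric_tab[[m]][idx], cohort[[sc]][idx],
                            if (!is.null(covd)) covd[idx, , drop = FALSE]),
        error = function(e) NULL)
      if (is.null(pc)) next
      rows[[paste(m, sc)]] <- data.frame(group = g, metric = m, score = sc,
                                         r = pc$r, df = pc$df, p = pc$p)
    }
    if (!length(rows)) next  # e.g. too few subjects for the covariate set
    tab <- do.call(rbind, c(rows, make.row.names = FALSE))
    # FDR family: all metric x score pairs within one group
    tab$q <- bh_fdr(tab$p)
    out[[g]] <- tab
  }
  if (!length(out)) return(NULL)
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Demographics and clinical characteristics table
#'
#' Per-group descriptive statistics with the omnibus test per row:
#' mean +- sd and one-way ANOVA for continuous variables, count (%) and
#' Pearson chi-square for binary markers, LSD post hoc columns for rows
#' with a significant omnibus test. With a single group only the
#' descriptive columns are produced.
#'
#' @param cohort a [cohort_table()].
#' @return data.frame, one row per characteristic.
#' @export
make_demographics_table <- function(cohort) {
  groups <- levels(droplevels(cohort$group))
  if (!length(groups)) stop("empty cohort", call. = FALSE)
  if (any(table(cohort$group)[groups] == 0))
    stop("empty group", call. = FALSE)
  skip <- c("id", "group", grep("^true_", names(cohort), value = TRUE))
  vars <- setdiff(names(cohort), skip)
  is_binary <- vapply(vars, function(v) {
    x <- cohort[[v]]
    is.numeric(x) && all(stats::na.omit(x) %in% c(0, 1))
  }, TRUE)
  multi <- length(groups) >= 2L
  pairs <- if (multi) utils::combn(groups, 2L)
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    row <- data.frame(variable = v,
                      type = if (is_binary[[v]]) "binary" else "continuous")
    posthoc_p <- NULL
    if (is_binary[[v]]) {
      for (g in groups) {
        idx <- cohort$group == g & !is.na(x)
        row[[g]] <- format_pct(sum(x[idx]), sum(idx))
      }
      row$p <- if (multi) {
        tab <- rbind(tapply(x, cohort$group, sum, na.rm = TRUE)[groups],
                     tapply(!is.na(x), cohort$group, sum)[groups] -
                       tapply(x, cohort$group, sum, na.rm = TRUE)[groups])
        format_p(suppressWarnings(chi_square_independence(tab)$p))
      } else "-"
      row$test <- if (multi) "chi-square" else "-"
    } else {
      for (g in groups) {
        idx <- cohort$group == g
        row[[g]] <- format_mean_sd(mean(x[idx], na.rm = TRUE),
                                   stats::sd(x[idx], na.rm = TRUE))
      }
      if (multi) {
        av <- anova_oneway(x, cohort$group)
        row$p <- format_p(av$p)
        row$test <- "ANOVA"
        if (is.finite(av$p) && av$p < 0.05)
          posthoc_p <- lsd_posthoc(x, cohort$group)$p
      } else {
        row$p <- "-"; row$test <- "-"
      }
    }
    if (multi) {
      for (k in seq_len(ncol(pairs))) {
        lbl <- paste(pairs[1L, k], "vs", pairs[2L, k])
        row[[lbl]] <- if (!is.null(posthoc_p))
          format_p(posthoc_p[pairs[1L, k], pairs[2L, k]]) else "-"
      }
    }
    row
  })
  do.call(rbind, rows)
}

#' Write a report bundle as TSV tables with metadata headers
#'
#' @param report an `"scfc_report"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("#scfcoupling %s seed=%d config=%s",
                 report$metadata$package_version, report$metadata$seed,
                 report$metadata$config_hash)
  wr <- function(df, name) {
    if (is.null(df)) return()
    path <- file.path(dir, name)
    writeLines(hdr, path)
    suppressWarnings(
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA", append = TRUE))
    path
  }
  wr(report$demographics, "demographics.tsv")
  wr(report$group_comparison, "group_comparison.tsv")
  wr(report$correlations, "correlations.tsv")
  wr(report$curves, "curves.tsv")
  wr(report$coupling_auc, "coupling_auc.tsv")
  wr(report$topology_auc, "topology_auc.tsv")
  if (!is.null(report$enodal_auc))
    wr(data.frame(id = rownames(report$enodal_auc), report$enodal_auc,
                  check.names = FALSE), "enodal_auc.tsv")
  invisible(dir)
}

#' @export
print.scfc_report <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<scfc_report> %d subjects (%s), %d regions, %d thresholds\n",
              md$n_subjects, paste(md$groups, collapse = "/"),
              md$n_regions, length(md$thresholds)))
  cat(sprintf("  seed %d, config %s, %.1f s\n", md$seed, md$config_hash,
              md$elapsed_s))
  if (!is.null(x$group_comparison)) {
    cat("  group comparison (AUC metrics):\n")
    gc <- x$group_comparison
    for (i in seq_len(nrow(gc)))
      cat(sprintf("    %-28s F = %6.2f, p = %s\n", gc$metric[i], gc$F[i],
                  format_p(gc$p[i])))
  }
  invisible(x)
}
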