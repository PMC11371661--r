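#' Nearest correlation matrix by alternating projection
#'
#' Projects a symmetric matrix onto the set of valid correlation matrices
#' by alternating eigenvalue clipping (floor `1e-8`) with unit-diagonal
#' rescaling, iterated to a fixed point. Strictly positive-definite
#' correlation matrices are fixed points.
#'
#' @param m square symmetric numeric matrix.
#' @param eig_floor eigenvalue floor.
#' @param tol convergence tolerance on the max absolute change.
#' @param maxit maximum iterations.
#' @return positive semidefinite matrix with unit diagonal.
#' @export
nearest_correlation <- function(m, eig_floor = 1e-8, tol = 1e-10,
                                maxit = 200L) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("'m' must be a square matrix", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8)
    stop("'m' must be symmetric", call. = FALSE)
  y <- (m + t(m)) / 2
  diag(y) <- 1
  ds <- matrix(0, nrow(y), ncol(y))  # Dykstra correction
  for (it in seq_len(maxit)) {
    prev <- y
    r <- y - ds
    e <- eigen(r, symmetric = TRUE)
    ev <- pmax(e$values, eig_floor)
    x <- e$vectors %*% (ev * t(e$vectors))
    x <- (x + t(x)) / 2
    ds <- x - r
    y <- x
    diag(y) <- 1
    if (max(abs(y - prev)) < tol) break
  }
  # final strict projection: clip then rescale to an exact unit diagonal
  e <- eigen(y, symmetric = TRUE)
  ev <- pmax(e$values, eig_floor)
  y <- e$vectors %*% (ev * t(e$vectors))
  y <- (y + t(y)) / 2
  d <- sqrt(diag(y))
  y <- y / tcrossprod(d)
  diag(y) <- 1
  dimnames(y) <- dimnames(m)
  y
}

#' Generate a modular structural connectivity matrix
#'
#' Edge weights are log-normal connection probabilities with a location
#' shift for within-module edges, giving the block structure typical of
#' tractography networks: within-module connections are stochastically
#' stronger than between-module ones.
#'
#' @param n_regions number of regions (>= 3).
#' @param partition a [module_partition()] over `n_regions` regions, or
#'   `NULL` for an unstructured network.
#' @param meanlog_between log-scale location of between-module weights.
#' @param within_shift additive log-scale shift for within-module weights.
#' @param sdlog log-scale spread.
#' @return a structural [connectivity_matrix()]. Uses the current RNG
#'   stream; seed with [set.seed()] for reproducibility.
#' @export
generate_base_sc <- function(n_regions, partition = NULL,
                             meanlog_between = -4, within_shift = 1,
                             sdlog = 0.45) {
  if (n_regions < 3L) stop("n_regions must be >= 3", call. = FALSE)
  labs <- if (!is.null(partition)) names(partition$module)
          else paste0("R", seq_len(n_regions))
  if (length(labs) != n_regions)
    stop("partition covers ", length(labs), " regions, expected ",
         n_regions, call. = FALSE)
  ut <- which(upper.tri(matrix(0, n_regions, n_regions)), arr.ind = TRUE)
  meanlog <- rep(meanlog_between, nrow(ut))
  if (!is.null(partition)) {
    memb <- unname(partition$module[labs])
    within <- memb[ut[, 1L]] == memb[ut[, 2L]]
    meanlog[within] <- meanlog_between + within_shift
  }
  w <- matrix(0, n_regions, n_regions, dimnames = list(labs, labs))
  vals <- stats::rlnorm(nrow(ut), meanlog = meanlog, sdlog = sdlog)
  w[ut] <- vals
  w[ut[, 2:1]] <- vals
  connectivity_matrix(w, kind = "structural")
}

# rank-normalize to standard normal scores (average ranks for ties)
rank_normalize <- function(x) {
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

# note: normalization is global (one rank transform over all edges), so the
# within-module SC elevation carries through to FC; the scope-specific
# loading then controls the conditional SC-FC association per scope

#' Generate a functional connectivity matrix coupled to a structural one
#'
#' Realizes a controllable edge-wise SC-FC association. Each edge belongs
#' to a scope: within-module edges to their module, between-module edges to
#' the whole-brain scope (all edges when `partition` is `NULL`). The
#' structural weights are rank-normalized to normal scores `z` (one global
#' rank transform, so the modular block structure of SC carries through to
#' FC), a latent edge value is drawn as
#' `latent = a * z + sqrt(1 - a^2) * eps` with `eps ~ N(0, noise_sd^2)`
#' and scope-specific association `a`, and the functional weight is the
#' absolute value of a Fisher-z-scale squashing,
#' `|tanh(squash_scale * (latent + squash_shift))|`, which maps into
#' \[0, 1) and matches the absolute-FC convention. The estimated coupling
#' is a monotone (attenuated) function of `a`.
#'
#' @param sc structural [connectivity_matrix()].
#' @param coupling_targets either a single value in (-1, 1) applied to all
#'   edges, or a named vector with one entry per module plus
#'   `"whole_brain"` for between-module edges.
#' @param noise_sd standard deviation of the latent noise (> 0).
#' @param partition a [module_partition()] (required for per-module
#'   targets).
#' @param squash_scale,squash_shift squashing parameters; the shift keeps
#'   the latent mostly positive so the absolute value rarely folds.
#' @return a functional [connectivity_matrix()]. Uses the current RNG
#'   stream.
#' @export
generate_fc_from_sc <- function(sc, coupling_targets, noise_sd = 1,
                                partition = NULL,
                                squash_scale = 0.25, squash_shift = 2) {
  if (any(abs(coupling_targets) >= 1))
    stop("coupling targets must lie in (-1, 1)", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  labs <- region_labels(sc)
  n <- nrow(sc)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  scv <- unclass(sc)[ut]
  scope <- rep("whole_brain", nrow(ut))
  if (!is.null(partition)) {
    check_partition_regions(partition, labs)
    memb <- unname(partition$module[labs])
    within <- memb[ut[, 1L]] == memb[ut[, 2L]]
    scope[within] <- memb[ut[, 1L]][within]
  }
  if (length(coupling_targets) == 1L && is.null(names(coupling_targets)))
    coupling_targets <- stats::setNames(rep(coupling_targets,
                                            length(unique(scope))),
                                        unique(scope))
  miss <- setdiff(unique(scope), names(coupling_targets))
  if (length(miss))
    stop("no coupling target for scope(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  fcv <- numeric(nrow(ut))
  zg <- rank_normalize(scv)
  for (sp in unique(scope)) {
    idx <- which(scope == sp)
    if (stats::var(scv[idx]) < .Machine$double.eps)
      stop("degenerate SC: zero weight variance in scope '", sp, "'",
           call. = FALSE)
    a <- coupling_targets[[sp]]
    latent <- a * zg[idx] +
      sqrt(1 - a^2) * stats::rnorm(length(idx), 0, noise_sd)
    fcv[idx] <- abs(tanh(squash_scale * (latent + squash_shift)))
  }
  fc <- matrix(0, n, n, dimnames = list(labs, labs))
  fc[ut] <- fcv
  fc[ut[, 2:1]] <- fcv
  connectivity_matrix(fc, kind = "functional")
}

#' Generate regional time series with a target correlation structure
#'
#' Draws `T` samples from a zero-mean multivariate normal whose correlation
#' matrix is the nearest valid correlation matrix to the target FC (unit
#' diagonal imposed internally). The empirical absolute correlation of the
#' output converges to the target as `T` grows, inverting the FC
#' construction of [build_fc()].
#'
#' @param fc_target functional [connectivity_matrix()] (used as the target
#'   inter-regional correlation, diagonal set to 1).
#' @param T number of time points (>= 3; a warning is issued below
#'   `n_regions + 1`, where the sample correlation matrix is rank
#'   deficient).
#' @param sampling_interval metadata, seconds.
#' @return a [timeseries_matrix()] (regions x T). Uses the current RNG
#'   stream.
#' @export
generate_time_series <- function(fc_target, T, sampling_interval = NA_real_) {
  n <- nrow(fc_target)
  if (T < 3L) stop("T must be >= 3", call. = FALSE)
  if (T < n + 1L)
    warning("T < n_regions + 1: sample correlation will be rank deficient")
  cm <- unclass(fc_target)
  diag(cm) <- 1
  cm <- nearest_correlation(cm)
  s <- MASS::mvrnorm(T, mu = rep(0, n), Sigma = cm)
  timeseries_matrix(t(s), region_labels = region_labels(fc_target),
                    sampling_interval = sampling_interval)
}

#' Convert an estimated-coupling target to a latent loading
#'
#' The estimated SC-FC coupling is a monotone but attenuated function of
#' the generator's latent loading `a`: attenuation arises from the
#' rank-to-raw shape mismatch, the absolute-tanh squashing, and the
#' range restriction of correlating only the strongest functional edges at
#' each sparsity. Published coupling values live on the estimated scale, so
#' group targets are mapped through the inverse of a fixed calibration
#' curve: the mean estimated whole-brain coupling AUC of the generator at
#' its design point (90 regions, five-module partition, default threshold
#' series, `noise_sd = 1`), tabulated once by simulation over a latent
#' grid. Interpolation is monotone piecewise linear; the sign is carried
#' through unchanged and the result is capped at |a| = 0.995.
#'
#' @param estimated numeric vector of targets on the estimated-coupling
#'   scale, in (-1, 1).
#' @return latent loadings of the same length.
#' @export
latent_loading <- function(estimated) {
  # design-point calibration knots: (mean estimated AUC, latent loading)
  # the 0.40-0.60 band (where published whole-brain couplings land) is
  # refined by a pooled local-linear fit for faithful group spacing
  est_knots <- c(0, 0.0190, 0.0573, 0.0856, 0.1553, 0.2077, 0.2835,
                 0.3593, 0.4569, 0.5826, 0.7211, 0.8211, 0.9167, 1)
  lat_knots <- c(0, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50,
                 0.60, 0.70, 0.80, 0.90, 0.95, 0.99, 1)
  s <- sign(estimated)
  a <- stats::approx(est_knots, lat_knots, xout = abs(estimated),
                     rule = 2)$y
  pmin(a, 0.995) * s
}

#' Default cognition model for the synthetic cohort
#'
#' Each score is a linear function of the subject's *true* whole-brain
#' coupling (centered at 0.278) and of age and education (centered at their
#' population means), plus Gaussian noise. Slopes are signed so that lower
#' coupling worsens every score (SCWT and TMT are higher-is-worse), with
#' magnitudes giving latent coupling-cognition correlations around 0.5-0.6,
#' i.e. observed (estimation-attenuated) partial correlations in the
#' 0.2-0.4 range typical of patient cohorts.
#'
#' @return named list, one element per score, each with `mean`,
#'   `slope_coupling`, `slope_age`, `slope_education`, `slope_sex`,
#'   `slope_head_motion`, `sd`.
#' @export
default_cognition_model <- function() {
  spec <- function(mean, slope_coupling, slope_age, slope_education, sd)
    list(mean = mean, slope_coupling = slope_coupling, slope_age = slope_age,
         slope_education = slope_education, slope_sex = 0,
         slope_head_motion = 0, sd = sd)
  list(
    MoCA = spec(25.4, 150, -0.05, 0.15, 3),
    AVLT = spec(61, 600, -0.2, 0.5, 12),
    SCWT = spec(150, -2250, 0.8, -1.5, 45),
    SDMT = spec(33, 625, -0.25, 0.6, 12.5),
    TMT  = spec(130, -3500, 1.5, -2.5, 95)
  )
}

#' Default per-group coupling targets
#'
#' Group-ordered whole-brain and modular coupling targets (estimated scale)
#' for the three study groups (severe CSVD burden, mild burden, healthy
#' controls), centered on the regime reported for real CSVD cohorts:
#' whole-brain coupling AUC ordered CSVD-s < CSVD-m < HC around 0.27-0.28,
#' with the default-mode module highest and the auditory/motor module
#' lowest. The `between` entry is the loading applied to between-module
#' edges; it is derived at the generator's design point so that the
#' *marginal* whole-brain estimate (a mixture of within- and between-module
#' edges, roughly 35%/65% of retained edges) lands on the `whole_brain`
#' target.
#'
#' @return named list of named numeric vectors (one per group).
#' @export
default_coupling_targets <- function() {
  list(
    "CSVD-s" = c(whole_brain = 0.268, auditory_motor = 0.192, vision = 0.247,
                 attention = 0.255, dmn = 0.389, limbic_subcortical = 0.262,
                 between = 0.2627),
    "CSVD-m" = c(whole_brain = 0.278, auditory_motor = 0.214, vision = 0.250,
                 attention = 0.281, dmn = 0.393, limbic_subcortical = 0.291,
                 between = 0.2592),
    "HC"     = c(whole_brain = 0.284, auditory_motor = 0.228, vision = 0.249,
                 attention = 0.264, dmn = 0.395, limbic_subcortical = 0.297,
                 between = 0.2746)
  )
}

#' Simulation configuration for a synthetic coupled-connectome cohort
#'
#' Bundles and validates everything [generate_cohort()] needs. Defaults
#' emulate the three-group CSVD study design: 90 AAL regions in five
#' functional modules, group sizes 54/106/79, group-ordered coupling
#' targets, covariates centered on typical elderly-cohort values
#' (age N(62, 8^2) years, education N(12, 3.3^2) years, sex Bernoulli(0.55),
#' head motion N(0.12, 0.04^2) mm truncated at 0.01), and cognition linearly
#' tied to true whole-brain coupling.
#'
#' @param n_regions number of regions.
#' @param partition [module_partition()] over those regions; scaled-down
#'   configurations may pass a smaller partition.
#' @param group_n named integer vector of per-group subject counts (all
#'   >= 2); names define the group order (reference group last).
#' @param coupling_targets named list (per group) of named target vectors,
#'   see [default_coupling_targets()].
#' @param coupling_sd between-subject sd of the subject-level coupling
#'   deviation (added to every scope's target).
#' @param target_scale `"estimated"` (default): targets are interpreted on
#'   the estimated-coupling scale and mapped to latent loadings through
#'   [latent_loading()]; `"latent"`: targets are the loadings themselves.
#' @param efficiency_shift named numeric per group: exponent shift applied
#'   as `fc^(1 - shift)`, a monotone weight transform that raises (shift >
#'   0) or lowers (shift < 0) weighted efficiency without changing edge
#'   ranks or coupling ordering. Default 0 for all groups.
#' @param noise_sd latent edge-noise sd.
#' @param cognition_model see [default_cognition_model()]; `NULL` disables
#'   scores.
#' @param covariates list with elements `age` (mean, sd), `education`
#'   (mean, sd), `sex_p`, `head_motion` (mean, sd, floor).
#' @param T time-series length, or `NULL` (default) to skip time series.
#' @param seed integer seed for the cohort's single RNG stream.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_regions = 90L,
                       partition = default_partition(),
                       group_n = c("CSVD-s" = 54L, "CSVD-m" = 106L, "HC" = 79L),
                       coupling_targets = default_coupling_targets(),
                       coupling_sd = 0.015,
                       target_scale = c("estimated", "latent"),
                       efficiency_shift = NULL,
                       noise_sd = 1,
                       cognition_model = default_cognition_model(),
                       covariates = list(age = c(62, 8), education = c(12, 3.3),
                                         sex_p = 0.55,
                                         head_motion = c(0.12, 0.04, 0.01)),
                       T = NULL, seed = 1L) {
  if (length(partition$module) != n_regions)
    stop("partition size disagrees with n_regions", call. = FALSE)
  if (is.null(names(group_n)) || any(group_n < 2L))
    stop("group_n must be named, all >= 2", call. = FALSE)
  miss <- setdiff(names(group_n), names(coupling_targets))
  if (length(miss))
    stop("no coupling targets for group(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (g in names(group_n)) {
    tg <- coupling_targets[[g]]
    if (any(abs(tg) >= 1))
      stop("coupling targets must lie in (-1, 1)", call. = FALSE)
    need <- c("whole_brain", partition$module_names)
    if (!all(need %in% names(tg)))
      stop("group '", g, "' is missing targets for: ",
           paste(setdiff(need, names(tg)), collapse = ", "), call. = FALSE)
  }
  if (is.null(efficiency_shift))
    efficiency_shift <- stats::setNames(rep(0, length(group_n)), names(group_n))
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (coupling_sd < 0) stop("coupling_sd must be nonnegative", call. = FALSE)
  if (!is.null(T) && T < n_regions + 10L)
    stop("T must be >= n_regions + 10 when time series are requested",
         call. = FALSE)
  structure(list(n_regions = as.integer(n_regions), partition = partition,
                 group_n = group_n, coupling_targets = coupling_targets,
                 coupling_sd = coupling_sd,
                 target_scale = match.arg(target_scale),
                 efficiency_shift = efficiency_shift, noise_sd = noise_sd,
                 cognition_model = cognition_model, covariates = covariates,
                 T = T, seed = as.integer(seed)),
            class = "sim_config")
}

rtrunc_norm <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  pmax(x, lower)
}

#' Generate a synthetic coupled-connectome cohort
#'
#' For every subject: draws a subject-level coupling deviation (common to
#' all scopes), a fresh modular structural network, a functional network
#' coupled to it at the subject's targets ([generate_fc_from_sc()]),
#' covariates, and cognitive scores from the linear cognition model on the
#' subject's true whole-brain coupling. All randomness flows through one
#' RNG stream seeded from `config$seed`, so identical configurations give
#' identical cohorts.
#'
#' @param config a [sim_config()].
#' @return object of class `"synthetic_cohort"`: list with `subjects` (each
#'   a list `id`, `group`, `sc`, `fc`, optional `ts`, `true_coupling`),
#'   `cohort` (a [cohort_table()] including ground-truth column
#'   `true_coupling_wb`), `truth` (per-subject per-scope target data.frame)
#'   and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cv <- config$covariates
  subjects <- list()
  rows <- list()
  truth <- list()
  scopes <- c("whole_brain", config$partition$module_names)
  sid <- 0L
  for (g in names(config$group_n)) {
    targets <- config$coupling_targets[[g]][scopes]
    shift <- config$efficiency_shift[[g]]
    for (k in seq_len(config$group_n[[g]])) {
      sid <- sid + 1L
      id <- sprintf("sub-%03d", sid)
      dev <- stats::rnorm(1L, 0, config$coupling_sd)
      a <- pmin(pmax(targets + dev, -0.99), 0.99)
      # between-module edges take the dedicated "between" target when the
      # group declares one (whole_brain is then the marginal target that
      # the mixture of scopes realizes), else the whole_brain target
      gen_a <- a
      btw <- config$coupling_targets[[g]]["between"]
      if (!is.na(btw))
        gen_a[["whole_brain"]] <- min(max(btw + dev, -0.99), 0.99)
      a_lat <- if (config$target_scale == "estimated") latent_loading(gen_a)
               else gen_a
      sc <- generate_base_sc(config$n_regions, config$partition)
      fc <- generate_fc_from_sc(sc, a_lat, noise_sd = config$noise_sd,
                                partition = config$partition)
      if (shift != 0) {
        w <- unclass(fc)^(1 - shift)
        diag(w) <- 0
        fc <- connectivity_matrix(w, kind = "functional")
      }
      ts <- if (!is.null(config$T)) generate_time_series(fc, config$T)
      age <- stats::rnorm(1L, cv$age[1L], cv$age[2L])
      edu <- stats::rnorm(1L, cv$education[1L], cv$education[2L])
      sex <- stats::rbinom(1L, 1L, cv$sex_p)
      hm <- rtrunc_norm(1L, cv$head_motion[1L], cv$head_motion[2L],
                        cv$head_motion[3L])
      row <- list(id = id, group = g, age = age, sex = sex, education = edu,
                  head_motion = hm)
      for (scn in names(config$cognition_model)) {
        m <- config$cognition_model[[scn]]
        row[[scn]] <- m$mean +
          m$slope_coupling * (a[["whole_brain"]] - 0.278) +
          m$slope_age * (age - cv$age[1L]) +
          m$slope_education * (edu - cv$education[1L]) +
          m$slope_sex * sex +
          m$slope_head_motion * (hm - cv$head_motion[1L]) +
          stats::rnorm(1L, 0, m$sd)
      }
      row$true_coupling_wb <- a[["whole_brain"]]
      rows[[sid]] <- as.data.frame(row, check.names = FALSE)
      truth[[sid]] <- data.frame(id = id, group = g, scope = scopes,
                                 target = unname(a))
      subjects[[sid]] <- list(id = id, group = g, sc = sc, fc = fc, ts = ts,
                              true_coupling = a)
    }
  }
  df <- do.call(rbind, rows)
  cohort <- cohort_table(df, groups = names(config$group_n),
                         scores = names(config$cognition_model))
  structure(list(subjects = subjects, cohort = cohort,
                 truth = do.call(rbind, truth), config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d regions, seed %d\n",
              length(x$subjects), x$config$n_regions, x$config$seed))
  print(x$cohort)
  invisible(x)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Emits `<id>_sc.tsv` and `<id>_fc.tsv` per subject (plus `<id>_ts.tsv`
#' when time series were generated), `cohort.tsv`, `truth.tsv` and
#' `partition.tsv`, all in the package's delimited-text dialects.
#'
#' @param x a `"synthetic_cohort"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_cohort <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in x$subjects) {
    write_matrix(s$sc, file.path(dir, paste0(s$id, "_sc.tsv")))
    write_matrix(s$fc, file.path(dir, paste0(s$id, "_fc.tsv")))
    if (!is.null(s$ts))
      write_timeseries(s$ts, file.path(dir, paste0(s$id, "_ts.tsv")))
  }
  write_cohort(x$cohort, file.path(dir, "cohort.tsv"))
  utils::write.table(x$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_partition(x$config$partition, file.path(dir, "partition.tsv"))
  invisible(dir)
}
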