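# Synthetic lifespan cohort: demographics matching the study's group
# structure, age-dependent ground-truth microstructure with configurable
# planted correlations, simulated noisy signals, and an end-to-end study
# runner. The planted trajectory values are fixtures chosen inside the
# fitting priors; they are not measured tissue values.

#' Default per-metric age trajectories
#'
#' Linear trajectories specified by their values at ages 19 and 85 years
#' and the target Pearson correlation with age; the residual SD is solved
#' at generation time so the expected correlation matches the target given
#' the realised age variance. Signs follow the lifespan pattern: soma
#' fraction, soma radius and intra-neurite diffusivity decline with age;
#' neurite and extracellular fractions and extracellular diffusivity rise.
#' `normalized_volume` declines (target r -0.74); `null_metric` is a pure
#' noise column with zero slope used for type-I error checks.
#'
#' @param include_null include the zero-slope `null_metric` row.
#' @return Tibble: `metric`, `value_19`, `value_85`, `quad`, `target_r`,
#'   `resid_sd` (NA = solve from `target_r`).
#' @export
default_trajectories <- function(include_null = TRUE) {
  tr <- tibble::tribble(
    ~metric,              ~value_19, ~value_85, ~quad, ~target_r, ~resid_sd,
    "f_is",                  0.28,     0.18,     0,     -0.75,     NA,
    "f_in",                  0.30,     0.34,     0,      0.33,     NA,
    "r_s",                   8.5,      7.0,      0,     -0.44,     NA,
    "D_in",                  1.80,     1.60,     0,     -0.25,     NA,
    "D_ec",                  0.90,     1.10,     0,      0.46,     NA,
    "normalized_volume",     0.40,     0.28,     0,     -0.74,     NA
  )
  if (include_null) {
    tr <- dplyr::bind_rows(tr, tibble::tibble(
      metric = "null_metric", value_19 = 0.5, value_85 = 0.5, quad = 0,
      target_r = 0, resid_sd = 0.05))
  }
  tr
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the study's demographic structure: 33 young
#' (Normal(25.5, 3.6^2) truncated to 19-34, 18 F), 21 middle-aged
#' (Normal(44.3, 6.6^2), 35-54, 13 F), 18 older (Normal(67.1, 7.7^2),
#' 55-85, 9 F) — 72 subjects, 40 F / 32 M — scanned with the 8-shell
#' protocol at SNR 50.
#'
#' @param group_n subjects per group (young, middle, older).
#' @param age_mean,age_sd,age_min,age_max truncated-normal age parameters
#'   per group.
#' @param n_female females per group.
#' @param snr b = 0 signal-to-noise ratio of the simulated scans.
#' @param trajectories per-metric trajectory table, see
#'   [default_trajectories()].
#' @param regions region names; each gets the same trajectory table.
#' @param n_voxels_per_region voxels simulated (and averaged after
#'   fitting) per subject x region, emulating the ROI mean over many
#'   voxels.
#' @param n_train,n_trees training size / forest size of the regressor the
#'   study runner trains when no model is supplied.
#' @param priors fitting priors, see [sandi_priors()].
#' @param protocol acquisition protocol.
#' @param seed master seed expanded into per-stage substreams.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(group_n = c(young = 33, middle = 21, older = 18),
                          age_mean = c(25.5, 44.3, 67.1),
                          age_sd = c(3.6, 6.6, 7.7),
                          age_min = c(19, 35, 55),
                          age_max = c(34, 54, 85),
                          n_female = c(18, 13, 9),
                          snr = 50,
                          trajectories = default_trajectories(),
                          regions = "cerebral_cortex",
                          n_voxels_per_region = 16,
                          n_train = 3e4, n_trees = 100,
                          priors = sandi_priors(),
                          protocol = connectome_protocol(),
                          seed = 1) {
  if (any(group_n <= 0)) stop("group sizes must be positive")
  if (any(n_female > group_n)) stop("n_female cannot exceed group size")
  if (any(age_min >= age_max)) stop("infeasible truncation bounds")
  structure(list(group_n = group_n, age_mean = age_mean, age_sd = age_sd,
                 age_min = age_min, age_max = age_max, n_female = n_female,
                 snr = snr, trajectories = trajectories, regions = regions,
                 n_voxels_per_region = n_voxels_per_region,
                 n_train = n_train, n_trees = n_trees, priors = priors,
                 protocol = protocol, seed = seed),
            class = "cohort_config")
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate synthetic subject demographics
#'
#' @param config a [cohort_config()].
#' @param seed overrides `config$seed` when given.
#' @return Tibble: `subject`, `age` (years), `sex` (`"F"`/`"M"`), `group`.
#' @export
generate_demographics <- function(config = cohort_config(), seed = NULL) {
  seed <- if (is.null(seed)) config$seed else seed
  with_seed(substream_seed(seed, 11), {
    groups <- names(config$group_n)
    rows <- lapply(seq_along(groups), function(g) {
      n <- config$group_n[g]
      age <- rtruncnorm(n, config$age_mean[g], config$age_sd[g],
                        config$age_min[g], config$age_max[g])
      sex <- sample(rep(c("F", "M"), c(config$n_female[g],
                                       n - config$n_female[g])))
      tibble::tibble(age = age, sex = sex, group = groups[g])
    })
    out <- dplyr::bind_rows(rows)
    out$subject <- sprintf("S%03d", seq_len(nrow(out)))
    out$group <- factor(out$group, levels = groups)
    out[, c("subject", "age", "sex", "group")]
  })
}

metric_bounds <- function(priors) {
  list(f_is = c(0.01, 0.99), f_in = c(0.01, 0.99),
       r_s = priors$r_s, D_in = priors$D_in, D_ec = priors$D_ec,
       normalized_volume = c(1e-3, 0.999), null_metric = c(-Inf, Inf))
}

#' Generate ground-truth microstructure for a synthetic cohort
#'
#' Each metric follows `value = intercept + slope * age + quad * age^2 +
#' Normal(0, resid_sd)`; when `resid_sd` is `NA` it is solved so that the
#' expected Pearson correlation with age equals `target_r` given the
#' realised age distribution. Draws falling outside the metric bounds
#' (fitting priors for tissue parameters, (0, 1) for volume) are redrawn;
#' the extracellular fraction is derived from `f_ec = 1 - f_in - f_is`.
#'
#' @param subjects demographics tibble from [generate_demographics()].
#' @param trajectories trajectory table, see [default_trajectories()].
#' @param regions region names (the trajectory applies to each).
#' @param priors [sandi_priors()] used as bounds for the tissue metrics.
#' @param seed integer seed.
#' @return Tibble: one row per subject x region with demographics, the
#'   true SANDI parameters, `normalized_volume`, and any extra metrics.
#' @export
generate_ground_truth <- function(subjects,
                                  trajectories = default_trajectories(),
                                  regions = "cerebral_cortex",
                                  priors = sandi_priors(), seed = 1) {
  if (any(abs(trajectories$target_r) >= 1, na.rm = TRUE)) {
    stop("|target_r| must be < 1")
  }
  bounds <- metric_bounds(priors)
  out <- list()
  for (ri in seq_along(regions)) {
    rec <- subjects
    rec$region <- regions[ri]
    age <- rec$age
    with_seed(substream_seed(seed, 20 + ri), {
      for (k in seq_len(nrow(trajectories))) {
        tr <- trajectories[k, ]
        slope <- (tr$value_85 - tr$value_19) / 66
        intercept <- tr$value_19 - slope * 19
        g <- intercept + slope * age + tr$quad * age^2
        sdg <- stats::sd(g)
        rs <- tr$resid_sd
        if (is.na(rs)) {
          if (tr$target_r == 0 || sdg == 0) {
            stop("cannot solve residual SD for a flat trajectory; give resid_sd")
          }
          if (sign(stats::cor(g, age)) != sign(tr$target_r)) {
            stop("trajectory slope sign contradicts target_r for ", tr$metric)
          }
          rs <- sdg * sqrt(1 / tr$target_r^2 - 1)
        }
        v <- g + stats::rnorm(length(age), 0, rs)
        bd <- bounds[[tr$metric]]
        if (is.null(bd)) bd <- c(-Inf, Inf)
        tries <- 0
        while (any(bad <- v < bd[1] | v > bd[2])) {
          v[bad] <- g[bad] + stats::rnorm(sum(bad), 0, rs)
          tries <- tries + 1
          if (tries > 100) stop("trajectory for ", tr$metric,
                                " keeps escaping its bounds")
        }
        rec[[tr$metric]] <- v
      }
      # keep the fraction simplex feasible
      if (all(c("f_in", "f_is") %in% names(rec))) {
        tries <- 0
        while (any(bad <- rec$f_in + rec$f_is > 0.99)) {
          sc <- 0.99 / (rec$f_in[bad] + rec$f_is[bad])
          rec$f_in[bad] <- rec$f_in[bad] * sc
          rec$f_is[bad] <- rec$f_is[bad] * sc
          tries <- tries + 1
          if (tries > 100) stop("fraction simplex infeasible")
        }
        rec$f_ec <- 1 - rec$f_in - rec$f_is
      }
    })
    out[[ri]] <- rec
  }
  dplyr::bind_rows(out)
}

#' Simulate noisy spherical-mean signals for cohort records
#'
#' For each record the noise-free shell signal is computed from the SANDI
#' forward model; Rician noise at `sigma = 1/snr` is then applied to each
#' directional replicate (32 or 64 per shell, as acquired) and to each
#' b = 0 volume before averaging, reproducing the small Rician floor that
#' in vivo spherical means carry.
#'
#' @param records tibble with columns `f_in`, `f_is`, `f_ec`, `r_s`,
#'   `D_in`, `D_ec` (true parameters per record).
#' @param protocol acquisition protocol.
#' @param snr b = 0 SNR (> 0).
#' @param seed integer seed.
#' @param D_is fixed intra-soma diffusivity.
#' @return A `spherical_mean` with one row per record.
#' @export
simulate_cohort_signals <- function(records, protocol = connectome_protocol(),
                                    snr = 50, seed = 1, D_is = 3) {
  if (!(snr > 0)) stop("snr must be > 0")
  shells <- group_shells(protocol)
  bnz <- shell_bvalues(shells)
  ndir <- shells$n_dir[!shells$is_b0]
  nb0 <- sum(shells$n_dir[shells$is_b0])
  pars <- sandi_params(f_in = records$f_in, f_is = records$f_is,
                       r_s = records$r_s, D_in = records$D_in,
                       D_ec = records$D_ec, D_is = D_is)
  clean <- sandi_signal(pars, b = bnz, delta = protocol$delta,
                        Delta = protocol$Delta)
  sigma <- 1 / snr
  n <- nrow(clean$values)
  with_seed(substream_seed(seed, 31), {
    b0ref <- rowMeans(add_rician_noise(matrix(1, n, nb0), sigma))
    vals <- vapply(seq_along(bnz), function(j) {
      rowMeans(add_rician_noise(
        matrix(clean$values[, j], n, ndir[j]), sigma))
    }, numeric(n)) / b0ref
    spherical_mean(matrix(vals, nrow = n), bnz, b0_mean = b0ref)
  })
}

#' Run the full synthetic study end to end
#'
#' Demographics -> ground truth -> noisy signals (`n_voxels_per_region`
#' voxels per subject x region) -> random-forest fit -> ROI means ->
#' correlation table, group ANCOVA and age-trend fits, plus a recovery
#' report comparing planted against realised and recovered effects.
#'
#' The regressor is trained at the effective per-shell noise level of the
#' direction-averaged signals (`sigma / sqrt(n_directions)`), matching the
#' simulation.
#'
#' @param config a [cohort_config()].
#' @param model optional pre-trained `sandi_rf` (reused across seeds for
#'   speed; it must match the protocol fingerprint).
#' @param seed overrides `config$seed` when given.
#' @return List of class `sandi_study`: `demographics`, `ground_truth`,
#'   `cohort` (subject x region estimated metrics), `results_table`,
#'   `group_comparisons`, `age_trends`, `recovery`, `model`, `config`.
#' @export
run_end_to_end <- function(config = cohort_config(), model = NULL,
                           seed = NULL) {
  seed <- if (is.null(seed)) config$seed else seed
  protocol <- config$protocol
  shells <- group_shells(protocol)
  demo <- generate_demographics(config, seed = seed)
  truth <- generate_ground_truth(demo, config$trajectories, config$regions,
                                 config$priors, seed = seed)
  nvox <- config$n_voxels_per_region
  vox <- truth[rep(seq_len(nrow(truth)), each = nvox), ]
  sm <- simulate_cohort_signals(vox, protocol, snr = config$snr, seed = seed)
  if (is.null(model)) {
    ndir <- shells$n_dir[!shells$is_b0]
    sigma_shell <- (1 / config$snr) / sqrt(ndir)
    ts <- build_training_set(priors = config$priors, protocol = protocol,
                             sigma = sigma_shell, n_train = config$n_train,
                             seed = substream_seed(seed, 41))
    model <- train_regressor(ts, n_trees = config$n_trees,
                             seed = substream_seed(seed, 42))
  }
  est <- predict_params(model, sm)
  est$subject <- vox$subject
  est$region <- vox$region
  roi <- dplyr::summarise(
    dplyr::group_by(est, .data$subject, .data$region),
    dplyr::across(dplyr::all_of(sandi_metric_names()), mean),
    .groups = "drop")
  extra <- setdiff(names(truth), c(names(demo), sandi_metric_names(), "region"))
  cohort <- dplyr::left_join(
    dplyr::left_join(roi, truth[, c("subject", "region", extra)],
                     by = c("subject", "region")),
    demo, by = "subject")
  metrics <- c(sandi_metric_names(),
               intersect("null_metric", names(cohort)))
  results <- build_results_table(cohort, metrics = metrics,
                                 targets = c("age", "normalized_volume"))
  comparisons <- list()
  trends <- list()
  for (rg in config$regions) {
    df <- cohort[cohort$region == rg, ]
    for (m in sandi_metric_names()) {
      key <- paste(rg, m, sep = ".")
      comparisons[[key]] <- compare_groups_ancova(df, m)
      trends[[key]] <- polynomial_age_fit(df, m)
    }
  }
  recovery <- recovery_report(truth, cohort, results, config)
  structure(list(demographics = demo, ground_truth = truth, cohort = cohort,
                 results_table = results, group_comparisons = comparisons,
                 age_trends = trends, recovery = recovery, model = model,
                 config = config),
            class = "sandi_study")
}

recovery_report <- function(truth, cohort, results, config) {
  tr <- config$trajectories
  rows <- lapply(seq_len(nrow(tr)), function(k) {
    m <- tr$metric[k]
    planted <- tr$target_r[k]
    per_region <- lapply(config$regions, function(rg) {
      tt <- truth[truth$region == rg, ]
      realised <- if (m %in% names(tt)) stats::cor(tt[[m]], tt$age) else NA
      res <- results[results$metric == m & results$region == rg &
                       results$target == "age", ]
      tibble::tibble(metric = m, region = rg, planted_r = planted,
                     realised_r = realised,
                     recovered_r = if (nrow(res)) res$r else NA_real_,
                     recovered_fdr_p = if (nrow(res)) res$fdr_p else NA_real_)
    })
    dplyr::bind_rows(per_region)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.sandi_study <- function(x, ...) {
  cat(sprintf("<sandi_study> %d subjects x %d region(s), SNR %g\n",
              nrow(x$demographics), length(x$config$regions), x$config$snr))
  cat("recovery (age correlations):\n")
  print(x$recovery)
  invisible(x)
}
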