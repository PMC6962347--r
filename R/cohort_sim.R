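#' Default per-group SWE velocity means and SDs
#'
#' The generator's default group structure: four AHA plaque types
#' (III, V, VI, VII), two imaging views (L = longitudinal,
#' T = transverse) and four velocity metrics (group velocity `gv` and
#' phase-velocity band means `pv200`, `pv300`, `pv400`). Values are the
#' cohort means and standard deviations reported for a 27-plaque carotid
#' cohort; type VI (complex, rupture-prone) plaques carry the highest
#' velocities, most markedly in the transverse view.
#'
#' @return A list with 3D arrays `means` and `sds`, dimensions
#'   (aha_type, view, metric), in m/s.
#' @export
default_velocity_parameters <- function() {
  types <- c("III", "V", "VI", "VII")
  views <- c("L", "T")
  metrics <- c("gv", "pv200", "pv300", "pv400")
  means <- array(NA_real_, c(4, 2, 4), dimnames = list(types, views, metrics))
  sds <- array(NA_real_, c(4, 2, 4), dimnames = list(types, views, metrics))
  means[, "L", "gv"] <- c(4.2, 4.0, 5.8, 4.1)
  sds[, "L", "gv"] <- c(1.1, 1.1, 0.6, 1.0)
  means[, "T", "gv"] <- c(3.6, 3.3, 7.3, 3.1)
  sds[, "T", "gv"] <- c(1.3, 0.7, 2.5, 0.6)
  means[, "L", "pv200"] <- c(3.0, 4.0, 4.6, 3.8)
  sds[, "L", "pv200"] <- c(0.7, 1.1, 1.1, 2.2)
  means[, "T", "pv200"] <- c(3.0, 3.0, 3.5, 2.5)
  sds[, "T", "pv200"] <- c(1.3, 1.5, 1.2, 0.4)
  means[, "L", "pv300"] <- c(3.8, 4.1, 6.1, 4.8)
  sds[, "L", "pv300"] <- c(1.0, 1.5, 2.1, 2.4)
  means[, "T", "pv300"] <- c(3.3, 3.2, 5.0, 3.4)
  sds[, "T", "pv300"] <- c(2.5, 1.5, 2.5, 0.6)
  means[, "L", "pv400"] <- c(4.8, 4.1, 7.0, 4.6)
  sds[, "L", "pv400"] <- c(1.7, 1.9, 1.4, 1.9)
  means[, "T", "pv400"] <- c(4.1, 4.3, 5.2, 4.1)
  sds[, "T", "pv400"] <- c(1.8, 1.4, 2.1, 0.8)
  list(means = means, sds = sds)
}

#' Default plaque-component and lipid generator table
#'
#' One row per covariate: its marginal mean and SD on its own scale, the
#' velocity metric it is anchored to (`"<metric>_<view>"`), the target
#' Pearson correlation to that anchor, the probability that the value is
#' missing for a given plaque, and an optional lower clip. Defaults mirror
#' the correlation pattern reported for the cohort: lipid-rich necrotic
#' core (LRNC) burden and cap volume correlate positively with group
#' velocity; calcification positively and loose matrix negatively with
#' high-band phase velocity; intraplaque haemorrhage (IPH) is defined for
#' few plaques and anchors negatively to the mid band; plaque geometry is
#' uncorrelated. Lipid panel scales follow typical statin-treated values.
#'
#' @return A data.frame with columns `name`, `mean`, `sd`, `anchor`,
#'   `target_r`, `missing_fraction`, `clip_lo`, `clip_hi`.
#' @export
default_component_table <- function() {
  data.frame(
    name = c(
      "lrnc_pct", "nc_vol_mm3", "cap_vol_mm3", "calc_vol_mm3",
      "loose_matrix_vol_mm3", "iph_vol_mm3", "cap_nc_ratio",
      "length_mm", "thickness_mm", "area_mm2",
      "hdl_mg_dl", "ldl_mg_dl", "tg_mg_dl", "total_chol_mg_dl"
    ),
    mean = c(20, 120, 150, 40, 30, 25, 1.5, 15, 3.5, 40,
      46.9, 89.1, 175.3, 170.1),
    sd = c(10, 60, 70, 18, 14, 12, 0.7, 5, 1, 15,
      14.3, 37.3, 107.7, 41.3),
    anchor = c(
      "gv_T", "gv_T", "gv_L", "pv400_T", "pv400_T", "pv300_L", "pv400_T",
      "gv_L", "gv_L", "gv_L", "gv_T", "gv_T", "pv400_T", "gv_T"
    ),
    target_r = c(0.58, 0.62, 0.60, 0.64, -0.64, -0.94, -0.61,
      0, 0, 0, 0.56, 0, -0.52, 0),
    missing_fraction = c(0, 0, 0, 0, 0, 0.7, 0, 0, 0, 0, 0, 0, 0, 0),
    clip_lo = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    clip_hi = c(100, rep(Inf, 13))
  )
}

#' Configuration for the synthetic cohort generator
#'
#' @param group_sizes Named integer vector, plaques per AHA type;
#'   default `c(III = 7, V = 8, VI = 8, VII = 4)` (27 plaques).
#' @param velocity_means,velocity_sds 3D arrays (aha_type, view, metric)
#'   in m/s; defaults from [default_velocity_parameters()].
#' @param acquisitions_per_plaque Length-2 integer range; each plaque and
#'   view draws its acquisition count uniformly from it. Default 5 to 15.
#' @param acquisition_sd Per-acquisition measurement noise SD in m/s;
#'   default 1.5 (per-plaque SWE scatter of 1-2 m/s).
#' @param components Covariate generator table as in
#'   [default_component_table()]; each covariate is tied to its anchor
#'   velocity by the standard bivariate-normal device so the sample
#'   Pearson correlation matches `target_r` in expectation.
#' @param seed Integer seed; the generator is a pure function of it.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(group_sizes = c(III = 7, V = 8, VI = 8, VII = 4),
                              velocity_means = NULL, velocity_sds = NULL,
                              acquisitions_per_plaque = c(5L, 15L),
                              acquisition_sd = 1.5,
                              components = default_component_table(),
                              seed = 1L) {
  defaults <- default_velocity_parameters()
  if (is.null(velocity_means)) velocity_means <- defaults$means
  if (is.null(velocity_sds)) velocity_sds <- defaults$sds
  stopifnot(
    all(group_sizes >= 1), all(velocity_sds >= 0),
    identical(dim(velocity_means), dim(velocity_sds)),
    length(acquisitions_per_plaque) == 2,
    acquisitions_per_plaque[1] >= 1,
    acquisitions_per_plaque[2] >= acquisitions_per_plaque[1],
    acquisition_sd >= 0
  )
  if (!is.null(components)) {
    stopifnot(
      is.data.frame(components),
      all(c("name", "mean", "sd", "anchor", "target_r",
        "missing_fraction") %in% names(components)),
      all(abs(components$target_r) <= 1),
      all(components$missing_fraction >= 0 & components$missing_fraction <= 1)
    )
  }
  structure(
    list(
      group_sizes = group_sizes, velocity_means = velocity_means,
      velocity_sds = velocity_sds,
      acquisitions_per_plaque = as.integer(acquisitions_per_plaque),
      acquisition_sd = acquisition_sd, components = components,
      seed = as.integer(seed)
    ),
    class = "cohort_sim_config"
  )
}

#' Simulate a synthetic plaque cohort
#'
#' One plaque per row and view: the plaque's true velocity for each
#' (view, metric) is drawn from its AHA group's normal distribution, a
#' uniformly drawn number of acquisitions adds independent measurement
#' noise, and the per-plaque summary is the mean, sample SD and count of
#' those acquisitions. Covariates are generated from the standardised
#' anchor velocity `z` as `mean + sd * (R * z + sqrt(1 - R^2) * eps)`,
#' which attains the target Pearson correlation in expectation, then
#' clipped to their physical range and masked missing at the configured
#' rate. Covariates and the AHA label are plaque-level: identical in the
#' L and T rows of a plaque.
#'
#' @param config A [cohort_sim_config()].
#' @return A data.frame of class `cohort_table`: columns `plaque_id`,
#'   `subject_id`, `view`, `aha_type`, then `<metric>_mean`,
#'   `<metric>_sd`, `<metric>_n` per velocity metric, then one column per
#'   covariate.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  dn <- dimnames(config$velocity_means)
  types <- dn[[1]]
  views <- dn[[2]]
  metrics <- dn[[3]]
  aha <- rep(names(config$group_sizes), config$group_sizes)
  n_plaque <- length(aha)
  ids <- sprintf("P%02d", seq_len(n_plaque))

  rows <- list()
  for (v in views) {
    df <- data.frame(
      plaque_id = ids, subject_id = sprintf("S%02d", seq_len(n_plaque)),
      view = v, aha_type = aha, stringsAsFactors = FALSE
    )
    for (m in metrics) {
      mu <- config$velocity_means[aha, v, m]
      sig <- config$velocity_sds[aha, v, m]
      true <- stats::rnorm(n_plaque, mu, sig)
      n_acq <- sample(
        seq(config$acquisitions_per_plaque[1],
          config$acquisitions_per_plaque[2]),
        n_plaque,
        replace = TRUE
      )
      agg <- vapply(seq_len(n_plaque), function(p) {
        acq <- true[p] + stats::rnorm(n_acq[p], 0, config$acquisition_sd)
        a <- aggregate_plaque(acq)
        c(a$mean, a$sd, a$n)
      }, numeric(3))
      df[[paste0(m, "_mean")]] <- agg[1, ]
      df[[paste0(m, "_sd")]] <- agg[2, ]
      df[[paste0(m, "_n")]] <- as.integer(agg[3, ])
    }
    rows[[v]] <- df
  }

  comps <- config$components
  if (!is.null(comps) && nrow(comps) > 0) {
    clip_lo <- if ("clip_lo" %in% names(comps)) comps$clip_lo else
      rep(-Inf, nrow(comps))
    clip_hi <- if ("clip_hi" %in% names(comps)) comps$clip_hi else
      rep(Inf, nrow(comps))
    for (i in seq_len(nrow(comps))) {
      parts <- strsplit(comps$anchor[i], "_(?=[LT]$)", perl = TRUE)[[1]]
      anchor_metric <- parts[1]
      anchor_view <- parts[2]
      av <- rows[[anchor_view]][[paste0(anchor_metric, "_mean")]]
      z <- as.numeric(scale(av))
      if (any(!is.finite(z))) z <- rep(0, n_plaque)
      r <- comps$target_r[i]
      val <- comps$mean[i] + comps$sd[i] *
        (r * z + sqrt(1 - r^2) * stats::rnorm(n_plaque))
      val <- pmin(pmax(val, clip_lo[i]), clip_hi[i])
      miss <- stats::runif(n_plaque) < comps$missing_fraction[i]
      val[miss] <- NA_real_
      for (v in views) rows[[v]][[comps$name[i]]] <- val
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}
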