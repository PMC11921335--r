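#' Below-limit-of-detection handling
#'
#' Applies a stated policy to values below a per-VOC limit of detection:
#' `"keep"` (default; values pass through), `"half-lod"` (replaced by
#' LOD/2) or `"drop"` (removed). The log-domain outlier treatment cannot
#' accept zeros, so pipelines feeding it must use `"drop"` or
#' `"half-lod"`; [run_pipeline()] enforces and logs this.
#'
#' @param values Numeric concentrations.
#' @param lod Limit(s) of detection, >= 0 (scalar or per value).
#' @param policy `"keep"`, `"half-lod"` or `"drop"`.
#' @return For `"keep"`/`"half-lod"`, a vector the same length as
#'   `values`; for `"drop"`, the retained values only.
#' @examples
#' handle_below_lod(c(0, 0.5), lod = 0.2, policy = "half-lod")
#' @export
handle_below_lod <- function(values, lod, policy = c("keep", "half-lod", "drop")) {
  if (is.character(policy) && length(policy) == 1L &&
      !policy %in% c("keep", "half-lod", "drop"))
    stop("unknown below-LOD policy: '", policy, "'", call. = FALSE)
  policy <- match.arg(policy)
  if (any(lod < 0)) stop("'lod' must be >= 0", call. = FALSE)
  below <- values < lod
  switch(policy,
         keep = values,
         `half-lod` = ifelse(below, lod / 2, values),
         drop = values[!below])
}

#' Pipeline configuration
#'
#' Collects every setting of the end-to-end analysis. `cohort` may be a
#' [cohort_spec()] (the cohort is generated), a directory written by
#' [write_cohort()], or a `voc_cohort` object.
#'
#' @param cohort Input cohort (spec, directory, or object).
#' @param acr_params [acr_params()] for the CO2 mass balance.
#' @param classes VOC class definitions, as [voc_classes()].
#' @param outlier_scope VOCs receiving outlier treatment (default the
#'   aromatics).
#' @param outlier_threshold Modified Z-score threshold (default 3.5).
#' @param risk_table [read_risk_table()] table.
#' @param ef [exposure_factors()].
#' @param lod Optional data frame `voc`, `lod` of detection limits.
#' @param lod_policy Below-LOD policy, see [handle_below_lod()].
#' @param alpha Significance level for all tests.
#' @param n_resamples Bootstrap resamples for CIs.
#' @param seed Integer seed for all stochastic steps.
#' @param out_dir Optional directory; when set, all tables are written as
#'   CSV.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            acr_params = ivoc::acr_params(),
                            classes = voc_classes(),
                            outlier_scope = classes$aromatics,
                            outlier_threshold = 3.5,
                            risk_table = read_risk_table(),
                            ef = exposure_factors(),
                            lod = NULL, lod_policy = "keep",
                            alpha = 0.05, n_resamples = 1000,
                            seed = 1L, out_dir = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  structure(list(cohort = cohort, acr_params = acr_params,
                 classes = classes, outlier_scope = outlier_scope,
                 outlier_threshold = outlier_threshold,
                 risk_table = risk_table, ef = ef, lod = lod,
                 lod_policy = lod_policy, alpha = alpha,
                 n_resamples = n_resamples, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

season_value_summary <- function(values, season) {
  seasons <- intersect(c("winter", "spring", "summer", "autumn"),
                       unique(as.character(season)))
  do.call(rbind, lapply(seasons, function(s) {
    v <- values[season == s]
    q <- boxplot_summary(v)$percentiles
    data.frame(season = s, n = length(v), mean = mean(v),
               median = unname(q["p50"]), p5 = unname(q["p5"]),
               p25 = unname(q["p25"]), p75 = unname(q["p75"]),
               p95 = unname(q["p95"]))
  }))
}

can_test <- function(groups) {
  length(groups) >= 2L && all(vapply(groups, length, 1L) >= 2L)
}

#' Run the full indoor-VOC exposure analysis
#'
#' Orchestrates the pipeline: cohort (simulated or loaded) -> per-home
#' air change rate from the CO2 mass balance -> log-scale modified
#' Z-score outlier treatment of indoor aromatics -> per-VOC time-averaged
#' emission rates, TVOC, class totals and min-max normalised totals ->
#' inhalation risk benchmarks (LCR, HQ, exceedance fractions) -> seasonal
#' and urban/rural nonparametric comparisons. Deterministic for a given
#' config and seed; every dropped record is logged with a reason.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `ivoc_report`: list of tables and test
#'   results (`homes`, `acr`, `acr_by_season`, `treated_concentrations`,
#'   `exclusions`, `tvoc`, `emissions`, `total_emission`,
#'   `monoterpene_emission`, `normalized_total`,
#'   `normalized_monoterpene`, `tvoc_by_season`, `emission_by_season`,
#'   `lcr`, `hq`, `exceedance`, `tests`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- config$cohort
  if (inherits(cohort, "cohort_spec")) cohort <- generate_cohort(cohort, config$classes)
  else if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "voc_cohort"))
  homes <- cohort$homes
  conc <- cohort$concentrations
  exclusions <- data.frame(home_id = character(), voc = character(),
                           value = numeric(), reason = character())

  ## 1. ACR inference
  acr_tab <- infer_acr(homes, params = config$acr_params)

  ## 2. below-LOD handling (indoor concentrations)
  policy <- config$lod_policy
  if (!is.null(config$lod) && policy != "keep") {
    lod <- config$lod$lod[match(conc$voc, config$lod$voc)]
    lod[is.na(lod)] <- 0
    below <- conc$indoor < lod
    if (policy == "half-lod") {
      conc$indoor[below] <- lod[below] / 2
    } else {
      exclusions <- rbind(exclusions, data.frame(
        home_id = conc$home_id[below], voc = conc$voc[below],
        value = conc$indoor[below], reason = "below_lod_dropped"))
      conc <- conc[!below, ]
    }
  }
  if (any(conc$indoor <= 0 & conc$voc %in% config$outlier_scope))
    stop("zero/negative indoor concentrations in the outlier-treatment ",
         "scope: use lod_policy 'drop' or 'half-lod'", call. = FALSE)

  ## 3. outlier treatment (indoor aromatics, one-sided high)
  ot <- treat_outliers_by_voc(conc, scope = config$outlier_scope,
                              threshold = config$outlier_threshold)
  if (nrow(ot$removed))
    exclusions <- rbind(exclusions, data.frame(
      home_id = ot$removed$home_id, voc = ot$removed$voc,
      value = ot$removed$indoor, reason = "modified_z_outlier"))
  treated <- ot$treated

  ## 4. TVOC (raw quantified concentrations, per home)
  tv <- stats::aggregate(conc$indoor, by = list(home_id = conc$home_id),
                         FUN = sum)
  names(tv)[2] <- "tvoc"
  tv$season <- homes$season[match(tv$home_id, homes$home_id)]

  ## 5. emission rates (treated concentrations) and aggregates
  emis <- emission_table(treated, acr_tab)
  total_emis <- class_total(emis, unique(emis$voc))
  names(total_emis)[2] <- "total_q"
  mono_emis <- class_total(emis, config$classes$monoterpenes)
  names(mono_emis)[2] <- "monoterpene_q"
  norm <- tryCatch(normalize_emissions(emis), error = function(e) {
    warning("normalisation skipped: ", conditionMessage(e), call. = FALSE)
    NULL
  })
  if (!is.null(norm)) {
    norm_total <- class_total(norm, unique(norm$voc), value = "x_hat")
    names(norm_total)[2] <- "normalized_total"
    norm_mono <- class_total(norm, config$classes$monoterpenes,
                             value = "x_hat")
    names(norm_mono)[2] <- "normalized_monoterpene"
  } else {
    norm_total <- norm_mono <- NULL
  }
  season_of <- function(id) homes$season[match(id, homes$home_id)]
  total_emis$season <- season_of(total_emis$home_id)
  mono_emis$season <- season_of(mono_emis$home_id)
  if (!is.null(norm_total)) {
    norm_total$season <- season_of(norm_total$home_id)
    norm_mono$season <- season_of(norm_mono$home_id)
  }

  ## 6. risk benchmarks (raw indoor concentrations)
  in_risk <- conc$voc %in% config$risk_table$voc
  skipped_risk <- unique(conc$voc[!in_risk])
  if (length(skipped_risk))
    warning("VOC(s) without risk benchmarks excluded from LCR/HQ: ",
            paste(skipped_risk, collapse = ", "), call. = FALSE)
  rc <- conc[in_risk, ]
  lcr <- lifetime_cancer_risk(rc$indoor, rc$voc, config$risk_table,
                              config$ef, home_id = rc$home_id)
  hq <- hazard_quotient(rc$indoor, rc$voc, config$risk_table,
                        config$ef, home_id = rc$home_id)
  exceed <- exceedance_summary(lcr[lcr$assessable, ], hq[hq$assessable, ])

  ## 7. statistics
  tests <- list()
  n_hom <- nrow(homes)
  if (n_hom >= 2L) {
    acr_groups <- split(acr_tab$acr, acr_tab$season)
    acr_groups <- acr_groups[vapply(acr_groups, length, 1L) > 0L]
    if (can_test(acr_groups) && length(acr_groups) > 2L) {
      tests$acr_season <- list(omnibus = kruskal_wallis(acr_groups),
                               pairwise = dunn_posthoc(acr_groups))
    } else if (can_test(acr_groups)) {
      tests$acr_season <- compare_groups(acr_tab, "acr", "season",
                                         alpha = config$alpha)
    }
    ## urban vs rural indoor aromatics (treated), Holm across VOCs
    arom <- treated[treated$voc %in% config$outlier_scope, ]
    arom$urban <- homes$urban[match(arom$home_id, homes$home_id)]
    ur <- list()
    for (v in unique(arom$voc)) {
      gv <- split(arom$indoor[arom$voc == v], arom$urban[arom$voc == v])
      if (can_test(gv) && length(gv) == 2L) {
        bm <- brunner_munzel(gv[["FALSE"]], gv[["TRUE"]],
                             alpha = config$alpha)
        ur[[v]] <- data.frame(voc = v, statistic = bm$statistic,
                              effect = bm$effect, p_raw = bm$p_raw,
                              median_rural = stats::median(gv[["FALSE"]]),
                              median_urban = stats::median(gv[["TRUE"]]))
      }
    }
    if (length(ur)) {
      ur <- do.call(rbind, ur)
      ur$p_adjusted <- holm_adjust(ur$p_raw)
      rownames(ur) <- NULL
      tests$urban_rural_aromatics <- ur
    }
    for (nm in c("tvoc", "total_emission", "normalized_total",
                 "normalized_monoterpene")) {
      df <- switch(nm, tvoc = tv, total_emission = total_emis,
                   normalized_total = norm_total,
                   normalized_monoterpene = norm_mono)
      if (is.null(df)) next
      col <- switch(nm, tvoc = "tvoc", total_emission = "total_q",
                    normalized_total = "normalized_total",
                    normalized_monoterpene = "normalized_monoterpene")
      gv <- split(df[[col]], df$season)
      gv <- gv[vapply(gv, length, 1L) > 0L]
      if (can_test(gv))
        tests[[paste0(nm, "_season")]] <-
          if (length(gv) == 2L)
            list(omnibus = brunner_munzel(gv[[1L]], gv[[2L]]),
                 pairwise = NULL)
          else list(omnibus = kruskal_wallis(gv),
                    pairwise = dunn_posthoc(gv))
    }
  } else {
    warning("fewer than 2 homes: group comparisons skipped", call. = FALSE)
  }

  acr_season <- if (n_hom >= 1L)
    summarise_acr_by_season(acr_tab, n_resamples = config$n_resamples,
                            seed = config$seed)

  report <- structure(list(
    homes = homes, acr = acr_tab, acr_by_season = acr_season,
    treated_concentrations = treated, exclusions = exclusions,
    tvoc = tv, emissions = emis, total_emission = total_emis,
    monoterpene_emission = mono_emis, normalized_total = norm_total,
    normalized_monoterpene = norm_mono,
    tvoc_by_season = if (n_hom) season_value_summary(tv$tvoc, tv$season),
    emission_by_season = if (n_hom)
      season_value_summary(total_emis$total_q, total_emis$season),
    monoterpene_by_season = if (n_hom)
      season_value_summary(mono_emis$monoterpene_q, mono_emis$season),
    lcr = lcr, hq = hq, exceedance = exceed, tests = tests,
    config = config), class = "ivoc_report")

  if (!is.null(config$out_dir)) write_report_tables(report, config$out_dir)
  report
}

write_report_tables <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("acr", "acr_by_season", "treated_concentrations", "exclusions",
            "tvoc", "emissions", "total_emission", "monoterpene_emission",
            "normalized_total", "normalized_monoterpene",
            "tvoc_by_season", "emission_by_season",
            "monoterpene_by_season", "lcr", "hq", "exceedance")
  for (t in tabs)
    if (is.data.frame(report[[t]]))
      utils::write.csv(report[[t]], file.path(dir, paste0(t, ".csv")),
                       row.names = FALSE)
  if (!is.null(report$tests$urban_rural_aromatics))
    utils::write.csv(report$tests$urban_rural_aromatics,
                     file.path(dir, "urban_rural_aromatics.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @export
print.ivoc_report <- function(x, ...) {
  cat(sprintf("Indoor VOC exposure report: %d homes, %d VOCs\n",
              nrow(x$homes), length(unique(x$emissions$voc))))
  if (!is.null(x$acr_by_season)) {
    cat("Seasonal median ACR (h^-1):\n")
    print(x$acr_by_season[, c("season", "n", "median", "mean",
                              "ci_lower", "ci_upper")],
          row.names = FALSE, digits = 3)
  }
  if (!is.null(x$tvoc))
    cat(sprintf("TVOC median: %.0f ug m^-3\n", stats::median(x$tvoc$tvoc)))
  if (!is.null(x$emission_by_season)) {
    cat("Seasonal median total emission rate (ug h^-1):\n")
    print(x$emission_by_season[, c("season", "n", "median")],
          row.names = FALSE, digits = 4)
  }
  if (nrow(x$exclusions))
    cat(sprintf("%d record(s) excluded (see $exclusions)\n",
                nrow(x$exclusions)))
  invisible(x)
}

#' @export
summary.ivoc_report <- function(object, ...) {
  print(object)
  if (!is.null(object$tests$acr_season)) {
    cat("\nACR across seasons:\n")
    print(object$tests$acr_season$omnibus)
  }
  if (!is.null(object$tests$urban_rural_aromatics)) {
    cat("\nUrban vs rural treated indoor aromatics (Brunner-Munzel, Holm-adjusted):\n")
    print(object$tests$urban_rural_aromatics, row.names = FALSE, digits = 3)
  }
  if (!is.null(object$exceedance)) {
    cat("\nRisk threshold exceedance fractions:\n")
    print(object$exceedance, row.names = FALSE, digits = 3)
  }
  invisible(object)
}
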