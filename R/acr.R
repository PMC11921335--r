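#' Constants of the occupancy CO2 mass balance
#'
#' Bundles the assumed constants of the steady-state CO2 mass balance used
#' to infer air change rates (ACR): per-occupant CO2 generation rates, the
#' outdoor CO2 mixing ratio, and the fraction of gross room volume occupied
#' by furnishings.
#'
#' @param g_adult CO2 generation rate per adult, L min^-1.
#' @param g_child CO2 generation rate per child, L min^-1.
#' @param co2_outdoor Outdoor (external) CO2 mixing ratio, ppm.
#' @param furnishing_fraction Fraction of gross room volume occupied by
#'   internal furnishings; the diluent volume is `volume_raw * (1 -
#'   furnishing_fraction)`. Must lie in `[0, 1)`.
#'
#' @return An object of class `acr_params`.
#' @examples
#' acr_params()
#' acr_params(co2_outdoor = 420)
#' @export
acr_params <- function(g_adult = 0.312, g_child = 0.174,
                       co2_outdoor = 450, furnishing_fraction = 0.07) {
  stopifnot(is.numeric(g_adult), length(g_adult) == 1L,
            is.numeric(g_child), length(g_child) == 1L,
            is.numeric(co2_outdoor), length(co2_outdoor) == 1L,
            is.numeric(furnishing_fraction), length(furnishing_fraction) == 1L)
  if (g_adult <= 0) stop("'g_adult' must be > 0", call. = FALSE)
  if (g_child <= 0) stop("'g_child' must be > 0", call. = FALSE)
  if (co2_outdoor <= 0) stop("'co2_outdoor' must be > 0", call. = FALSE)
  if (furnishing_fraction < 0 || furnishing_fraction >= 1)
    stop("'furnishing_fraction' must be in [0, 1)", call. = FALSE)
  structure(list(g_adult = g_adult, g_child = g_child,
                 co2_outdoor = co2_outdoor,
                 furnishing_fraction = furnishing_fraction),
            class = "acr_params")
}

#' @export
print.acr_params <- function(x, ...) {
  cat("CO2 mass-balance parameters\n",
      sprintf("  generation: adult %.3f, child %.3f L min^-1\n",
              x$g_adult, x$g_child),
      sprintf("  outdoor CO2: %g ppm; furnishing fraction: %g\n",
              x$co2_outdoor, x$furnishing_fraction), sep = "")
  invisible(x)
}

#' Furnishing-adjusted (diluent) room volume
#'
#' Reduces the gross measured room volume by the furnishing fraction so the
#' volume term of the mass balance represents available diluent air.
#'
#' @param volume_raw Gross room volume, m^3 (vectorised).
#' @param params An [acr_params()] object.
#' @return Adjusted volume, m^3.
#' @examples
#' adjusted_volume(100) # 93 with the default 7 % reduction
#' @export
adjusted_volume <- function(volume_raw, params = acr_params()) {
  stopifnot(inherits(params, "acr_params"), is.numeric(volume_raw))
  if (any(!is.finite(volume_raw)) || any(volume_raw <= 0))
    stop("'volume_raw' must be finite and > 0", call. = FALSE)
  volume_raw * (1 - params$furnishing_fraction)
}

# Occupancy-adjusted CO2 source strength, m^3 h^-1.
# L min^-1 -> m^3 h^-1 is *60/1000 = *0.06 (dimensional analysis).
co2_generation_total <- function(n_adults, n_children, occupancy_fraction,
                                 params = acr_params()) {
  (n_adults * params$g_adult + n_children * params$g_child) *
    occupancy_fraction * 0.06
}

#' Infer air change rate from indoor CO2
#'
#' Steady-state single-zone CO2 mass balance: occupants generate CO2 at a
#' known occupancy-weighted rate, and ventilation dilutes it against the
#' outdoor mixing ratio, so
#' \deqn{ACR = \frac{(n_A G_{p,A} + n_C G_{p,C})\,f_{occ} \times 0.06}
#'   {V_{adj}\,(C_{in} - C_{ex}) \times 10^{-6}}}
#' with generation rates in L min^-1 (converted to m^3 h^-1), volumes in
#' m^3 and mixing ratios in ppm (converted to volume fraction), giving ACR
#' in h^-1.
#'
#' Accepts either a data frame of homes (columns `volume_raw`, `n_adults`,
#' `n_children`, `occupancy_fraction`, `co2_indoor`) or the individual
#' vectors. Indoor CO2 at or below the outdoor level, or zero occupants,
#' are rejected: the steady-state model is undefined there, and clamping
#' would silently hide bad data.
#'
#' @param homes Optional data frame of homes with the columns above;
#'   additional columns (e.g. `home_id`, `season`) are carried through.
#' @param volume_raw,n_adults,n_children,occupancy_fraction,co2_indoor
#'   Per-home inputs, used when `homes` is not supplied.
#' @param params An [acr_params()] object.
#'
#' @return A data frame with one row per home: `acr` (h^-1), the
#'   audit columns `volume_adjusted` (m^3), `co2_excess` (ppm) and
#'   `generation_total` (m^3 h^-1), plus any carried-through columns.
#' @examples
#' infer_acr(volume_raw = 53.7634, n_adults = 2, n_children = 0,
#'           occupancy_fraction = 1, co2_indoor = 1000)
#' @export
infer_acr <- function(homes = NULL, volume_raw = NULL, n_adults = NULL,
                      n_children = NULL, occupancy_fraction = NULL,
                      co2_indoor = NULL, params = acr_params()) {
  stopifnot(inherits(params, "acr_params"))
  if (!is.null(homes)) {
    need <- c("volume_raw", "n_adults", "n_children",
              "occupancy_fraction", "co2_indoor")
    missing_cols <- setdiff(need, names(homes))
    if (length(missing_cols))
      stop("'homes' is missing required columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    volume_raw <- homes$volume_raw
    n_adults <- homes$n_adults
    n_children <- homes$n_children
    occupancy_fraction <- homes$occupancy_fraction
    co2_indoor <- homes$co2_indoor
  }
  if (any(volume_raw <= 0)) stop("'volume_raw' must be > 0", call. = FALSE)
  if (any(n_adults < 0) || any(n_children < 0) ||
      any(n_adults + n_children < 1))
    stop("at least one occupant is required: ACR is undefined by this method for unoccupied rooms",
         call. = FALSE)
  if (any(occupancy_fraction <= 0) || any(occupancy_fraction > 1))
    stop("'occupancy_fraction' must be in (0, 1]", call. = FALSE)
  excess <- co2_indoor - params$co2_outdoor
  if (any(excess <= 0))
    stop("indoor CO2 must exceed the assumed outdoor level (",
         params$co2_outdoor, " ppm); non-positive excess is non-physical ",
         "for the steady-state occupancy model", call. = FALSE)

  vol_adj <- adjusted_volume(volume_raw, params)
  gen <- co2_generation_total(n_adults, n_children, occupancy_fraction, params)
  acr <- gen / (vol_adj * excess * 1e-6)

  out <- data.frame(acr = acr, volume_adjusted = vol_adj,
                    co2_excess = excess, generation_total = gen)
  if (!is.null(homes)) {
    carry <- setdiff(names(homes), names(out))
    out <- cbind(homes[carry], out)
  }
  out
}

#' Indoor CO2 implied by a known air change rate
#'
#' Algebraic inverse of [infer_acr()]: given a true ACR and the same
#' occupancy and volume terms, returns the steady-state indoor CO2 mixing
#' ratio (ppm). Used by the synthetic cohort generator so that ACR
#' recovery is an exact round trip.
#'
#' @inheritParams infer_acr
#' @param acr Air change rate, h^-1 (> 0).
#' @return Indoor CO2 mixing ratio, ppm.
#' @export
co2_from_acr <- function(acr, volume_raw, n_adults, n_children,
                         occupancy_fraction, params = acr_params()) {
  if (any(acr <= 0)) stop("'acr' must be > 0", call. = FALSE)
  vol_adj <- adjusted_volume(volume_raw, params)
  gen <- co2_generation_total(n_adults, n_children, occupancy_fraction, params)
  params$co2_outdoor + gen / (acr * vol_adj) * 1e6
}

#' Seasonal summary of inferred air change rates
#'
#' Summarises ACR by season with the study's boxplot percentiles and a
#' bootstrap percentile confidence interval for the seasonal mean.
#'
#' @param acr_table Data frame with columns `season` and `acr`.
#' @param n_resamples Bootstrap resamples for the CI of the mean.
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level.
#' @return A data frame with one row per season: `n`, `mean`, `median`,
#'   `p5`, `p25`, `p75`, `p95`, `ci_lower`, `ci_upper`.
#' @export
summarise_acr_by_season <- function(acr_table, n_resamples = 1000,
                                    seed = 1L, conf = 0.95) {
  stopifnot(is.data.frame(acr_table),
            all(c("season", "acr") %in% names(acr_table)))
  if (nrow(acr_table) == 0L) stop("empty ACR table", call. = FALSE)
  seasons <- intersect(c("winter", "spring", "summer", "autumn"),
                       unique(as.character(acr_table$season)))
  rows <- lapply(seq_along(seasons), function(i) {
    s <- seasons[i]
    v <- acr_table$acr[acr_table$season == s]
    q <- boxplot_summary(v)$percentiles
    ci <- bootstrap_ci(v, statistic = mean, n_resamples = n_resamples,
                       seed = seed + i, conf = conf)
    data.frame(season = s, n = length(v), mean = mean(v),
               median = unname(q["p50"]), p5 = unname(q["p5"]),
               p25 = unname(q["p25"]), p75 = unname(q["p75"]),
               p95 = unname(q["p95"]),
               ci_lower = ci$lower, ci_upper = ci$upper)
  })
  do.call(rbind, rows)
}
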