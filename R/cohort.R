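#' Season of a sample start date
#'
#' Meteorological month-based mapping: winter is December--February,
#' spring March--May, summer June--August, autumn September--November.
#' For multi-day time-integrated samples the start date decides the season.
#'
#' @param date A `Date` vector (or anything `as.Date()` accepts).
#' @return Character vector of `"winter"`, `"spring"`, `"summer"`,
#'   `"autumn"`.
#' @examples
#' assign_season(as.Date(c("2023-06-15", "2023-12-01")))
#' @export
assign_season <- function(date) {
  date <- tryCatch(as.Date(date), error = function(e)
    stop("invalid date: ", conditionMessage(e), call. = FALSE))
  if (any(is.na(date))) stop("invalid date", call. = FALSE)
  m <- as.integer(format(date, "%m"))
  c("winter", "winter", "spring", "spring", "spring",
    "summer", "summer", "summer", "autumn", "autumn",
    "autumn", "winter")[m]
}

#' Default VOC panel for the synthetic cohort
#'
#' A realistic home-air panel: the high-abundance oxygenates and aerosol
#' propellants that dominate total VOC mass, the traffic/paint aromatics
#' (BTEX and trimethylbenzenes), fragrance monoterpenes, and the
#' toxicologically notable species carried by the bundled risk table.
#' `indoor_median`/`indoor_gsd` parameterise the log-normal *indoor-source*
#' term (the concentration increment above outdoor ingress, ug m^-3);
#' `outdoor_median`/`outdoor_gsd` parameterise outdoor concentrations.
#'
#' @return Data frame with columns `voc`, `class`, `indoor_median`,
#'   `indoor_gsd`, `outdoor_median`, `outdoor_gsd`.
#' @export
default_voc_panel <- function() {
  p <- read.csv(system.file("extdata", "voc_panel.csv", package = "ivoc"),
                stringsAsFactors = FALSE)
  p
}

#' VOC class membership
#'
#' Editable class definitions (BTEX, trimethylbenzenes, monoterpenes) used
#' for class totals, the outlier-treatment scope and the urban aromatic
#' shift. `aromatics` is the union of `btex` and `tmb`.
#'
#' @param path Optional YAML file with named lists of VOC names; defaults
#'   to the bundled configuration.
#' @return Named list of character vectors.
#' @export
voc_classes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "voc_classes.yaml", package = "ivoc")
  cls <- yaml::read_yaml(path)
  cls <- lapply(cls, as.character)
  if (!("aromatics" %in% names(cls)))
    cls$aromatics <- unique(c(cls$btex, cls$tmb))
  cls
}

default_occupancy_dist <- function() {
  g <- expand.grid(n_adults = 1:2, n_children = 0:3)
  g$prob <- 1 / nrow(g)
  g
}

default_seasonal_acr <- function() {
  data.frame(season = c("winter", "spring", "summer", "autumn"),
             median = c(0.70, 1.10, 1.20, 0.85),
             gsd = c(1.45, 1.45, 1.45, 1.45))
}

#' Specification of a synthetic home cohort
#'
#' Collects every knob of the synthetic generator: cohort size, the VOC
#' panel with per-VOC log-normal parameters, seasonal air-change-rate
#' structure, the urban/rural split and outdoor aromatic shift, episodic
#' painting-style indoor aromatic spikes, room volumes and occupancy.
#'
#' @param n_homes Number of homes (>= 0).
#' @param seed Integer seed; the same spec and seed reproduce the cohort
#'   bit-for-bit.
#' @param voc_panel Data frame as in [default_voc_panel()].
#' @param seasonal_acr Data frame with columns `season`, `median` (h^-1)
#'   and `gsd`, one row per season.
#' @param urban_fraction Proportion of urban homes in `[0, 1]`.
#' @param urban_aromatic_multiplier Factor (>= 1) applied to outdoor
#'   BTEX/TMB medians in urban homes.
#' @param spike_prob Probability in `[0, 1]` that a home has an episodic
#'   painting-style aromatic spike.
#' @param spike_multiplier Factor (>= 1) applied to the indoor-source
#'   aromatic term of spiked homes.
#' @param volume_range Length-2 numeric, min/max gross room volume m^3.
#' @param occupancy_dist Data frame `n_adults`, `n_children`, `prob`
#'   giving the occupancy distribution; at least one occupant per row.
#' @param occupancy_fraction_range Length-2 numeric in (0, 1], min/max
#'   fraction of the sampling period spent in the sampled room.
#' @param co2_noise_gsd Geometric SD of optional multiplicative noise on
#'   the CO2 excess; 1 (the default) means none, so ACR recovery is exact.
#' @param date_range Length-2 `Date`, the sampling window.
#' @param acr_params An [acr_params()] object used to invert the CO2 mass
#'   balance when generating indoor CO2.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_homes = 124, seed = 1L,
                        voc_panel = default_voc_panel(),
                        seasonal_acr = default_seasonal_acr(),
                        urban_fraction = 0.6,
                        urban_aromatic_multiplier = 1.69 / 0.78,
                        spike_prob = 0.05, spike_multiplier = 50,
                        volume_range = c(30, 110),
                        occupancy_dist = default_occupancy_dist(),
                        occupancy_fraction_range = c(0.3, 0.8),
                        co2_noise_gsd = 1,
                        date_range = as.Date(c("2023-03-01", "2024-04-30")),
                        acr_params = ivoc::acr_params()) {
  spec <- structure(list(
    n_homes = as.integer(n_homes), seed = as.integer(seed),
    voc_panel = voc_panel, seasonal_acr = seasonal_acr,
    urban_fraction = urban_fraction,
    urban_aromatic_multiplier = urban_aromatic_multiplier,
    spike_prob = spike_prob, spike_multiplier = spike_multiplier,
    volume_range = as.numeric(volume_range),
    occupancy_dist = occupancy_dist,
    occupancy_fraction_range = as.numeric(occupancy_fraction_range),
    co2_noise_gsd = co2_noise_gsd,
    date_range = as.Date(date_range), acr_params = acr_params),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  fail <- function(field, why)
    stop(sprintf("invalid cohort spec: '%s' %s", field, why), call. = FALSE)
  if (is.na(spec$n_homes) || spec$n_homes < 0) fail("n_homes", "must be >= 0")
  if (is.na(spec$seed)) fail("seed", "must be an integer")
  vp <- spec$voc_panel
  need <- c("voc", "class", "indoor_median", "indoor_gsd",
            "outdoor_median", "outdoor_gsd")
  if (!is.data.frame(vp) || nrow(vp) == 0L)
    fail("voc_panel", "must be a non-empty data frame")
  if (!all(need %in% names(vp)))
    fail("voc_panel", paste("must have columns", paste(need, collapse = ", ")))
  if (any(vp$indoor_median <= 0) || any(vp$outdoor_median <= 0))
    fail("voc_panel", "medians must be strictly positive")
  if (any(vp$indoor_gsd < 1) || any(vp$outdoor_gsd < 1))
    fail("voc_panel", "geometric SDs must be >= 1")
  sa <- spec$seasonal_acr
  if (!is.data.frame(sa) ||
      !all(c("winter", "spring", "summer", "autumn") %in% sa$season))
    fail("seasonal_acr", "must have rows for all four seasons")
  if (any(sa$median <= 0)) fail("seasonal_acr", "medians must be > 0")
  for (f in c("urban_fraction", "spike_prob")) {
    v <- spec[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) fail(f, "must be in [0, 1]")
  }
  for (f in c("urban_aromatic_multiplier", "spike_multiplier"))
    if (spec[[f]] < 1) fail(f, "must be >= 1")
  vr <- spec$volume_range
  if (length(vr) != 2L || any(vr <= 0) || vr[1] > vr[2])
    fail("volume_range", "must be positive min <= max")
  od <- spec$occupancy_dist
  if (!is.data.frame(od) ||
      !all(c("n_adults", "n_children", "prob") %in% names(od)) ||
      any(od$prob < 0) || sum(od$prob) <= 0)
    fail("occupancy_dist", "must be a data frame of n_adults, n_children, prob")
  if (any(od$n_adults + od$n_children < 1))
    fail("occupancy_dist", "every occupancy state needs >= 1 occupant")
  fr <- spec$occupancy_fraction_range
  if (length(fr) != 2L || any(fr <= 0) || any(fr > 1) || fr[1] > fr[2])
    fail("occupancy_fraction_range", "must be within (0, 1], min <= max")
  if (spec$co2_noise_gsd < 1) fail("co2_noise_gsd", "must be >= 1")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d homes, seed %d, %d VOCs\n",
              x$n_homes, x$seed, nrow(x$voc_panel)),
      sprintf("  urban fraction %.2f (outdoor aromatic multiplier %.2f)\n",
              x$urban_fraction, x$urban_aromatic_multiplier),
      sprintf("  spike prob %.2f (x%.0f on indoor aromatics)\n",
              x$spike_prob, x$spike_multiplier), sep = "")
  invisible(x)
}

# Draw from a log-normal given median and geometric SD.
rlnorm_med <- function(n, median, gsd) {
  stats::rlnorm(n, meanlog = log(median), sdlog = log(gsd))
}

#' Generate a synthetic home cohort
#'
#' Draws a cohort of homes with log-normally distributed VOC
#' concentrations, seasonal air-change-rate structure, an urban/rural
#' outdoor aromatic shift, and rare painting-style indoor aromatic spikes.
#' Indoor concentrations are built mechanistically as outdoor ingress plus
#' a log-normal indoor-source increment, and indoor CO2 is obtained by
#' inverting the occupancy mass balance from each home's drawn true ACR,
#' so [infer_acr()] recovers the stored `true_acr` exactly (when
#' `co2_noise_gsd = 1`).
#'
#' @param spec A [cohort_spec()].
#' @param classes VOC class definitions, as from [voc_classes()]; the
#'   `aromatics` entry defines which species receive the urban shift and
#'   spikes.
#' @return An object of class `voc_cohort`: a list with `homes` (one row
#'   per home: identifiers, date/season, urban and spike flags, volume,
#'   occupancy, indoor CO2 and the generator-only `true_acr`) and
#'   `concentrations` (one row per home x VOC: `indoor`, `outdoor`,
#'   ug m^-3).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_homes = 5, seed = 42))
#' coh$homes[, c("home_id", "season", "urban", "co2_indoor")]
#' @export
generate_cohort <- function(spec, classes = voc_classes()) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  n <- spec$n_homes
  empty_homes <- data.frame(
    home_id = character(), sample_date = as.Date(character()),
    season = character(), urban = logical(), spike = logical(),
    volume_raw = numeric(), n_adults = integer(), n_children = integer(),
    occupancy_fraction = numeric(), co2_indoor = numeric(),
    true_acr = numeric())
  if (n == 0L)
    return(structure(list(homes = empty_homes,
                          concentrations = data.frame(
                            home_id = character(), voc = character(),
                            class = character(), indoor = numeric(),
                            outdoor = numeric()),
                          spec = spec),
                     class = "voc_cohort"))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(spec$seed)

  home_id <- sprintf("H%03d", seq_len(n))
  dates <- seq(spec$date_range[1], spec$date_range[2], by = "day")
  sample_date <- sample(dates, n, replace = TRUE)
  season <- assign_season(sample_date)
  urban <- stats::runif(n) < spec$urban_fraction
  spike <- stats::runif(n) < spec$spike_prob
  volume_raw <- stats::runif(n, spec$volume_range[1], spec$volume_range[2])
  occ_idx <- sample.int(nrow(spec$occupancy_dist), n, replace = TRUE,
                        prob = spec$occupancy_dist$prob)
  n_adults <- as.integer(spec$occupancy_dist$n_adults[occ_idx])
  n_children <- as.integer(spec$occupancy_dist$n_children[occ_idx])
  occupancy_fraction <- stats::runif(n, spec$occupancy_fraction_range[1],
                                     spec$occupancy_fraction_range[2])

  sa <- spec$seasonal_acr
  med <- sa$median[match(season, sa$season)]
  gsd <- sa$gsd[match(season, sa$season)]
  true_acr <- rlnorm_med(n, med, gsd)

  co2_excess <- co2_from_acr(true_acr, volume_raw, n_adults, n_children,
                             occupancy_fraction, spec$acr_params) -
    spec$acr_params$co2_outdoor
  if (spec$co2_noise_gsd > 1)
    co2_excess <- co2_excess * rlnorm_med(n, 1, spec$co2_noise_gsd)
  co2_indoor <- spec$acr_params$co2_outdoor + co2_excess

  homes <- data.frame(home_id = home_id, sample_date = sample_date,
                      season = season, urban = urban, spike = spike,
                      volume_raw = volume_raw, n_adults = n_adults,
                      n_children = n_children,
                      occupancy_fraction = occupancy_fraction,
                      co2_indoor = co2_indoor, true_acr = true_acr)

  vp <- spec$voc_panel
  aromatic <- vp$voc %in% classes$aromatics
  conc <- vector("list", nrow(vp))
  for (j in seq_len(nrow(vp))) {
    out_med <- rep(vp$outdoor_median[j], n)
    if (aromatic[j])
      out_med[urban] <- out_med[urban] * spec$urban_aromatic_multiplier
    outdoor <- rlnorm_med(n, out_med, vp$outdoor_gsd[j])
    src <- rlnorm_med(n, vp$indoor_median[j], vp$indoor_gsd[j])
    if (aromatic[j]) src[spike] <- src[spike] * spec$spike_multiplier
    conc[[j]] <- data.frame(home_id = home_id, voc = vp$voc[j],
                            class = vp$class[j], indoor = outdoor + src,
                            outdoor = outdoor)
  }
  concentrations <- do.call(rbind, conc)
  concentrations <- concentrations[order(concentrations$home_id,
                                         concentrations$voc), ]
  rownames(concentrations) <- NULL

  structure(list(homes = homes, concentrations = concentrations,
                 spec = spec), class = "voc_cohort")
}

#' @export
print.voc_cohort <- function(x, ...) {
  cat(sprintf("Synthetic home cohort: %d homes x %d VOCs (%d urban, %d spiked)\n",
              nrow(x$homes), length(unique(x$concentrations$voc)),
              sum(x$homes$urban), sum(x$homes$spike)))
  if (nrow(x$homes)) {
    tb <- table(x$homes$season)
    cat("  seasons:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a cohort spec from a YAML file
#'
#' Scalar fields map directly to [cohort_spec()] arguments; `voc_panel`,
#' `seasonal_acr` and `occupancy_dist` are lists of records, and
#' `acr_params` a mapping of [acr_params()] arguments. Missing fields take
#' the package defaults. A commented example ships at
#' `system.file("extdata", "cohort_spec_example.yaml", package = "ivoc")`.
#'
#' @param path Path to a YAML file.
#' @return A [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (f in c("n_homes", "seed", "urban_fraction",
              "urban_aromatic_multiplier", "spike_prob", "spike_multiplier",
              "volume_range", "occupancy_fraction_range", "co2_noise_gsd"))
    if (!is.null(y[[f]])) args[[f]] <- unlist(y[[f]])
  as_records <- function(x) do.call(rbind, lapply(x, as.data.frame))
  if (!is.null(y$voc_panel)) args$voc_panel <- as_records(y$voc_panel)
  if (!is.null(y$seasonal_acr)) args$seasonal_acr <- as_records(y$seasonal_acr)
  if (!is.null(y$occupancy_dist))
    args$occupancy_dist <- as_records(y$occupancy_dist)
  if (!is.null(y$date_range)) args$date_range <- as.Date(unlist(y$date_range))
  if (!is.null(y$acr_params))
    args$acr_params <- do.call(acr_params, y$acr_params)
  do.call(cohort_spec, args)
}

#' Write / read a cohort as tidy delimited tables
#'
#' `write_cohort()` writes `homes.csv` (one row per home) and
#' `concentrations.csv` (one row per home x VOC) under `dir`;
#' `read_cohort()` reads them back. Column names are stable and match the
#' fields documented in [generate_cohort()].
#'
#' @param cohort A `voc_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns a `voc_cohort` (without the generating spec).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "voc_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$homes, file.path(dir, "homes.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$concentrations,
                   file.path(dir, "concentrations.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  homes <- utils::read.csv(file.path(dir, "homes.csv"),
                           stringsAsFactors = FALSE)
  homes$sample_date <- as.Date(homes$sample_date)
  conc <- utils::read.csv(file.path(dir, "concentrations.csv"),
                          stringsAsFactors = FALSE)
  structure(list(homes = homes, concentrations = conc, spec = NULL),
            class = "voc_cohort")
}
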