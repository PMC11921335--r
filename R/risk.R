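#' Exposure factors for inhalation risk benchmarks
#'
#' Standard US EPA/ATSDR inhalation exposure factors used to convert a
#' measured concentration into an exposure concentration. The defaults
#' (16 h day^-1 at home, 365 d y^-1, 70-year exposure over a 70-year
#' averaging time) are a documented stand-in, fully overridable from
#' configuration.
#'
#' @param hours_at_home_per_day Exposure time ET, h day^-1 (0, 24].
#' @param days_per_year Exposure frequency EF, d y^-1 (0, 365].
#' @param exposure_duration_years Exposure duration ED, y.
#' @param averaging_time_years Averaging time AT, y; lifetime for cancer
#'   risk, and set equal to ED for hazard quotients. Must satisfy
#'   ED <= AT.
#' @return An object of class `exposure_factors`.
#' @export
exposure_factors <- function(hours_at_home_per_day = 16,
                             days_per_year = 365,
                             exposure_duration_years = 70,
                             averaging_time_years = 70) {
  if (hours_at_home_per_day <= 0 || hours_at_home_per_day > 24)
    stop("'hours_at_home_per_day' must be in (0, 24]", call. = FALSE)
  if (days_per_year <= 0 || days_per_year > 365)
    stop("'days_per_year' must be in (0, 365]", call. = FALSE)
  if (exposure_duration_years <= 0 || averaging_time_years <= 0)
    stop("durations must be > 0", call. = FALSE)
  if (exposure_duration_years > averaging_time_years)
    stop("'exposure_duration_years' must not exceed 'averaging_time_years'",
         call. = FALSE)
  structure(list(hours_at_home_per_day = hours_at_home_per_day,
                 days_per_year = days_per_year,
                 exposure_duration_years = exposure_duration_years,
                 averaging_time_years = averaging_time_years),
            class = "exposure_factors")
}

#' @export
print.exposure_factors <- function(x, ...) {
  cat(sprintf("Exposure factors: ET %g h/d, EF %g d/y, ED %g y, AT %g y\n",
              x$hours_at_home_per_day, x$days_per_year,
              x$exposure_duration_years, x$averaging_time_years))
  invisible(x)
}

#' Per-VOC toxicity benchmark table
#'
#' Reads a risk table of per-VOC inhalation unit risks (IUR, per
#' ug m^-3) and non-cancer reference concentrations (RfC, ug m^-3);
#' either may be absent for a given VOC. The bundled default carries
#' IRIS-published values with a provenance column; it is a convenience
#' default, not a hard-coded constant — pass your own file to override.
#'
#' @param path CSV with columns `voc`, `iur`, `rfc` (empty = absent) and
#'   optionally `provenance`; default the bundled table.
#' @return Data frame of class `risk_table`.
#' @export
read_risk_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "risk_table.csv", package = "ivoc")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("voc", "iur", "rfc") %in% names(tab)))
  if (any(tab$iur < 0, na.rm = TRUE))
    stop("IUR values must be >= 0", call. = FALSE)
  if (any(tab$rfc <= 0, na.rm = TRUE))
    stop("RfC values must be > 0", call. = FALSE)
  class(tab) <- c("risk_table", "data.frame")
  tab
}

#' Exposure concentration
#'
#' Time-adjusted concentration
#' \deqn{EC = C \times \frac{ET}{24} \times \frac{EF}{365} \times \frac{ED}{AT}}
#' so that continuous lifetime exposure (ET = 24, EF = 365, ED = AT)
#' returns the measured concentration unchanged.
#'
#' @param c Concentration, ug m^-3 (vectorised, >= 0).
#' @param ef An [exposure_factors()] object.
#' @return Exposure concentration, ug m^-3.
#' @export
exposure_concentration <- function(c, ef = exposure_factors()) {
  stopifnot(inherits(ef, "exposure_factors"))
  if (any(c < 0)) stop("concentrations must be >= 0", call. = FALSE)
  c * (ef$hours_at_home_per_day / 24) * (ef$days_per_year / 365) *
    (ef$exposure_duration_years / ef$averaging_time_years)
}

lookup_risk <- function(voc, table, col) {
  i <- match(voc, table$voc)
  ifelse(is.na(i), NA_real_, table[[col]][i])
}

#' Lifetime cancer risk from inhalation
#'
#' LCR = IUR x EC, where the inhalation unit risk is the upper-bound
#' excess lifetime cancer risk per 1 ug m^-3 of continuous lifetime
#' exposure. Homes are flagged when LCR strictly exceeds the 1-in-1e6
#' de-minimis threshold. A VOC without an IUR yields an explicit
#' not-assessable result (`NA` with `assessable = FALSE`), never a silent
#' zero.
#'
#' @param c Concentration(s), ug m^-3.
#' @param voc VOC name(s), recycled against `c`.
#' @param table A [read_risk_table()] table.
#' @param ef An [exposure_factors()] object (AT is the lifetime).
#' @param home_id Optional identifier column to carry through.
#' @return Data frame: `home_id` (if given), `voc`,
#'   `exposure_concentration`, `lcr`, `exceeds_lcr_1e6`, `assessable`.
#' @export
lifetime_cancer_risk <- function(c, voc, table = read_risk_table(),
                                 ef = exposure_factors(), home_id = NULL) {
  ec <- exposure_concentration(c, ef)
  iur <- lookup_risk(voc, table, "iur")
  lcr <- iur * ec
  out <- data.frame(voc = voc, exposure_concentration = ec, lcr = lcr,
                    exceeds_lcr_1e6 = !is.na(lcr) & lcr > 1e-6,
                    assessable = !is.na(iur))
  if (!is.null(home_id)) out <- cbind(home_id = home_id, out)
  out
}

#' Non-cancer hazard quotient
#'
#' HQ = EC / RfC with the averaging time set equal to the exposure
#' duration (the non-cancer convention), flagged when HQ strictly
#' exceeds 1. A VOC without an RfC yields an explicit not-assessable
#' result.
#'
#' @inheritParams lifetime_cancer_risk
#' @param ef An [exposure_factors()] object; its AT is replaced by ED
#'   internally, per the HQ convention.
#' @return Data frame: `home_id` (if given), `voc`,
#'   `exposure_concentration`, `hq`, `exceeds_hq_1`, `assessable`.
#' @export
hazard_quotient <- function(c, voc, table = read_risk_table(),
                            ef = exposure_factors(), home_id = NULL) {
  ef_hq <- exposure_factors(ef$hours_at_home_per_day, ef$days_per_year,
                            ef$exposure_duration_years,
                            ef$exposure_duration_years)
  ec <- exposure_concentration(c, ef_hq)
  rfc <- lookup_risk(voc, table, "rfc")
  hq <- ec / rfc
  out <- data.frame(voc = voc, exposure_concentration = ec, hq = hq,
                    exceeds_hq_1 = !is.na(hq) & hq > 1,
                    assessable = !is.na(rfc))
  if (!is.null(home_id)) out <- cbind(home_id = home_id, out)
  out
}

#' Per-VOC exceedance fractions
#'
#' Fraction of homes exceeding the LCR 1e-6 and/or HQ 1 thresholds, per
#' VOC, over assessable results only: a VOC lacking the relevant
#' benchmark never appears in that summary.
#'
#' @param lcr_results Result of [lifetime_cancer_risk()] (or `NULL`).
#' @param hq_results Result of [hazard_quotient()] (or `NULL`).
#' @return Data frame `voc`, `metric` (`"lcr"` or `"hq"`), `n`,
#'   `n_exceed`, `fraction_exceed`.
#' @export
exceedance_summary <- function(lcr_results = NULL, hq_results = NULL) {
  if (is.null(lcr_results) && is.null(hq_results))
    stop("no results supplied", call. = FALSE)
  one <- function(res, flag, metric) {
    res <- res[res$assessable, ]
    if (nrow(res) == 0L) return(NULL)
    agg <- stats::aggregate(res[[flag]], by = list(voc = res$voc),
                            FUN = function(z) c(n = length(z), k = sum(z)))
    data.frame(voc = agg$voc, metric = metric, n = agg$x[, "n"],
               n_exceed = agg$x[, "k"],
               fraction_exceed = agg$x[, "k"] / agg$x[, "n"])
  }
  out <- rbind(
    if (!is.null(lcr_results)) one(lcr_results, "exceeds_lcr_1e6", "lcr"),
    if (!is.null(hq_results)) one(hq_results, "exceeds_hq_1", "hq"))
  rownames(out) <- NULL
  out
}
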