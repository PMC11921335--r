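#' Time-averaged VOC emission rate
#'
#' Steady-state single-zone balance in which ventilation is the only
#' removal process: the whole-period source strength implied by an
#' indoor/outdoor concentration difference is
#' \deqn{q = ACR \times V_{adj} \times (C_{in} - C_{out})}
#' in ug h^-1. Negative values (outdoor exceeding indoor, i.e. net
#' ingress/sink) are retained, not clamped: they carry meaning and are
#' flagged downstream. Set `floor_zero = TRUE` to clamp at zero for
#' replication studies.
#'
#' @param c_in,c_out Indoor and outdoor concentrations, ug m^-3
#'   (vectorised).
#' @param acr Air change rate, h^-1 (> 0).
#' @param volume_adjusted Furnishing-adjusted room volume, m^3 (> 0).
#' @param floor_zero Clamp negative rates at zero? Default `FALSE`.
#' @return Emission rate(s), ug h^-1.
#' @examples
#' emission_rate(c_in = 12, c_out = 2, acr = 1.3615, volume_adjusted = 50)
#' @export
emission_rate <- function(c_in, c_out, acr, volume_adjusted,
                          floor_zero = FALSE) {
  if (any(acr <= 0)) stop("'acr' must be > 0", call. = FALSE)
  if (any(volume_adjusted <= 0))
    stop("'volume_adjusted' must be > 0", call. = FALSE)
  if (any(c_in < 0) || any(c_out < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  q <- acr * volume_adjusted * (c_in - c_out)
  if (floor_zero) q <- pmax(q, 0)
  q
}

#' Total VOC (TVOC) concentration of a sample
#'
#' Operational total-VOC metric: the arithmetic sum of all quantified VOC
#' concentrations in the sample. Species absent from the map simply
#' contribute nothing, so the metric depends on what was quantified.
#'
#' @param sample_concentrations Named numeric vector (or list) of
#'   concentrations, ug m^-3.
#' @return TVOC, ug m^-3.
#' @examples
#' tvoc(c(ethanol = 320, limonene = 15, benzene = 0.7))
#' @export
tvoc <- function(sample_concentrations) {
  x <- unlist(sample_concentrations)
  if (length(x) == 0L) stop("empty concentration map", call. = FALSE)
  if (any(x < 0)) stop("concentrations must be >= 0", call. = FALSE)
  sum(x)
}

#' Per-home emission table
#'
#' Joins a tidy concentration table with per-home ACR results and applies
#' [emission_rate()] per home x VOC. Records with a missing outdoor
#' concentration are skipped with a warning rather than assuming zero
#' outdoor ingress.
#'
#' @param conc Data frame `home_id`, `voc`, `indoor`, `outdoor`.
#' @param acr_table Data frame with `home_id`, `acr`, `volume_adjusted`
#'   (as from [infer_acr()]).
#' @param floor_zero Passed to [emission_rate()].
#' @return Data frame `home_id`, `voc`, `q` (ug h^-1), the inputs
#'   `c_in`, `c_out`, `acr`, `volume_adjusted`, and a logical
#'   `net_ingress` flag marking negative rates.
#' @export
emission_table <- function(conc, acr_table, floor_zero = FALSE) {
  stopifnot(all(c("home_id", "voc", "indoor", "outdoor") %in% names(conc)),
            all(c("home_id", "acr", "volume_adjusted") %in% names(acr_table)))
  i <- match(conc$home_id, acr_table$home_id)
  keep <- !is.na(i) & !is.na(conc$outdoor) & !is.na(conc$indoor)
  if (any(is.na(conc$outdoor)))
    warning(sum(is.na(conc$outdoor)),
            " record(s) skipped: missing outdoor concentration")
  conc <- conc[keep, ]
  i <- i[keep]
  q <- emission_rate(conc$indoor, conc$outdoor, acr_table$acr[i],
                     acr_table$volume_adjusted[i], floor_zero = floor_zero)
  data.frame(home_id = conc$home_id, voc = conc$voc, q = q,
             c_in = conc$indoor, c_out = conc$outdoor,
             acr = acr_table$acr[i],
             volume_adjusted = acr_table$volume_adjusted[i],
             net_ingress = q < 0)
}

#' Per-home class total of emission rates
#'
#' Sums emission rates (or any per-home x VOC value column) over a VOC
#' class (e.g. monoterpenes); homes lacking all member species get 0.
#'
#' @param records Data frame with `home_id`, `voc` and the value column.
#' @param members Character vector of VOC names in the class.
#' @param value Name of the value column (default `"q"`).
#' @return Data frame `home_id`, `total`.
#' @export
class_total <- function(records, members, value = "q") {
  stopifnot(is.data.frame(records),
            all(c("home_id", "voc", value) %in% names(records)))
  if (length(members) == 0L) stop("'members' must be non-empty", call. = FALSE)
  homes <- unique(records$home_id)
  sub <- records[records$voc %in% members, ]
  agg <- if (nrow(sub)) stats::aggregate(sub[[value]],
                                         by = list(home_id = sub$home_id),
                                         FUN = sum)
  else data.frame(home_id = character(), x = numeric())
  total <- agg$x[match(homes, agg$home_id)]
  total[is.na(total)] <- 0
  data.frame(home_id = homes, total = total)
}

#' Min-max normalised emission rates
#'
#' Rescales each VOC's emission rates across homes to `[0, 1]`:
#' \deqn{\hat X_a = (X_a - X_{a,min}) / (X_{a,max} - X_{a,min})}
#' so that single dominant emitters (ethanol, propane, butane) cannot
#' swamp summed cross-VOC comparisons. A VOC whose rates are constant
#' across homes has no scale and is rejected by name.
#'
#' @param records Data frame `home_id`, `voc`, `q`.
#' @return Data frame `home_id`, `voc`, `x_hat` in `[0, 1]`.
#' @export
normalize_emissions <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("home_id", "voc", "q") %in% names(records)))
  out <- records[c("home_id", "voc")]
  out$x_hat <- NA_real_
  for (v in unique(records$voc)) {
    idx <- records$voc == v
    q <- records$q[idx]
    if (length(q) < 2L || max(q) == min(q))
      stop("cannot normalise '", v,
           "': constant emission-rate series (max = min)", call. = FALSE)
    out$x_hat[idx] <- (q - min(q)) / (max(q) - min(q))
  }
  out
}

#' Sensitivity grid for an emission rate
#'
#' Recomputes q over a grid of fractional perturbations of ACR and
#' volume. Because q is multiplicative in both, the grid is exactly
#' `q * (1 + delta_acr) * (1 + delta_vol)`; the function recomputes it
#' from the perturbed inputs so the structure is auditable.
#'
#' @param c_in,c_out,acr,volume_adjusted As in [emission_rate()]
#'   (scalars).
#' @param acr_perturbations,volume_perturbations Fractional perturbations
#'   (each > -1), e.g. `c(-0.1, 0, 0.1)`.
#' @return Matrix of q values, rows indexed by ACR perturbation, columns
#'   by volume perturbation (dimnames give the fractions).
#' @export
sensitivity_grid <- function(c_in, c_out, acr, volume_adjusted,
                             acr_perturbations = c(-0.1, 0, 0.1),
                             volume_perturbations = c(-0.1, 0, 0.1)) {
  if (any(acr_perturbations <= -1) || any(volume_perturbations <= -1))
    stop("perturbation fractions must be > -1", call. = FALSE)
  g <- outer(acr_perturbations, volume_perturbations,
             function(da, dv) emission_rate(c_in, c_out, acr * (1 + da),
                                            volume_adjusted * (1 + dv)))
  dimnames(g) <- list(acr = format(acr_perturbations),
                      volume = format(volume_perturbations))
  g
}
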