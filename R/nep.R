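#' Annual soil respiration
#'
#' Empirical climate-and-substrate model of the annual soil respiration
#' rate: an exponential temperature response times two saturating
#' Michaelis-Menten-type factors in precipitation and topsoil organic
#' carbon,
#' \deqn{Rs = 1.55\, e^{0.031 T} \frac{P}{P + 0.68} \frac{SOC}{SOC + 2.23}.}
#' Rs is strictly increasing in each argument on the positive domain and
#' vanishes when P = 0 or SOC = 0.
#'
#' @param T_c annual mean temperature, degrees C.
#' @param P_m annual precipitation, metres (not mm).
#' @param soc soil organic carbon density of the 0-20 cm layer, kg C m^-2.
#' @return Rs in kg C m^-2 yr^-1 (same shape as the inputs).
#' @export
soil_respiration <- function(T_c, P_m, soc) {
  if (any(P_m < 0, na.rm = TRUE)) stop("precipitation must be >= 0", call. = FALSE)
  if (any(soc < 0, na.rm = TRUE)) stop("SOC must be >= 0", call. = FALSE)
  1.55 * exp(0.031 * T_c) * (P_m / (P_m + 0.68)) * (soc / (soc + 2.23))
}

#' Heterotrophic respiration from soil respiration
#'
#' Power-law partition of soil respiration into its heterotrophic component,
#' \eqn{Rh = 0.6163\, Rs^{0.7918}}, fitted on paired field measurements
#' across forest, cropland and grassland sites; applied here in
#' kg C m^-2 yr^-1 (the unit Rs is produced in).
#'
#' @param rs soil respiration, kg C m^-2 yr^-1 (>= 0).
#' @return Rh in kg C m^-2 yr^-1.
#' @export
heterotrophic_respiration <- function(rs) {
  if (any(rs < 0, na.rm = TRUE)) stop("Rs must be >= 0", call. = FALSE)
  0.6163 * rs^0.7918
}

#' Net ecosystem productivity
#'
#' NEP = NPP - Rh per pixel: soil respiration from climate and topsoil
#' carbon, its heterotrophic share by the power law, converted from kg to
#' g C m^-2 yr^-1, and subtracted from NPP.  Negative values (carbon
#' sources) are legitimate output.
#'
#' @param npp NPP grid, g C m^-2 yr^-1.
#' @param temperature annual mean temperature grid, degrees C.
#' @param precipitation annual precipitation grid, metres.
#' @param soc soil organic carbon grid, kg C m^-2.
#' @param precip_unit `"m"` (default) or `"mm"`; mm inputs are divided by
#'   1000 before use.
#' @return list of co-registered grids: `npp`, `rs` (kg C m^-2 yr^-1),
#'   `rh` and `nep` (both g C m^-2 yr^-1).
#' @export
nep <- function(npp, temperature, precipitation, soc, precip_unit = c("m", "mm")) {
  precip_unit <- match.arg(precip_unit)
  assert_coregistered(npp, temperature, precipitation, soc)
  p <- precipitation$values
  if (precip_unit == "mm") p <- p / 1000
  rs <- soil_respiration(temperature$values, p, soc$values)
  rh_g <- heterotrophic_respiration(rs) * 1000
  nep_v <- npp$values - rh_g
  list(npp = npp,
       rs = grid_like(as.vector(rs), npp),
       rh = grid_like(as.vector(rh_g), npp),
       nep = grid_like(as.vector(nep_v), npp))
}

#' Classify pixels as carbon sink, source or neutral
#'
#' Positive NEP marks a carbon sink, negative a carbon source, zero is
#' neutral.
#'
#' @param nep_grid NEP `tercab_grid`.
#' @return grid coded -1 (source), 0 (neutral), +1 (sink); `NA` propagates.
#' @export
classify_sink_source <- function(nep_grid) {
  stopifnot(inherits(nep_grid, "tercab_grid"))
  grid_like(as.vector(sign(nep_grid$values)), nep_grid)
}
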