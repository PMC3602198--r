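#' Convert OD600 to dry cell weight
#'
#' Linear through the origin with the calibration factor
#' 1 OD600 = 0.3877 g DCW/L (spectrophotometric standard curve for
#' K. oxytoca batch cultures).
#'
#' @param od600 Optical density at 600 nm (>= 0).
#' @param factor g DCW per litre per OD unit.
#' @return g DCW/L.
#' @examples
#' od_to_dcw(1.0)   # 0.3877
#' @export
od_to_dcw <- function(od600, factor = 0.3877) {
  if (any(od600 < 0)) stop("od600 must be >= 0", call. = FALSE)
  od600 * factor
}

#' Product yield on substrate
#' @param delta_product Product formed, g/L.
#' @param delta_substrate Substrate consumed, g/L (> 0).
#' @return Yield, g/g.
#' @examples
#' product_yield(30, 90)  # ~0.333 g/g
#' @export
product_yield <- function(delta_product, delta_substrate) {
  if (any(delta_substrate <= 0)) {
    stop("substrate consumption must be > 0", call. = FALSE)
  }
  delta_product / delta_substrate
}

#' Volumetric productivity
#' @param product_conc Final product concentration, g/L.
#' @param elapsed Elapsed time, h (> 0).
#' @return g/L/h.
#' @export
productivity <- function(product_conc, elapsed) {
  if (any(elapsed <= 0)) stop("elapsed time must be > 0", call. = FALSE)
  product_conc / elapsed
}

#' Mutant-to-wild-type percentage
#'
#' `100 * mutant / wildtype`, reported both at full precision and rounded
#' to the nearest integer (the presentation used for statements like
#' "about 6% of the wild type" or "about 176%").
#'
#' @param mutant_value,wildtype_value Positive comparables (wild type > 0).
#' @return List with `percent` (unrounded) and `rounded` (integer).
#' @examples
#' relative_percent(1.9, 32)  # about 6%
#' relative_percent(30, 17)   # about 176%
#' @export
relative_percent <- function(mutant_value, wildtype_value) {
  if (any(wildtype_value <= 0)) {
    stop("wildtype_value must be > 0", call. = FALSE)
  }
  p <- 100 * mutant_value / wildtype_value
  list(percent = p, rounded = round_half_up(p, 0L))
}

#' Molar masses bundled with the package
#'
#' g/mol for the species appearing in fermentation summaries.
#' @return Named numeric vector.
#' @export
kox_molar_masses <- function() {
  c(glucose = 180.16, glycerol = 92.09, btd = 90.12, acetoin = 88.11,
    lactate = 90.08, acetate = 60.05, ethanol = 46.07, formate = 46.03,
    succinate = 118.09)
}

#' Observed yield as a fraction of the model's theoretical maximum
#'
#' Computes the theoretical maximum mass yield by FBA: growth is not
#' required (the biomass lower bound is zeroed), the product secretion is
#' maximized at the configured substrate uptake, and the molar yield is
#' converted to g/g with the molar masses. Returns
#' `100 * observed_yield / theoretical_yield`. For 2,3-BD on glucose the
#' core model's theoretical maximum is 1 mol/mol = 0.500 g/g, so an
#' observed 0.478 g/g reports 95.6%.
#'
#' @param observed_yield Observed mass yield, g product / g substrate.
#' @param model A `cb_model` with open substrate uptake.
#' @param product_exchange,substrate_exchange Exchange reaction ids.
#' @param molar_masses Named vector with entries `product` and `substrate`
#'   (g/mol), e.g. `c(product = 90.12, substrate = 180.16)`.
#' @return List with `theoretical_yield` (g/g), `percent` and `rounded`.
#' @export
theoretical_yield_fraction <- function(observed_yield, model,
                                       product_exchange,
                                       substrate_exchange,
                                       molar_masses = c(product = 90.12,
                                                        substrate = 180.16)) {
  m2 <- model
  if (!is.null(m2$objective)) {
    m2 <- set_reaction_bounds(m2, m2$objective, lb = 0)
  }
  if ("ATPM" %in% names(m2$reactions)) {
    m2 <- set_reaction_bounds(m2, "ATPM", lb = 0)  # yield, not maintenance
  }
  res <- optimize_fluxes(m2, product_exchange, "max")
  if (res$status != "optimal") stop("model infeasible", call. = FALSE)
  uptake <- -res$fluxes[[substrate_exchange]]
  if (uptake <= 0) stop("no substrate uptake in optimum", call. = FALSE)
  molar_yield <- res$fluxes[[product_exchange]] / uptake
  th <- molar_yield * molar_masses[["product"]] / molar_masses[["substrate"]]
  if (th <= 0) stop("zero theoretical yield", call. = FALSE)
  p <- 100 * observed_yield / th
  list(theoretical_yield = th, molar_yield = molar_yield,
       percent = p, rounded = round_half_up(p, 1L))
}

#' Read a fermentation time course
#'
#' CSV with columns `time_h`, `od600`, then one column per species in
#' g/L (e.g. `glucose`, `btd`, `lactate`, ...). Concentrations must be
#' non-negative and times non-decreasing.
#'
#' @param path CSV file.
#' @return `data.frame` of class `fermentation_record`.
#' @export
read_fermentation_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "od600") %in% names(x))) {
    stop("fermentation CSV needs columns time_h and od600", call. = FALSE)
  }
  if (any(x$time_h < 0)) stop("negative time", call. = FALSE)
  conc <- x[, setdiff(names(x), c("time_h", "od600")), drop = FALSE]
  if (any(as.matrix(conc) < 0, na.rm = TRUE)) {
    stop("negative concentration", call. = FALSE)
  }
  class(x) <- c("fermentation_record", class(x))
  x
}

#' Summarize a fermentation run
#'
#' Final dry cell weight, consumed substrate, product formed, mass yield
#' and volumetric productivity, assuming constant broth volume (batch
#' operation).
#'
#' @param record A [read_fermentation_csv()] table.
#' @param product,substrate Column names (default `btd`, `glucose`).
#' @param od_factor Passed to [od_to_dcw()].
#' @return One-row `data.frame`: `end_time_h`, `final_dcw_g_l`,
#'   `substrate_consumed_g_l`, `product_g_l`, `yield_g_g`,
#'   `productivity_g_l_h`.
#' @export
ferm_summary <- function(record, product = "btd", substrate = "glucose",
                         od_factor = 0.3877) {
  stopifnot(product %in% names(record), substrate %in% names(record))
  last <- nrow(record)
  dt <- record$time_h[last] - record$time_h[1L]
  dS <- record[[substrate]][1L] - record[[substrate]][last]
  dP <- record[[product]][last] - record[[product]][1L]
  data.frame(
    end_time_h = record$time_h[last],
    final_dcw_g_l = od_to_dcw(record$od600[last], od_factor),
    substrate_consumed_g_l = dS,
    product_g_l = dP,
    yield_g_g = product_yield(dP, dS),
    productivity_g_l_h = productivity(dP, dt))
}
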