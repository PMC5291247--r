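#' Count cross-linker adducts from a mass difference
#'
#' `floor((observed - theoretical) * 1000 / adduct)`: the number of whole
#' cross-linker adducts accounted for by the excess of an observed
#' (e.g. SEC-MALS) mass over the theoretical polypeptide mass. Floor matches
#' the reporting convention of the source arithmetic (2.7 kDa / 174 Da =
#' 15.5 is reported as "approximately 15").
#'
#' @param observed_kda observed mass, kDa.
#' @param theoretical_kda theoretical mass, kDa.
#' @param adduct_da per-adduct mass, Da.
#' @return integer adduct count.
#' @export
count_adducts <- function(observed_kda, theoretical_kda, adduct_da) {
  if (any(c(observed_kda, theoretical_kda, adduct_da) <= 0))
    stop("masses must be positive")
  if (observed_kda < theoretical_kda)
    stop("observed mass below theoretical mass (negative difference)")
  as.integer(floor((observed_kda - theoretical_kda) * 1000 / adduct_da))
}

#' Total mass of a complex from its components
#'
#' @param components data.frame (or list coercible to one) with columns
#'   `mass_kda` and `count`.
#' @return total mass, kDa.
#' @export
complex_mass <- function(components) {
  components <- as.data.frame(components)
  if (nrow(components) == 0L) return(0)
  if (any(components$count < 1)) stop("counts must be >= 1")
  sum(components$mass_kda * components$count)
}
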