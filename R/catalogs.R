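#' Flavonoid analyte catalog
#'
#' The fifteen flavonoid and anthocyanin analytes quantified in dried peel,
#' in the fixed column order of the bundled quantification table. Codes are
#' the field's flattened subscript symbols (e.g. \code{Y_HY} for hyperoside);
#' contents are in mg per g dried peel.
#'
#' @return A data.frame with columns \code{code} and \code{name}, 15 rows.
#' @export
#' @examples
#' analyte_catalog()$code
analyte_catalog <- function() {
  data.frame(
    code = c("Y_HY", "Y_LU", "Y_KP", "Y_QI", "Y_C", "Y_RU", "Y_CA", "Y_QU",
             "Y_HE", "Y_AP", "Y_PH", "Y_PG", "Y_CGT", "Y_CGC", "Y_CSA"),
    name = c("hyperoside", "luteolin", "kaempferol", "quercitrin", "catechin",
             "rutin", "chlorogenic acid", "quercetin", "hesperetin",
             "apigenin", "peonidin O-hexoside", "peonidin 3-O-glucoside",
             "cyanidin 3-O-galactoside", "cyanidin 3-O-glucoside",
             "cyanidin O-syringic acid"),
    stringsAsFactors = FALSE
  )
}

#' Annual climate-factor catalog
#'
#' The ten annual climate factors used as exogenous drivers, with their units.
#'
#' @return A data.frame with columns \code{code}, \code{name}, \code{unit},
#'   10 rows.
#' @export
climate_catalog <- function() {
  data.frame(
    code = c("X_AMT", "X_AMAT", "X_AMIT", "X_RH", "X_AAP",
             "X_MW", "X_MAW", "X_EW", "X_ASD", "X_ASP"),
    name = c("annual mean temperature", "annual mean maximum temperature",
             "annual mean minimum temperature", "annual relative humidity",
             "annual average precipitation", "mean wind speed",
             "maximum wind speed", "extreme wind speed",
             "annual sunshine duration", "percentage of sunshine"),
    unit = c("degC", "degC", "degC", "%", "mm", "m/s", "m/s", "m/s", "h", "%"),
    stringsAsFactors = FALSE
  )
}

#' CIELAB color axis codes
#'
#' @return Character vector \code{c("L", "a", "b")}: lightness, the
#'   green--red axis and the blue--yellow axis of CIELAB color space.
#' @export
color_axes <- function() c("L", "a", "b")

# geography columns recognised in sample tables
geo_columns <- function() c("altitude", "longitude", "latitude")
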