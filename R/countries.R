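# ISO-3166 alpha-2 country codes and the informal-name alias table used by
# registry and trade inputs. The alias table covers the names that appear in
# conservation reporting (e.g. "RSA" for South Africa, "DRC" for the
# Democratic Republic of the Congo); CITES exports themselves use ISO codes.

.iso_alpha2 <- c(
  "AD", "AE", "AF", "AG", "AI", "AL", "AM", "AO", "AQ", "AR", "AS", "AT",
  "AU", "AW", "AX", "AZ", "BA", "BB", "BD", "BE", "BF", "BG", "BH", "BI",
  "BJ", "BL", "BM", "BN", "BO", "BQ", "BR", "BS", "BT", "BV", "BW", "BY",
  "BZ", "CA", "CC", "CD", "CF", "CG", "CH", "CI", "CK", "CL", "CM", "CN",
  "CO", "CR", "CU", "CV", "CW", "CX", "CY", "CZ", "DE", "DJ", "DK", "DM",
  "DO", "DZ", "EC", "EE", "EG", "EH", "ER", "ES", "ET", "FI", "FJ", "FK",
  "FM", "FO", "FR", "GA", "GB", "GD", "GE", "GF", "GG", "GH", "GI", "GL",
  "GM", "GN", "GP", "GQ", "GR", "GS", "GT", "GU", "GW", "GY", "HK", "HM",
  "HN", "HR", "HT", "HU", "ID", "IE", "IL", "IM", "IN", "IO", "IQ", "IR",
  "IS", "IT", "JE", "JM", "JO", "JP", "KE", "KG", "KH", "KI", "KM", "KN",
  "KP", "KR", "KW", "KY", "KZ", "LA", "LB", "LC", "LI", "LK", "LR", "LS",
  "LT", "LU", "LV", "LY", "MA", "MC", "MD", "ME", "MF", "MG", "MH", "MK",
  "ML", "MM", "MN", "MO", "MP", "MQ", "MR", "MS", "MT", "MU", "MV", "MW",
  "MX", "MY", "MZ", "NA", "NC", "NE", "NF", "NG", "NI", "NL", "NO", "NP",
  "NR", "NU", "NZ", "OM", "PA", "PE", "PF", "PG", "PH", "PK", "PL", "PM",
  "PN", "PR", "PS", "PT", "PW", "PY", "QA", "RE", "RO", "RS", "RU", "RW",
  "SA", "SB", "SC", "SD", "SE", "SG", "SH", "SI", "SJ", "SK", "SL", "SM",
  "SN", "SO", "SR", "SS", "ST", "SV", "SX", "SY", "SZ", "TC", "TD", "TF",
  "TG", "TH", "TJ", "TK", "TL", "TM", "TN", "TO", "TR", "TT", "TV", "TW",
  "TZ", "UA", "UG", "UM", "US", "UY", "UZ", "VA", "VC", "VE", "VG", "VI",
  "VN", "VU", "WF", "WS", "YE", "YT", "ZA", "ZM", "ZW",
  # retired codes that still appear in historical CITES annual reports
  "XX", "ZR", "CS", "SU", "YU", "DD", "AN"
)

.country_aliases <- c(
  "RSA"                  = "ZA",
  "SOUTH AFRICA"         = "ZA",
  "DRC"                  = "CD",
  "ZAIRE"                = "CD",
  "SWAZILAND"            = "SZ",
  "ESWATINI"             = "SZ",
  "IVORY COAST"          = "CI",
  "TANZANIA"             = "TZ",
  "BOTSWANA"             = "BW",
  "NAMIBIA"              = "NA",
  "KENYA"                = "KE",
  "ETHIOPIA"             = "ET",
  "SUDAN"                = "SD",
  "SOUTH SUDAN"          = "SS",
  "ZAMBIA"               = "ZM",
  "MALAWI"               = "MW",
  "MOZAMBIQUE"           = "MZ",
  "ZIMBABWE"             = "ZW",
  "RWANDA"               = "RW",
  "INDIA"                = "IN",
  "GABON"                = "GA",
  "ANGOLA"               = "AO",
  "UGANDA"               = "UG",
  "NIGERIA"              = "NG",
  "BENIN"                = "BJ",
  "BURKINA FASO"         = "BF",
  "NIGER"                = "NE",
  "SENEGAL"              = "SN",
  "CAMEROON"             = "CM",
  "CHAD"                 = "TD",
  "CAR"                  = "CF",
  "CENTRAL AFRICAN REPUBLIC" = "CF",
  "SOMALIA"              = "SO"
)

#' Normalise a country identifier to ISO-3166 alpha-2
#'
#' Accepts an alpha-2 code in any case, or one of the packaged informal
#' aliases used in conservation reporting (e.g. `"RSA"`, `"DRC"`).
#'
#' @param x character vector of country identifiers.
#' @param strict if `TRUE` (default), unknown identifiers raise an error;
#'   otherwise they are returned as `NA`.
#' @return character vector of upper-case alpha-2 codes.
#' @examples
#' normalize_country(c("za", "RSA", "DRC"))
#' @export
normalize_country <- function(x, strict = TRUE) {
  up <- toupper(trimws(as.character(x)))
  out <- ifelse(up %in% names(.country_aliases), unname(.country_aliases[up]), up)
  bad <- !is.na(out) & !(out %in% .iso_alpha2) & nzchar(out)
  if (any(bad)) {
    if (strict) {
      stop("unknown country identifier(s): ", paste(unique(up[bad]), collapse = ", "),
           call. = FALSE)
    }
    out[bad] <- NA_character_
  }
  out
}

is_iso_alpha2 <- function(x) {
  toupper(x) %in% .iso_alpha2
}
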