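# Montage naming: the X_Y_L_B scheme (anode site, cathode site, electrode
# dimensions in cm). Cathode name tokens map to internal site labels so that
# "CP5_Neck_5_5" parses to cathode "neck_nape" and formats back identically.

.CATHODE_TOKEN_TO_SITE <- c(SO = "SO_contra", Maxilla = "maxilla_contra",
                            Neck = "neck_nape")
.SITE_TO_CATHODE_TOKEN <- c(SO_contra = "SO", maxilla_contra = "Maxilla",
                            neck_nape = "Neck")

.knownSites <- function() rownames(.electrodeUnitVectors())

.siteFromToken <- function(token) {
  if (token %in% names(.CATHODE_TOKEN_TO_SITE))
    return(unname(.CATHODE_TOKEN_TO_SITE[token]))
  if (token %in% .knownSites()) return(token)
  stop("unknown electrode label: ", token)
}

.tokenFromSite <- function(site) {
  if (site %in% names(.SITE_TO_CATHODE_TOKEN))
    return(unname(.SITE_TO_CATHODE_TOKEN[site]))
  site
}

#' Parse an X_Y_L_B montage name
#'
#' Parses names such as `"CP5_CZ_5_5"` (anode CP5, cathode CZ, 5 x 5 cm^2) or
#' `"TP7_Neck_5_7"` (cathode at the nape of the neck). The total current
#' defaults to the conventional 2 mA.
#'
#' @param name montage name string in the `X_Y_L_B` format.
#' @param current total current in mA.
#' @return A [MontageSpec-class].
#' @examples
#' parseMontageName("CP5_CZ_5_5")
#' @export
parseMontageName <- function(name, current = 2) {
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(parts) != 4L)
    stop("malformed montage name (expected ANODE_CATHODE_L_B): ", name)
  anode <- parts[1]
  if (!anode %in% .knownSites()) stop("unknown electrode label: ", anode)
  cathode <- .siteFromToken(parts[2])
  sizeL <- suppressWarnings(as.numeric(parts[3]))
  sizeB <- suppressWarnings(as.numeric(parts[4]))
  if (is.na(sizeL) || is.na(sizeB) || sizeL <= 0 || sizeB <= 0)
    stop("malformed electrode dimensions in montage name: ", name)
  MontageSpec(anode, cathode, sizeL, sizeB, current)
}

#' Format a MontageSpec as its X_Y_L_B name
#'
#' @param spec a [MontageSpec-class].
#' @return The canonical montage name string.
#' @export
formatMontageName <- function(spec) {
  stopifnot(is(spec, "MontageSpec"))
  fmt <- function(x) sub("\\.?0+$", "", sprintf("%g", x))
  paste(spec@anode, .tokenFromSite(spec@cathode), fmt(spec@sizeL),
        fmt(spec@sizeB), sep = "_")
}

#' Enumerate the ten montages of the montage-selection experiment
#'
#' Five dorsal-pathway montages (anode CP5, cathodes CZ, SO, maxilla, nape of
#' the neck and contralateral homologue CP6) and five ventral-pathway montages
#' (anode TP7, same cathode scheme with homologue TP8), at the given electrode
#' size.
#'
#' @param sizeL,sizeB electrode dimensions in cm.
#' @param current total current in mA.
#' @return A named list of 10 [MontageSpec-class] objects; names are the
#'   `X_Y_L_B` montage names, dorsal montages first.
#' @examples
#' names(enumerateStandardMontages(5, 5))
#' @export
enumerateStandardMontages <- function(sizeL = 5, sizeB = 5, current = 2) {
  cathodes <- c("CZ", "SO_contra", "maxilla_contra", "neck_nape")
  specs <- c(
    lapply(c(cathodes, "CP6"), function(ct)
      MontageSpec("CP5", ct, sizeL, sizeB, current)),
    lapply(c(cathodes, "TP8"), function(ct)
      MontageSpec("TP7", ct, sizeL, sizeB, current)))
  names(specs) <- vapply(specs, formatMontageName, character(1))
  specs
}
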