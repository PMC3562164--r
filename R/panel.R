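#' Read a drug panel table
#'
#' A panel is a tab-separated table with columns
#' \code{abbreviation}, \code{name}, \code{starting_concentration_uM},
#' \code{ppc_uM} and \code{components}. \code{ppc_uM} is left empty when the
#' peak plasma concentration is not determined ("N.D."); such drugs can be
#' assayed and classified but never ranked. \code{components} lists the
#' constituent single-agent codes joined by "+" (equal to the abbreviation
#' for single agents).
#'
#' @param path path to a panel TSV.
#' @return data.frame with columns \code{abbreviation}, \code{name},
#'   \code{starting_concentration_uM}, \code{ppc_uM} (NA = not determined),
#'   \code{components} (list column of character vectors).
#' @export
readPanel <- function(path) {
  stopIfNot(file.exists(path), sprintf("panel file not found: %s", path))
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(
                     abbreviation = "character", name = "character",
                     starting_concentration_uM = "numeric",
                     ppc_uM = "character", components = "character"))
  required <- c("abbreviation", "name", "starting_concentration_uM",
                "ppc_uM", "components")
  stopIfNot(all(required %in% names(df)),
            sprintf("panel format error: expected columns %s",
                    paste(required, collapse = ", ")))
  df$ppc_uM <- suppressWarnings(as.numeric(df$ppc_uM))
  df$components <- lapply(strsplit(df$components, "+", fixed = TRUE), trimws)
  validatePanel(df)
  df
}

validatePanel <- function(panel) {
  stopIfNot(!anyDuplicated(panel$abbreviation),
            "panel error: duplicate drug abbreviations")
  stopIfNot(all(panel$starting_concentration_uM > 0),
            "panel error: starting concentrations must be positive")
  ok_ppc <- is.na(panel$ppc_uM) | panel$ppc_uM > 0
  stopIfNot(all(ok_ppc), "panel error: ppc must be positive when present")
  invisible(panel)
}

#' The default 14-drug chemosensitivity panel
#'
#' Fourteen single-agent anticancer drugs with the starting concentration of
#' the dilution series (1\% of the clinical vial concentration, in uM) and
#' the peak plasma concentration (ppc) used as the clinical-achievability
#' reference. Irinotecan (CPT) has no determined ppc and is therefore never
#' ranked.
#'
#' @return panel data.frame (see \code{\link{readPanel}}).
#' @examples
#' panel <- defaultPanel()
#' panel[panel$abbreviation == "PXL", "ppc_uM"]  # 5.86
#' @export
defaultPanel <- function() {
  readPanel(system.file("extdata", "default_panel.tsv",
                        package = "chemoRank", mustWork = TRUE))
}

#' Look up the ppc of a drug in a panel
#' @param panel panel data.frame.
#' @param drug drug code.
#' @return ppc in uM, or NA when not determined or the drug (for example a
#'   combination without a combination-level ppc entry) is absent.
#' @export
panelPpc <- function(panel, drug) {
  i <- match(drug, panel$abbreviation)
  if (is.na(i)) NA_real_ else panel$ppc_uM[i]
}
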