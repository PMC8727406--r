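# Bundled published national indicators and helpers around them.

#' Published national June indicators for Poland, 2010-2019
#'
#' Loads the indicator table bundled with the package: for each June of
#' 2010-2019 and for the 2010-2018 reference mean, relative all-cause
#' mortality (`tmrel`, percent of the reference mean; unpublished years are
#' `NA`), relative strong-heat-related mortality (`shrmrel`), mean monthly
#' midday UTCI (`utci_12_mean`, degC), the number of strong plus very
#' strong heat-stress days (`stress_days`), and monthly mean O3 and PM2.5
#' concentrations with their percent-of-reference values. The table is the
#' natural input for [table1_report()]-style consistency checks and for
#' anomaly calculations when no station archive is at hand.
#'
#' @param path File to read; defaults to the bundled table.
#' @return Data frame with a character `period` column (`"2010"` ...
#'   `"2019"`, `"2010-2018"` for the published reference mean) and the
#'   numeric columns above.
#' @export
read_published_indicators <- function(path = NULL) {
  path <- path %||% system.file(
    "extdata", "poland_june_indicators_2010_2019.tsv",
    package = "bioheat", mustWork = TRUE
  )
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", na.strings = "NA",
                           colClasses = c("character", rep("numeric", 8)),
                           stringsAsFactors = FALSE)
  tab
}
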