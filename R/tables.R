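#' Published Ethiopia 2011/2016 index tables
#'
#' The printed proximate-determinant index values for the two Ethiopian
#' DHS rounds, bundled as plain-CSV package data: the national indices of
#' both rounds (`table1`) and the stratified tables by region, wealth
#' quintile, education and residence (`stratified_2016`,
#' `stratified_2011`). These are the aggregate-mode inputs for
#' reproducing the published worked numbers.
#'
#' Two transcription notes. The source's national table labels its
#' composed-TFR row "TF"; here that row is labelled `TFR` (the TF used
#' throughout the stratified tables is 15.3). The 2011 "Higher" education
#' row is malformed at source (Ci printed as 0, TFR as 0.00); it is kept
#' as printed and carries `quality_flag = TRUE`.
#'
#' @return A list with data frames `table1` (quantity, y2011, y2016),
#'   `stratified_2016` and `stratified_2011` (variable, level, Cm, Cc,
#'   Ci, Cfw, TF, TFR, quality_flag).
#' @export
#' @examples
#' ethiopia_tables()$table1
ethiopia_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "bongaarts",
                                  mustWork = TRUE)
  read <- function(f) utils::read.csv(path(f), stringsAsFactors = FALSE,
                                      check.names = FALSE)
  flag_rows <- function(df) {
    df$quality_flag <- df$Ci <= 0 | df$Ci > 1 | df$TFR <= 0
    df
  }
  list(table1 = read("table1_indices.csv"),
       stratified_2016 = flag_rows(read("table2_stratified_2016.csv")),
       stratified_2011 = flag_rows(read("table3_stratified_2011.csv")))
}
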