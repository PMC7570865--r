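#' Published Alaska burned-area accuracy statistics
#'
#' Returns the published per-year accuracy statistics of four global
#' MODIS-era burned-area products (Fire_CCI 4.1 and 5.1, MCD45A1 C5.1,
#' MCD64A1 C6) validated against the Alaska Fire Service fire-perimeter
#' record for 2000-2017, as printed in the original assessment: the annual
#' reference burned area (`afs_ha`), each product's detected percentage
#' (`p_pct`, 2 dp), and its commission, omission and total errors (`ce`,
#' `oe`, `te`, 3 dp). The `year` column is character, with an `"all_years"`
#' row per product holding the reference-area-weighted summary.
#'
#' These numbers are shipped as *inputs* for consistency auditing (see
#' [recompute_total_errors()]): the `te` column can be reproduced from
#' `ce`, `oe` and `p_pct` via `TE = CE * P + OE` to within the rounding of
#' the printed inputs.
#'
#' @return A tibble with columns `year`, `afs_ha`, `product`, `p_pct`,
#'   `ce`, `oe`, `te`.
#' @examples
#' rep <- reported_alaska_accuracy()
#' recompute_total_errors(rep[rep$year == "all_years", ])
#' @export
reported_alaska_accuracy <- function() {
  path <- system.file("extdata", "alaska_reported_accuracy.csv",
                      package = "firescar", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(year = "character"))
  tibble::as_tibble(tab)
}
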