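#' Published meta-analytic dataset size configurations
#'
#' Size parameters (number of contrasts, total and maximum foci counts) of
#' 20 published cognitive and psychological meta-analytic datasets, used to
#' configure null simulations at realistic study counts and foci densities.
#' The mean foci per contrast is derived as `total_foci / n_contrasts`.
#'
#' @return data.frame with columns `dataset`, `n_contrasts`, `total_foci`,
#'   `max_foci`, `mean_foci`.
#' @export
cbma_dataset_sizes <- function() {
  path <- system.file("extdata", "meta_dataset_sizes.tsv", package = "cbmr",
                      mustWork = TRUE)
  tbl <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = TRUE)
  tbl$mean_foci <- tbl$total_foci / tbl$n_contrasts
  tbl
}
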