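#' Published reference luminance/contrast measurements
#'
#' Per-sample mean CIELAB lightness (`L_*`) and global contrast factor
#' (`C_*`) for eight clinical fundus samples, before enhancement and after
#' enhancement with the binomial, median and Gaussian background filters, as
#' published with the enhancement method this package implements. The
#' clinical images themselves are not redistributable; the table supports
#' the worked-example arithmetic (column averages and gain computations)
#' used to validate the reporting machinery.
#'
#' @return A `data.frame` with columns `sample`, `L_before`, `C_before`,
#'   `L_binomial`, `C_binomial`, `L_median`, `C_median`, `L_gaussian`,
#'   `C_gaussian`.
#' @export
reference_measurements <- function() {
  utils::read.csv(system.file("extdata", "reference_measurements.csv",
                              package = "fundusbf", mustWork = TRUE))
}

#' Quality reports built from the published reference measurements
#'
#' Turns [reference_measurements()] into a list of `quality_report` objects
#' for one filter family, ready for [average_report()].
#'
#' @param filter One of `"binomial"`, `"median"`, `"gaussian"`.
#' @return List of eight `quality_report` objects.
#' @export
reference_reports <- function(filter = c("binomial", "median", "gaussian")) {
  filter <- match.arg(filter)
  tab <- reference_measurements()
  lapply(seq_len(nrow(tab)), function(i) quality_report(
    luminosity_before = tab$L_before[i],
    contrast_before = tab$C_before[i],
    luminosity_after = tab[[paste0("L_", filter)]][i],
    contrast_after = tab[[paste0("C_", filter)]][i],
    filter_descriptor = list(family = filter),
    sample = as.character(tab$sample[i])
  ))
}
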