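# End-to-end enhancement pipeline and the benchmark loop.
#
# Stage order: split channels -> ROI by thresholding -> store R/G, B/G
# ratios (from the original channels) -> masked 3x3 pre-filter -> background
# brightness per channel -> luminosity adjustment (gap + baseline), full-
# information adjusted green -> constrained ROI-wide equalization -> color
# recombination from the stored ratios.

#' Pipeline configuration
#'
#' Validated bundle of the tunable parameters; defaults are the production
#' settings (41 x 41 binomial filter flattened with `alpha = 0.1`, baseline
#' 128, clip factor 2).
#'
#' @param filter Background filter family: `"binomial"`, `"gaussian"` or
#'   `"median"`.
#' @param size Odd filter size in pixels (default 41).
#' @param alpha Binomial flattening factor in `(0, 1]` (default 0.1).
#' @param sigma Gaussian spread (default 5).
#' @param threshold ROI threshold on the channel mean, 8-bit units
#'   (default 20).
#' @param baseline Background luminosity target (default 128).
#' @param clip_factor Equalization clip limit multiple (default 2).
#' @param epsilon Green floor for the ratio maps (default 1).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(filter = c("binomial", "gaussian", "median"),
                            size = 41, alpha = 0.1, sigma = 5,
                            threshold = 20, baseline = 128,
                            clip_factor = 2, epsilon = 1) {
  filter <- match.arg(filter)
  if (length(size) != 1L || size < 3 || size != floor(size) || size %% 2 != 1)
    stop("filter size must be a single odd integer >= 3, got ", deparse(size))
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (sigma <= 0) stop("sigma must be positive")
  if (clip_factor <= 0) stop("clip_factor must be positive")
  structure(list(filter = filter, size = as.integer(size), alpha = alpha,
                 sigma = sigma, threshold = threshold, baseline = baseline,
                 clip_factor = clip_factor, epsilon = epsilon),
            class = "pipeline_config")
}

background_kernel <- function(config) {
  w <- (config$size - 1L) %/% 2L
  switch(config$filter,
    binomial = scale_and_flatten(binomial_2d(w), alpha = config$alpha),
    gaussian = gaussian_kernel(size = config$size, sigma = config$sigma),
    median = NULL
  )
}

#' Enhance a fundus image
#'
#' Runs the full enhancement: ROI detection, ratio storage, masked 3x3
#' pre-filtering, per-channel background-brightness estimation, luminosity
#' adjustment to the baseline, constrained equalization of the
#' full-information green channel, and ratio-based color recombination.
#'
#' @param image A [fundus_image()].
#' @param config A [pipeline_config()].
#' @param keep_intermediates Keep the masks, surfaces and adjusted channels
#'   in the result (default `FALSE`).
#' @param compute_report Compute the before/after quality report (default
#'   `TRUE`; the metrics pass costs a few Lab conversions of the full image).
#' @param verbose Print per-stage progress with timings.
#' @return A `fundus_enhancement` list: `image` (the enhanced
#'   [fundus_image()]), `report` (a `quality_report` or `NULL`), `config`,
#'   and `intermediates` when requested (`roi`, `ratios`, `prefiltered`,
#'   `surfaces`, `adjusted` with `ar`, `ag`, `ab`, `agf`, `mapping`, `eg`).
#' @export
enhance <- function(image, config = pipeline_config(),
                    keep_intermediates = FALSE, compute_report = TRUE,
                    verbose = FALSE) {
  stopifnot(inherits(image, "fundus_image"), inherits(config, "pipeline_config"))
  say <- function(stage, t0) if (verbose)
    message(sprintf("[%s] %.2fs", stage, (proc.time() - t0)[["elapsed"]]))
  stage <- function(name, expr) {
    t0 <- proc.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say(name, t0)
    out
  }

  mask <- stage("roi", detect_roi(image, threshold = config$threshold))
  ratios <- stage("ratios",
                  compute_ratio_maps(image, mask, epsilon = config$epsilon))

  pre <- stage("prefilter", {
    lapply(list(red = image$red, green = image$green, blue = image$blue),
           function(ch) { ch[!mask] <- 0; masked_average_3x3(ch, mask) })
  })

  kernel <- background_kernel(config)
  surfaces <- stage("background", {
    lapply(pre, function(ch)
      if (config$filter == "median")
        masked_median_surface(ch, mask, window = config$size)
      else
        estimate_background(ch, mask, kernel))
  })

  adjusted <- stage("adjust", {
    pre_img <- fundus_image(pre$red, pre$green, pre$blue)
    list(
      ar = adjust_channel(pre$red, surfaces$red, mask, config$baseline),
      ag = adjust_channel(pre$green, surfaces$green, mask, config$baseline),
      ab = adjust_channel(pre$blue, surfaces$blue, mask, config$baseline),
      agf = adjust_green_full(pre_img, surfaces, mask, config$baseline)
    )
  })

  mapping <- stage("equalize",
                   build_constrained_mapping(adjusted$agf, mask,
                                             clip_factor = config$clip_factor))
  eg <- apply_mapping(adjusted$agf, mask, mapping)

  out_image <- stage("recombine", recombine(eg, ratios, mask))

  report <- NULL
  if (compute_report) {
    report <- stage("metrics", quality_report(
      luminosity_before = mean_luminosity(image, mask),
      contrast_before = global_contrast_factor(image, mask),
      luminosity_after = mean_luminosity(out_image, mask),
      contrast_after = global_contrast_factor(out_image, mask),
      filter_descriptor = list(family = config$filter, size = config$size,
                               alpha = config$alpha, sigma = config$sigma)
    ))
  }

  res <- list(image = out_image, report = report, config = config)
  if (keep_intermediates)
    res$intermediates <- list(roi = mask, ratios = ratios, prefiltered = pre,
                              surfaces = surfaces, adjusted = adjusted,
                              mapping = mapping, eg = eg)
  structure(res, class = "fundus_enhancement")
}

#' @export
print.fundus_enhancement <- function(x, ...) {
  cat(sprintf("<fundus_enhancement: %s filter %dx%d>\n",
              x$config$filter, x$config$size, x$config$size))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Benchmark several background filters over a set of images
#'
#' Runs the full pipeline on every image x filter combination and collects
#' a quality report per run plus an average row per filter (gains recomputed
#' from the averaged before/after values). A failing image is recorded and
#' skipped; the run continues.
#'
#' @param images Nonempty list of [fundus_image()] objects (or paths readable
#'   by [read_fundus()]); names label the samples.
#' @param config Base [pipeline_config()]; the `filter` field is overridden
#'   per run.
#' @param filters Character vector of filter families to compare.
#' @return A `benchmark_table`: `reports` (list of `quality_report` per
#'   filter, including the average), `table` (a `data.frame` in the layout
#'   sample x filter with L/C before and after), `errors`.
#' @export
benchmark <- function(images, config = pipeline_config(),
                      filters = c("binomial", "median", "gaussian")) {
  if (length(images) == 0L) stop("no images to benchmark")
  if (length(filters) == 0L) stop("no filters to benchmark")
  if (is.null(names(images)))
    names(images) <- sprintf("sample%02d", seq_along(images))
  reports <- list(); errors <- list(); rows <- list()
  for (f in filters) {
    cfg <- config; cfg$filter <- f
    freports <- list()
    for (nm in names(images)) {
      img <- images[[nm]]
      if (is.character(img)) img <- read_fundus(img)
      res <- tryCatch(enhance(img, cfg), error = function(e) e)
      if (inherits(res, "error")) {
        errors[[paste(f, nm, sep = ":")]] <- conditionMessage(res)
        next
      }
      rep <- res$report
      rep$sample <- nm
      freports[[nm]] <- rep
      rows[[paste(f, nm, sep = ":")]] <- cbind(as.data.frame(rep),
                                               filter = f)
    }
    if (length(freports) > 0) {
      avg <- average_report(freports)
      freports[["average"]] <- avg
      rows[[paste(f, "average", sep = ":")]] <- cbind(as.data.frame(avg),
                                                      filter = f)
    }
    reports[[f]] <- freports
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(reports = reports, table = tab, errors = errors),
            class = "benchmark_table")
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat("<benchmark_table>\n")
  print(x$table, digits = 4)
  if (length(x$errors)) {
    cat("errors:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n")
  }
  invisible(x)
}

#' Write a benchmark table as CSV or JSON
#'
#' @param bench A `benchmark_table` from [benchmark()].
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(bench, path) {
  stopifnot(inherits(bench, "benchmark_table"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(bench$table, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(bench$table, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  } else stop("unsupported report format '", ext, "'")
  invisible(path)
}
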