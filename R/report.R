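# Output: CSV table of the Pareto front and a static scatter plot.

#' Write the Pareto front to CSV
#'
#' One row per design with columns `design_id`, `knockouts`
#' (pipe-separated original reaction ids, sorted), `n_kos`, `growth_rate`,
#' `product_flux`, `coupling_strength`, `coupling_class`. Floats carry 6
#' significant digits; rows are sorted by descending growth rate, then
#' descending product flux. Identical archives produce byte-identical
#' files.
#'
#' @param archive a `pareto_archive`.
#' @param candidates the `candidate_set` (for expanding composites).
#' @param path output CSV path.
#' @return the front as a data.frame, invisibly.
#' @export
write_front_csv <- function(archive, candidates, path) {
  df <- front_table(archive, candidates)
  if (nrow(df) == 0)
    warning("archive is empty; writing header-only CSV", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

front_table <- function(archive, candidates) {
  n <- length(archive$designs)
  if (n == 0)
    return(data.frame(design_id = character(0), knockouts = character(0),
                      n_kos = integer(0), growth_rate = character(0),
                      product_flux = character(0),
                      coupling_strength = character(0),
                      coupling_class = character(0)))
  kos <- vapply(archive$designs, function(d)
    paste(expand_composites(d, candidates), collapse = "|"), "")
  F <- archive$fitness
  ord <- order(-F[, 1], -F[, 2], kos)
  fmt <- function(x) sprintf("%.6g", x)
  data.frame(design_id = sprintf("D%03d", seq_len(n)),
             knockouts = kos[ord],
             n_kos = vapply(archive$designs[ord], function(d)
               length(expand_composites(d, candidates)), 0L),
             growth_rate = fmt(F[ord, 1]),
             product_flux = fmt(F[ord, 2]),
             coupling_strength = fmt(F[ord, 3]),
             coupling_class = archive$classes[ord],
             stringsAsFactors = FALSE)
}

#' Plot the Pareto front
#'
#' Static scatter of growth rate (x) against guaranteed product flux (y),
#' markers colored by coupling strength with a labeled colorbar. Nothing
#' is written for an empty archive (with a warning).
#'
#' @param archive a `pareto_archive`.
#' @param path output image path (`.png` or `.svg` by extension).
#' @param width,height device size in pixels (png) or inches (svg).
#' @return `path` invisibly, or `NULL` for an empty archive.
#' @export
plot_front <- function(archive, path, width = 800, height = 600) {
  if (!length(archive$designs)) {
    warning("archive is empty; no plot written", call. = FALSE)
    return(invisible(NULL))
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height),
         svg = grDevices::svg(path, width = width / 100, height = height / 100),
         stop("unsupported plot format: .", ext, call. = FALSE))
  on.exit(grDevices::dev.off())
  F <- archive$fitness
  cs <- F[, 3]
  pal <- grDevices::colorRampPalette(c("#313695", "#ffffbf", "#a50026"))(101)
  idx <- 1 + round(100 * (cs - (-1)) / 2)  # CS in [-1, 1]
  graphics::layout(matrix(1:2, 1, 2), widths = c(5, 1))
  graphics::par(mar = c(4.5, 4.5, 2, 1))
  graphics::plot(F[, 1], F[, 2], pch = 21, cex = 1.6, bg = pal[idx],
                 xlab = "growth rate (1/h)",
                 ylab = "guaranteed product flux (mmol/gDW/h)",
                 main = "Pareto front of knockout designs")
  graphics::par(mar = c(4.5, 1, 2, 3))
  z <- matrix(seq(-1, 1, length.out = 101), nrow = 1)
  graphics::image(1, seq(-1, 1, length.out = 101), z, col = pal,
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("coupling strength", side = 4, line = 2, cex = 0.9)
  invisible(path)
}
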