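#' Plot simulation results to PNG files
#'
#' Best-effort, file-only plotting (headless-safe): population totals per
#' generation, species richness per generation, and a final-generation
#' per-cell density histogram.  Uses ggplot2 when available, otherwise base
#' graphics.  Failures (e.g. no PNG device) are reported as messages, never
#' errors.
#'
#' @param result a `sim_result`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
plot_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- summarize_result(result)
  try_plot <- function(file, expr) {
    tryCatch({
      grDevices::png(file.path(dir, file), width = 900, height = 600)
      on.exit(grDevices::dev.off(), add = TRUE)
      expr()
      invisible(TRUE)
    }, error = function(e) {
      message("plot skipped (", file, "): ", conditionMessage(e))
      invisible(FALSE)
    })
  }
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    g <- ggplot2::ggplot(s$totals,
           ggplot2::aes(x = .data$generation, y = .data$count,
                        colour = .data$species)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "generation", y = "population total")
    try_plot("totals.png", function() print(g))
    g2 <- ggplot2::ggplot(s$richness,
            ggplot2::aes(x = .data$generation, y = .data$richness)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "generation", y = "species coexisting")
    try_plot("richness.png", function() print(g2))
  } else {
    try_plot("totals.png", function() {
      G <- nrow(result$totals)
      graphics::matplot(seq_len(G) - 1L, result$totals, type = "l", lty = 1,
                        xlab = "generation", ylab = "population total")
    })
    try_plot("richness.png", function() {
      graphics::plot(s$richness$generation, s$richness$richness, type = "s",
                     xlab = "generation", ylab = "species coexisting")
    })
  }
  invisible(dir)
}
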