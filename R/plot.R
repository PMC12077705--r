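#' Plot derived PFS endpoints
#'
#' Two-panel base-graphics display: (a) boxplots of PFS months by method,
#' and (b) automated versus clinical-standard PFS as a scatterplot with the
#' identity line (points above it: the automated date came earlier) and a
#' per-method ordinary-least-squares trendline.
#'
#' @param x A `pfs_endpoints` object from [derive_pfs()].
#' @param which `"both"`, `"box"` or `"scatter"`.
#' @param ... Passed to [graphics::boxplot()] / [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pfs_endpoints <- function(x, which = c("both", "box", "scatter"), ...) {
  which <- match.arg(which)
  wide <- aggregate_pfs(x$results)
  methods <- x$methods
  if (which == "both") {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  if (which %in% c("both", "box")) {
    graphics::boxplot(wide[, methods],
      ylab = "PFS (months from CRT end)",
      main = "PFS by derivation method", ...
    )
  }
  if (which %in% c("both", "scatter") && "clinical" %in% methods) {
    auto <- setdiff(methods, "clinical")
    cols <- grDevices::hcl.colors(max(length(auto), 2L), "Dark 3")
    lim <- range(unlist(wide[, methods]), na.rm = TRUE)
    graphics::plot(NA,
      xlim = lim, ylim = lim,
      xlab = "Clinical-standard PFS (months)",
      ylab = "Automated PFS (months)",
      main = "Automated vs clinical PFS", ...
    )
    graphics::abline(0, 1, col = "darkgreen", lwd = 2)
    for (i in seq_along(auto)) {
      m <- auto[i]
      ok <- !is.na(wide[[m]]) & !is.na(wide$clinical)
      graphics::points(wide$clinical[ok], wide[[m]][ok],
        col = cols[i], pch = 16
      )
      if (sum(ok) >= 3 && length(unique(wide$clinical[ok])) > 1) {
        tr <- ols_trend(wide$clinical[ok], wide[[m]][ok])
        graphics::abline(tr$intercept, tr$slope, col = cols[i], lty = 2)
      }
    }
    graphics::legend("topleft",
      legend = auto, col = cols[seq_along(auto)],
      pch = 16, bty = "n"
    )
  }
  invisible(x)
}
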