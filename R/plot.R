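# Profile plotting, following the field's colour convention:
# T blue, O red, M green.

#' Plot T, O and M profiles of a unit
#'
#' Line plot of the theoretical (blue), observed (red) and modified
#' (green) hydrophobicity distributions along the unit, with the fitted K
#' and RD in the title. Optional residue annotations (catalytic sites,
#' interface positions) are drawn as points along the x axis.
#'
#' @param x an [EffectiveStructure-class] or a [profileTable()] data.frame.
#' @param config a [fodConfig()] list (ignored for a precomputed table).
#' @param annotate optional integer vector of unit positions to mark.
#' @param ... passed to [graphics::matplot()].
#' @return the profile table, invisibly.
#' @export
plotProfiles <- function(x, config = fodConfig(), annotate = NULL, ...) {
  tb <- if (is.data.frame(x)) x else profileTable(x, config)
  m <- as.matrix(tb[, c("T", "O", "M")])
  pos <- seq_len(nrow(tb))
  graphics::matplot(pos, m, type = "l", lty = 1, lwd = 2,
                    col = c("blue", "red", "darkgreen"),
                    xlab = "residue (unit order)", ylab = "hydrophobicity",
                    main = sprintf("%s   RD = %.3f, K = %.1f",
                                   attr(tb, "unitLabel"),
                                   attr(tb, "rd"), attr(tb, "k")), ...)
  if (!is.null(annotate))
    graphics::points(annotate, rep(0, length(annotate)), pch = 19,
                     col = "black")
  graphics::legend("topright", legend = c("T", "O", "M"), lty = 1, lwd = 2,
                   col = c("blue", "red", "darkgreen"), bty = "n")
  invisible(tb)
}
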