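#' Plot amplitude survival curves with and without the reference set
#'
#' Log-scale survival curves P(amplitude > a) for all genes (solid) and for
#' all genes excluding the reference set (dashed); the detected threshold,
#' when any, is marked by a vertical line. The amplitude at which the two
#' curves start to separate is the natural cutoff for calling genes
#' periodically expressed.
#'
#' @param report a \linkS4class{ThresholdReport}.
#' @param main plot title.
#' @export
plotSurvivalCurves <- function(report, main = "POP amplitude survival curves") {
    keep <- report@survivalAll > 0 | report@survivalExcluded > 0
    g <- report@grid[keep]
    ymin <- min(c(report@survivalAll[report@survivalAll > 0],
                  report@survivalExcluded[report@survivalExcluded > 0]))
    graphics::plot(g, pmax(report@survivalAll[keep], ymin), type = "s",
                   log = "y", xlab = "POP amplitude a",
                   ylab = "P(amplitude > a)", main = main, lwd = 2)
    graphics::lines(g, pmax(report@survivalExcluded[keep], ymin), type = "s",
                    lty = 2, lwd = 2)
    if (!is.na(report@threshold))
        graphics::abline(v = report@threshold, col = "grey40", lty = 3)
    graphics::legend("bottomleft",
                     legend = c("all genes", "excluding reference set",
                                if (!is.na(report@threshold))
                                    sprintf("threshold = %.3g", report@threshold)),
                     lty = c(1, 2, if (!is.na(report@threshold)) 3),
                     lwd = c(2, 2, if (!is.na(report@threshold)) 1),
                     bty = "n")
    invisible(NULL)
}

#' Polar scatter of per-gene POP coefficients
#'
#' Plots each gene at radius = amplitude and angle = phase; an optional
#' group labelling (e.g. cell-cycle stage clusters) colours the points.
#' Genes expressed at the same stage of the cycle cluster at similar
#' angles.
#'
#' @param table a \linkS4class{GenePopTable}.
#' @param groups optional named vector mapping gene identifier -> label;
#'   unlabelled genes are drawn in grey.
#' @param main plot title.
#' @export
plotPopPolar <- function(table, groups = NULL,
                         main = "POPs in polar coordinates") {
    th <- table$phase * pi / 180
    r <- table$amplitude
    x <- r * cos(th)
    y <- r * sin(th)
    lim <- max(r) * 1.1
    col <- rep("grey70", nrow(table))
    if (!is.null(groups)) {
        lab <- unlist(groups)[match(table$gene, names(unlist(groups)))]
        lv <- sort(unique(stats::na.omit(lab)))
        pal <- grDevices::hcl.colors(max(3, length(lv)), "Dark 3")
        col[!is.na(lab)] <- pal[match(lab[!is.na(lab)], lv)]
    }
    graphics::plot(x, y, asp = 1, xlim = c(-lim, lim), ylim = c(-lim, lim),
                   pch = 16, cex = 0.6, col = col, xlab = "r cos(theta)",
                   ylab = "r sin(theta)", main = main)
    graphics::symbols(0, 0, circles = max(r), inches = FALSE, add = TRUE,
                      fg = "grey80")
    graphics::abline(h = 0, v = 0, col = "grey90")
    if (!is.null(groups)) {
        graphics::legend("topright", legend = lv, col = pal[seq_along(lv)],
                         pch = 16, bty = "n", cex = 0.8)
    }
    invisible(NULL)
}
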