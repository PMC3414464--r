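# The area-versus-NII plot: NII on x, area on y, one color per class,
# reference ellipse and rectangular threshold lines overlaid. The ellipse
# visualizes the reference cloud; the dashed lines are the actual class
# boundaries.

.NMA_COLORS <- c(N = "#4daf4a", I = "#e41a1c", LR = "#377eb8",
                 LI = "#984ea3", SR = "#ff7f00", S = "#999999",
                 SI = "#a65628")

.plotNMAPanel <- function(table, model) {
    th <- nmaThresholds(model)
    ell <- ellipseOutline(model)
    xr <- range(c(table$NII, ell[, "nii"], th["niiSi"]))
    yr <- range(c(table$Area, ell[, "area"]))
    graphics::plot(table$NII, table$Area, col = .NMA_COLORS[as.character(table$Class)],
                   pch = 16, cex = 0.8, xlab = "NII", ylab = "Area",
                   xlim = xr + c(-0.05, 0.05) * diff(xr),
                   ylim = yr + c(-0.05, 0.05) * diff(yr),
                   main = "Nuclear morphometric analysis")
    graphics::lines(ell[, "nii"], ell[, "area"], col = "black", lwd = 1.5)
    graphics::abline(h = th[c("areaLow", "areaHigh")], lty = 2, col = "grey40")
    graphics::abline(v = th[c("niiIrr", "niiSi")], lty = 2, col = "grey40")
    summ <- summarizePopulations(table)
    labs <- sprintf("%s: %.1f%%", summ$class, summ$percent)
    graphics::legend("topright", legend = labs, col = .NMA_COLORS, pch = 16,
                     cex = 0.8, bg = "white")
    labs
}

#' Plot the NMA classification
#'
#' Scatter of area versus NII colored by class, with the normal-reference
#' ellipse, the four threshold lines and a legend carrying the per-class
#' percentages. Written as both PNG and SVG next to each other.
#'
#' @param table classified measurement data.frame (NII and Class present).
#' @param model the \linkS4class{ReferenceModel} used for classification.
#' @param file output path; the extension is replaced by .png and .svg.
#' @param width,height device size in inches.
#' @return invisibly, a list with nPoints, legend labels, the files written
#'   and the ellipse center.
#' @export
plotNMA <- function(table, model, file, width = 7, height = 5) {
    if (nrow(table) == 0L) stop("empty table")
    if (!all(c("NII", "Class") %in% names(table)))
        stop("table must carry NII and Class columns")
    base <- sub("\\.(png|svg)$", "", file)
    files <- paste0(base, c(".png", ".svg"))
    grDevices::png(files[1], width = width, height = height, units = "in",
                   res = 150)
    labs <- .plotNMAPanel(table, model)
    grDevices::dev.off()
    grDevices::svg(files[2], width = width, height = height)
    .plotNMAPanel(table, model)
    grDevices::dev.off()
    invisible(list(nPoints = nrow(table), legend = labs, files = files,
                   ellipseCenter = c(nii = model@meanNII,
                                     area = model@meanArea)))
}
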