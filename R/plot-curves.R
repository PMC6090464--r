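# Figure-analogue rendering of the ensemble-averaged sweep curves.

plotKinds <- c("mi_vs_n", "lcc_vs_n", "mi_vs_lcc", "clustering_vs_n",
               "delta_clustering_vs_lcc", "ks_vs_n", "ks_vs_lcc")

requireColumns <- function(et, cols) {
  bad <- cols[vapply(cols, function(cl)
    is.null(et[[cl]]) || all(is.na(et[[cl]])), logical(1))]
  if (length(bad))
    stop(sprintf("table carries no usable values for column(s): %s",
                 paste(bad, collapse = ", ")))
}

perP <- function(et) split(et, et$p)

#' Plot ensemble-averaged sweep curves
#'
#' Renders one of the standard views of a sweep: mean mutual information
#' versus threshold multiplier per activation density ("mi_vs_n"), largest
#' component fraction versus n ("lcc_vs_n"), mutual information against
#' component fraction per p ("mi_vs_lcc"), clustering coefficient versus n
#' ("clustering_vs_n"), stepwise clustering change against component
#' fraction ("delta_clustering_vs_lcc"), and the KS distance of both
#' distribution models versus n ("ks_vs_n") or against the component
#' fraction ("ks_vs_lcc"). The device is chosen from the file extension
#' (.pdf or .png).
#'
#' @param result a [SweepResult-class].
#' @param kind one of the seven curve kinds above.
#' @param path image file to write.
#' @return the path, invisibly.
#' @export
plotCurves <- function(result, kind, path) {
  stopifnot(is(result, "SweepResult"))
  if (!kind %in% plotKinds)
    stop(sprintf("unknown kind '%s'; available: %s", kind,
                 paste(plotKinds, collapse = ", ")))
  et <- result@ensembleTable
  if (!nrow(et)) stop("empty sweep table")

  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    grDevices::png(path, width = 900, height = 650)
  } else {
    grDevices::pdf(path, width = 7, height = 5)
  }
  on.exit(grDevices::dev.off())

  drawPerP <- function(xcol, ycol, xlab, ylab) {
    requireColumns(et, c(xcol, ycol))
    groups <- perP(et)
    xs <- unlist(lapply(groups, `[[`, xcol))
    ys <- unlist(lapply(groups, `[[`, ycol))
    plot(range(xs, na.rm = TRUE), range(ys, na.rm = TRUE), type = "n",
         xlab = xlab, ylab = ylab)
    for (g in seq_along(groups)) {
      gd <- groups[[g]]
      lines(gd[[xcol]], gd[[ycol]], col = g, lty = g)
      points(gd[[xcol]], gd[[ycol]], col = g, pch = g)
    }
    legend("topright", legend = sprintf("p = %g", as.numeric(names(groups))),
           col = seq_along(groups), lty = seq_along(groups),
           pch = seq_along(groups), bty = "n")
  }
  drawSingle <- function(xcol, ycol, xlab, ylab) {
    requireColumns(et, c(xcol, ycol))
    gd <- et[!duplicated(et$n), , drop = FALSE]
    gd <- gd[order(gd$n), , drop = FALSE]
    plot(gd[[xcol]], gd[[ycol]], type = "b", xlab = xlab, ylab = ylab)
  }
  drawModels <- function(xcol, xlab) {
    requireColumns(et, c(xcol, "ks_boundary_power"))
    gd <- et[!duplicated(et$n), , drop = FALSE]
    gd <- gd[order(gd$n), , drop = FALSE]
    ys <- cbind(gd$ks_boundary_power, gd$ks_truncated_power_law)
    graphics::matplot(gd[[xcol]], ys, type = "b", pch = 1:2, col = 1:2,
                      lty = 1:2, xlab = xlab, ylab = "KS distance")
    legend("topleft", legend = c("boundary power", "truncated power law"),
           col = 1:2, lty = 1:2, pch = 1:2, bty = "n")
  }

  switch(kind,
    mi_vs_n = drawPerP("n", "m", "threshold multiplier n",
                       "mean mutual information (nats)"),
    lcc_vs_n = drawSingle("n", "lcc_fraction", "threshold multiplier n",
                          "largest component fraction"),
    mi_vs_lcc = drawPerP("lcc_fraction", "m", "largest component fraction",
                         "mean mutual information (nats)"),
    clustering_vs_n = drawSingle("n", "clustering",
                                 "threshold multiplier n",
                                 "clustering coefficient C"),
    delta_clustering_vs_lcc = drawSingle("lcc_fraction", "delta_clustering",
                                         "largest component fraction",
                                         "Delta C"),
    ks_vs_n = drawModels("n", "threshold multiplier n"),
    ks_vs_lcc = drawModels("lcc_fraction", "largest component fraction"))
  invisible(path)
}
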