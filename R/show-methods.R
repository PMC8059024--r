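#' @describeIn DCorResult-class compact display of the test result.
#' @param object object to display.
setMethod("show", "DCorResult", function(object) {
    cat("Gene-set distance association test\n")
    if (!is.na(object@nGenes))
        cat("  genes matched:", object@nGenes, "\n")
    cat(sprintf("  n = %d subjects, df = %s\n", object@n,
                format(object@df)))
    cat(sprintf("  distance correlation r_d = %.6g\n", object@rd))
    cat(sprintf("  t = %.6g, one-sided p = %.6g\n", object@td, object@pT))
    if (!is.na(object@pPerm))
        cat(sprintf("  permutation p = %.6g (B = %d)\n", object@pPerm,
                    as.integer(object@nPerm)))
    invisible(object)
})

#' @describeIn ScreenResult-class display the top of the screen table.
#' @param object object to display.
setMethod("show", "ScreenResult", function(object) {
    tab <- object@results
    cat("Gene-set screen:", nrow(tab), "sets (",
        sum(tab$status != "ok"), "flagged ), FDR method:",
        object@fdrMethod, "\n")
    print(utils::head(tab, 10), row.names = FALSE, digits = 4)
    if (nrow(tab) > 10) cat("  ... and", nrow(tab) - 10, "more rows\n")
    invisible(object)
})

#' @describeIn EliminationTrace-class summarize the elimination path.
#' @param object object to display.
setMethod("show", "EliminationTrace", function(object) {
    cat("Backward elimination over", length(object@subsets[[1]]), "genes\n")
    cat("  best subset (", length(object@bestSubset), "genes ):",
        paste(object@bestSubset, collapse = ", "), "\n")
    cat(sprintf("  best p = %.6g  [selection-biased; not a Type I error rate]\n",
                object@bestP))
    invisible(object)
})

#' @describeIn GeneSet-class one-line display.
#' @param object object to display.
setMethod("show", "GeneSet", function(object) {
    cat("GeneSet \"", object@name, "\": ", length(object@genes), " genes\n",
        sep = "")
    invisible(object)
})

#' @describeIn SimulationConfig-class one-line display.
#' @param object object to display.
setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig: collection %s, %s endpoint, %s association, n = %d, reps = %d\n",
        object@collection, object@endpoint, object@association, object@n,
        object@reps))
    invisible(object)
})
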