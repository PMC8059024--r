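#' Read an expression matrix from TSV/CSV
#'
#' Loads a delimited numeric matrix with gene and sample identifiers,
#' validates it (unique identifiers, numeric cells, no missing values —
#' offending cells are named in the error), and returns it in the internal
#' subjects x genes orientation. The on-disk default is genes in rows and
#' samples in columns, the common convention for expression tables; pass
#' `orientation = "samples_x_genes"` for pre-transposed files.
#'
#' @param path file path; fields separated by tabs (default) or the `sep`
#'   given. First row = column identifiers, first column = row identifiers.
#' @param orientation `"genes_x_samples"` (default) or `"samples_x_genes"`.
#' @param sep field separator; defaults to tab, use `","` for CSV.
#' @return numeric matrix, subjects in rows, genes in columns.
#' @export
readExpression <- function(path, orientation = c("genes_x_samples", "samples_x_genes"),
                           sep = "\t") {
    orientation <- match.arg(orientation)
    tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             comment.char = "")
    ids <- as.character(tab[[1]])
    if (anyDuplicated(ids))
        stop("duplicate row identifiers: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (anyDuplicated(colnames(tab)[-1]))
        stop("duplicate column identifiers: ",
             paste(unique(colnames(tab)[-1][duplicated(colnames(tab)[-1])]),
                   collapse = ", "))
    vals <- tab[, -1, drop = FALSE]
    for (j in seq_along(vals)) {
        v <- vals[[j]]
        if (is.character(v)) v <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(v))
        if (length(bad))
            stop("missing or non-numeric value at row \"", ids[bad[1]],
                 "\", column \"", colnames(vals)[j], "\"")
        vals[[j]] <- v
    }
    M <- as.matrix(vals)
    rownames(M) <- ids
    if (orientation == "genes_x_samples") M <- t(M)
    M
}

#' Write an expression matrix
#'
#' Inverse of [readExpression()]: writes the internal subjects x genes
#' matrix in the requested on-disk orientation. Round-tripping reproduces
#' the matrix and identifiers exactly (up to numeric formatting precision
#' of 15 significant digits).
#'
#' @param X subjects x genes numeric matrix with dimnames.
#' @inheritParams readExpression
#' @export
writeExpression <- function(path, X, orientation = c("genes_x_samples", "samples_x_genes"),
                            sep = "\t") {
    orientation <- match.arg(orientation)
    M <- if (orientation == "genes_x_samples") t(X) else X
    df <- data.frame(id = rownames(M), M, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- ""
    utils::write.table(format(df, digits = 15, trim = TRUE), path, sep = sep,
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Parses the tab-separated GMT format: each line is
#' `name <TAB> description <TAB> gene1 <TAB> gene2 ...`. Duplicate genes
#' within a set are removed with a warning; lines with fewer than three
#' fields raise an error naming the line; an empty file (or one with no
#' sets) is an error.
#'
#' @param path GMT file path.
#' @return named list of [GeneSet-class] objects, in file order.
#' @export
readGMT <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) stop("empty gene-set collection: ", path)
    sets <- lapply(seq_along(lines), function(i) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        f <- trimws(f)
        f <- f[nzchar(f) | seq_along(f) <= 2]
        if (length(f) < 3)
            stop("malformed GMT line ", i, ": expected name, description, ",
                 "and at least one gene")
        genes <- f[-(1:2)]
        if (anyDuplicated(genes)) {
            warning("duplicate gene(s) in set \"", f[1], "\" (line ", i,
                    "); deduplicated")
            genes <- unique(genes)
        }
        new("GeneSet", name = f[1], description = f[2], genes = genes)
    })
    names(sets) <- vapply(sets, function(s) s@name, character(1))
    sets
}

#' Read a phenotype table and construct an endpoint
#'
#' Loads a delimited phenotype table (first column = subject identifiers)
#' and builds a typed endpoint from the named column(s), aligned to the
#' subjects of an expression matrix by an explicit inner join. Subjects
#' present on only one side are dropped with a message reporting the count;
#' the analysis n is the post-join count.
#'
#' @param path phenotype TSV/CSV path.
#' @param endpointType `"quantitative"`, `"categorical"`, or `"survival"`.
#' @param column column name for quantitative/categorical endpoints.
#' @param timeCol,statusCol column names for survival endpoints; status
#'   must be coded 1 = event, 0 = censored, times must be positive.
#' @param subjects optional character vector (e.g. `rownames(X)`) to align
#'   against; when given, the returned endpoint follows this ordering.
#' @param sep field separator, default tab.
#' @return an [Endpoint-class]; the retained subject identifiers are in
#'   `@subjectIds`.
#' @export
readPhenotype <- function(path, endpointType = c("quantitative", "categorical", "survival"),
                          column = NULL, timeCol = NULL, statusCol = NULL,
                          subjects = NULL, sep = "\t") {
    endpointType <- match.arg(endpointType)
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             comment.char = "")
    ids <- as.character(tab[[1]])
    if (anyDuplicated(ids))
        stop("duplicate subject identifiers in phenotype table")
    if (!is.null(subjects)) {
        keep <- intersect(subjects, ids)
        dropPheno <- length(ids) - length(keep)
        dropExpr <- length(subjects) - length(keep)
        if (length(keep) == 0) stop("no subjects shared between tables")
        if (dropPheno > 0 || dropExpr > 0)
            message("inner join dropped ", dropExpr, " expression and ",
                    dropPheno, " phenotype subject(s); analysis n = ",
                    length(keep))
        tab <- tab[match(keep, ids), , drop = FALSE]
        ids <- keep
    }
    getCol <- function(nm) {
        if (is.null(nm) || !nm %in% colnames(tab))
            stop("column \"", nm, "\" not found in phenotype table")
        tab[[nm]]
    }
    switch(endpointType,
        quantitative = {
            v <- getCol(column)
            if (!is.numeric(v) || !all(is.finite(v)))
                stop("quantitative endpoint column \"", column,
                     "\" must be finite numeric")
            quantitativeEndpoint(v, subjectIds = ids)
        },
        categorical = categoricalEndpoint(getCol(column), subjectIds = ids),
        survival = {
            tm <- getCol(timeCol)
            st <- getCol(statusCol)
            if (!is.numeric(tm) || any(!is.finite(tm) | tm <= 0))
                stop("survival times in \"", timeCol,
                     "\" must be positive finite numbers")
            if (!all(st %in% c(0, 1)))
                stop("status column \"", statusCol,
                     "\" must be coded 1 = event, 0 = censored")
            survivalEndpoint(tm, st, subjectIds = ids)
        })
}

#' Write a screen result table
#'
#' Writes the per-set table of a [ScreenResult-class] as TSV with p- and
#' q-values printed to 6 significant digits (ordering and q-values are
#' computed on the full-precision values before formatting).
#'
#' @param x a [ScreenResult-class].
#' @param path output file path.
#' @export
writeScreenResult <- function(x, path) {
    tab <- resultsTable(x)
    for (cl in c("rd", "td", "pT", "pPerm", "q"))
        tab[[cl]] <- signif(tab[[cl]], 6)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
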