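#' Accessors for GenotypePanel
#'
#' `dosage()` returns the SNPs x lines integer dosage matrix (copies of
#' `allele_b`, `NA` missing). `snpMap()` returns the SNP map as a data.frame.
#' `lineIds()` returns the line identifiers. `groupAssignment()` returns the
#' line-to-group assignment as a named character vector (or `NULL` when none
#' is set); the replacement form accepts a named character vector or a
#' two-column data.frame (`line_id`, `group`).
#'
#' @param x a [GenotypePanel-class]
#' @param value group assignment (see description)
#' @return see description
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname panel-accessors
#' @export
setMethod("dosage", "GenotypePanel", function(x) assay(x, "dosage"))

#' @rdname panel-accessors
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' @rdname panel-accessors
#' @export
setMethod("snpMap", "GenotypePanel", function(x) {
    df <- as.data.frame(rowData(x))
    rownames(df) <- NULL
    df[, c("snp_id", "chromosome", "position_bp", "allele_a", "allele_b")]
})

#' @rdname panel-accessors
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' @rdname panel-accessors
#' @export
setMethod("lineIds", "GenotypePanel", function(x) colnames(x))

#' @rdname panel-accessors
#' @export
setGeneric("groupAssignment", function(x) standardGeneric("groupAssignment"))

#' @rdname panel-accessors
#' @export
setMethod("groupAssignment", "GenotypePanel", function(x) {
    cd <- colData(x)
    if (!("group" %in% colnames(cd))) return(NULL)
    stats::setNames(as.character(cd$group), rownames(cd))
})

#' @rdname panel-accessors
#' @export
setGeneric("groupAssignment<-",
           function(x, value) standardGeneric("groupAssignment<-"))

#' @rdname panel-accessors
#' @export
setMethod("groupAssignment<-", "GenotypePanel", function(x, value) {
    if (is.data.frame(value)) {
        if (ncol(value) < 2)
            stop("group data.frame needs columns line_id, group")
        value <- stats::setNames(as.character(value[[2]]),
                                 as.character(value[[1]]))
    }
    if (is.null(names(value)))
        stop("group assignment must be named by line id")
    if (any(!nzchar(value)) || anyNA(value))
        stop("group labels must be non-empty")
    unknown <- setdiff(names(value), lineIds(x))
    if (length(unknown))
        stop("assigned line id(s) not in panel: ",
             paste(head(unknown, 5), collapse = ", "))
    g <- rep(NA_character_, ncol(x))
    names(g) <- lineIds(x)
    g[names(value)] <- value
    colData(x)$group <- unname(g)
    x
})

#' Lines belonging to one group
#'
#' @param x a [GenotypePanel-class] with a group assignment
#' @param group group label
#' @return character vector of line ids
#' @export
groupLines <- function(x, group) {
    g <- groupAssignment(x)
    if (is.null(g)) stop("panel has no group assignment")
    names(g)[!is.na(g) & g == group]
}
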