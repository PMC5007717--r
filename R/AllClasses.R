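#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#'   colData<-
NULL

#' GenotypePanel: SNP genotypes for a panel of inbred lines
#'
#' A `GenotypePanel` holds unphased biallelic SNP calls for a panel of
#' (near-)inbred lines as a [SummarizedExperiment::SummarizedExperiment]
#' with SNPs as rows and lines as columns. The single assay, `"dosage"`,
#' is an integer matrix counting copies of `allele_b` per call:
#' 0 = homozygous `allele_a`, 1 = heterozygous, 2 = homozygous `allele_b`,
#' `NA` = missing. The SNP map (id, chromosome, 1-based physical position,
#' the two allele codes) lives in `rowData`; an optional line-to-group
#' assignment lives in `colData$group`, with `"Mixed"` reserved for lines
#' not confidently assigned.
#'
#' Every statistic in the package is a function of the dosage matrix and
#' the map, so statistics symmetric in allele labelling are invariant to
#' which allele of a SNP is designated `allele_b`.
#'
#' @slot .dummy unused; the class only adds validity on top of
#'   `SummarizedExperiment`.
#'
#' @seealso [GenotypePanel()] for construction, [readHapMap()] and
#'   [readGenotypeTable()] for file input.
#' @export
setClass("GenotypePanel", contains = "SummarizedExperiment")

.validGenotypePanel <- function(object) {
    msg <- character()
    if (!("dosage" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'dosage' is required")
    rd <- rowData(object)
    need <- c("snp_id", "chromosome", "position_bp", "allele_a", "allele_b")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        return(paste("rowData lacks column(s):", paste(miss, collapse = ", ")))
    if (anyDuplicated(rd$snp_id))
        msg <- c(msg, "snp_id values must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "line ids must be unique")
    if (any(rd$allele_a == rd$allele_b))
        msg <- c(msg, "allele_a must differ from allele_b at every SNP")
    placed <- rd$chromosome != "unknown"
    if (any(placed & (is.na(rd$position_bp) | rd$position_bp < 1)))
        msg <- c(msg, "placed SNPs need position_bp >= 1")
    d <- assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
        msg <- c(msg, "dosage values must be in {0, 1, 2, NA}")
    if (length(msg)) msg else TRUE
}
setValidity("GenotypePanel", .validGenotypePanel)

#' Construct a GenotypePanel
#'
#' @param dosage integer matrix, SNPs x lines, entries in `{0, 1, 2, NA}`
#'   counting copies of `allele_b`. Row names are ignored; column names, if
#'   present, are taken as line ids when `lineIds` is missing.
#' @param map data.frame (or DataFrame) with columns `snp_id`, `chromosome`,
#'   `position_bp`, `allele_a`, `allele_b`, one row per SNP in the order of
#'   `dosage` rows. Chromosomes are character labels (`"1"`..`"10"` for
#'   maize, plus `"unknown"` for unplaced SNPs, which carry `NA` positions).
#' @param lineIds character vector of unique line ids (columns of `dosage`).
#' @param groups optional named character vector or two-column data.frame
#'   (`line_id`, `group`) assigning lines to groups; stored in
#'   `colData$group`. Lines without an assignment get `NA`.
#' @return A [GenotypePanel-class] object.
#' @examples
#' map <- data.frame(snp_id = c("s1", "s2"), chromosome = "1",
#'                   position_bp = c(100L, 200L),
#'                   allele_a = "A", allele_b = "G")
#' d <- matrix(c(0L, 2L, 1L, NA), nrow = 2,
#'             dimnames = list(NULL, c("L1", "L2")))
#' gp <- GenotypePanel(d, map)
#' gp
#' @export
GenotypePanel <- function(dosage, map, lineIds = colnames(dosage),
                          groups = NULL) {
    map <- as.data.frame(map)
    if (is.null(lineIds))
        stop("lineIds are required (or give dosage column names)")
    if (anyDuplicated(lineIds))
        stop("duplicate line ids: ",
             paste(unique(lineIds[duplicated(lineIds)]), collapse = ", "))
    if (nrow(map) != nrow(dosage) || length(lineIds) != ncol(dosage))
        stop("dosage dimensions do not match map rows x lineIds")
    storage.mode(dosage) <- "integer"
    dimnames(dosage) <- list(map$snp_id, lineIds)
    map$chromosome <- as.character(map$chromosome)
    map$position_bp <- as.integer(map$position_bp)
    cd <- DataFrame(row.names = lineIds)
    se <- SummarizedExperiment(
        assays = list(dosage = dosage),
        rowData = DataFrame(map, row.names = map$snp_id),
        colData = cd)
    gp <- new("GenotypePanel", se)
    if (!is.null(groups))
        groupAssignment(gp) <- groups
    validObject(gp)
    gp
}

#' @describeIn GenotypePanel-class compact display
#' @param object a `GenotypePanel`
#' @export
setMethod("show", "GenotypePanel", function(object) {
    d <- assay(object, "dosage")
    cat("GenotypePanel:", nrow(object), "SNPs x", ncol(object), "lines\n")
    chr <- unique(rowData(object)$chromosome)
    cat("  chromosomes:", paste(head(chr, 12), collapse = " "),
        if (length(chr) > 12) "..." else "", "\n")
    cat(sprintf("  missing: %.2f%%  heterozygous: %.2f%% of calls\n",
                100 * mean(is.na(d)),
                100 * mean(d == 1L, na.rm = TRUE)))
    g <- groupAssignment(object)
    if (!is.null(g)) {
        tb <- table(g, useNA = "no")
        cat("  groups:", paste(sprintf("%s(%d)", names(tb), tb),
                               collapse = " "), "\n")
    }
    invisible(NULL)
})
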