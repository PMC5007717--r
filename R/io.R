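#' Read a HapMap-dialect genotype file
#'
#' Parses the tab-separated HapMap text dialect: 11 metadata columns
#' (`rs#`, `alleles`, `chrom`, `pos`, `strand`, `assembly#`, `center`,
#' `protLSID`, `assayLSID`, `panelLSID`, `QCcode`) followed by one
#' two-letter genotype column per line. `alleles` is `"A/G"`-style; the
#' second allele becomes `allele_b`, the dosage-counted allele. Genotypes
#' `"NN"` and `"--"` are missing; heterozygote letter order is irrelevant
#' (`"AG"` and `"GA"` are the same call). Strand is ignored: array
#' genotypes are reported on a fixed strand.
#'
#' @param path file path
#' @return a [GenotypePanel-class]
#' @seealso [writeHapMap()], [readGenotypeTable()]
#' @export
readHapMap <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, comment.char = "",
                             colClasses = "character",
                             na.strings = character())
    meta <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
              "center", "protLSID", "assayLSID", "panelLSID", "QCcode")
    got <- colnames(tab)[seq_len(min(11L, ncol(tab)))]
    bad <- which(got != meta[seq_along(got)])
    if (ncol(tab) < 11L || length(bad))
        stop("malformed HapMap header: expected column '",
             meta[if (length(bad)) bad[1] else ncol(tab) + 1L],
             "' at position ", if (length(bad)) bad[1] else ncol(tab) + 1L)
    lines <- colnames(tab)[-seq_len(11L)]
    al <- strsplit(tab$alleles, "/", fixed = TRUE)
    if (any(lengths(al) != 2L))
        stop("malformed 'alleles' field; expected 'X/Y'")
    a <- vapply(al, `[`, "", 1L)
    b <- vapply(al, `[`, "", 2L)
    pos <- suppressWarnings(as.integer(tab$pos))
    map <- data.frame(snp_id = tab[["rs#"]], chromosome = tab$chrom,
                      position_bp = ifelse(tab$chrom == "unknown", NA, pos),
                      allele_a = a, allele_b = b)
    n_snp <- nrow(tab)
    d <- matrix(NA_integer_, n_snp, length(lines),
                dimnames = list(map$snp_id, lines))
    if (n_snp && length(lines)) {
        geno <- as.matrix(tab[, -seq_len(11L), drop = FALSE])
        c1 <- substr(geno, 1L, 1L)
        c2 <- substr(geno, 2L, 2L)
        okc <- c("N", "-")
        valid1 <- c1 == a | c1 == b | c1 %in% okc
        valid2 <- c2 == a | c2 == b | c2 %in% okc
        if (any(!valid1 | !valid2)) {
            idx <- which(!valid1 | !valid2, arr.ind = TRUE)[1, ]
            stop("invalid genotype letter at SNP '", map$snp_id[idx[1]],
                 "', line '", lines[idx[2]], "'")
        }
        d <- (c1 == b) + (c2 == b)
        d[c1 %in% okc | c2 %in% okc] <- NA_integer_
        storage.mode(d) <- "integer"
        dimnames(d) <- list(map$snp_id, lines)
    }
    GenotypePanel(d, map, lines)
}

#' Write a HapMap-dialect genotype file
#'
#' Emits the 11-metadata-column HapMap dialect accepted by [readHapMap()].
#' SNPs are written sorted by (chromosome, position), unplaced SNPs last;
#' homozygotes as doubled letters, heterozygotes as `allele_a` then
#' `allele_b`, missing as `"NN"`.
#'
#' @param panel a [GenotypePanel-class]
#' @param path output file path
#' @return invisibly, `path`
#' @export
writeHapMap <- function(panel, path) {
    map <- snpMap(panel)
    d <- dosage(panel)
    ord <- order(is.na(map$position_bp),
                 match(map$chromosome, .chromLevels(map$chromosome)),
                 map$position_bp)
    map <- map[ord, , drop = FALSE]
    d <- d[ord, , drop = FALSE]
    aa <- paste0(map$allele_a, map$allele_a)
    ab <- paste0(map$allele_a, map$allele_b)
    bb <- paste0(map$allele_b, map$allele_b)
    geno <- matrix("NN", nrow(d), ncol(d))
    for (j in seq_len(ncol(d))) {
        v <- d[, j]
        geno[, j] <- ifelse(is.na(v), "NN",
                            ifelse(v == 0L, aa, ifelse(v == 1L, ab, bb)))
    }
    out <- data.frame(`rs#` = map$snp_id,
                      alleles = paste0(map$allele_a, "/", map$allele_b),
                      chrom = map$chromosome,
                      pos = ifelse(is.na(map$position_bp), 0L,
                                   map$position_bp),
                      strand = "+", `assembly#` = "NA", center = "NA",
                      protLSID = "NA", assayLSID = "NA", panelLSID = "NA",
                      QCcode = "NA", check.names = FALSE)
    out <- cbind(out, as.data.frame(geno, optional = TRUE))
    colnames(out)[-seq_len(11L)] <- colnames(d)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a plain genotype dosage table
#'
#' Tab-separated dialect with header
#' `snp_id chrom pos allele_a allele_b <line1> <line2> ...`; one row per
#' SNP, dosage entries in `{0, 1, 2}` (count of `allele_b`) with `"."` for
#' missing. An empty data section yields a valid zero-SNP panel.
#'
#' @param path file path
#' @return a [GenotypePanel-class]
#' @seealso [writeGenotypeTable()]
#' @export
readGenotypeTable <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, comment.char = "",
                             colClasses = "character",
                             na.strings = character())
    fixed <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
    if (ncol(tab) < 5L || !identical(colnames(tab)[1:5], fixed))
        stop("malformed genotype-table header: expected columns ",
             paste(fixed, collapse = ", "))
    lines <- colnames(tab)[-seq_len(5L)]
    pos <- suppressWarnings(as.integer(tab$pos))
    map <- data.frame(snp_id = tab$snp_id, chromosome = tab$chrom,
                      position_bp = ifelse(tab$chrom == "unknown", NA, pos),
                      allele_a = tab$allele_a, allele_b = tab$allele_b)
    d <- matrix(NA_integer_, nrow(tab), length(lines),
                dimnames = list(map$snp_id, lines))
    if (nrow(tab) && length(lines)) {
        raw <- as.matrix(tab[, -seq_len(5L), drop = FALSE])
        ok <- raw %in% c("0", "1", "2", ".")
        if (!all(ok)) {
            idx <- which(!matrix(ok, nrow(raw)), arr.ind = TRUE)[1, ]
            stop("dosage entry '", raw[idx[1], idx[2]], "' at SNP '",
                 map$snp_id[idx[1]], "', line '", lines[idx[2]],
                 "' is not one of 0, 1, 2, .")
        }
        raw[raw == "."] <- NA
        d <- matrix(as.integer(raw), nrow(raw),
                    dimnames = list(map$snp_id, lines))
    }
    GenotypePanel(d, map, lines)
}

#' Write a plain genotype dosage table
#'
#' Canonical form of the dialect read by [readGenotypeTable()]: SNPs sorted
#' by (chromosome, position) with unplaced SNPs last, lines in panel order,
#' missing dosages as `"."`.
#'
#' @param panel a [GenotypePanel-class]
#' @param path output file path
#' @return invisibly, `path`
#' @export
writeGenotypeTable <- function(panel, path) {
    map <- snpMap(panel)
    d <- dosage(panel)
    ord <- order(is.na(map$position_bp),
                 match(map$chromosome, .chromLevels(map$chromosome)),
                 map$position_bp)
    map <- map[ord, , drop = FALSE]
    d <- d[ord, , drop = FALSE]
    chr <- matrix(as.character(d), nrow(d))
    chr[is.na(chr)] <- "."
    out <- data.frame(snp_id = map$snp_id, chrom = map$chromosome,
                      pos = ifelse(is.na(map$position_bp), "",
                                   as.character(map$position_bp)),
                      allele_a = map$allele_a, allele_b = map$allele_b)
    out <- cbind(out, as.data.frame(chr, optional = TRUE))
    colnames(out)[-seq_len(5L)] <- colnames(d)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a line-to-group assignment table
#'
#' Two-column tab-separated file with header `line_id<TAB>group`.
#'
#' @param path file path
#' @return named character vector mapping line id to group label
#' @export
readGroupsTable <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character")
    if (ncol(tab) < 2L)
        stop("groups table needs columns line_id, group")
    stats::setNames(tab[[2]], tab[[1]])
}
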