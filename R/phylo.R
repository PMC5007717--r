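#' Nei genetic distance between lines
#'
#' Per-line allele "frequencies" at a biallelic locus come from that
#' single line's genotype — (1, 0), (0.5, 0.5) or (0, 1) for the two
#' homozygotes and the heterozygote — and loci missing in either line of
#' a pair are skipped. The default is Nei's 1972 standard distance
#' \eqn{D = -\ln(J_{xy} / \sqrt{J_x J_y})}{D = -ln(Jxy / sqrt(Jx Jy))}
#' with \eqn{J} the across-loci means of allele-frequency products;
#' `method = "neiDA"` gives Nei's 1983 DA distance
#' \eqn{D_A = 1 - \frac{1}{L}\sum_l \sum_u \sqrt{x_{lu} y_{lu}}}{
#' DA = 1 - mean over loci of sum_u sqrt(x_u y_u)}.
#'
#' Identical lines get distance 0; a pair sharing no polymorphic overlap
#' such that \eqn{J_{xy} = 0} gets `Inf`; a pair with zero jointly called
#' loci gets `NA`.
#'
#' @param panel a [GenotypePanel-class]
#' @param method `"nei1972"` (default) or `"neiDA"`
#' @param lines optional subset of line ids
#' @return symmetric distance matrix (lines x lines, zero diagonal)
#' @export
neiDistance <- function(panel, method = c("nei1972", "neiDA"),
                        lines = NULL) {
    method <- match.arg(method)
    d <- dosage(panel)
    if (!is.null(lines)) d <- d[, lines, drop = FALSE]
    B <- d / 2                       # per-line freq of allele_b
    A <- 1 - B
    called <- !is.na(d)
    A0 <- A; A0[!called] <- 0
    B0 <- B; B0[!called] <- 0
    N <- crossprod(called)           # jointly called loci per pair
    if (method == "nei1972") {
        Sxy <- crossprod(A0) + crossprod(B0)
        U <- A0^2 + B0^2             # per-cell sum of squared freqs
        Sx <- t(U) %*% called        # Sx[i, j]: sum over loci called in both
        Jxy <- Sxy / N
        Jx <- Sx / N
        Jy <- t(Jx)
        ratio <- Jxy / sqrt(Jx * Jy)
        D <- -log(ratio)
        D[Jxy == 0] <- Inf
    } else {
        Sxy <- crossprod(sqrt(A0)) + crossprod(sqrt(B0))
        D <- 1 - Sxy / N
    }
    D[N == 0] <- NA_real_
    diag(D) <- 0
    dimnames(D) <- list(colnames(d), colnames(d))
    D
}

#' Neighbor-joining tree
#'
#' Saitou–Nei neighbor joining with the Studier–Keppler Q-criterion
#' \eqn{Q(i,j) = (r-2) d(i,j) - R_i - R_j}{Q(i,j) = (r-2)d(i,j) - Ri - Rj}.
#' Ties in Q are broken deterministically by the smallest (i, j) index
#' pair of the current distance matrix. On an additive matrix the
#' generating tree is reconstructed exactly. Negative branch-length
#' estimates are floored at zero (with a message) unless
#' `clampNegative = FALSE`.
#'
#' @param D symmetric distance matrix with finite entries, n >= 3,
#'   labelled rows/columns
#' @param clampNegative floor negative branch lengths at 0?
#' @return an unrooted [ape::phylo] tree with the input labels as tips
#' @export
neighborJoining <- function(D, clampNegative = TRUE) {
    D <- as.matrix(D)
    n <- nrow(D)
    if (n < 3L) stop("need at least 3 taxa")
    if (any(!is.finite(D)))
        stop("distance matrix has non-finite entries; filter loci ",
             "(e.g. drop loci private to single lines) and recompute")
    labs <- rownames(D)
    if (is.null(labs)) labs <- paste0("t", seq_len(n))
    nodeId <- seq_len(n)             # phylo ids of active clusters
    nextInternal <- n + 1L
    edges <- matrix(0L, 0L, 2L)
    lens <- numeric(0)
    nneg <- 0L
    while (length(nodeId) > 3L) {
        r <- nrow(D)
        R <- rowSums(D)
        Q <- (r - 2) * D - outer(R, R, `+`)
        diag(Q) <- Inf
        # smallest Q; ties broken by smallest (i, j) index pair
        ut <- which(upper.tri(Q), arr.ind = TRUE)
        q <- Q[ut]
        cand <- which(q <= min(q) + 1e-12)
        cand <- cand[order(ut[cand, 1], ut[cand, 2])][1]
        i <- ut[cand, 1]; j <- ut[cand, 2]
        li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
        lj <- D[i, j] - li
        newD <- (D[i, ] + D[j, ] - D[i, j]) / 2
        keep <- setdiff(seq_len(r), c(i, j))
        edges <- rbind(edges, c(nextInternal, nodeId[i]),
                       c(nextInternal, nodeId[j]))
        lens <- c(lens, li, lj)
        D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newD[keep]),
                    c(newD[keep], 0))
        D <- D2
        nodeId <- c(nodeId[keep], nextInternal)
        nextInternal <- nextInternal + 1L
    }
    # final three clusters: closed-form star resolution
    la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    edges <- rbind(edges, c(nextInternal, nodeId[1]),
                   c(nextInternal, nodeId[2]), c(nextInternal, nodeId[3]))
    lens <- c(lens, la, lb, lc)
    if (clampNegative && any(lens < 0)) {
        nneg <- sum(lens < 0)
        message(nneg, " negative branch-length estimate(s) floored at 0")
        lens <- pmax(lens, 0)
    }
    # renumber internal nodes so the final (degree-3) node is n+1, as ape
    # stores unrooted trees rooted at a trivial basal trichotomy
    nInternal <- nextInternal - n
    remap <- c(seq_len(n), rev(seq_len(nInternal)) + n)
    edges <- matrix(remap[edges], ncol = 2L)
    tree <- structure(list(edge = edges, edge.length = lens,
                           tip.label = labs, Nnode = nInternal),
                      class = "phylo")
    ape::reorder.phylo(tree, "cladewise")
}

#' Write a tree in Newick format
#'
#' Standard Newick with branch lengths and a terminating semicolon.
#' Labels containing Newick metacharacters or whitespace are
#' single-quoted (embedded quotes doubled).
#'
#' @param tree an [ape::phylo] tree
#' @param path output file path
#' @param digits significant digits for branch lengths
#' @return invisibly, the Newick string
#' @export
writeNewick <- function(tree, path, digits = 12) {
    quoteLab <- function(x) {
        bad <- grepl("[](),:;'\\[ \t]", x)
        x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
        x
    }
    n <- length(tree$tip.label)
    kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
    fmt <- function(len) format(len, digits = digits, trim = TRUE,
                                scientific = FALSE)
    rec <- function(node) {
        if (node <= n) return(quoteLab(tree$tip.label[node]))
        rows <- kids[[as.character(node)]]
        parts <- vapply(rows, function(e)
            paste0(rec(tree$edge[e, 2]), ":", fmt(tree$edge.length[e])),
            "")
        paste0("(", paste(parts, collapse = ","), ")")
    }
    root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
    s <- paste0(rec(root), ";")
    writeLines(s, path)
    invisible(s)
}
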