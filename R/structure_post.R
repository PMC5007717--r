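#' Evanno delta-K from admixture log-likelihood replicates
#'
#' Post-processes replicate log-likelihoods LnP(D) of an admixture model
#' run over a contiguous range of K. For each interior K,
#' \eqn{\Delta K = |\bar L(K+1) - 2 \bar L(K) + \bar L(K-1)| / s(K)}{
#' deltaK = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))},
#' the absolute second difference of the replicate means scaled by the
#' replicate standard deviation at K (n-1 denominator). Endpoints are
#' undefined, as is any K whose replicate standard deviation is zero
#' (noted via message). The statistic is invariant to adding a constant
#' to every log-likelihood.
#'
#' @param lnpd data.frame with columns `K` (integer) and `lnpd`
#'   (replicate log-likelihoods; `replicate` column optional)
#' @return data.frame per K: `K`, `n_replicates`, `mean_lnpd`, `sd_lnpd`,
#'   `delta_k` (`NA` at endpoints / zero-sd K)
#' @examples
#' tab <- data.frame(K = rep(2:4, each = 3),
#'                   lnpd = c(-1000, -1000, -1000,
#'                            -905, -900, -895,
#'                            -880, -880, -880))
#' deltaK(tab)
#' @export
deltaK <- function(lnpd) {
    stopifnot(all(c("K", "lnpd") %in% colnames(lnpd)))
    ks <- sort(unique(lnpd$K))
    if (length(ks) > 1 && any(diff(ks) != 1))
        stop("K values must be contiguous")
    m <- tapply(lnpd$lnpd, lnpd$K, mean)[as.character(ks)]
    s <- tapply(lnpd$lnpd, lnpd$K, stats::sd)[as.character(ks)]
    nrep <- tapply(lnpd$lnpd, lnpd$K, length)[as.character(ks)]
    dk <- rep(NA_real_, length(ks))
    for (t in seq_along(ks)) {
        if (t == 1L || t == length(ks)) next
        if (is.na(s[t]) || s[t] == 0) {
            message("sd of LnP(D) at K = ", ks[t],
                    " is zero or undefined; delta-K undefined there")
            next
        }
        dk[t] <- abs(m[t + 1L] - 2 * m[t] + m[t - 1L]) / s[t]
    }
    data.frame(K = ks, n_replicates = as.integer(nrep),
               mean_lnpd = as.numeric(m), sd_lnpd = as.numeric(s),
               delta_k = dk, row.names = NULL)
}

#' Threshold-based group assignment from membership coefficients
#'
#' Assigns each line to the component with the largest membership
#' coefficient when that coefficient reaches the threshold, otherwise to
#' the reserved `"Mixed"` class. Lowering the threshold never moves a
#' line from a named group to Mixed. The threshold used should be
#' recorded with any run (the appropriate value depends on the breeding
#' background of the panel).
#'
#' @param membership numeric matrix, lines x K, rows summing to 1
#'   (tolerance 1e-6); row names are line ids
#' @param labels character vector, one group label per component
#' @param threshold minimum coefficient for a named assignment
#'   (default 0.6, a conventional admixture cut)
#' @return named character vector: line id -> group label (or `"Mixed"`)
#' @export
assignGroups <- function(membership, labels, threshold = 0.6) {
    membership <- as.matrix(membership)
    if (length(labels) != ncol(membership))
        stop("need one label per membership component")
    if (any(membership < 0) ||
        any(abs(rowSums(membership) - 1) > 1e-6))
        stop("membership rows must be non-negative and sum to 1")
    best <- max.col(membership, ties.method = "first")
    val <- membership[cbind(seq_len(nrow(membership)), best)]
    out <- ifelse(val >= threshold, labels[best], "Mixed")
    names(out) <- rownames(membership)
    out
}

#' Read a log-likelihood replicate table
#'
#' Tab-separated file with header `K<TAB>replicate<TAB>lnpd`.
#'
#' @param path file path
#' @return data.frame suitable for [deltaK()]
#' @export
readLnpdTable <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t")
    stopifnot(all(c("K", "lnpd") %in% colnames(tab)))
    tab$K <- as.integer(tab$K)
    tab
}

#' Read a membership-coefficient table
#'
#' Tab-separated file with header `line_id<TAB>q1<TAB>...<TAB>qK`.
#'
#' @param path file path
#' @return numeric matrix (lines x K) with line ids as row names
#' @export
readMembershipTable <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- as.character(tab[[1]])
    storage.mode(m) <- "double"
    m
}
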