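#' Length-scaled TPM and count-scale abundance
#'
#' Converts gene-level counts and effective lengths into transcripts per
#' million, then into "length-scaled" count-scale values: TPM multiplied by
#' the gene's average effective length over samples, with each column
#' rescaled so it sums to the sample's library size.  The length-scaled
#' matrix is the quantity the expression filter ("average length-scaled
#' TPM >= 1 in at least one stage") is applied to.
#'
#' @param counts genes x samples non-negative matrix.
#' @param efflen genes x samples positive matrix of effective lengths (bp),
#'   or a per-gene vector.
#' @return list with matrices \code{tpm} (columns sum to 1e6, except
#'   all-zero columns which stay zero) and \code{lengthScaled} (columns sum
#'   to the column sums of \code{counts}).
#' @export
lengthScaledTPM <- function(counts, efflen) {
    counts <- as.matrix(counts)
    if (is.null(dim(efflen)))
        efflen <- matrix(efflen, nrow(counts), ncol(counts),
                         dimnames = dimnames(counts))
    if (any(efflen <= 0)) stop("zero or negative effective length")
    rate <- counts / efflen
    denom <- colSums(rate)
    tpm <- sweep(rate, 2, ifelse(denom > 0, denom, 1), "/") * 1e6
    tpm[, denom == 0] <- 0

    meanLen <- rowMeans(efflen)
    cfa <- tpm * meanLen
    libsize <- colSums(counts)
    csum <- colSums(cfa)
    ls <- sweep(cfa, 2, ifelse(csum > 0, libsize / csum, 0), "*")
    list(tpm = tpm, lengthScaled = ls)
}

#' Per-stage mean expression and expressed calls
#'
#' Averages a (length-scaled TPM) matrix over the replicates of each
#' developmental stage and calls a gene expressed in a stage when the mean
#' meets the threshold under the chosen comparator.
#'
#' @param mat genes x samples matrix (typically \code{lengthScaled} from
#'   [lengthScaledTPM()]).
#' @param stage character vector mapping each column to a stage; every
#'   column must be mapped.
#' @param threshold expression threshold (default 1).
#' @param comparator \code{">="} (default) or \code{">"}.
#' @return list with \code{mean} (genes x stages) and \code{expressed}
#'   (logical genes x stages).
#' @export
stageExpression <- function(mat, stage, threshold = 1,
                            comparator = c(">=", ">")) {
    comparator <- match.arg(comparator)
    if (length(stage) != ncol(mat) || anyNA(stage))
        stop("every sample column must be mapped to a stage")
    stages <- unique(stage)
    mean_ <- sapply(stages, function(s)
        rowMeans(mat[, stage == s, drop = FALSE]))
    if (is.null(dim(mean_)))
        mean_ <- matrix(mean_, nrow = 1,
                        dimnames = list(rownames(mat), stages))
    expressed <- if (comparator == ">=") mean_ >= threshold else
        mean_ > threshold
    list(mean = mean_, expressed = expressed)
}

#' Expression-intersection (UpSet) partition
#'
#' Assigns every gene to exactly one subset: the combination of stages in
#' which it is expressed.  Subset counts therefore sum to the number of
#' genes (the empty combination collects genes expressed nowhere).
#'
#' @param expressed logical genes x stages matrix (see [stageExpression()]).
#' @return data.frame with one row per stage combination: one logical
#'   column per stage, \code{subset} (label, "+"-joined stage names, "none"
#'   for the empty set) and \code{n}.
#' @export
expressionIntersections <- function(expressed) {
    stages <- colnames(expressed)
    combo <- apply(expressed, 1, function(z) paste(as.integer(z),
                                                   collapse = ""))
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(stages)))
    colnames(grid) <- stages
    key <- apply(grid, 1, function(z) paste(as.integer(z), collapse = ""))
    n <- as.integer(table(factor(combo, levels = key)))
    lab <- apply(grid, 1, function(z)
        if (!any(z)) "none" else paste(stages[as.logical(z)], collapse = "+"))
    out <- data.frame(grid, subset = lab, n = n, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization.  One sample is
#' chosen as reference (the one whose upper quartile of nonzero
#' library-scaled counts is closest to the mean upper quartile); for every
#' other sample, gene-wise log-ratios (M) and log-abundances (A) against
#' the reference are doubly trimmed (30% on M, 5% on A by default), and the
#' precision-weighted mean M is exponentiated into a scaling factor.
#' Factors are rescaled to have geometric mean 1, so a pure sequencing-depth
#' difference yields factors of exactly 1.
#'
#' @param counts genes x samples non-negative matrix; no all-zero columns.
#' @param libsizes per-sample library sizes (default column sums).
#' @param trim_m two-sided trim fraction on M-values (default 0.3).
#' @param trim_a two-sided trim fraction on A-values (default 0.05).
#' @return numeric vector of per-sample factors, geometric mean 1.
#'   Effective library sizes are \code{libsizes * factors}.
#' @export
tmmFactors <- function(counts, libsizes = colSums(counts), trim_m = 0.3,
                       trim_a = 0.05) {
    counts <- as.matrix(counts)
    if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
    if (any(colSums(counts) == 0)) stop("all-zero sample column")
    uq <- vapply(seq_len(ncol(counts)), function(j) {
        y <- counts[, j]
        stats::quantile(y[y > 0] / libsizes[j], 0.75, names = FALSE)
    }, numeric(1))
    ref <- which.min(abs(uq - mean(uq)))

    oneFactor <- function(j) {
        if (j == ref) return(1)
        yj <- counts[, j]; yr <- counts[, ref]
        keep <- yj > 0 & yr > 0
        yj <- yj[keep]; yr <- yr[keep]
        nj <- libsizes[j]; nr <- libsizes[ref]
        M <- log2((yj / nj) / (yr / nr))
        A <- 0.5 * log2((yj / nj) * (yr / nr))
        if (length(M) == 0L || max(abs(M)) < 1e-6) return(1)
        n <- length(M)
        loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
        loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
        keep2 <- rank(M) >= loM & rank(M) <= hiM &
            rank(A) >= loA & rank(A) <= hiA
        if (!any(keep2)) return(1)
        w <- (nj - yj) / (nj * yj) + (nr - yr) / (nr * yr)
        f <- sum(M[keep2] / w[keep2]) / sum(1 / w[keep2])
        if (!is.finite(f)) f <- 0
        2^f
    }
    f <- vapply(seq_len(ncol(counts)), oneFactor, numeric(1))
    f <- f / .geoMean(f)
    unname(f)
}

#' Negative-binomial conditional exact test for two groups
#'
#' Tests whether two groups of NB-distributed counts share a mean.
#' Libraries are first equalized by deterministically rescaling each
#' sample's counts to the geometric-mean library size; the group sums are
#' then compared under the conditional distribution of the first group's
#' sum given the total, with group-sum NB sizes \code{n_g / dispersion}.
#' At dispersion 0 this reduces exactly to the conditional binomial test.
#'
#' The default double-tail p-value is \code{min(1, 2 * min(lower, upper))}
#' with the observed outcome included in both tails; \code{tail = "smallp"}
#' instead sums all outcomes no more probable than the observed one.
#'
#' @param yA,yB non-negative count vectors for the two groups.
#' @param libsizes effective library sizes, ordered as \code{c(yA, yB)};
#'   default all equal.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2); >= 0.
#' @param tail "doubletail" (default) or "smallp".
#' @return p-value in (0, 1].
#' @export
nbExactTest <- function(yA, yB, libsizes = NULL, dispersion = 0,
                        tail = c("doubletail", "smallp")) {
    tail <- match.arg(tail)
    if (dispersion < 0) stop("dispersion must be >= 0")
    if (any(c(yA, yB) < 0)) stop("negative counts")
    nA <- length(yA); nB <- length(yB)
    if (is.null(libsizes)) libsizes <- rep(1, nA + nB)
    common <- .geoMean(libsizes)
    y <- c(yA, yB) * common / libsizes
    sA <- sum(y[seq_len(nA)]); sB <- sum(y[nA + seq_len(nB)])
    a <- round(sA); t <- round(sA + sB)
    if (t == 0) return(1)
    a <- min(a, t)
    x <- 0:t
    if (dispersion == 0) {
        logf <- stats::dbinom(x, t, nA / (nA + nB), log = TRUE)
    } else {
        mu <- t / (nA + nB)
        logf <- stats::dnbinom(x, size = nA / dispersion, mu = nA * mu,
                               log = TRUE) +
            stats::dnbinom(t - x, size = nB / dispersion, mu = nB * mu,
                           log = TRUE)
    }
    f <- exp(logf - max(logf))
    f <- f / sum(f)
    if (tail == "doubletail") {
        lower <- sum(f[x <= a])
        upper <- sum(f[x >= a])
        min(1, 2 * min(lower, upper))
    } else {
        min(1, sum(f[f <= f[a + 1L] * (1 + 1e-10)]))
    }
}

#' Moment-based NB dispersion estimation
#'
#' Estimates the negative-binomial dispersion phi (variance = mu + phi mu^2)
#' from replicated counts.  Counts are first rescaled to a common
#' (geometric-mean) library size; within-group sample means and variances
#' are then pooled across genes by inverting the NB variance function,
#' with negative estimates floored at 0.  In "trended" mode the pooled
#' estimate is computed within equal-occupancy log-abundance bins and
#' linearly interpolated over log mean abundance, so dispersion can vary
#' smoothly with expression strength.
#'
#' @param counts genes x samples matrix.
#' @param groups vector assigning samples to groups; within-group
#'   replication is required in at least one group.
#' @param libsizes effective library sizes (default column sums).
#' @param mode "common" or "trended".
#' @param bins number of abundance bins for the trend (default 10).
#' @return per-gene dispersion vector (constant in "common" mode).
#' @export
estimateDispersion <- function(counts, groups,
                               libsizes = colSums(counts),
                               mode = c("common", "trended"), bins = 10L) {
    mode <- match.arg(mode)
    counts <- as.matrix(counts)
    groups <- as.character(groups)
    tab <- table(groups)
    if (!any(tab >= 2L))
        stop("dispersion estimation requires replicates in at least one group")
    common <- .geoMean(libsizes)
    z <- sweep(counts, 2, common / libsizes, "*")

    repGroups <- names(tab)[tab >= 2L]
    num <- matrix(0, nrow(z), length(repGroups))
    den <- matrix(0, nrow(z), length(repGroups))
    for (k in seq_along(repGroups)) {
        zz <- z[, groups == repGroups[k], drop = FALSE]
        n <- ncol(zz)
        mu <- rowMeans(zz)
        s2 <- apply(zz, 1, stats::var)
        num[, k] <- (n - 1) * (s2 - mu)
        den[, k] <- (n - 1) * mu^2
    }
    gnum <- rowSums(num); gden <- rowSums(den)
    pooled <- function(idx) {
        d <- sum(gden[idx])
        if (d <= 0) 0 else max(0, sum(gnum[idx]) / d)
    }
    if (mode == "common")
        return(rep(pooled(seq_len(nrow(z))), nrow(z)))

    abund <- rowMeans(z)
    ok <- abund > 0
    if (sum(ok) < 2L) return(rep(pooled(seq_len(nrow(z))), nrow(z)))
    la <- log(abund[ok])
    nb <- max(1L, min(bins, floor(sum(ok) / 2L)))
    qs <- stats::quantile(la, probs = seq(0, 1, length.out = nb + 1L))
    bin <- cut(la, breaks = unique(qs), include.lowest = TRUE)
    centers <- tapply(la, bin, mean)
    phi_bin <- vapply(levels(bin), function(b)
        pooled(which(ok)[bin == b]), numeric(1))
    disp <- rep(pooled(seq_len(nrow(z))), nrow(z))
    if (length(unique(centers[!is.na(centers)])) >= 2L) {
        fit <- stats::approx(centers, phi_bin, xout = la, rule = 2)$y
        disp[ok] <- pmax(0, fit)
    } else {
        disp[ok] <- phi_bin[as.integer(bin)]
    }
    disp
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), the single FDR
#' routine shared by the differential-expression and enrichment stages.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted values, same length and order as \code{p}.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Call fed-stage differentially expressed genes
#'
#' The full differential-expression pipeline for a developmental
#' [StageCounts-class] series: filter genes by average length-scaled TPM,
#' TMM-normalize, estimate (trended) dispersion, run the NB conditional
#' exact test of the fed (juvenile) stage against the pooled unfed stages,
#' BH-adjust, and call DEGs at \code{log2FC > fc} and \code{FDR < fdr}.
#'
#' @param sc a [StageCounts-class] object.
#' @param fed stage label of the fed (post-feeding) group (default
#'   "juvenile"); all other stages form the unfed group.  With
#'   \code{perStage = TRUE} a separate result is returned per unfed stage.
#' @param tpm_threshold,tpm_comparator expression filter applied to
#'   per-stage mean length-scaled TPM before testing (default > 1).
#' @param fc log2 fold-change threshold, strict (default 2).
#' @param fdr BH-adjusted p-value threshold, strict (default 0.01).
#' @param dispersion_mode "trended" (default) or "common".
#' @param tail exact-test tail rule, see [nbExactTest()].
#' @param perStage if TRUE, contrast the fed stage against each unfed stage
#'   separately and return a list of results.
#' @return data.frame with one row per tested gene: \code{gene_id},
#'   \code{log2fc} (fed over unfed, 0.5 pseudo-count inside the ratio),
#'   \code{pvalue}, \code{fdr}, \code{is_deg}; genes failing the expression
#'   filter are listed in \code{attr(, "filtered_out")}.
#' @export
callDEGs <- function(sc, fed = "juvenile", tpm_threshold = 1,
                     tpm_comparator = ">", fc = 2, fdr = 0.01,
                     dispersion_mode = c("trended", "common"),
                     tail = c("doubletail", "smallp"), perStage = FALSE) {
    stopifnot(is(sc, "StageCounts"))
    dispersion_mode <- match.arg(dispersion_mode)
    tail <- match.arg(tail)
    stage <- stageOf(sc)
    if (!fed %in% stage) stop("fed stage '", fed, "' not present")
    cts <- assay(sc, "counts")

    lst <- lengthScaledTPM(cts, effLengths(sc))
    se <- stageExpression(lst$lengthScaled, stage, tpm_threshold,
                          tpm_comparator)
    keep <- rowSums(se$expressed) > 0
    filtered_out <- rownames(cts)[!keep]
    cts <- cts[keep, , drop = FALSE]

    oneContrast <- function(unfedStages) {
        grp <- ifelse(stage == fed, "fed", "unfed")
        use <- stage == fed | stage %in% unfedStages
        y <- cts[, use, drop = FALSE]
        g <- grp[use]
        lib <- colSums(y)
        eff <- lib * tmmFactors(y, lib)
        disp <- estimateDispersion(y, g, eff, mode = dispersion_mode)
        fedIdx <- which(g == "fed"); unfIdx <- which(g == "unfed")
        p <- vapply(seq_len(nrow(y)), function(i)
            nbExactTest(y[i, fedIdx], y[i, unfIdx], eff[c(fedIdx, unfIdx)],
                        disp[i], tail = tail), numeric(1))
        z <- sweep(y, 2, .geoMean(eff) / eff, "*")
        mF <- rowMeans(z[, fedIdx, drop = FALSE])
        mU <- rowMeans(z[, unfIdx, drop = FALSE])
        lfc <- log2((mF + 0.5) / (mU + 0.5))
        q <- bhAdjust(p)
        res <- data.frame(gene_id = rownames(y), log2fc = lfc, pvalue = p,
                          fdr = q, is_deg = lfc > fc & q < fdr,
                          stringsAsFactors = FALSE)
        rownames(res) <- NULL
        attr(res, "filtered_out") <- filtered_out
        res
    }
    unfed <- setdiff(unique(stage), fed)
    if (perStage) {
        out <- lapply(unfed, function(s) oneContrast(s))
        names(out) <- unfed
        out
    } else {
        oneContrast(unfed)
    }
}
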