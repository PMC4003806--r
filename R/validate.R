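#' @importFrom stats pbinom p.adjust
#' @importFrom utils read.delim write.table
NULL

#' Two-sided exact binomial p-value by tail doubling
#'
#' Exact test of a proportion against \code{p0}: the smaller of the two
#' tail probabilities P(K <= k) and P(K >= k) is doubled and capped at 1.
#' At \code{p0 = 0.5} this is symmetric in k and n - k.  Vectorized over
#' \code{k} and \code{m}.
#'
#' @param k observed successes.
#' @param m number of trials (>= 1).
#' @param p0 null proportion (default 0.5).
#' @return p-values in (0, 1].
#' @examples
#' exactBinomPvalue(10, 10)   # 2 * 0.5^10 = 1/512
#' @export
exactBinomPvalue <- function(k, m, p0 = 0.5) {
    if (any(m < 1) || any(k < 0) || any(k > m))
        stop("need 0 <= k <= m and m >= 1")
    lower <- pbinom(k, m, p0)
    upper <- pbinom(k - 1, m, p0, lower.tail = FALSE)
    pmin(1, 2 * pmin(lower, upper))
}

#' Benjamini-Yekutieli adjusted p-values
#'
#' FDR control valid under arbitrary dependence among tests:
#' \code{q_(i) = p_(i) * m * c(m) / i} with \code{c(m) = sum(1/j)},
#' made monotone from the largest rank down and capped at 1, returned in
#' input order.
#'
#' @param pvalues numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values, same order as input.
#' @export
benjaminiYekutieli <- function(pvalues) {
    if (length(pvalues) == 0L)
        return(numeric())
    if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(pvalues, method = "BY")
}

#' Score individual segregants at candidate markers
#'
#' Fine-mapping statistics over individually genotyped segregants: at each
#' marker, \code{k} of \code{m} scored segregants display the
#' superior-parent variant; under no linkage k ~ Binomial(m, 1/2).  Each
#' marker gets a two-sided exact binomial p-value, a Benjamini-Yekutieli
#' adjusted p-value, and a linked flag (\code{adjusted < alpha}).
#'
#' @param genotypes data.frame with columns \code{MARKER}, \code{POS},
#'   \code{K_SUPERIOR}, \code{M_SCORED}.
#' @param alpha significance level on the adjusted p-values (default 0.05,
#'   i.e. a 95\% confidence level).
#' @return The input data.frame with columns \code{pvalue},
#'   \code{padj}, \code{linked} appended.
#' @examples
#' g <- data.frame(MARKER = c("S4", "S5"), POS = c(100, 200),
#'                 K_SUPERIOR = c(19, 10), M_SCORED = c(20, 20))
#' scoreIndividualSegregants(g)
#' @export
scoreIndividualSegregants <- function(genotypes, alpha = 0.05) {
    req <- c("MARKER", "POS", "K_SUPERIOR", "M_SCORED")
    missing <- setdiff(req, colnames(genotypes))
    if (length(missing))
        stop("genotype table is missing column(s): ",
             paste(missing, collapse = ", "))
    out <- genotypes
    if (nrow(genotypes) == 0L) {
        out$pvalue <- numeric(); out$padj <- numeric()
        out$linked <- logical()
        return(out)
    }
    out$pvalue <- exactBinomPvalue(genotypes$K_SUPERIOR,
                                   genotypes$M_SCORED)
    out$padj <- benjaminiYekutieli(out$pvalue)
    out$linked <- out$padj < alpha
    out
}

#' Read an individual-segregant genotype table
#'
#' TSV with header columns \code{MARKER}, \code{POS}, \code{K_SUPERIOR},
#' \code{M_SCORED}; \code{#}-prefixed lines ignored.
#'
#' @param path path to the TSV file.
#' @return A data.frame suitable for [scoreIndividualSegregants()].
#' @export
readGenotypeTable <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                     stringsAsFactors = FALSE, check.names = FALSE)
    req <- c("MARKER", "POS", "K_SUPERIOR", "M_SCORED")
    missing <- setdiff(req, colnames(df))
    if (length(missing))
        stop("genotype table is missing column(s): ",
             paste(missing, collapse = ", "))
    if (nrow(df) && (any(df$K_SUPERIOR < 0) || any(df$K_SUPERIOR > df$M_SCORED)))
        stop("K_SUPERIOR must lie in [0, M_SCORED]")
    df
}
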