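#' @importFrom GenomicRanges start end
#' @importFrom stats sd
NULL

#' Score called regions against the known causal site
#'
#' The three benchmark metrics for one dataset: whether some called region
#' contains the causal position (recovery), the size in bp of that region,
#' and the number of false-positive regions (regions not containing the
#' causal site; fragments of a split true region count as false positives).
#'
#' @param regions a sorted, non-overlapping \link[GenomicRanges]{GRanges}
#'   of called regions.
#' @param causalPos causal site position (bp).
#' @param chrom chromosome of the causal site; defaults to the single
#'   chromosome present in \code{regions} (any value matches when
#'   \code{regions} is empty).
#' @return List with \code{recovered} (logical), \code{causalRegionSize}
#'   (bp, NA when not recovered), \code{fpCount}, and
#'   \code{allRegionSizes}.
#' @export
scorePredictions <- function(regions, causalPos, chrom = NULL) {
    stopifnot(is(regions, "GRanges"))
    if (length(regions) > 1L) {
        perChrom <- split(regions, as.character(seqnames(regions)))
        for (gr in perChrom) {
            if (length(gr) > 1L) {
                o <- order(start(gr))
                if (any(start(gr)[o][-1L] <= end(gr)[o][-length(gr)]))
                    stop("regions must be non-overlapping")
            }
        }
    }
    if (length(regions) == 0L)
        return(list(recovered = FALSE, causalRegionSize = NA_real_,
                    fpCount = 0L, allRegionSizes = numeric()))
    onChrom <- if (is.null(chrom)) rep(TRUE, length(regions))
               else as.character(seqnames(regions)) == chrom
    hit <- onChrom & start(regions) <= causalPos & end(regions) >= causalPos
    sizes <- end(regions) - start(regions) + 1
    list(recovered = any(hit),
         causalRegionSize = if (any(hit)) sizes[which(hit)[1L]] else NA_real_,
         fpCount = sum(!hit),
         allRegionSizes = sizes)
}

#' Benchmark the pipeline over replicated simulations
#'
#' For each row of \code{grid} (columns may override any
#' \linkS4class{SimulationConfig} field or the analysis settings
#' \code{alphaP}, \code{betaP}, \code{rate}, \code{cutoff}), runs
#' \code{nReplicates} independent simulate-and-analyze replicates and
#' aggregates the recovery rate, the mean size of the causal region among
#' recovered replicates, and the mean number of false-positive regions per
#' dataset, each with a Monte-Carlo standard error.  Replicate seeds are
#' derived deterministically from \code{seed}.
#'
#' @param grid data.frame of settings, one row per condition; missing
#'   columns take their defaults.
#' @param nReplicates replicates per condition (default 100).
#' @param seed master seed.
#' @return A data.frame with one row per condition: the grid columns plus
#'   \code{recoveryRate}, \code{recoverySE}, \code{meanCausalSize},
#'   \code{causalSizeSE}, \code{meanFp}, \code{fpSE}, \code{nReplicates}.
#' @examples
#' runBenchmark(data.frame(psc = 0.95, nMarkers = 200), nReplicates = 3,
#'              seed = 1)
#' @export
runBenchmark <- function(grid, nReplicates = 100, seed = 1) {
    stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
    simFields <- c("chromLength", "nMarkers", "nSegregants", "coverage",
                   "psc", "crossoverRate", "seqError", "coverageMode")
    anaFields <- c("alphaP", "betaP", "rate", "sExp", "cutoff")
    unknown <- setdiff(colnames(grid), c(simFields, anaFields))
    if (length(unknown))
        stop("unknown grid column(s): ", paste(unknown, collapse = ", "))
    out <- vector("list", nrow(grid))
    for (g in seq_len(nrow(grid))) {
        simArgs <- as.list(grid[g, intersect(colnames(grid), simFields),
                                drop = FALSE])
        anaArgs <- as.list(grid[g, intersect(colnames(grid), anaFields),
                                drop = FALSE])
        rec <- logical(nReplicates)
        fp <- integer(nReplicates)
        size <- rep(NA_real_, nReplicates)
        for (i in seq_len(nReplicates)) {
            repSeed <- replicateSeed(seed, (g - 1L) * nReplicates + i)
            cfg <- do.call(SimulationConfig, c(simArgs, list(seed = repSeed)))
            pool <- simulateDataset(cfg)
            fit <- do.call(runBsaHmm, c(list(markers = poolMarkers(pool)),
                                        anaArgs))
            sc <- scorePredictions(linkedRegions(fit), causalPos(pool))
            rec[i] <- sc$recovered
            fp[i] <- sc$fpCount
            size[i] <- sc$causalRegionSize
        }
        row <- grid[g, , drop = FALSE]
        row$recoveryRate <- mean(rec)
        row$recoverySE <- sd(rec) / sqrt(nReplicates)
        row$meanCausalSize <- if (any(rec)) mean(size[rec]) else NA_real_
        row$causalSizeSE <- if (sum(rec) > 1L)
            sd(size[rec]) / sqrt(sum(rec)) else NA_real_
        row$meanFp <- mean(fp)
        row$fpSE <- sd(fp) / sqrt(nReplicates)
        row$nReplicates <- nReplicates
        out[[g]] <- row
    }
    do.call(rbind, out)
}

#' Deterministic replicate seed stream
#'
#' Derives a replicate seed from a master seed and a replicate index so
#' that benchmark replicates are independent yet fully reproducible.
#' Values stay below 2^31.
#'
#' @param masterSeed integer master seed.
#' @param index positive replicate index.
#' @return A single integer seed.
#' @export
replicateSeed <- function(masterSeed, index) {
    as.integer((as.numeric(masterSeed) * 48271 + as.numeric(index) * 69621) %%
               2147483647)
}
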