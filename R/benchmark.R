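#' Generate a synthetic enrichment-free null background
#'
#' Emulates the per-taxon log2 fold changes a differential abundance
#' tool reports when comparing two random splits of healthy samples:
#' i.i.d. values centred at zero with no set structure. The default
#' normal(0, 0.5) keeps |log2FC| > 1 uncommon, as in such null splits;
#' a scaled Student-t is available for heavier tails. Taxon identifiers
#' are drawn from the fixture universe so backgrounds intersect fixture
#' database sets.
#'
#' @param nTaxa Number of taxa (>= 50).
#' @param distribution `"normal"` or `"student_t"`.
#' @param mu,sigma Normal mean and standard deviation (sigma > 0).
#' @param df,scale Student-t degrees of freedom and scale (scale > 0).
#' @param universeSize Size of the identifier universe to draw from
#'   (default `nTaxa`: every universe taxon is observed).
#' @param seed Integer seed, or `NULL` to consume the current RNG
#'   stream.
#' @return A [RankedTaxa-class] of `nTaxa` entries.
#' @export
generateNullBackground <- function(nTaxa = 300,
                                   distribution = c("normal",
                                                    "student_t"),
                                   mu = 0, sigma = 0.5, df = 3,
                                   scale = 0.5,
                                   universeSize = nTaxa, seed = NULL) {
    distribution <- match.arg(distribution)
    nTaxa <- as.integer(nTaxa)
    if (nTaxa < 50L)
        stop("nTaxa must be >= 50 for a meaningful background")
    if (sigma <= 0 || scale <= 0)
        stop("sigma and scale must be positive")
    if (universeSize < nTaxa)
        stop("universeSize must be >= nTaxa")
    .withSeed(seed, function() {
        ids <- if (universeSize == nTaxa) fixtureUniverse(universeSize)
               else sample(fixtureUniverse(universeSize), nTaxa)
        vals <- switch(distribution,
                       normal = stats::rnorm(nTaxa, mu, sigma),
                       student_t = stats::rt(nTaxa, df) * scale)
        RankedTaxa(vals, taxa = ids)
    })
}

#' Screen a null background for pre-existing enrichment
#'
#' Runs the enrichment test on the candidate background and accepts it
#' only if no set reaches `fdr < alpha` -- backgrounds carrying chance
#' enrichment would contaminate a sensitivity benchmark's null.
#'
#' @param background A [RankedTaxa-class].
#' @param db A [TaxonSetDatabase-class].
#' @param alpha FDR screening threshold (default 0.05).
#' @param minSize Passed to [runTaxonSetEnrichment()].
#' @return `TRUE` if the background is accepted. A database in which no
#'   set is testable is accepted vacuously.
#' @export
screenNull <- function(background, db, alpha = 0.05, minSize = 5) {
    res <- withCallingHandlers(
        runTaxonSetEnrichment(background, db, minSize = minSize),
        warning = function(w) invokeRestart("muffleWarning"))
    nrow(res) == 0L || !any(res$fdr < alpha)
}

#' Implant an enrichment signal into a null background
#'
#' Replaces the rank values of the target set's detected members with
#' i.i.d. draws from a uniform distribution whose bounds encode the
#' target effect size: by default
#' `Uniform(log2(E)/2, 3*log2(E)/2)`, so the implanted median is exactly
#' `log2(E)` -- a median E-fold change -- and the support stays positive
#' for E > 1. With `direction = "decrease"` the draws are negated. All
#' other taxa are untouched. A `"shift"` mode, which adds the draws to
#' the existing values instead of replacing them, is available for
#' sensitivity analysis.
#'
#' @param background A [RankedTaxa-class].
#' @param targetSet A [TaxonSet-class] with at least one member detected
#'   in the background.
#' @param effectSize Fold change E >= 1 (E = 1 gives a degenerate
#'   zero-width implant: the no-signal limit).
#' @param direction `"increase"` or `"decrease"`.
#' @param bounds Optional length-2 numeric `(lo, hi)` in log2 units
#'   overriding the default rule.
#' @param mode `"replace"` (default) or `"shift"`.
#' @param seed Integer seed, or `NULL` to consume the current stream.
#' @return A [RankedTaxa-class] with the signal implanted.
#' @export
implantSignal <- function(background, targetSet, effectSize,
                          direction = c("increase", "decrease"),
                          bounds = NULL, mode = c("replace", "shift"),
                          seed = NULL) {
    direction <- match.arg(direction)
    mode <- match.arg(mode)
    stopifnot(is(background, "RankedTaxa"), is(targetSet, "TaxonSet"))
    if (effectSize < 1)
        stop("effectSize must be >= 1 (a fold change)")
    if (is.null(bounds))
        bounds <- c(log2(effectSize) / 2, 3 * log2(effectSize) / 2)
    if (length(bounds) != 2L || bounds[1L] > bounds[2L])
        stop("bounds must be (lo, hi) with lo <= hi")
    vals <- rankValues(background)
    hit <- names(vals) %in% members(targetSet)
    if (!any(hit))
        stop("target set ", sQuote(setId(targetSet)),
             " shares no taxa with the background")
    .withSeed(seed, function() {
        draws <- stats::runif(sum(hit), bounds[1L], bounds[2L])
        if (direction == "decrease")
            draws <- -draws
        vals[hit] <- if (mode == "replace") draws else vals[hit] + draws
        RankedTaxa(vals)
    })
}

.SIZE_CLASSES <- list(small = c(1L, 9L), medium = c(10L, 50L),
                      large = c(51L, .Machine$integer.max))

#' Signal-implantation sensitivity benchmark
#'
#' Estimates the true positive rate (TPR) of the enrichment test per
#' (set size class, effect size) cell by signal implantation. For each
#' replicate: draw a synthetic null background
#' ([generateNullBackground()]); screen it for pre-existing enrichment
#' and redraw until accepted ([screenNull()], bounded retries); pick,
#' uniformly at random, a target set whose detected-member count falls
#' in the class bounds (small < 10, medium 10-50, large > 50 detected
#' members) and is testable (>= `minSize`); implant the effect
#' ([implantSignal()]); rerun the enrichment; count a detection when the
#' target set's FDR falls below `detectionFdr`. Fully reproducible from
#' `seed`.
#'
#' @param db A [TaxonSetDatabase-class] with at least one eligible set
#'   per requested class.
#' @param effects Numeric vector of fold changes to test.
#' @param classes Subset of `c("small", "medium", "large")`.
#' @param nReps Replicates per (class, effect) cell.
#' @param seed Integer seed.
#' @param nTaxa,distribution,mu,sigma,df,scale,universeSize Background
#'   configuration, see [generateNullBackground()].
#' @param detectionFdr FDR threshold counting a detection (default
#'   0.05, the same alpha used for null screening).
#' @param screenAlpha FDR threshold for null screening.
#' @param minSize Minimum detected members per testable set.
#' @param maxScreenRetries Redraw budget per replicate before erroring
#'   (a systematic self-rejection loop indicates the background
#'   distribution cannot pass screening).
#' @param direction,mode Passed to [implantSignal()].
#' @return A `data.frame` with columns `size_class`, `effect_size`,
#'   `n_reps`, `n_detected`, `tpr`.
#' @export
runBenchmark <- function(db, effects = c(1.5, 2, 2.5, 3, 4, 5),
                         classes = c("small", "medium", "large"),
                         nReps = 1000, seed = 1,
                         nTaxa = 300,
                         distribution = "normal", mu = 0, sigma = 0.5,
                         df = 3, scale = 0.5, universeSize = nTaxa,
                         detectionFdr = 0.05, screenAlpha = 0.05,
                         minSize = 5, maxScreenRetries = 50,
                         direction = "increase", mode = "replace") {
    stopifnot(is(db, "TaxonSetDatabase"))
    classes <- match.arg(classes, names(.SIZE_CLASSES),
                         several.ok = TRUE)
    nReps <- as.integer(nReps)
    stopifnot(nReps >= 1L)
    universe <- fixtureUniverse(universeSize)
    # class membership judged on detected members; with the default
    # full-universe background, detected size equals set size
    detSize <- vapply(taxonSets(db), function(s)
        sum(members(s) %in% universe), integer(1))
    eligible <- lapply(.SIZE_CLASSES[classes], function(b)
        names(taxonSets(db))[detSize >= max(b[1L], minSize) &
                             detSize <= b[2L]])
    for (cl in classes)
        if (length(eligible[[cl]]) == 0L)
            stop("database has no testable set in class ", sQuote(cl))
    .withSeed(seed, function() {
        grid <- expand.grid(size_class = classes,
                            effect_size = effects,
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
        grid <- grid[order(match(grid$size_class, classes),
                           grid$effect_size), , drop = FALSE]
        grid$n_reps <- nReps
        grid$n_detected <- 0L
        for (g in seq_len(nrow(grid))) {
            cl <- grid$size_class[[g]]
            E <- grid$effect_size[[g]]
            hits <- 0L
            for (r in seq_len(nReps)) {
                bg <- NULL
                for (try in seq_len(maxScreenRetries)) {
                    cand <- generateNullBackground(
                        nTaxa = nTaxa, distribution = distribution,
                        mu = mu, sigma = sigma, df = df, scale = scale,
                        universeSize = universeSize, seed = NULL)
                    if (screenNull(cand, db, alpha = screenAlpha,
                                   minSize = minSize)) {
                        bg <- cand
                        break
                    }
                }
                if (is.null(bg))
                    stop("null screening rejected ", maxScreenRetries,
                         " consecutive backgrounds; use a larger ",
                         "background or a different distribution")
                pool <- eligible[[cl]]
                target <- db[[if (length(pool) == 1L) pool
                              else sample(pool, 1L)]]
                implanted <- implantSignal(bg, target, E,
                                           direction = direction,
                                           mode = mode, seed = NULL)
                res <- withCallingHandlers(
                    runTaxonSetEnrichment(implanted, db,
                                          minSize = minSize),
                    warning = function(w)
                        invokeRestart("muffleWarning"))
                row <- res[res$set_id == setId(target), , drop = FALSE]
                if (nrow(row) == 1L && row$fdr < detectionFdr)
                    hits <- hits + 1L
            }
            grid$n_detected[[g]] <- hits
        }
        grid$tpr <- grid$n_detected / grid$n_reps
        rownames(grid) <- NULL
        grid
    })
}
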