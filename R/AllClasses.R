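#' @import methods
NULL

.CATEGORIES <- c("health_disease", "metabolite_producers",
                 "published_associations", "custom")

#' RankedTaxa: per-taxon rank values from differential abundance analysis
#'
#' A named numeric vector wrapper holding one rank value per taxon, the
#' input to taxon set enrichment. Values are dimensionless effect sizes --
#' typically log2 fold changes between two sample groups, but any
#' per-taxon score (a correlation coefficient, a test statistic) works,
#' because the enrichment test depends only on the ordering of values.
#' Identifiers may be NCBI taxonomy IDs (decimal strings) or verbatim
#' taxon names; matching against set members is by exact identifier
#' equality.
#'
#' @slot values Named numeric vector; names are taxon identifiers.
#' @seealso [RankedTaxa()], [runTaxonSetEnrichment()]
#' @export
setClass("RankedTaxa", representation(values = "numeric"))

setValidity("RankedTaxa", function(object) {
    v <- object@values
    ids <- names(v)
    if (length(v) < 2L)
        return("at least 2 ranked taxa are required")
    if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
        return("every rank value must carry a non-empty taxon identifier")
    if (anyDuplicated(ids))
        return(paste0("duplicate taxon identifiers: ",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (any(!is.finite(v)))
        return("rank values must be finite (no NA/NaN/Inf)")
    TRUE
})

#' Construct a RankedTaxa object
#'
#' @param values Numeric vector of rank values (e.g. log2 fold changes).
#' @param taxa Character vector of taxon identifiers; defaults to
#'   `names(values)`.
#' @return A [RankedTaxa-class] object.
#' @examples
#' rt <- RankedTaxa(c(Fp = -1.2, Rh = -0.8, Ec = 0.3))
#' taxonIds(rt)
#' @export
RankedTaxa <- function(values, taxa = names(values)) {
    v <- as.numeric(values)
    names(v) <- as.character(taxa)
    new("RankedTaxa", values = v)
}

#' TaxonSet: a named group of taxa sharing a property
#'
#' The microbiome analogue of a gene set: butyrate producers, a disease
#' signature, a taxonomic grouping. Members are taxon identifiers --
#' canonical NCBI taxonomy IDs as decimal strings, or verbatim names for
#' taxa that were never mapped to a taxid.
#'
#' @slot setId Short unique identifier within a database.
#' @slot displayName Human-readable name.
#' @slot category One of `health_disease`, `metabolite_producers`,
#'   `published_associations`, `custom`.
#' @slot members Character vector of unique taxon identifiers.
#' @export
setClass("TaxonSet", representation(setId = "character",
                                    displayName = "character",
                                    category = "character",
                                    members = "character"))

setValidity("TaxonSet", function(object) {
    if (length(object@setId) != 1L || !nzchar(object@setId))
        return("setId must be a single non-empty string")
    if (length(object@category) != 1L ||
        !(object@category %in% .CATEGORIES))
        return(paste0("category must be one of: ",
                      paste(.CATEGORIES, collapse = ", ")))
    if (length(object@members) == 0L)
        return("members must be non-empty")
    if (anyDuplicated(object@members))
        return("members must not contain duplicates")
    if (any(!nzchar(object@members)))
        return("members must be non-empty strings")
    TRUE
})

#' Construct a TaxonSet
#'
#' @param setId Unique set identifier.
#' @param members Character vector of taxon identifiers (duplicates are
#'   an error here; use [readTaxonSets()] for tolerant import).
#' @param displayName Human-readable name; defaults to `setId`.
#' @param category Set category; defaults to `"custom"`.
#' @return A [TaxonSet-class] object.
#' @export
TaxonSet <- function(setId, members, displayName = setId,
                     category = "custom") {
    new("TaxonSet", setId = as.character(setId),
        displayName = as.character(displayName),
        category = as.character(category),
        members = as.character(members))
}

#' TaxonSetDatabase: an ordered, non-redundant collection of taxon sets
#'
#' Models a taxon-set database: an ordered list of [TaxonSet-class]
#' objects with unique identifiers, optional free-form provenance
#' strings per set, and (after [filterDetectable()]) the per-set list of
#' members detected in a ranked input.
#'
#' @slot sets List of [TaxonSet-class] objects, named by `setId`.
#' @slot sourceMetadata Named character vector of provenance strings
#'   (may be empty).
#' @slot detected Named list recording, per set, the members found in
#'   the ranked input that the database was last filtered against.
#'   Empty unless set by [filterDetectable()].
#' @export
setClass("TaxonSetDatabase", representation(sets = "list",
                                            sourceMetadata = "character",
                                            detected = "list"))

setValidity("TaxonSetDatabase", function(object) {
    if (!all(vapply(object@sets, is, logical(1), "TaxonSet")))
        return("all elements of sets must be TaxonSet objects")
    ids <- unname(vapply(object@sets, function(s) s@setId, character(1)))
    if (anyDuplicated(ids))
        return(paste0("duplicate set ids: ",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (length(object@sets) && !identical(unname(names(object@sets)), ids))
        return("sets must be named by their setId")
    if (length(object@detected) &&
        !all(names(object@detected) %in% ids))
        return("detected entries must correspond to set ids")
    TRUE
})

#' Construct a TaxonSetDatabase
#'
#' @param sets List of [TaxonSet-class] objects.
#' @param sourceMetadata Optional named character vector of provenance
#'   strings, named by set id.
#' @return A [TaxonSetDatabase-class] object.
#' @export
TaxonSetDatabase <- function(sets = list(), sourceMetadata = character()) {
    ids <- vapply(sets, function(s) s@setId, character(1))
    names(sets) <- ids
    new("TaxonSetDatabase", sets = sets,
        sourceMetadata = sourceMetadata, detected = list())
}

#' TaxidCache: an offline store of NCBI taxonomy name resolutions
#'
#' Persists name-to-taxid lookups so enrichment pipelines are
#' reproducible and testable without network access. Keys are normalized
#' taxon names (see [normalizeName()]); each entry records the resolved
#' taxid (a positive integer rendered as a decimal string, or the
#' sentinel `"UNRESOLVED"`) and an ISO-8601 retrieval timestamp.
#'
#' @slot entries Named list; each element is
#'   `list(taxid = <string>, retrieved_at = <string>)`.
#' @export
setClass("TaxidCache", representation(entries = "list"))

setValidity("TaxidCache", function(object) {
    e <- object@entries
    if (length(e) == 0L)
        return(TRUE)
    if (is.null(names(e)) || any(!nzchar(names(e))))
        return("cache entries must be named by normalized taxon name")
    if (anyDuplicated(names(e)))
        return("cache entry names must be unique")
    ok <- vapply(e, function(x) {
        is.list(x) && all(c("taxid", "retrieved_at") %in% names(x)) &&
            (identical(x$taxid, "UNRESOLVED") ||
             grepl("^[0-9]+$", x$taxid))
    }, logical(1))
    if (!all(ok))
        return("each entry needs a taxid (decimal string or UNRESOLVED) and retrieved_at")
    TRUE
})

#' Construct a TaxidCache
#'
#' @param entries Named list of `list(taxid =, retrieved_at =)` records;
#'   defaults to an empty cache.
#' @return A [TaxidCache-class] object.
#' @export
TaxidCache <- function(entries = list()) {
    new("TaxidCache", entries = entries)
}
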