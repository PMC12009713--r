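#' @rdname RankedTaxa-class
#' @param object,x A `RankedTaxa`, `TaxonSet` or `TaxonSetDatabase`.
#' @export
setGeneric("taxonIds", function(object) standardGeneric("taxonIds"))

#' @rdname RankedTaxa-class
#' @export
setGeneric("rankValues", function(object) standardGeneric("rankValues"))

#' @rdname TaxonSet-class
#' @param object,x A `TaxonSet`.
#' @export
setGeneric("setId", function(object) standardGeneric("setId"))

#' @rdname TaxonSet-class
#' @export
setGeneric("displayName", function(object) standardGeneric("displayName"))

#' @rdname TaxonSet-class
#' @export
setGeneric("category", function(object) standardGeneric("category"))

#' @rdname TaxonSet-class
#' @export
setGeneric("members", function(object) standardGeneric("members"))

#' @rdname TaxonSetDatabase-class
#' @param object,x A `TaxonSetDatabase`.
#' @export
setGeneric("taxonSets", function(object) standardGeneric("taxonSets"))

#' @rdname TaxonSetDatabase-class
#' @export
setGeneric("detectedMembers",
           function(object) standardGeneric("detectedMembers"))

#' @rdname TaxidCache-class
#' @param object A `TaxidCache`.
#' @export
setGeneric("cacheEntries", function(object) standardGeneric("cacheEntries"))

## ---- RankedTaxa ----

#' @rdname RankedTaxa-class
#' @export
setMethod("taxonIds", "RankedTaxa", function(object) names(object@values))

#' @rdname RankedTaxa-class
#' @export
setMethod("rankValues", "RankedTaxa", function(object) object@values)

#' @rdname RankedTaxa-class
#' @export
setMethod("length", "RankedTaxa", function(x) length(x@values))

setMethod("show", "RankedTaxa", function(object) {
    v <- object@values
    cat("RankedTaxa with", length(v), "taxa\n")
    cat("  rank values: median", format(stats::median(v), digits = 4),
        " range [", format(min(v), digits = 4), ",",
        format(max(v), digits = 4), "]\n")
    k <- utils::head(seq_along(v), 4L)
    cat("  head:", paste0(names(v)[k], "=", format(v[k], digits = 3),
                          collapse = ", "), "\n")
})

## ---- TaxonSet ----

#' @rdname TaxonSet-class
#' @export
setMethod("setId", "TaxonSet", function(object) object@setId)

#' @rdname TaxonSet-class
#' @export
setMethod("displayName", "TaxonSet", function(object) object@displayName)

#' @rdname TaxonSet-class
#' @export
setMethod("category", "TaxonSet", function(object) object@category)

#' @rdname TaxonSet-class
#' @export
setMethod("members", "TaxonSet", function(object) object@members)

#' @rdname TaxonSet-class
#' @export
setMethod("length", "TaxonSet", function(x) length(x@members))

setMethod("show", "TaxonSet", function(object) {
    cat("TaxonSet", sQuote(object@setId),
        paste0("(", object@category, ")"), "with",
        length(object@members), "members\n")
})

## ---- TaxonSetDatabase ----

#' @rdname TaxonSetDatabase-class
#' @export
setMethod("taxonSets", "TaxonSetDatabase", function(object) object@sets)

#' @rdname TaxonSetDatabase-class
#' @export
setMethod("detectedMembers", "TaxonSetDatabase",
          function(object) object@detected)

#' @rdname TaxonSetDatabase-class
#' @export
setMethod("length", "TaxonSetDatabase", function(x) length(x@sets))

#' @rdname TaxonSetDatabase-class
#' @export
setMethod("names", "TaxonSetDatabase", function(x) names(x@sets))

#' @rdname TaxonSetDatabase-class
#' @param i Set index or set id.
#' @export
setMethod("[[", "TaxonSetDatabase", function(x, i) x@sets[[i]])

#' @rdname TaxonSetDatabase-class
#' @param j,drop,... Ignored (matrix-style subsetting is not supported).
#' @export
setMethod("[", "TaxonSetDatabase", function(x, i, j, ..., drop = TRUE) {
    sets <- x@sets[i]
    ids <- names(sets)
    meta <- x@sourceMetadata[names(x@sourceMetadata) %in% ids]
    db <- TaxonSetDatabase(sets, meta)
    db@detected <- x@detected[names(x@detected) %in% ids]
    validObject(db)
    db
})

setMethod("show", "TaxonSetDatabase", function(object) {
    n <- length(object@sets)
    cat("TaxonSetDatabase with", n, "taxon sets\n")
    if (n) {
        sz <- vapply(object@sets, function(s) length(s@members), integer(1))
        cat("  set sizes: ", min(sz), "-", max(sz),
            " (median ", stats::median(sz), ")\n", sep = "")
        tab <- table(vapply(object@sets, function(s) s@category,
                            character(1)))
        cat("  categories:", paste0(names(tab), "=", tab, collapse = ", "),
            "\n")
    }
    if (length(object@detected))
        cat("  detected-member records for", length(object@detected),
            "sets\n")
})

## ---- TaxidCache ----

#' @rdname TaxidCache-class
#' @export
setMethod("cacheEntries", "TaxidCache", function(object) object@entries)

#' @rdname TaxidCache-class
#' @param x A `TaxidCache`.
#' @export
setMethod("length", "TaxidCache", function(x) length(x@entries))

setMethod("show", "TaxidCache", function(object) {
    n <- length(object@entries)
    unres <- sum(vapply(object@entries,
                        function(x) identical(x$taxid, "UNRESOLVED"),
                        logical(1)))
    cat("TaxidCache with", n, "entries (", unres, "unresolved )\n")
})
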