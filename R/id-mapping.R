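#' Normalize a taxon name
#'
#' Canonicalizes the cosmetic variation that differs between taxonomy
#' sources before any lookup: underscores become single spaces, runs of
#' whitespace collapse, surrounding whitespace is stripped, and the
#' square brackets of provisional genus notation (`[Ruminococcus]`) are
#' removed. Case and strain designators are preserved -- they are
#' meaningful. Idempotent.
#'
#' @param raw Character vector of taxon names (non-empty).
#' @return Character vector of normalized names.
#' @examples
#' normalizeName("Faecalibacterium_prausnitzii")
#' normalizeName("[Ruminococcus] torques")
#' @export
normalizeName <- function(raw) {
    if (length(raw) == 0L)
        stop("no names supplied")
    raw <- as.character(raw)
    out <- gsub("_", " ", raw, fixed = TRUE)
    out <- gsub("[][]", "", out)
    out <- trimws(gsub("[[:space:]]+", " ", out))
    if (any(is.na(out) | !nzchar(out)))
        stop("empty or whitespace-only taxon name at position ",
             which(is.na(out) | !nzchar(out))[1L])
    out
}

#' Read / write a taxid cache
#'
#' The cache is a JSON object keyed by normalized name, each value
#' `{"taxid": "...", "retrieved_at": "..."}` -- human-auditable and
#' diff-friendly. Round-trips losslessly.
#'
#' @param path Cache file path.
#' @return [readTaxidCache()]: a [TaxidCache-class]; an empty cache if
#'   the file does not exist.
#' @export
readTaxidCache <- function(path) {
    if (!file.exists(path))
        return(TaxidCache())
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    cache <- TaxidCache(lapply(raw, function(x)
        list(taxid = as.character(x$taxid),
             retrieved_at = as.character(x$retrieved_at))))
    validObject(cache)
    cache
}

#' @rdname readTaxidCache
#' @param cache A [TaxidCache-class].
#' @return [writeTaxidCache()]: `path`, invisibly.
#' @export
writeTaxidCache <- function(cache, path) {
    stopifnot(is(cache, "TaxidCache"))
    jsonlite::write_json(cacheEntries(cache), path, auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(path)
}

# One esearch query against NCBI taxonomy, with exponential backoff.
# Returns a taxid string or NA when unresolvable / unreachable.
.entrezTaxidLookup <- function(name, apiKey = NULL, retries = 3L) {
    term <- utils::URLencode(paste0("\"", name, "\"[Scientific Name]"),
                             reserved = TRUE)
    url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/",
                  "esearch.fcgi?db=taxonomy&retmode=json&term=", term,
                  if (!is.null(apiKey)) paste0("&api_key=", apiKey))
    for (k in seq_len(retries)) {
        res <- tryCatch(jsonlite::fromJSON(url),
                        error = function(e) NULL)
        if (!is.null(res)) {
            ids <- unlist(res$esearchresult$idlist)
            return(if (length(ids)) as.character(ids[[1L]])
                   else NA_character_)
        }
        Sys.sleep(0.5 * 2^k)
    }
    warning("NCBI lookup failed for ", sQuote(name),
            "; marking unresolved", call. = FALSE)
    NA_character_
}

#' Resolve taxon names to NCBI taxonomy IDs
#'
#' Names are normalized ([normalizeName()]) and resolved against the
#' cache first. With `online = TRUE`, cache misses are queried against
#' the NCBI Entrez taxonomy name-search endpoint (rate-limited to under
#' 3 requests/second without an API key, as NCBI requires) and written
#' back to the cache; lookup failures never abort the run -- the name is
#' marked unresolved with a warning. With `online = FALSE` the result is
#' a pure function of `(names, cache)` and no network access occurs.
#'
#' Unresolved names are reported, not dropped: downstream enrichment
#' matches them verbatim against set members, so name-keyed sets still
#' work and the background distribution is not silently thinned.
#'
#' @param names Character vector of taxon names (duplicates allowed; one
#'   lookup per unique normalized name).
#' @param cache A [TaxidCache-class] (default empty).
#' @param online Permit Entrez queries for cache misses.
#' @param apiKey Optional NCBI API key (lifts the rate limit).
#' @return A list with `taxids` (named character: normalized name ->
#'   taxid, resolved names only), `unresolved` (character vector of
#'   normalized names), and `cache` (the updated [TaxidCache-class]).
#' @export
namesToTaxids <- function(names, cache = TaxidCache(), online = FALSE,
                          apiKey = NULL) {
    stopifnot(is(cache, "TaxidCache"))
    norm <- unique(normalizeName(names))
    entries <- cacheEntries(cache)
    taxids <- character()
    unresolved <- character()
    for (nm in norm) {
        hit <- entries[[nm]]
        if (is.null(hit) && isTRUE(online)) {
            if (is.null(apiKey))
                Sys.sleep(0.34)
            tid <- .entrezTaxidLookup(nm, apiKey = apiKey)
            hit <- list(taxid = if (is.na(tid)) "UNRESOLVED" else tid,
                        retrieved_at = format(Sys.time(),
                                              "%Y-%m-%dT%H:%M:%SZ",
                                              tz = "UTC"))
            entries[[nm]] <- hit
        }
        if (is.null(hit) || identical(hit$taxid, "UNRESOLVED"))
            unresolved <- c(unresolved, nm)
        else
            taxids[[nm]] <- hit$taxid
    }
    out <- TaxidCache(entries)
    validObject(out)
    list(taxids = taxids, unresolved = unresolved, cache = out)
}

#' Translate RankedTaxa identifiers through a taxid cache
#'
#' Convenience wrapper used by the command-line `run` subcommand: each
#' taxon identifier that resolves to a taxid is replaced by it;
#' unresolved identifiers pass through verbatim so enrichment can still
#' match on names.
#'
#' @param ranked A [RankedTaxa-class].
#' @inheritParams namesToTaxids
#' @return A [RankedTaxa-class] with translated identifiers.
#' @export
translateTaxonIds <- function(ranked, cache = TaxidCache(),
                              online = FALSE, apiKey = NULL) {
    stopifnot(is(ranked, "RankedTaxa"))
    res <- namesToTaxids(taxonIds(ranked), cache, online = online,
                         apiKey = apiKey)
    norm <- normalizeName(taxonIds(ranked))
    new <- ifelse(norm %in% names(res$taxids),
                  unname(res$taxids[norm]), norm)
    if (anyDuplicated(new))
        stop("taxid translation collapsed distinct taxa onto one id: ",
             paste(unique(new[duplicated(new)]), collapse = ", "))
    RankedTaxa(rankValues(ranked), taxa = new)
}

#' Synthetic taxid cache covering the fixture universe
#'
#' Builds a cache mapping the pseudo-names `"Fixturella sp. <taxid>"` of
#' the synthetic universe onto their identifiers, so name-resolution
#' paths can be exercised entirely offline against fixture databases.
#'
#' @param universeSize Size of the fixture universe.
#' @return A [TaxidCache-class].
#' @export
fixtureTaxidCache <- function(universeSize) {
    ids <- fixtureUniverse(universeSize)
    entries <- lapply(ids, function(tid)
        list(taxid = tid, retrieved_at = "2025-06-01T00:00:00Z"))
    names(entries) <- paste("Fixturella sp.", ids)
    TaxidCache(entries)
}
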