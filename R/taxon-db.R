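#' Read a taxon-set database from GMT or JSON
#'
#' GMT is the line-oriented tab-separated set format standard in
#' enrichment tooling: `name<TAB>description<TAB>member1<TAB>member2...`.
#' The JSON schema is a top-level array of objects
#' `{set_id, display_name, category, members}`; `category` defaults to
#' `"custom"` when absent (GMT carries no category field, so GMT imports
#' are always `"custom"`). Duplicate members within a set are silently
#' deduplicated with a logged warning; duplicate set ids are an error.
#'
#' @param path Path to the database file.
#' @param format `"gmt"`, `"json"`, or `"auto"` (decide from the file
#'   extension, falling back to content sniffing).
#' @return A validated [TaxonSetDatabase-class].
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines("butyrate\tdesc\t853\t40518\t301301\t46503\t39491", gmt)
#' db <- readTaxonSets(gmt)
#' length(db[["butyrate"]])
#' @export
readTaxonSets <- function(path, format = c("auto", "gmt", "json")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("file not found: ", path)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- if (ext == "gmt") "gmt"
                  else if (ext == "json") "json"
                  else {
                      first <- substr(trimws(paste(readLines(path, n = 5L,
                                                             warn = FALSE),
                                                   collapse = "")), 1, 1)
                      if (identical(first, "[")) "json" else "gmt"
                  }
    }
    if (format == "gmt") .readGmt(path) else .readJsonDb(path)
}

.dedupMembers <- function(members, setId) {
    if (anyDuplicated(members)) {
        warning("set ", sQuote(setId), ": ",
                sum(duplicated(members)),
                " duplicate member(s) removed", call. = FALSE)
        members <- unique(members)
    }
    members
}

.readGmt <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L)
        stop("no sets found in ", path)
    sets <- vector("list", length(lines))
    for (i in seq_along(lines)) {
        fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        while (length(fields) && !nzchar(fields[[length(fields)]]))
            fields <- fields[-length(fields)]
        if (length(fields) < 3L)
            stop("malformed GMT line ", i, " in ", path,
                 ": need at least name, description and one member")
        mem <- fields[-(1:2)]
        mem <- mem[nzchar(mem)]
        mem <- .dedupMembers(mem, fields[[1]])
        sets[[i]] <- TaxonSet(setId = fields[[1]],
                              displayName = fields[[2]],
                              category = "custom", members = mem)
    }
    ids <- vapply(sets, setId, character(1))
    if (anyDuplicated(ids))
        stop("duplicate set ids in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    db <- TaxonSetDatabase(sets)
    validObject(db)
    db
}

.readJsonDb <- function(path) {
    recs <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                     error = function(e)
                         stop("malformed JSON in ", path, ": ",
                              conditionMessage(e), call. = FALSE))
    if (!is.list(recs) || length(recs) == 0L)
        stop("no sets found in ", path)
    sets <- vector("list", length(recs))
    meta <- character()
    for (i in seq_along(recs)) {
        r <- recs[[i]]
        if (!is.list(r) || is.null(r$set_id) || is.null(r$members) ||
            length(r$members) == 0L)
            stop("malformed record ", i, " in ", path,
                 ": set_id and non-empty members are required")
        mem <- .dedupMembers(as.character(unlist(r$members)), r$set_id)
        sets[[i]] <- TaxonSet(
            setId = r$set_id,
            displayName = if (is.null(r$display_name)) r$set_id
                          else r$display_name,
            category = if (is.null(r$category)) "custom" else r$category,
            members = mem)
        if (!is.null(r$source))
            meta[[as.character(r$set_id)]] <- as.character(r$source)
    }
    ids <- vapply(sets, setId, character(1))
    if (anyDuplicated(ids))
        stop("duplicate set ids in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    db <- TaxonSetDatabase(sets, meta)
    validObject(db)
    db
}

#' Write a taxon-set database to GMT or JSON
#'
#' JSON round-trips all fields; GMT preserves set id, display name and
#' members but drops the category (re-imported GMT sets are `"custom"`).
#'
#' @param db A [TaxonSetDatabase-class].
#' @param path Output path.
#' @param format `"gmt"`, `"json"`, or `"auto"` (from extension,
#'   defaulting to JSON).
#' @return `path`, invisibly.
#' @export
writeTaxonSets <- function(db, path, format = c("auto", "gmt", "json")) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- if (ext == "gmt") "gmt" else "json"
    }
    if (format == "gmt") {
        lines <- vapply(taxonSets(db), function(s)
            paste(c(setId(s), displayName(s), members(s)),
                  collapse = "\t"), character(1))
        writeLines(lines, path)
    } else {
        meta <- db@sourceMetadata
        recs <- lapply(taxonSets(db), function(s) {
            r <- list(set_id = setId(s), display_name = displayName(s),
                      category = category(s),
                      members = as.list(members(s)))
            if (setId(s) %in% names(meta))
                r$source <- meta[[setId(s)]]
            r
        })
        jsonlite::write_json(unname(recs), path, auto_unbox = TRUE,
                             pretty = TRUE)
    }
    invisible(path)
}

#' Keep only taxon sets detectable in a ranked input
#'
#' A set is testable only if enough of its members were detected in the
#' input data; sets with fewer than `minSize` detected members are
#' dropped before any statistics are computed (default 5). The detected
#' members of each surviving set are recorded on the returned database
#' (see [detectedMembers()]).
#'
#' @param db A [TaxonSetDatabase-class].
#' @param ranked A [RankedTaxa-class].
#' @param minSize Minimum number of detected members (positive integer).
#' @return A filtered [TaxonSetDatabase-class]; possibly empty.
#' @export
filterDetectable <- function(db, ranked, minSize = 5) {
    stopifnot(is(db, "TaxonSetDatabase"), is(ranked, "RankedTaxa"))
    minSize <- as.integer(minSize)
    if (is.na(minSize) || minSize < 1L)
        stop("minSize must be a positive integer")
    ids <- taxonIds(ranked)
    det <- lapply(taxonSets(db), function(s)
        members(s)[members(s) %in% ids])
    keep <- vapply(det, length, integer(1)) >= minSize
    out <- db[which(keep)]
    out@detected <- det[keep]
    validObject(out)
    out
}

#' Deterministic universe of synthetic taxon identifiers
#'
#' Synthetic decimal-string identifiers used by the fixture database and
#' null-background generators, disjoint from real NCBI taxids by
#' construction (offset into a high range).
#'
#' @param universeSize Number of identifiers.
#' @return Character vector of `universeSize` identifiers.
#' @export
fixtureUniverse <- function(universeSize) {
    universeSize <- as.integer(universeSize)
    stopifnot(universeSize >= 1L)
    as.character(9000000L + seq_len(universeSize))
}

#' Generate a synthetic taxon-set database
#'
#' Builds a reproducible stand-in for a curated taxon-set database, with
#' set sizes drawn uniformly from three classes: small (2-9 members),
#' medium (10-50) and large (51 up to `min(150, universeSize)`). Members
#' are sampled without replacement per set from a shared identifier
#' universe, so sets overlap -- as real metabolite-producer and disease
#' signature sets do, since one species belongs to many sets.
#'
#' @param nSmall,nMedium,nLarge Number of sets per size class.
#' @param universeSize Size of the shared taxon universe
#'   (see [fixtureUniverse()]); must admit the largest requested class.
#' @param seed Integer seed; the result is byte-identical given the seed.
#' @return A [TaxonSetDatabase-class] with `nSmall + nMedium + nLarge`
#'   sets, categories cycling over the three curated-database categories.
#' @examples
#' db <- generateFixtureDB(2, 2, 1, universeSize = 300, seed = 1)
#' db
#' @export
generateFixtureDB <- function(nSmall, nMedium, nLarge, universeSize,
                              seed) {
    nSmall <- as.integer(nSmall); nMedium <- as.integer(nMedium)
    nLarge <- as.integer(nLarge)
    universeSize <- as.integer(universeSize)
    stopifnot(nSmall >= 0L, nMedium >= 0L, nLarge >= 0L)
    classes <- list(small = c(2L, 9L), medium = c(10L, 50L),
                    large = c(51L, min(150L, universeSize)))
    want <- c(small = nSmall, medium = nMedium, large = nLarge)
    for (cl in names(want))
        if (want[[cl]] > 0L && universeSize < classes[[cl]][1L])
            stop("universeSize = ", universeSize,
                 " cannot accommodate a ", cl, " set (needs >= ",
                 classes[[cl]][1L], " taxa)")
    universe <- fixtureUniverse(universeSize)
    cats <- setdiff(.CATEGORIES, "custom")
    .withSeed(seed, function() {
        sets <- list()
        k <- 0L
        for (cl in names(want)) {
            b <- classes[[cl]]
            hi <- min(b[2L], universeSize)
            for (i in seq_len(want[[cl]])) {
                k <- k + 1L
                size <- if (b[1L] >= hi) hi
                        else sample(b[1L]:hi, 1L)
                id <- sprintf("%s_%02d", cl, i)
                sets[[id]] <- TaxonSet(
                    setId = id,
                    displayName = sprintf("synthetic %s set %d", cl, i),
                    category = cats[(k - 1L) %% length(cats) + 1L],
                    members = sample(universe, size))
            }
        }
        db <- TaxonSetDatabase(sets)
        validObject(db)
        db
    })
}
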