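.DIALECTS <- list(
    generic   = list(taxon = NA_character_, rank = NA_character_),
    linda     = list(taxon = "taxon", rank = "log2FoldChange"),
    aldex2    = list(taxon = "taxon", rank = "effect"),
    fastancom = list(taxon = "taxon", rank = "beta"))

#' Read a differential abundance result table into RankedTaxa
#'
#' Ingests the per-taxon output of any differential abundance tool:
#' tab- or comma-separated text with a taxon-name column and a numeric
#' rank column (log2 fold change, effect size, correlation). Dialect
#' presets supply the default column names of common tools -- `linda`
#' (`log2FoldChange`), `aldex2` (`effect`), `fastancom` (`beta`), each
#' with taxon column `taxon` -- while `taxonCol`/`rankCol` always
#' override; the `generic` dialect requires both to be given.
#'
#' Taxon names are passed through [normalizeName()]. Rows whose rank
#' value is missing or non-finite are dropped with a logged count; a
#' duplicated taxon is ambiguous input and an error.
#'
#' @param path Path to the table.
#' @param taxonCol,rankCol Column names; override any dialect preset.
#' @param dialect One of `"generic"`, `"linda"`, `"aldex2"`,
#'   `"fastancom"`.
#' @param delimiter Field delimiter; default inferred from the file
#'   extension (`,` for `.csv`, tab otherwise).
#' @return A [RankedTaxa-class].
#' @export
readDaTable <- function(path, taxonCol = NULL, rankCol = NULL,
                        dialect = c("generic", "linda", "aldex2",
                                    "fastancom"),
                        delimiter = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stop("file not found: ", path)
    preset <- .DIALECTS[[dialect]]
    taxonCol <- taxonCol %||% preset$taxon
    rankCol <- rankCol %||% preset$rank
    if (is.na(taxonCol) || is.na(rankCol))
        stop("dialect 'generic' requires explicit taxonCol and rankCol")
    if (is.null(delimiter))
        delimiter <- if (tolower(tools::file_ext(path)) == "csv") ","
                     else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                             quote = "\"", comment.char = "",
                             check.names = FALSE,
                             stringsAsFactors = FALSE)
    for (col in c(taxonCol, rankCol))
        if (!col %in% colnames(tab))
            stop("column ", sQuote(col), " not found in ", path,
                 "; available columns: ",
                 paste(colnames(tab), collapse = ", "))
    taxa <- normalizeName(as.character(tab[[taxonCol]]))
    vals <- suppressWarnings(as.numeric(tab[[rankCol]]))
    bad <- !is.finite(vals)
    if (any(bad)) {
        .log(sum(bad), " row(s) with missing/non-finite rank values ",
             "dropped from ", basename(path))
        taxa <- taxa[!bad]
        vals <- vals[!bad]
    }
    if (length(vals) == 0L)
        stop("all rows of ", path, " had missing rank values")
    if (anyDuplicated(taxa))
        stop("duplicate taxon in ", path, ": ",
             paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
    RankedTaxa(vals, taxa = taxa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
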