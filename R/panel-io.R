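#' Read an RH genotype matrix
#'
#' Reads a delimited genotype matrix: header row of hybrid ids, first column
#' of marker ids, cells coding retained/absent/missing calls. Default codes
#' are `1` / `0` / `NA`; aliases are configurable (e.g. `missing = c("NA",
#' "U", "-")`). Marker order in the file is the storage order — nothing is
#' sorted, since marker order is the object under study.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param codes named list with character vectors `retained`, `absent`,
#'   `missing` of accepted cell tokens.
#' @return an [RHPanel-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("marker\th1\th2", "mA\t1\t0", "mB\tNA\t1"), tf)
#' readPanel(tf)
#' @export
readPanel <- function(path, dialect = c("tsv", "csv"),
                      codes = list(retained = "1", absent = "0",
                                   missing = "NA")) {
    dialect <- match.arg(dialect)
    sep <- if (dialect == "tsv") "\t" else ","
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     colClasses = "character", na.strings = NULL,
                     stringsAsFactors = FALSE)
    if (nrow(df) == 0L)
        stop("no markers in ", path)
    if (ncol(df) < 2L)
        stop("no hybrids in ", path)
    ids <- df[[1]]
    if (anyDuplicated(ids))
        stop("duplicate marker id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    hyb <- colnames(df)[-1]
    raw <- as.matrix(df[, -1, drop = FALSE])
    M <- matrix(NA_integer_, nrow = nrow(raw), ncol = ncol(raw),
                dimnames = list(ids, hyb))
    M[raw %in% codes$retained] <- .RETAINED
    M[raw %in% codes$absent] <- .ABSENT
    known <- matrix(raw %in% unlist(codes), nrow = nrow(raw))
    if (!all(known)) {
        bad <- which(!known, arr.ind = TRUE)[1, ]
        stop(sprintf("malformed cell code '%s' at marker '%s', hybrid '%s'",
                     raw[bad[1], bad[2]], ids[bad[1]], hyb[bad[2]]))
    }
    RHPanel(M)
}

#' Write an RH genotype matrix
#'
#' Inverse of [readPanel()]: `readPanel(writePanel(p, f))` reproduces the
#' panel cell-for-cell. Cells are written as `1` / `0` / `NA`.
#'
#' @param panel an [RHPanel-class]; must have at least one hybrid.
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
writePanel <- function(panel, path, dialect = c("tsv", "csv")) {
    stopifnot(is(panel, "RHPanel"))
    dialect <- match.arg(dialect)
    if (nHybrids(panel) == 0L)
        stop("panel has no hybrids")
    m <- calls(panel)
    out <- cbind(marker = rownames(m),
                 as.data.frame(m, check.names = FALSE))
    write.table(out, path, sep = if (dialect == "tsv") "\t" else ",",
                quote = FALSE, row.names = FALSE, na = "NA")
    invisible(path)
}

#' Export a panel in the CarthaGene radiated-hybrid dialect
#'
#' Writes the text dialect consumed by the CarthaGene mapping program for
#' radiation hybrid data: a data-type declaration line, a line with the
#' hybrid and marker counts, then one `*marker genotypes` line per marker
#' with one symbol per hybrid — `1` retained, `0` absent, `-` missing — so
#' maps can be cross-checked against the original tool.
#'
#' @param panel an [RHPanel-class]; marker ids must contain no whitespace.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
exportCarthagene <- function(panel, path) {
    stopifnot(is(panel, "RHPanel"))
    ids <- markerNames(panel)
    if (any(grepl("[[:space:]]", ids)))
        stop("marker ids must not contain whitespace: ",
             paste(ids[grepl("[[:space:]]", ids)], collapse = ", "))
    m <- calls(panel)
    sym <- matrix("-", nrow = nrow(m), ncol = ncol(m))
    sym[!is.na(m) & m == .RETAINED] <- "1"
    sym[!is.na(m) & m == .ABSENT] <- "0"
    geno <- apply(sym, 1L, paste, collapse = "")
    lines <- c("data type radiated hybrid",
               paste(nHybrids(panel), nMarkers(panel), "0 0"),
               paste0("*", ids, " ", geno))
    writeLines(lines, path)
    invisible(path)
}

#' Read a reference marker order
#'
#' Two-column delimited file: rank, marker id. Rows are sorted by rank; ids
#' must be unique. Used as the reference side of [orderConcordance()].
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return character vector of marker ids in reference order.
#' @export
readReferenceOrder <- function(path, dialect = c("tsv", "csv")) {
    dialect <- match.arg(dialect)
    df <- read.delim(path, sep = if (dialect == "tsv") "\t" else ",",
                     header = TRUE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("expected columns: rank, marker_id")
    ids <- as.character(df[[2]][order(df[[1]])])
    if (anyDuplicated(ids))
        stop("duplicate marker id(s) in reference order")
    ids
}
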