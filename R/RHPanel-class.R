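#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats optimize pchisq rbinom runif rpois setNames
#' @importFrom utils read.delim write.table head
NULL

# genotype codes used in the calls assay: 1 = retained, 0 = absent, NA = missing
.RETAINED <- 1L
.ABSENT <- 0L

#' RHPanel: a radiation hybrid genotype panel
#'
#' An `RHPanel` holds the genotype matrix of a radiation hybrid (RH) panel:
#' markers (rows) scored across hybrid cell lines (columns), each call being
#' retained (`1`), absent (`0`) or missing (`NA`). The class extends
#' [SummarizedExperiment::SummarizedExperiment] with a single `"calls"` assay;
#' marker metadata (chromosome, physical position, reference rank, marker
#' class) lives in `rowData` and provenance (irradiation combination, dose,
#' simulation truth) in `metadata`.
#'
#' @slot .  See [SummarizedExperiment::SummarizedExperiment]; the `"calls"`
#'   assay is an integer matrix over \{0, 1, NA\} with unique rownames
#'   (marker ids) and unique colnames (hybrid ids).
#'
#' @seealso [readPanel()], [simulatePanel()], [retentionReport()]
#' @export
setClass("RHPanel", contains = "SummarizedExperiment")

.validRHPanel <- function(object) {
    msg <- NULL
    if (!("calls" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'calls' is required")
    else {
        m <- SummarizedExperiment::assay(object, "calls")
        bad <- !(m %in% c(0L, 1L) | is.na(m))
        if (any(bad))
            msg <- c(msg, "calls must be 0 (absent), 1 (retained) or NA (missing)")
    }
    rn <- rownames(object)
    if ((is.null(rn) && nrow(object) > 0L) || anyDuplicated(rn))
        msg <- c(msg, "marker ids (rownames) must be present and unique")
    cn <- colnames(object)
    if ((is.null(cn) && ncol(object) > 0L) || anyDuplicated(cn))
        msg <- c(msg, "hybrid ids (colnames) must be present and unique")
    if (is.null(msg)) TRUE else msg
}
setValidity("RHPanel", .validRHPanel)

#' Construct an RHPanel from a genotype matrix
#'
#' @param calls integer/numeric matrix, markers x hybrids, values in
#'   \{0, 1, NA\}. Rownames are marker ids, colnames hybrid ids; default ids
#'   `M1..` / `H1..` are supplied when absent.
#' @param chromosome character vector of chromosome labels per marker
#'   (recycled), e.g. `"5A"`.
#' @param position_bp optional non-negative integer positions (bp) per marker.
#' @param ref_rank optional integer rank of each marker in a reference order
#'   (deletion-bin or genome-zipper rank).
#' @param marker_class optional marker class per marker (`"SSR"` or `"EST"`).
#' @param meta named list of free-form provenance (combination label, dose).
#'
#' @return an [RHPanel-class] object.
#' @examples
#' m <- matrix(c(1, 0, NA, 1, 0, 0), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("mA", "mB", "mC"), c("h1", "h2")))
#' p <- RHPanel(m, chromosome = "5A")
#' callCounts(p)
#' @export
RHPanel <- function(calls, chromosome = NA_character_, position_bp = NA_integer_,
                    ref_rank = NA_integer_, marker_class = NA_character_,
                    meta = list()) {
    calls <- as.matrix(calls)
    storage.mode(calls) <- "integer"
    if (is.null(rownames(calls)) && nrow(calls) > 0L)
        rownames(calls) <- paste0("M", seq_len(nrow(calls)))
    if (is.null(colnames(calls)) && ncol(calls) > 0L)
        colnames(calls) <- paste0("H", seq_len(ncol(calls)))
    nm <- nrow(calls)
    pos <- suppressWarnings(as.integer(position_bp))
    if (any(!is.na(pos) & pos < 0))
        stop("position_bp must be >= 0")
    rd <- S4Vectors::DataFrame(
        chromosome = rep_len(as.character(chromosome), nm),
        position_bp = rep_len(pos, nm),
        ref_rank = rep_len(as.integer(ref_rank), nm),
        marker_class = rep_len(as.character(marker_class), nm),
        row.names = rownames(calls))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(calls = calls), rowData = rd, metadata = meta)
    new("RHPanel", se)
}

#' @rdname RHPanel-accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' Accessors for RHPanel objects
#'
#' `calls()` returns the genotype matrix (1 retained, 0 absent, NA missing);
#' `markerNames()` and `hybridNames()` the row/column ids; `markerInfo()` the
#' marker metadata as a data.frame; `nMarkers()`/`nHybrids()` the dimensions;
#' `callCounts()` the tally of retained/absent/missing calls.
#'
#' @param x an [RHPanel-class].
#' @return see individual descriptions.
#' @name RHPanel-accessors
#' @aliases calls markerNames hybridNames markerInfo nMarkers nHybrids callCounts
#' @examples
#' p <- RHPanel(matrix(c(1, NA, 0, 1), 2, 2))
#' nMarkers(p); callCounts(p)
NULL

#' @rdname RHPanel-accessors
#' @export
setMethod("calls", "RHPanel", function(x)
    SummarizedExperiment::assay(x, "calls"))

#' @rdname RHPanel-accessors
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))

#' @rdname RHPanel-accessors
#' @export
setMethod("markerNames", "RHPanel", function(x) rownames(x))

#' @rdname RHPanel-accessors
#' @export
setGeneric("hybridNames", function(x) standardGeneric("hybridNames"))

#' @rdname RHPanel-accessors
#' @export
setMethod("hybridNames", "RHPanel", function(x) colnames(x))

#' @rdname RHPanel-accessors
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname RHPanel-accessors
#' @export
setMethod("markerInfo", "RHPanel", function(x)
    as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname RHPanel-accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname RHPanel-accessors
#' @export
setMethod("nMarkers", "RHPanel", function(x) nrow(x))

#' @rdname RHPanel-accessors
#' @export
setGeneric("nHybrids", function(x) standardGeneric("nHybrids"))

#' @rdname RHPanel-accessors
#' @export
setMethod("nHybrids", "RHPanel", function(x) ncol(x))

#' @rdname RHPanel-accessors
#' @export
setGeneric("callCounts", function(x) standardGeneric("callCounts"))

#' @rdname RHPanel-accessors
#' @export
setMethod("callCounts", "RHPanel", function(x) {
    m <- calls(x)
    c(retained = sum(m == .RETAINED, na.rm = TRUE),
      absent = sum(m == .ABSENT, na.rm = TRUE),
      missing = sum(is.na(m)))
})

setMethod("show", "RHPanel", function(object) {
    cc <- callCounts(object)
    tot <- sum(cc)
    cat("RHPanel:", nMarkers(object), "markers x", nHybrids(object),
        "hybrids\n")
    if (tot > 0)
        cat(sprintf("  calls: %d retained (%.1f%%), %d absent, %d missing\n",
                    cc["retained"], 100 * cc["retained"] / tot,
                    cc["absent"], cc["missing"]))
    chr <- unique(markerInfo(object)$chromosome)
    chr <- chr[!is.na(chr)]
    if (length(chr))
        cat("  chromosomes:", paste(head(chr, 8), collapse = ", "),
            if (length(chr) > 8) "..." else "", "\n")
})
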