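#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData colData<-
NULL

#' VariantMatrix: multi-sample variant calls with read-level allele depths
#'
#' `VariantMatrix` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds haploid consensus genotypes for a cohort of isolates, together with
#' per-sample read depths supporting the reference and alternative alleles.
#' Rows are variant sites, columns are samples.
#'
#' Assays:
#' \describe{
#'   \item{genotype}{integer matrix; 0 = reference allele, k >= 1 = k-th
#'     alternative allele, `NA` = missing call.}
#'   \item{refDepth, altDepth}{integer matrices of reads supporting the
#'     reference and (summed over alternatives) the alternative alleles;
#'     `NA` when the source VCF carried no depth field.}
#' }
#'
#' Row metadata columns: `position` (0-based reference coordinate), `ref`,
#' `alt` (comma-separated for multiallelic sites) and `class`
#' (`"SNP"` or `"indel"`). Positions are strictly increasing.
#'
#' @seealso [readVariants()], [filterBiallelicMaf()], [findSegregatingSites()]
#' @export
setClass("VariantMatrix", contains = "SummarizedExperiment")

.validVariantMatrix <- function(object) {
    msg <- character()
    rd <- rowData(object)
    need <- c("position", "ref", "alt", "class")
    if (!all(need %in% colnames(rd)))
        return(paste("rowData must contain columns:", paste(need, collapse = ", ")))
    if (!all(c("genotype", "refDepth", "altDepth") %in% names(assays(object))))
        return("assays must contain 'genotype', 'refDepth' and 'altDepth'")
    pos <- rd$position
    if (length(pos) > 1L && any(diff(pos) <= 0))
        msg <- c(msg, "positions must be strictly increasing")
    if (any(pos < 0, na.rm = TRUE))
        msg <- c(msg, "positions must be non-negative (0-based)")
    bad <- !rd$class %in% c("SNP", "indel")
    if (any(bad))
        msg <- c(msg, "variant class must be 'SNP' or 'indel'")
    gt <- assay(object, "genotype")
    if (nrow(gt)) {
        nAlt <- lengths(strsplit(as.character(rd$alt), ",", fixed = TRUE))
        mx <- suppressWarnings(apply(gt, 1L, max, na.rm = TRUE))
        mx[!is.finite(mx)] <- 0
        if (any(mx > nAlt))
            msg <- c(msg, "genotype index exceeds the number of alternative alleles at its site")
        if (any(gt < 0, na.rm = TRUE))
            msg <- c(msg, "genotype indices must be >= 0")
    }
    if (length(msg)) msg else TRUE
}
setValidity("VariantMatrix", .validVariantMatrix)

#' Construct a VariantMatrix
#'
#' @param position integer vector of 0-based reference positions, strictly
#'   increasing.
#' @param ref,alt character vectors of reference and alternative alleles;
#'   `alt` may be comma-separated for multiallelic sites.
#' @param genotype integer matrix (sites x samples); 0 = ref, k = k-th alt,
#'   `NA` = missing.
#' @param refDepth,altDepth optional integer matrices matching `genotype`;
#'   `NULL` means depths unknown.
#' @param sampleIds character vector of sample identifiers; defaults to
#'   `colnames(genotype)`.
#' @param class optional character vector `"SNP"`/`"indel"`; inferred from
#'   allele lengths when `NULL`.
#' @return A [VariantMatrix-class] object.
#' @examples
#' vm <- VariantMatrix(position = c(9L, 99L), ref = c("A", "T"),
#'                     alt = c("G", "C"),
#'                     genotype = matrix(c(0L, 1L, 1L, 0L), 2,
#'                                       dimnames = list(NULL, c("s1", "s2"))))
#' variantPositions(vm)
#' @export
VariantMatrix <- function(position, ref, alt, genotype,
                          refDepth = NULL, altDepth = NULL,
                          sampleIds = colnames(genotype), class = NULL) {
    genotype <- as.matrix(genotype)
    storage.mode(genotype) <- "integer"
    n <- nrow(genotype)
    stopifnot(length(position) == n, length(ref) == n, length(alt) == n)
    if (is.null(sampleIds))
        sampleIds <- paste0("S", seq_len(ncol(genotype)))
    if (anyDuplicated(sampleIds))
        stop("duplicated sample ids: ",
             paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
    naMat <- function(x) {
        if (is.null(x)) {
            x <- matrix(NA_integer_, nrow(genotype), ncol(genotype))
        } else {
            x <- as.matrix(x)
            storage.mode(x) <- "integer"
        }
        dimnames(x) <- dimnames(genotype)
        x
    }
    if (is.null(class)) {
        altLens <- vapply(strsplit(as.character(alt), ",", fixed = TRUE),
                          function(a) max(nchar(a)), integer(1))
        class <- ifelse(nchar(ref) == 1L & altLens == 1L, "SNP", "indel")
    }
    colnames(genotype) <- sampleIds
    se <- SummarizedExperiment(
        assays = SimpleList(genotype = genotype,
                            refDepth = naMat(refDepth),
                            altDepth = naMat(altDepth)),
        rowData = DataFrame(position = as.integer(position),
                            ref = as.character(ref),
                            alt = as.character(alt),
                            class = as.character(class)))
    new("VariantMatrix", se)
}

#' @describeIn VariantMatrix number of variant sites and samples
#' @param object,x a `VariantMatrix`
#' @export
setMethod("show", "VariantMatrix", function(object) {
    cat("VariantMatrix:", nrow(object), "sites x", ncol(object), "samples\n")
    cls <- table(rowData(object)$class)
    cat("  classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
    cat("  depths:",
        if (all(is.na(assay(object, "refDepth")))) "absent" else "present", "\n")
    if (ncol(colData(object)))
        cat("  colData:", paste(colnames(colData(object)), collapse = ", "), "\n")
    invisible(NULL)
})

#' @rdname VariantMatrix
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname VariantMatrix
#' @export
setMethod("genotypes", "VariantMatrix", function(x) assay(x, "genotype"))

#' @rdname VariantMatrix
#' @export
setGeneric("refDepth", function(x) standardGeneric("refDepth"))
#' @rdname VariantMatrix
#' @export
setMethod("refDepth", "VariantMatrix", function(x) assay(x, "refDepth"))

#' @rdname VariantMatrix
#' @export
setGeneric("altDepth", function(x) standardGeneric("altDepth"))
#' @rdname VariantMatrix
#' @export
setMethod("altDepth", "VariantMatrix", function(x) assay(x, "altDepth"))

#' @rdname VariantMatrix
#' @export
setGeneric("variantPositions", function(x) standardGeneric("variantPositions"))
#' @rdname VariantMatrix
#' @export
setMethod("variantPositions", "VariantMatrix",
          function(x) rowData(x)$position)

#' @rdname VariantMatrix
#' @export
setGeneric("variantClass", function(x) standardGeneric("variantClass"))
#' @rdname VariantMatrix
#' @export
setMethod("variantClass", "VariantMatrix", function(x) rowData(x)$class)

#' @rdname VariantMatrix
#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))
#' @rdname VariantMatrix
#' @export
setMethod("refAllele", "VariantMatrix", function(x) rowData(x)$ref)

#' @rdname VariantMatrix
#' @export
setGeneric("altAllele", function(x) standardGeneric("altAllele"))
#' @rdname VariantMatrix
#' @export
setMethod("altAllele", "VariantMatrix", function(x) rowData(x)$alt)

#' @rdname VariantMatrix
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname VariantMatrix
#' @export
setMethod("sampleIds", "VariantMatrix", function(x) colnames(x))

#' DapcResult: discriminant analysis of principal components
#'
#' Container for a fitted DAPC model: the number of retained principal
#' components and discriminant axes, sample coordinates on the discriminant
#' axes, per-group posterior assignment probabilities, and the fraction of
#' samples assigned to their a priori group.
#'
#' @slot nPca number of retained principal components.
#' @slot nDa number of discriminant axes.
#' @slot scores samples x discriminant-axis coordinate matrix.
#' @slot posterior samples x groups assignment-probability matrix (rows sum
#'   to 1).
#' @slot assigned factor of argmax-posterior group per sample.
#' @slot groups factor of a priori group labels.
#' @slot assignmentRate fraction of samples whose assigned group equals their
#'   a priori label.
#' @slot eigenvalues discriminant eigenvalues.
#' @seealso [fitDapc()], [findClusters()], [selectNPca()]
#' @export
setClass("DapcResult",
         representation(nPca = "integer", nDa = "integer",
                        scores = "matrix", posterior = "matrix",
                        assigned = "factor", groups = "factor",
                        assignmentRate = "numeric", eigenvalues = "numeric"))

setValidity("DapcResult", function(object) {
    msg <- character()
    if (nrow(object@posterior)) {
        rs <- rowSums(object@posterior)
        if (any(abs(rs - 1) > 1e-9))
            msg <- c(msg, "posterior rows must sum to 1")
    }
    if (object@nDa > max(1L, nlevels(object@groups) - 1L))
        msg <- c(msg, "nDa may not exceed (number of groups - 1)")
    if (length(msg)) msg else TRUE
})

#' @describeIn DapcResult compact display
#' @param object a `DapcResult`
#' @export
setMethod("show", "DapcResult", function(object) {
    cat("DapcResult:", nrow(object@scores), "samples,",
        nlevels(object@groups), "groups\n")
    cat("  retained PCs:", object@nPca, " discriminant axes:", object@nDa, "\n")
    cat(sprintf("  correct assignment rate: %.3f\n", object@assignmentRate))
    invisible(NULL)
})

#' @rdname DapcResult
#' @param x a `DapcResult`
#' @export
setGeneric("assignmentRate", function(x) standardGeneric("assignmentRate"))
#' @rdname DapcResult
#' @export
setMethod("assignmentRate", "DapcResult", function(x) x@assignmentRate)

#' @rdname DapcResult
#' @export
setGeneric("assignmentProbs", function(x) standardGeneric("assignmentProbs"))
#' @rdname DapcResult
#' @export
setMethod("assignmentProbs", "DapcResult", function(x) x@posterior)

#' @rdname DapcResult
#' @export
setGeneric("dapcScores", function(x) standardGeneric("dapcScores"))
#' @rdname DapcResult
#' @export
setMethod("dapcScores", "DapcResult", function(x) x@scores)
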