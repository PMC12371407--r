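#' Biallelic minor-allele-frequency filter for structure analysis
#'
#' Reproduces the conventional `--max-alleles 2 --maf 0.05 --remove-indels`
#' site selection: indels are removed, only biallelic SNPs are kept, and the
#' minor allele frequency — computed over non-missing haploid calls — must be
#' strictly greater than `maf`. The sample set is unchanged and site order is
#' preserved, so the filter is idempotent.
#'
#' @param vm a [VariantMatrix-class].
#' @param maf minor-allele-frequency threshold (sites with MAF <= `maf` are
#'   removed).
#' @return The filtered [VariantMatrix-class]; empty (with a warning) when no
#'   site survives.
#' @export
filterBiallelicMaf <- function(vm, maf = 0.05) {
    if (nrow(vm) == 0L) return(vm)
    gt <- genotypes(vm)
    nAlts <- lengths(strsplit(altAllele(vm), ",", fixed = TRUE))
    keep <- logical(nrow(vm))
    for (i in seq_len(nrow(vm))) {
        if (variantClass(vm)[i] != "SNP" || nAlts[i] > 1L) next
        g <- gt[i, ]
        g <- g[!is.na(g)]
        if (!length(g)) next
        tab <- tabulate(g + 1L, nbins = 2L)
        if (sum(tab > 0L) != 2L) next
        keep[i] <- min(tab) / length(g) > maf
    }
    if (!any(keep))
        warning("no site passes the biallelic MAF filter")
    vm[keep, ]
}

#' Identify segregating sites from consensus calls
#'
#' A site is segregating when the number of samples whose consensus call is
#' an alternative allele is *strictly greater* than `min_carriers`
#' (the ~5% convention for cohorts of ~140 isolates: alternative variants
#' conserved in more than seven samples). Missing calls are never carriers. With
#' `min_carriers = 0` this returns exactly the polymorphic sites.
#'
#' @param vm a [VariantMatrix-class].
#' @param min_carriers integer carrier-count threshold.
#' @return An object of class `SegregatingSites`: a list with `positions`
#'   (0-based, subset of the input positions in order) and `min_carriers`.
#' @export
findSegregatingSites <- function(vm, min_carriers = 7L) {
    gt <- genotypes(vm)
    carriers <- if (nrow(vm))
        rowSums(!is.na(gt) & gt >= 1L) else integer(0)
    structure(list(positions = variantPositions(vm)[carriers > min_carriers],
                   min_carriers = as.integer(min_carriers)),
              class = "SegregatingSites")
}

#' @export
print.SegregatingSites <- function(x, ...) {
    cat("SegregatingSites:", length(x$positions),
        "sites (carrier count >", x$min_carriers, ")\n")
    invisible(x)
}

## resolve a site-set argument (SegregatingSites, numeric positions, or NULL
## meaning all sites of vm) to a vector of 0-based positions
.sitePositions <- function(sites, vm = NULL) {
    if (is.null(sites)) {
        if (is.null(vm)) stop("sites must be given")
        return(variantPositions(vm))
    }
    if (inherits(sites, "SegregatingSites")) return(sites$positions)
    as.integer(sites)
}

#' Subset a VariantMatrix to a site set
#'
#' @param vm a [VariantMatrix-class].
#' @param sites a `SegregatingSites` object or integer vector of 0-based
#'   positions.
#' @return The subsetted [VariantMatrix-class].
#' @export
variantsAtSites <- function(vm, sites) {
    vm[variantPositions(vm) %in% .sitePositions(sites, vm), ]
}
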