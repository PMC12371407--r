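#' @importFrom stats kmeans predict sd var
NULL

## samples x sites numeric 0/1 matrix with per-site mean imputation
.genotypeNumeric <- function(vm) {
    X <- t(genotypes(vm))
    storage.mode(X) <- "double"
    X[X > 1] <- 1  # alt-allele indicator regardless of alt index
    for (j in seq_len(ncol(X))) {
        m <- X[, j]
        if (anyNA(m)) {
            mu <- mean(m, na.rm = TRUE)
            if (is.nan(mu)) mu <- 0
            X[is.na(m), j] <- mu
        }
    }
    X
}

#' Principal component analysis of a genotype matrix
#'
#' Column-centred decomposition of the samples x sites 0/1 alt-allele
#' indicator matrix (missing calls mean-imputed per site). Eigenvalues are
#' the variances of the principal components (denominator n - 1), so their
#' sum equals the total variance of the centred matrix; retaining all
#' components reproduces the centred data exactly.
#'
#' @param vm a [VariantMatrix-class], or a samples x sites numeric matrix.
#' @return list with `scores` (samples x components), `eigenvalues`,
#'   `rotation` (sites x components) and `center`.
#' @export
genotypePca <- function(vm) {
    X <- if (is(vm, "VariantMatrix")) .genotypeNumeric(vm) else as.matrix(vm)
    if (nrow(X) < 2L) stop("need at least 2 samples")
    ctr <- colMeans(X)
    Xc <- sweep(X, 2L, ctr)
    if (all(abs(Xc) < 1e-12)) stop("zero-variance genotype matrix")
    sv <- svd(Xc)
    keep <- sv$d > max(sv$d) * 1e-9
    scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep],
                                                  nrow = sum(keep))
    rownames(scores) <- rownames(X)
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
    list(scores = scores,
         eigenvalues = sv$d[keep]^2 / (nrow(X) - 1L),
         rotation = sv$v[, keep, drop = FALSE], center = ctr)
}

#' BIC-scored k-means selection of the number of genetic clusters
#'
#' For each K in `kRange`, k-means (best of `restarts` seeded
#' initializations) is run on the first `nPca` principal-component score
#' columns and scored with the k-means BIC
#' \eqn{BIC(K) = n\,\ln(WSS_K/n) + K\,\ln(n)}, where \eqn{WSS_K} is the
#' total within-cluster sum of squares. The most likely number of genetic
#' groups minimizes the BIC.
#'
#' @param scores samples x components matrix (see [genotypePca()]).
#' @param kRange candidate cluster numbers (default 1:40).
#' @param nPca number of score columns used (default: all).
#' @param restarts k-means restarts per K.
#' @param seed optional integer seed (fixing it makes the curve
#'   bit-reproducible).
#' @return list with `bic` (data.frame `k`, `bic`), `best_k`, and `clusters`
#'   (labels at `best_k`).
#' @export
findClusters <- function(scores, kRange = 1:40, nPca = NULL, restarts = 20L,
                         seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (is.null(nPca)) nPca <- ncol(scores)
    X <- scores[, seq_len(min(nPca, ncol(scores))), drop = FALSE]
    n <- nrow(X)
    ok <- kRange[kRange < n]
    if (length(ok) < length(kRange))
        warning("cluster numbers >= sample count skipped: ",
                paste(setdiff(kRange, ok), collapse = ", "))
    fits <- vector("list", length(ok))
    bic <- vapply(seq_along(ok), function(i) {
        K <- ok[i]
        if (K == 1L) {
            wss <- sum(sweep(X, 2L, colMeans(X))^2)
            fits[[i]] <<- rep(1L, n)
        } else {
            km <- suppressWarnings(kmeans(X, centers = K, nstart = restarts,
                                          iter.max = 50L))
            wss <- km$tot.withinss
            fits[[i]] <<- km$cluster
        }
        n * log(max(wss, 1e-12) / n) + K * log(n)
    }, numeric(1))
    best <- ok[which.min(bic)]
    list(bic = data.frame(k = ok, bic = bic), best_k = best,
         clusters = fits[[which.min(bic)]])
}

## internal DAPC fit on precomputed PC scores; returns the lda model
.ldaOnScores <- function(scores, labels, nPca) {
    X <- scores[, seq_len(min(nPca, ncol(scores))), drop = FALSE]
    suppressWarnings(MASS::lda(X, grouping = labels))
}

#' Cross-validated choice of the number of retained principal components
#'
#' Stratified cross-validation of DAPC group assignment: for each candidate
#' number of retained PCs, samples are split into `folds` folds within each
#' group, a discriminant model is fitted on the training folds and the held
#' out samples are assigned; the candidate with the lowest root mean squared
#' assignment error (RMSE over folds of 1 - proportion correctly assigned)
#' is returned, ties resolved toward fewer components. Groups with a single
#' sample are excluded with a warning.
#'
#' @param scores samples x components matrix.
#' @param labels factor of a priori group labels.
#' @param candidates integer vector of candidate PC numbers.
#' @param folds number of CV folds.
#' @param seed optional integer seed (the fold split is the only randomness).
#' @return list with `n_pca` (the chosen candidate) and `rmse` (named
#'   numeric, per candidate).
#' @export
selectNPca <- function(scores, labels, candidates = NULL, folds = 5L,
                       seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    labels <- droplevels(factor(labels))
    singleton <- names(which(table(labels) < 2L))
    if (length(singleton)) {
        warning("group(s) with a single sample excluded: ",
                paste(singleton, collapse = ", "))
        keep <- !labels %in% singleton
        scores <- scores[keep, , drop = FALSE]
        labels <- droplevels(labels[keep])
    }
    n <- nrow(scores)
    maxPca <- min(ncol(scores), n - nlevels(labels) - 1L)
    if (is.null(candidates))
        candidates <- unique(pmax(1L, round(seq(2, maxPca, length.out = 8))))
    candidates <- sort(unique(pmin(candidates, maxPca)))
    fold <- integer(n)
    for (g in levels(labels)) {
        idx <- which(labels == g)
        fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    rmse <- vapply(candidates, function(p) {
        errs <- vapply(seq_len(folds), function(f) {
            tr <- fold != f; te <- !tr
            if (!any(te) || nlevels(droplevels(labels[tr])) < 2L)
                return(NA_real_)
            fit <- .ldaOnScores(scores[tr, , drop = FALSE],
                                droplevels(labels[tr]), p)
            pr <- predict(fit, scores[te, seq_len(min(p, ncol(scores))),
                                      drop = FALSE])
            1 - mean(as.character(pr$class) == as.character(labels[te]))
        }, numeric(1))
        sqrt(mean(errs^2, na.rm = TRUE))
    }, numeric(1))
    names(rmse) <- candidates
    list(n_pca = candidates[which.min(rmse)], rmse = rmse)
}

#' Fit a discriminant analysis of principal components
#'
#' Linear discriminant axes maximizing the between/within group variance
#' ratio on the retained principal components; assignment probabilities come
#' from the per-group Gaussian densities in discriminant space, and the
#' correct assignment rate is the fraction of samples whose maximum
#' posterior group equals their a priori label.
#'
#' @param scores samples x components matrix (see [genotypePca()]).
#' @param labels factor of a priori group labels (every group needs >= 2
#'   samples).
#' @param nPca number of retained principal components.
#' @param nDa number of discriminant axes (default
#'   `min(nlevels(labels) - 1, nPca)`).
#' @return A [DapcResult-class].
#' @export
fitDapc <- function(scores, labels, nPca, nDa = NULL) {
    labels <- droplevels(factor(labels))
    if (nlevels(labels) < 2L) stop("need at least 2 groups")
    small <- names(which(table(labels) < 2L))
    if (length(small))
        stop("group(s) smaller than 2 samples: ",
             paste(small, collapse = ", "))
    nPca <- min(nPca, ncol(scores))
    if (is.null(nDa)) nDa <- min(nlevels(labels) - 1L, nPca)
    nDa <- min(nDa, nlevels(labels) - 1L)
    fit <- .ldaOnScores(scores, labels, nPca)
    pr <- predict(fit, scores[, seq_len(nPca), drop = FALSE])
    ld <- pr$x[, seq_len(min(nDa, ncol(pr$x))), drop = FALSE]
    post <- pr$posterior
    post <- post / rowSums(post)
    new("DapcResult", nPca = as.integer(nPca), nDa = as.integer(nDa),
        scores = ld, posterior = post, assigned = pr$class, groups = labels,
        assignmentRate = mean(as.character(pr$class) ==
                              as.character(labels)),
        eigenvalues = fit$svd[seq_len(min(nDa, length(fit$svd)))]^2)
}
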