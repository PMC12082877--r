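#' Number of nontrivial FAMD dimensions
#'
#' For K quantitative variables and qualitative variables with c_q
#' categories each, the mixed-data factor analysis has
#' K + sum(c_q - 1) nontrivial dimensions, which also equals the total
#' inertia. Three quantitative metrics plus two 2-level labels give 5.
#'
#' @param nQuant number of quantitative variables (>= 0).
#' @param categoryCounts integer vector of category counts (each >= 2),
#'   one per qualitative variable; may be empty.
#' @return Integer dimension count.
#' @examples
#' famdDimensionCount(3, c(2, 2))  # 5
#' @export
famdDimensionCount <- function(nQuant, categoryCounts = integer(0)) {
  stopifnot(nQuant >= 0, all(categoryCounts >= 2))
  as.integer(nQuant + sum(categoryCounts - 1))
}

#' Factor analysis of mixed data
#'
#' Joint dimension reduction of quantitative and qualitative variables in
#' which both sets are normalized to balance their influence: quantitative
#' columns are standardized to mean 0 and variance 1 (variance divisor n),
#' and each qualitative variable is expanded to category indicators, each
#' indicator divided by the square root of its category proportion and then
#' centered (the MCA scaling). The combined n x (K + sum(c_q)) matrix,
#' scaled by 1/sqrt(n), is decomposed by SVD; eigenvalues are the squared
#' singular values. The sign of each dimension is fixed by making the
#' largest-magnitude quantitative loading positive.
#'
#' @param data data.frame holding the variables.
#' @param quantVars character names of quantitative columns (finite, no
#'   missing values, nonzero variance).
#' @param qualVars character names of qualitative columns (factors or
#'   character, >= 2 observed levels each).
#' @param nComponents number of dimensions to return (default: all
#'   nontrivial ones).
#' @return A [FAMDResult-class].
#' @examples
#' tab <- simulateCohort(cohortSimConfig(seed = 5))
#' res <- famd(tab, c("aspect_ratio", "m2", "mito_count"),
#'             c("sex", "genotype"))
#' famdEigenvalues(res)
#' @export
famd <- function(data, quantVars, qualVars = character(0),
                 nComponents = NULL) {
  stopifnot(is.data.frame(data), length(quantVars) + length(qualVars) >= 1,
            all(c(quantVars, qualVars) %in% names(data)))
  n <- nrow(data)
  cols <- list(); colVar <- character(0); quantIdx <- integer(0)
  for (v in quantVars) {
    x <- data[[v]]
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
      stop("quantitative column '", v, "' must be finite with no missing ",
           "values")
    s <- sqrt(sum((x - mean(x))^2) / n)
    if (s == 0)
      stop("normalization error: quantitative column '", v,
           "' has zero variance")
    cols[[length(cols) + 1L]] <- (x - mean(x)) / s
    colVar <- c(colVar, v)
    quantIdx <- c(quantIdx, length(cols))
  }
  catCounts <- integer(0)
  for (v in qualVars) {
    f <- droplevels(factor(data[[v]]))
    if (anyNA(f)) stop("qualitative column '", v, "' has missing values")
    if (nlevels(f) < 2L)
      stop("level error: qualitative column '", v,
           "' has fewer than 2 observed levels")
    catCounts <- c(catCounts, nlevels(f))
    ind <- stats::model.matrix(~ f - 1)
    prop <- colMeans(ind)
    for (j in seq_len(ncol(ind))) {
      z <- ind[, j] / sqrt(prop[j])
      cols[[length(cols) + 1L]] <- z - mean(z)
      colVar <- c(colVar, v)
    }
  }
  Z <- do.call(cbind, cols)
  nontrivial <- famdDimensionCount(length(quantVars), catCounts)
  if (n <= nontrivial)
    warning("fewer rows than nontrivial dimensions; trailing eigenvalues ",
            "will be rank-deficient")
  ndim <- if (is.null(nComponents)) nontrivial else
    min(as.integer(nComponents), nontrivial)
  sv <- svd(Z / sqrt(n))
  # eigenvalue table always spans every nontrivial dimension;
  # nComponents only limits the score/loading outputs
  eigAll <- sv$d[seq_len(min(nontrivial, length(sv$d)))]^2
  keep <- seq_len(min(ndim, length(sv$d)))
  d <- sv$d[keep]; U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  # sign convention: largest-|loading| quantitative (or first) column
  # positive in each dimension
  ref <- if (length(quantIdx)) quantIdx else seq_len(nrow(V))
  for (s in seq_along(keep)) {
    jstar <- ref[which.max(abs(V[ref, s]))]
    if (V[jstar, s] < 0) {
      V[, s] <- -V[, s]
      U[, s] <- -U[, s]
    }
  }
  totalInertia <- sum(sv$d^2)
  scores <- sqrt(n) * U %*% diag(d, length(d))
  rownames(scores) <- rownames(data)
  colnames(scores) <- paste0("Dim", seq_along(keep))
  vars <- c(quantVars, qualVars)
  contrib <- matrix(0, length(vars), length(keep),
                    dimnames = list(vars, colnames(scores)))
  for (v in vars)
    contrib[v, ] <- 100 * colSums(V[colVar == v, , drop = FALSE]^2)
  quantCor <- matrix(NA_real_, length(quantVars), length(keep),
                     dimnames = list(quantVars, colnames(scores)))
  for (v in quantVars)
    quantCor[v, ] <- vapply(seq_along(keep), function(s)
      stats::cor(data[[v]], scores[, s]), numeric(1))
  new("FAMDResult", eigenvalues = eigAll,
      percentVar = 100 * eigAll / totalInertia,
      cumPercent = cumsum(100 * eigAll / totalInertia),
      contributions = contrib, quantCor = quantCor, rowScores = scores,
      quantVars = as.character(quantVars), qualVars = as.character(qualVars),
      totalInertia = totalInertia)
}

#' Tag FAMD row scores with group labels
#'
#' Exports per-row dimension-1/2 coordinates tagged by the supplied labels
#' (e.g. genotype and sex), ready for factor-score maps.
#'
#' @param result a [FAMDResult-class].
#' @param labels data.frame of label columns aligned with the FAMD input
#'   rows.
#' @return data.frame with columns `Dim1`, `Dim2` (and further dimensions
#'   if present) followed by the label columns.
#' @export
famdScoresByGroup <- function(result, labels) {
  stopifnot(is(result, "FAMDResult"), is.data.frame(labels))
  if (nrow(labels) != nrow(result@rowScores))
    stop("alignment error: ", nrow(labels), " label rows for ",
         nrow(result@rowScores), " score rows")
  cbind(as.data.frame(result@rowScores), labels)
}
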