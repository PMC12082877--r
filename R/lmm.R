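# Sufficient statistics per animal for the random-intercept REML profile.
# With V = I + lambda Z Z', V is block diagonal over animals and
# V_i^{-1} = I - (lambda / (1 + lambda n_i)) J_i, so all GLS quantities
# reduce to per-animal cross products.
.lmmStats <- function(X, y, animal) {
  ids <- unique(animal)
  lapply(ids, function(id) {
    sel <- animal == id
    Xi <- X[sel, , drop = FALSE]; yi <- y[sel]
    list(n = sum(sel), XtX = crossprod(Xi), Xty = crossprod(Xi, yi),
         yty = sum(yi^2), Xt1 = colSums(Xi), yt1 = sum(yi))
  })
}

# minus twice the REML log-likelihood profiled over beta and sigma_e^2,
# up to an additive constant
.remlDeviance <- function(lambda, stats, N, p) {
  XtVX <- 0; XtVy <- 0; ytVy <- 0; logDetV <- 0
  for (s in stats) {
    ci <- lambda / (1 + lambda * s$n)
    XtVX <- XtVX + s$XtX - ci * tcrossprod(s$Xt1)
    XtVy <- XtVy + s$Xty - ci * s$Xt1 * s$yt1
    ytVy <- ytVy + s$yty - ci * s$yt1^2
    logDetV <- logDetV + log1p(lambda * s$n)
  }
  ch <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch)) return(list(dev = Inf))
  beta <- backsolve(ch, backsolve(ch, XtVy, transpose = TRUE))
  rss <- max(ytVy - 2 * sum(beta * XtVy) + sum(beta * (XtVX %*% beta)),
             .Machine$double.eps)
  sigma2 <- rss / (N - p)
  dev <- (N - p) * log(sigma2) + logDetV + 2 * sum(log(diag(ch)))
  list(dev = dev, beta = beta, sigma2 = sigma2, XtVX = XtVX,
       logDetV = logDetV)
}

#' Fit a random-intercept linear mixed model to per-neuron records
#'
#' Fits y = X beta + u_animal + e by REML, with genotype, sex and their
#' interaction as fixed effects and a random intercept per animal
#' (controlling for repeated measures within animals). The between-animal /
#' residual variance ratio lambda = sigma_u^2 / sigma_e^2 is profiled out
#' and optimized in one dimension on the log scale (Brent search bracketed
#' over [1e-8, 1e6], convergence tolerance < 1e-8 on lambda, with the
#' lambda = 0 boundary checked explicitly).
#'
#' @param records data.frame with columns `animal_id`, `sex`
#'   (male/female), `genotype` (WT/KO) and the response.
#' @param response name of the response column.
#' @param lambdaFixed optional fixed variance ratio; `lambdaFixed = 0`
#'   reduces the fit to ordinary two-way ANOVA on neurons.
#' @return A [MitoLMMFit-class].
#' @examples
#' tab <- simulateCohort(cohortSimConfig(seed = 11))
#' fitMitoLMM(tab, "m2")
#' @export
fitMitoLMM <- function(records, response, lambdaFixed = NULL) {
  stopifnot(is.data.frame(records), response %in% names(records))
  y <- records[[response]]
  stopifnot(all(is.finite(y)))
  sex <- factor(records$sex, levels = c("male", "female"))
  genotype <- factor(records$genotype, levels = c("WT", "KO"))
  animal <- as.character(records$animal_id)
  cellOf <- interaction(genotype, sex, drop = FALSE)
  animalCell <- tapply(as.character(cellOf), animal, function(x) {
    u <- unique(x)
    if (length(u) > 1L)
      stop("design error: animal mapped to more than one sex x genotype cell")
    u
  })
  if (length(table(droplevels(cellOf))) < nlevels(cellOf))
    stop("design error: a sex x genotype cell has zero animals")
  nAnimals <- length(unique(animal))
  if (nAnimals < 2L)
    stop("fit error: variance components are not identifiable with a ",
         "single animal")
  X <- stats::model.matrix(~ genotype * sex)
  N <- length(y); p <- ncol(X)
  st <- .lmmStats(X, y, animal)

  if (is.null(lambdaFixed)) {
    f <- function(loglam) .remlDeviance(exp(loglam), st, N, p)$dev
    opt <- stats::optimize(f, interval = log(c(1e-8, 1e6)), tol = 1e-10)
    lambda <- exp(opt$minimum)
    dev0 <- .remlDeviance(0, st, N, p)$dev
    if (dev0 <= opt$objective) lambda <- 0
  } else {
    stopifnot(lambdaFixed >= 0)
    lambda <- lambdaFixed
  }
  fit <- .remlDeviance(lambda, st, N, p)
  sigmaE <- sqrt(fit$sigma2)
  sigmaU <- sqrt(lambda * fit$sigma2)
  vcovBeta <- solve(fit$XtVX) * fit$sigma2
  beta <- drop(fit$beta); names(beta) <- colnames(X)
  remlLL <- -0.5 * ((N - p) * (log(2 * pi * fit$sigma2) + 1) +
                    fit$logDetV +
                    determinant(fit$XtVX, logarithm = TRUE)$modulus[1])
  # cell means over the genotype x sex grid via L beta
  grid <- expand.grid(genotype = levels(genotype), sex = levels(sex))
  L <- stats::model.matrix(~ genotype * sex, data = grid)
  means <- drop(L %*% beta)
  ses <- sqrt(diag(L %*% vcovBeta %*% t(L)))
  cellMeans <- data.frame(genotype = grid$genotype, sex = grid$sex,
                          emmean = means, se = ses)
  new("MitoLMMFit", response = response, beta = beta, vcovBeta = vcovBeta,
      sigmaU = sigmaU, sigmaE = sigmaE, lambda = lambda,
      remlLogLik = as.numeric(remlLL), df = nAnimals - nrow(grid),
      cellMeans = cellMeans, nObs = as.integer(N),
      nAnimals = as.integer(nAnimals))
}

#' Estimated marginal means over the sex x genotype grid
#'
#' Model-based cell means with standard errors from the fixed-effect
#' covariance; for a balanced design with sigma_u = 0 these equal the raw
#' cell averages.
#'
#' @param fit a [MitoLMMFit-class].
#' @return data.frame with one row per genotype x sex cell: `emmean`, `se`.
#' @export
estimatedMarginalMeans <- function(fit) {
  stopifnot(is(fit, "MitoLMMFit"))
  fit@cellMeans
}

#' Tukey-adjusted pairwise contrasts between cell means
#'
#' All 6 pairwise differences between the 4 sex x genotype cell means,
#' with standard errors from the fixed-effect covariance, t statistics,
#' unadjusted two-sided p-values, and Tukey family-wise adjusted p-values
#' from the studentized-range distribution with k = 4 groups and
#' containment error degrees of freedom (total animals - 4).
#'
#' @param fit a [MitoLMMFit-class].
#' @return data.frame of class `ContrastTable`, 6 rows with columns
#'   `contrast`, `estimate`, `se`, `t`, `df`, `p_value`, `p_adjusted`.
#' @export
tukeyContrasts <- function(fit) {
  stopifnot(is(fit, "MitoLMMFit"))
  df <- fit@df
  if (df <= 0)
    stop("df error: nonpositive error degrees of freedom (",
         fit@nAnimals, " animals for 4 cells)")
  cm <- fit@cellMeans
  grid <- cm[c("genotype", "sex")]
  Lgrid <- stats::model.matrix(~ genotype * sex, data = grid)
  labs <- paste(cm$genotype, cm$sex, sep = " ")
  combs <- utils::combn(nrow(cm), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
    i <- combs[1, k]; j <- combs[2, k]
    l <- Lgrid[i, ] - Lgrid[j, ]
    est <- sum(l * fit@beta)
    se <- sqrt(drop(t(l) %*% fit@vcovBeta %*% l))
    tval <- est / se
    data.frame(contrast = paste(labs[i], "-", labs[j]),
               estimate = est, se = se, t = tval, df = df,
               p_value = 2 * stats::pt(-abs(tval), df),
               p_adjusted = stats::ptukey(sqrt(2) * abs(tval),
                                          nmeans = 4, df = df,
                                          lower.tail = FALSE))
  }))
  out$p_adjusted <- pmax(out$p_adjusted, out$p_value)
  rownames(out) <- NULL
  class(out) <- c("ContrastTable", "data.frame")
  out
}
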