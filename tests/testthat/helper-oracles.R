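# Independent brute-force oracles used to validate the package
# implementations. These deliberately re-derive each quantity from first
# principles (loops, dense algebra) rather than calling package internals.

# --- connected components by explicit flood fill (stack-based) -------------
oracleFloodFill <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  if (connectivity == 8L) {
    moves <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                   c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    moves <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j)); lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(moves))) {
        r <- p[1] + moves[k, 1]; c <- p[2] + moves[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# --- exhaustive 256-level Otsu scan ----------------------------------------
oracleOtsu <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  w <- (hi - lo) / nbins
  bin <- pmin(pmax(floor((x - lo) / w) + 1L, 1L), nbins)
  mids <- lo + (seq_len(nbins) - 0.5) * w
  sigmaB <- rep(-Inf, nbins - 1L)
  for (k in seq_len(nbins - 1L)) {
    in0 <- bin <= k
    n0 <- sum(in0); n1 <- length(x) - n0
    if (n0 == 0L || n1 == 0L) next
    mu0 <- mean(mids[bin[in0]]); mu1 <- mean(mids[bin[!in0]])
    sigmaB[k] <- (n0 / length(x)) * (n1 / length(x)) * (mu0 - mu1)^2
  }
  best <- which(sigmaB >= max(sigmaB) - 1e-12)
  lo + mean(best) * w
}

# --- exhaustive Costes threshold scan --------------------------------------
oracleCostes <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  mx <- mean(a); my <- mean(b)
  sxx <- sum((a - mx)^2) / (n - 1); syy <- sum((b - my)^2) / (n - 1)
  sxy <- sum((a - mx) * (b - my)) / (n - 1)
  slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  intercept <- my - slope * mx
  for (tA in sort(unique(a), decreasing = TRUE)) {
    sel <- a < tA & b < slope * tA + intercept
    if (sum(sel) < 2L) next
    if (length(unique(a[sel])) < 2L || length(unique(b[sel])) < 2L) next
    r <- stats::cor(a[sel], b[sel])
    if (r <= 0) return(list(tA = tA, tB = slope * tA + intercept,
                            r = r, floor = FALSE))
  }
  list(tA = min(a), tB = slope * min(a) + intercept, r = NA_real_,
       floor = TRUE)
}

# --- pixel-sum Mander's oracle ---------------------------------------------
oracleManders <- function(a, b, tA = 0, tB = 0) {
  a <- as.numeric(a); b <- as.numeric(b)
  num1 <- 0; den1 <- 0; num2 <- 0; den2 <- 0
  for (i in seq_along(a)) {
    if (a[i] > tA) {
      den1 <- den1 + a[i]
      if (b[i] > tB) num1 <- num1 + a[i]
    }
    if (b[i] > tB) {
      den2 <- den2 + b[i]
      if (a[i] > tA) num2 <- num2 + b[i]
    }
  }
  c(M1 = num1 / den1, M2 = num2 / den2)
}

# --- aspect ratio from an explicit covariance eigen-decomposition ----------
oracleAspectRatio <- function(coords) {
  cv <- stats::cov(coords) * (nrow(coords) - 1) / nrow(coords)
  ev <- eigen(cv, symmetric = TRUE)$values
  sqrt(ev[1] / ev[2])
}

# --- dense-matrix profiled REML deviance for the random-intercept model ----
oracleRemlDeviance <- function(lambda, design, y, animal) {
  Z <- stats::model.matrix(~ factor(animal) - 1)
  V <- diag(length(y)) + lambda * tcrossprod(Z)
  Vi <- solve(V)
  XtVX <- t(design) %*% Vi %*% design
  beta <- solve(XtVX, t(design) %*% Vi %*% y)
  r <- y - design %*% beta
  sigma2 <- drop(t(r) %*% Vi %*% r) / (length(y) - ncol(design))
  as.numeric((length(y) - ncol(design)) * log(sigma2) +
    determinant(V, logarithm = TRUE)$modulus[1] +
    determinant(XtVX, logarithm = TRUE)$modulus[1])
}

# --- balanced-design ANOVA method-of-moments variance components -----------
oracleBalancedMoM <- function(records, response) {
  y <- records[[response]]
  animal <- as.character(records$animal_id)
  cell <- interaction(records$genotype, records$sex)
  animalMeans <- tapply(y, animal, mean)
  animalCell <- tapply(as.character(cell), animal, unique)
  m <- as.integer(table(animal)[1])
  msw <- sum(tapply(seq_along(y), animal, function(ii)
    sum((y[ii] - mean(y[ii]))^2))) / (length(animalMeans) * (m - 1))
  cellOfAnimal <- animalCell[names(animalMeans)]
  ssb <- sum(vapply(unique(cellOfAnimal), function(cl) {
    v <- animalMeans[cellOfAnimal == cl]
    sum((v - mean(v))^2)
  }, numeric(1)))
  msb <- m * ssb / (length(animalMeans) - length(unique(cellOfAnimal)))
  list(sigmaE2 = msw, sigmaU2 = max((msb - msw) / m, 0))
}

# --- small utility: a simulated noiseless image pair rounded to counts -----
syntheticCountImage <- function(seed, nObjects = 5, fieldSize = c(64, 64),
                                ...) {
  sim <- simulateMitoImage(imageSimConfig(
    fieldSizePx = fieldSize, nObjects = nObjects, seed = seed, ...))
  list(a = round(immChannel(sim$image)), b = round(ommChannel(sim$image)),
       truth = sim$truth)
}
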