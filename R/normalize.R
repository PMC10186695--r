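#' Mask low-coverage bins
#'
#' Flags bins whose marginal contact sum falls below \code{minFraction} times
#' the median positive marginal on their chromosome. The rule is scale-free,
#' so depth scaling does not change the mask. Masking is required before KR
#' balancing, which only operates on the unmasked submatrix.
#'
#' @param cm a raw or depth-normalized \linkS4class{ContactMatrix}.
#' @param minFraction fraction of the median positive marginal below which a
#'   bin is masked (default 0.1).
#' @return the \linkS4class{ContactMatrix} with an updated mask.
#' @export
maskLowCoverage <- function(cm, minFraction = 0.1) {
  if (!normalization(cm) %in% c("raw", "depth"))
    stop("mask low coverage on raw or depth-normalized matrices")
  mask <- binMask(cm)
  for (ch in chromNames(binGrid(cm))) {
    marg <- rowSums(contactMatrices(cm, ch))
    med <- median(marg[marg > 0])
    mask[[ch]] <- mask[[ch]] & marg > 0 & marg >= minFraction * med
  }
  if (!any(unlist(mask))) stop("all bins masked")
  replaceMatrices(cm, cm@matrices, mask = mask)
}

krScaling <- function(A, tol = 1e-6, maxIter = 1000) {
  # Knight-Ruiz inner-outer Newton iteration (conjugate-gradient inner solve)
  # for a positive vector x with rowSums(diag(x) %*% A %*% diag(x)) == 1.
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  delta <- 0.1; Delta <- 3
  g <- 0.9; etamax <- 0.1; eta <- etamax
  rt <- tol^2
  v <- x * drop(A %*% x)
  rk <- 1 - v
  rho_km1 <- drop(crossprod(rk))
  rout <- rho_km1; rold <- rout
  iter <- 0
  while (rout > rt) {
    iter <- iter + 1
    if (iter > maxIter)
      return(list(x = x, converged = FALSE, residual = sqrt(rout)))
    k <- 0; y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v; p <- Z
        rho_km1 <- drop(crossprod(rk, Z))
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * drop(A %*% (x * p)) + v * p
      alpha <- rho_km1 / drop(crossprod(p, w))
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        ind <- which(ap < 0)
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- which(ynew > Delta)
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- drop(crossprod(rk, Z))
      if (k > 5 * n) break
    }
    x <- x * y
    v <- x * drop(A %*% x)
    rk <- 1 - v
    rho_km1 <- drop(crossprod(rk))
    rout <- rho_km1
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta; eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), 0.5 * tol / res_norm)
  }
  list(x = x, converged = TRUE, residual = sqrt(rout))
}

#' Knight-Ruiz matrix balancing
#'
#' Finds, per chromosome, a positive vector x such that
#' \code{diag(x) \%*\% M \%*\% diag(x)} has equal unmasked row sums (equal to
#' 1) within \code{tol}, using the Knight-Ruiz inner-outer Newton iteration.
#' Masked bins are excluded from the computation (not zero-imputed) and their
#' rows/columns are zero in the balanced matrix.
#'
#' @param cm a masked \linkS4class{ContactMatrix}; the unmasked submatrix of
#'   each chromosome must be connected.
#' @param tol relative row-sum tolerance (default 1e-6).
#' @param maxIter maximum outer Newton iterations (default 1000).
#' @return a balanced \linkS4class{ContactMatrix} with the scaling vectors in
#'   the \code{balancing} slot.
#' @export
krBalance <- function(cm, tol = 1e-6, maxIter = 1000) {
  mats <- list(); scal <- list()
  for (ch in chromNames(binGrid(cm))) {
    m <- contactMatrices(cm, ch)
    keep <- binMask(cm, ch) & rowSums(m) > 0
    repeat {  # contacts only with masked bins can leave empty submatrix rows
      rs <- rowSums(m[keep, keep, drop = FALSE])
      if (all(rs > 0)) break
      keep[which(keep)[rs == 0]] <- FALSE
    }
    A <- m[keep, keep, drop = FALSE]
    fit <- krScaling(A, tol = tol, maxIter = maxIter)
    if (!fit$converged)
      stop(sprintf("KR did not converge on %s within %d iterations (residual %.3g)",
                   ch, maxIter, fit$residual))
    out <- matrix(0, nrow(m), ncol(m))
    out[keep, keep] <- A * tcrossprod(fit$x)
    mats[[ch]] <- out
    xv <- rep(NA_real_, nrow(m)); xv[keep] <- fit$x
    scal[[ch]] <- xv
  }
  mask <- binMask(cm)
  for (ch in names(mask)) mask[[ch]] <- mask[[ch]] & !is.na(scal[[ch]])
  replaceMatrices(cm, mats, normalization = "balanced", mask = mask,
                  balancing = scal)
}

#' Normalize two contact maps to equal sequencing depth
#'
#' Scales both maps to the smaller total contact sum, the standard
#' preparation before computing differential maps.
#'
#' @param cmA,cmB \linkS4class{ContactMatrix} objects on the same grid.
#' @return list of the two depth-normalized matrices.
#' @export
depthNormalize <- function(cmA, cmB) {
  if (!sameGrid(binGrid(cmA), binGrid(cmB))) stop("grids differ")
  tA <- totalContacts(cmA); tB <- totalContacts(cmB)
  if (tA <= 0 || tB <= 0) stop("zero total contacts")
  target <- min(tA, tB)
  scale1 <- function(cm, f)
    replaceMatrices(cm, lapply(cm@matrices, function(m) m * f),
                    normalization = "depth")
  list(scale1(cmA, target / tA), scale1(cmB, target / tB))
}

distanceMeans <- function(m, maskv) {
  n <- nrow(m)
  out <- rep(NaN, n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    ok <- maskv[i] & maskv[i + d]
    if (any(ok)) out[d + 1] <- mean(m[cbind(i[ok], i[ok] + d)])
  }
  out
}

#' Observed/expected transform
#'
#' Divides each diagonal of a balanced matrix by the mean of its unmasked
#' entries, removing the distance-decay trend. Masked bins become NaN. Each
#' O/E diagonal has mean 1 over unmasked entries, and the transform is
#' invariant to global scaling of the input.
#'
#' @param cm a balanced \linkS4class{ContactMatrix} (a depth-normalized map
#'   is accepted for exploratory use).
#' @return a \linkS4class{ContactMatrix} with normalization \code{"oe"}.
#' @export
oeTransform <- function(cm) {
  mats <- list()
  for (ch in chromNames(binGrid(cm))) {
    m <- contactMatrices(cm, ch)
    keep <- binMask(cm, ch)
    n <- nrow(m)
    dm <- distanceMeans(m, keep)
    expctd <- matrix(dm[abs(outer(seq_len(n), seq_len(n), "-")) + 1], n, n)
    oe <- m / expctd
    oe[!keep, ] <- NaN
    oe[, !keep] <- NaN
    mats[[ch]] <- oe
  }
  replaceMatrices(cm, mats, normalization = "oe")
}
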