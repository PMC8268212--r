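# Mixed-model machinery.
#
# The working representation rotates everything by the eigenvectors of the
# GRM subset to the trait's non-missing animals: with G = U diag(d) U', the
# model covariance sigmaG2*G + sigmaQ2*QQ' + sigmaE2*I becomes
# diag(sigmaG2*d + sigmaE2) plus a rank-n_strains term, so every V-solve in
# REML and in the per-variant GLS scan is O(n * n_strains^2) after a single
# eigendecomposition (and a single rotation of the dosage matrix) per
# missingness pattern.

.mlmContext <- function(G, keep, Q, S = NULL) {
  Gk <- G[keep, keep, drop = FALSE]
  eig <- eigen(Gk, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ctx <- list(keep = keep, U = U, d = d,
              xtil = as.vector(crossprod(U, rep(1, sum(keep)))),
              Qtil = crossprod(U, Q[keep, , drop = FALSE]),
              gIdentLike = sd(d) < 1e-8 * (mean(abs(d)) + 1e-12))
  if (!is.null(S)) {
    Sk <- S[keep, , drop = FALSE]
    ctx$Stil <- crossprod(U, Sk)
    f <- colMeans(Sk) / 2
    ctx$mafKeep <- pmin(f, 1 - f)
  }
  ctx
}

# Vinv %*% M for V = diag(a) + thq * Qtil Qtil' (Woodbury).
.vinvOp <- function(a, Qtil, thq) {
  if (thq <= 0 || ncol(Qtil) == 0L) {
    return(list(apply = function(M) M / a,
                logdet = sum(log(a)),
                diagv = 1 / a))
  }
  B <- Qtil / a
  Mq <- diag(1 / thq, ncol(Qtil)) + crossprod(Qtil, B)
  ch <- chol(Mq)
  Mqinv <- chol2inv(ch)
  list(apply = function(M) {
         M <- as.matrix(M)
         M / a - B %*% (Mqinv %*% crossprod(B, M))
       },
       logdet = sum(log(a)) + 2 * sum(log(diag(ch))) +
                ncol(Qtil) * log(thq),
       diagv = 1 / a - rowSums((B %*% Mqinv) * B))
}

# Restricted log-likelihood plus the pieces needed for AI-REML, all in the
# rotated basis. theta = (sigmaG2, sigmaQ2, sigmaE2).
.remlPieces <- function(theta, ytil, xtil, Qtil, d) {
  a <- theta[1] * d + theta[3]
  op <- .vinvOp(a, Qtil, theta[2])
  w <- as.vector(op$apply(xtil))
  cc <- sum(xtil * w)
  Vy <- as.vector(op$apply(ytil))
  xVy <- sum(xtil * Vy)
  r <- Vy - w * (xVy / cc)            # P y
  yPy <- sum(ytil * Vy) - xVy^2 / cc
  ll <- -0.5 * (op$logdet + log(cc) + yPy)
  Qr <- crossprod(Qtil, r)
  Qw <- crossprod(Qtil, w)
  trV <- c(sum(op$diagv * d),
           sum(Qtil * op$apply(Qtil)),
           sum(op$diagv))
  trP <- trV - c(sum(d * w^2), sum(Qw^2), sum(w^2)) / cc
  rBr <- c(sum(d * r^2), sum(Qr^2), sum(r^2))
  score <- -0.5 * (trP - rBr)
  V1 <- d * r
  V2 <- as.vector(Qtil %*% Qr)
  Vmat <- cbind(V1, V2, r)
  PV <- op$apply(Vmat) - w %o% (as.vector(crossprod(w, Vmat)) / cc)
  AI <- 0.5 * crossprod(Vmat, PV)
  list(ll = ll, score = score, AI = AI, trP = trP, rBr = rBr, r = r,
       yPy = yPy)
}

#' Estimate variance components by REML for one trait
#'
#' Fits \eqn{y = 1\mu + Qq + g + e} with \eqn{var(g) = G\sigma_g^2},
#' \eqn{var(q) = I\sigma_q^2} (covariance contribution \eqn{QQ'\sigma_q^2})
#' and \eqn{var(e) = I\sigma_e^2} by average-information REML with a
#' multiplicative fixed-point fallback and non-negativity constraints.
#' Convergence is declared when the relative change in the restricted
#' log-likelihood falls below \code{tol}.
#'
#' @param y named numeric vector of one trait's pre-adjusted phenotypes
#'   (names are animal ids; NA allowed).
#' @param strains a \linkS4class{StrainData}.
#' @param grm a \linkS4class{GRM} whose row order matches the animal ids.
#' @param grmIds animal ids labelling the GRM rows (defaults to the names of
#'   \code{y} when the GRM is unlabelled and conformable).
#' @param tol relative log-likelihood tolerance (default 1e-6).
#' @param maxIter maximum iterations (default 200).
#' @return A \linkS4class{VarianceComponents}. A GRM numerically proportional
#'   to the identity (so \eqn{\sigma_g^2} and \eqn{\sigma_e^2} are not
#'   separable) sets the boundary flag.
#' @export
estimateVarComp <- function(y, strains, grm, grmIds = NULL, tol = 1e-6,
                            maxIter = 200L) {
  ids <- names(y)
  if (is.null(ids)) stop("y must be named by animal id")
  G <- grmMatrix(grm)
  if (is.null(grmIds)) grmIds <- rownames(G)
  if (is.null(grmIds)) {
    if (nrow(G) != length(y)) stop("unlabelled GRM not conformable with y")
    grmIds <- ids
  }
  Qall <- strainProportions(strains)
  common <- Reduce(intersect, list(ids, grmIds, rownames(Qall)))
  y <- y[common]
  G <- G[match(common, grmIds), match(common, grmIds), drop = FALSE]
  Qall <- Qall[common, , drop = FALSE]
  keep <- !is.na(y)
  if (sum(keep) < 30L) stop("need at least 30 non-missing records")
  ctx <- .mlmContext(G, keep, Qall)
  yk <- y[keep]
  ytil <- as.vector(crossprod(ctx$U, yk))
  fit <- .remlSolve(ytil, ctx$xtil, ctx$Qtil, ctx$d, var(yk), tol, maxIter,
                    gIdentLike = ctx$gIdentLike)
  new("VarianceComponents", sigmaG = fit$theta[1], sigmaQ = fit$theta[2],
      sigmaE = fit$theta[3], logLik = fit$ll, n = sum(keep),
      converged = fit$converged, boundary = ctx$gIdentLike,
      iterations = fit$iterations)
}

.remlSolve <- function(ytil, xtil, Qtil, d, vy, tol = 1e-6, maxIter = 200L,
                       gIdentLike = FALSE) {
  theta <- vy * c(0.4, 0.1, 0.5)
  floorE <- 1e-8 * vy
  pieces <- .remlPieces(theta, ytil, xtil, Qtil, d)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxIter)) {
    llOld <- pieces$ll
    # free components: positive, or pinned at zero but with positive score
    free <- which(theta > 0 | pieces$score > 0)
    proposal <- theta
    if (it <= 2L) {
      proposal <- .fixedPointUpdate(theta, pieces, free, floorE)
    } else {
      AI <- pieces$AI[free, free, drop = FALSE]
      AI <- AI + diag(1e-8 * (mean(diag(AI)) + 1e-12), length(free))
      step <- tryCatch(solve(AI, pieces$score[free]), error = function(e) NULL)
      if (is.null(step)) {
        proposal <- .fixedPointUpdate(theta, pieces, free, floorE)
      } else {
        proposal[free] <- theta[free] + step
      }
    }
    # step-halving toward the current iterate on constraint violation or
    # log-likelihood decrease
    ok <- FALSE
    for (h in 0:10) {
      cand <- theta + (proposal - theta) / 2^h
      cand[cand < 0] <- 0
      cand[3] <- max(cand[3], floorE)
      candPieces <- tryCatch(
        .remlPieces(cand, ytil, xtil, Qtil, d),
        error = function(e) NULL)
      if (!is.null(candPieces) && is.finite(candPieces$ll) &&
          (candPieces$ll >= llOld - 1e-10 || h == 10)) {
        theta <- cand
        pieces <- candPieces
        ok <- TRUE
        break
      }
    }
    if (!ok) break
    if (abs(pieces$ll - llOld) / (abs(llOld) + 1) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && !gIdentLike)
    stop(sprintf(paste0("REML did not converge in %d iterations; last ",
                        "iterate sigmaG2=%.6g sigmaQ2=%.6g sigmaE2=%.6g ",
                        "logLik=%.6f"),
                 maxIter, theta[1], theta[2], theta[3], pieces$ll))
  list(theta = theta, ll = pieces$ll, converged = converged, iterations = it)
}

# multiplicative fixed-point update: theta_i <- theta_i * (r'B_i r)/tr(P B_i);
# its fixed point coincides with a zero REML score, and positivity is
# automatic, which makes it a robust opener before AI steps
.fixedPointUpdate <- function(theta, pieces, free, floorE) {
  out <- theta
  for (i in free) {
    if (pieces$trP[i] > 0 && pieces$rBr[i] >= 0)
      out[i] <- theta[i] * pieces$rBr[i] / pieces$trP[i]
  }
  out[3] <- max(out[3], floorE)
  out
}
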