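#' Fitted allele-frequency mixture model
#'
#' Result of \code{\link{fitMixtureEM}}: a finite mixture of populations
#' in which each individual's two allele copies per locus are drawn from
#' its population's allele frequencies (no admixture; soft assignments via
#' EM responsibilities).
#'
#' @slot K number of populations.
#' @slot freqs allele frequencies: matrix (allele columns x K), rows
#'   grouped by locus; attribute \code{locus} maps rows to loci.
#' @slot mixing mixing proportions, length K.
#' @slot Q membership probabilities, individuals x K; rows sum to 1.
#' @slot logLik final model log-likelihood (allele-copy likelihood).
#' @slot logLikTrace per-iteration log-likelihoods (non-decreasing).
#' @slot converged logical.
#' @export
setClass("SSRMixtureFit", representation(
  K = "integer", freqs = "matrix", mixing = "numeric", Q = "matrix",
  logLik = "numeric", logLikTrace = "numeric", converged = "logical"))

setValidity("SSRMixtureFit", function(object) {
  if (ncol(object@Q) != object@K) return("Q must have K columns")
  if (any(abs(rowSums(object@Q) - 1) > 1e-6)) return("Q rows must sum to 1")
  if (!is.finite(object@logLik)) return("log-likelihood must be finite")
  TRUE
})

setMethod("show", "SSRMixtureFit", function(object) {
  cat("SSRMixtureFit: K =", object@K, "|", nrow(object@Q), "individuals |",
      "logLik =", format(object@logLik, digits = 8),
      if (object@converged) "(converged)\n" else "(not converged)\n")
})

#' Membership probabilities of a mixture fit
#' @param fit an \code{SSRMixtureFit}.
#' @return matrix individuals x K, rows summing to 1.
#' @export
membership <- function(fit) fit@Q

#' Fit a population mixture to codominant genotypes by EM
#'
#' Each individual belongs to one of K populations; given the population,
#' its two allele copies at every locus are independent draws from that
#' population's allele frequencies (Hardy-Weinberg within populations).
#' EM alternates soft assignment of individuals (responsibilities) with
#' reestimation of mixing proportions and allele frequencies. The reported
#' log-likelihood is the allele-copy mixture log-likelihood (the constant
#' heterozygote pairing factor is omitted); it is non-decreasing over
#' iterations. Missing calls contribute nothing to the likelihood.
#'
#' @param x an \code{SSRGenotypes} object.
#' @param K number of populations (1 <= K <= individuals).
#' @param seed integer seed for the random initialization; the fit is
#'   deterministic given \code{seed}.
#' @param maxIter maximum EM iterations.
#' @param tol stop when the log-likelihood improves by less than this.
#' @param nStarts number of random restarts; the fit with the best final
#'   log-likelihood is returned. EM mixture likelihoods are multimodal;
#'   a few restarts make each fit land on the dominant optimum while the
#'   finite convergence tolerance leaves genuine run-to-run variability
#'   in replicate fits (which the Evanno statistics divide by).
#' @return an \code{SSRMixtureFit}.
#' @export
fitMixtureEM <- function(x, K, seed = 1L, maxIter = 500L, tol = 1e-6,
                         nStarts = 3L) {
  stopifnot(is(x, "SSRGenotypes"), K >= 1L, nStarts >= 1L)
  n <- ncol(x)
  if (K > n) stop("K exceeds the number of individuals")
  cm <- .allele_count_matrix(x)
  best <- NULL
  for (s in seq_len(nStarts)) {
    fit <- .fit_mixture_once(x, cm, K, seed = .derive_seed(seed, K, s * 31L),
                             maxIter = maxIter, tol = tol)
    if (is.null(best) || fit@logLik > best@logLik) best <- fit
    if (K == 1L) break    # closed form, no multimodality
  }
  best
}

.fit_mixture_once <- function(x, cm, K, seed, maxIter, tol) {
  n <- ncol(x)
  C <- cm$C                       # n x M allele-copy counts (0/1/2)
  locusOf <- cm$locus             # length M, locus index per column
  set.seed(as.integer(seed) %% .Machine$integer.max)
  Q <- matrix(rgamma(n * K, shape = 1), n, K)
  Q <- Q / rowSums(Q)
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    ## M-step: mixing proportions and per-population allele frequencies
    mixing <- colMeans(Q)
    num <- crossprod(C, Q)                       # M x K
    locusTotals <- rowsum(num, locusOf)          # L x K
    P <- num / locusTotals[locusOf, , drop = FALSE]
    P[!is.finite(P)] <- 0
    ## E-step
    logP <- log(P)
    logP[P == 0] <- -1e10
    ll <- C %*% logP                             # n x K
    A <- sweep(ll, 2L, log(pmax(mixing, 1e-300)), "+")
    mx <- apply(A, 1L, max)
    W <- exp(A - mx)
    rs <- rowSums(W)
    loglik <- sum(mx + log(rs))
    Q <- W / rs
    trace <- c(trace, loglik)
    if (iter > 1L && trace[iter] - trace[iter - 1L] < tol) {
      converged <- TRUE
      break
    }
  }
  rownames(Q) <- colnames(x)
  attr(P, "locus") <- rownames(x)[locusOf]
  new("SSRMixtureFit", K = as.integer(K), freqs = P, mixing = mixing,
      Q = Q, logLik = trace[length(trace)], logLikTrace = trace,
      converged = converged)
}

#' Evanno delta-K table from replicate run log-likelihoods
#'
#' For each K, summarizes replicate log-likelihoods by their mean and
#' standard deviation and computes the rate statistics
#' L'(K) = mean(K) - mean(K-1),
#' |L''(K)| = |mean(K+1) - 2 mean(K) + mean(K-1)| and
#' delta K = |L''(K)| / sd(K). L' needs K >= 2 and |L''|/delta K need
#' both neighbors, so delta K is defined for the interior K values only.
#' A zero standard deviation makes delta K undefined (NA) at that K.
#'
#' @param runs data.frame with columns \code{K} and \code{logLik}, at
#'   least 2 replicates per K over a contiguous K range.
#' @return data.frame with columns K, nReps, meanL, sdL, Lprime,
#'   LdoubleprimeAbs, deltaK, plus attribute \code{bestK} (argmax deltaK,
#'   NA when no deltaK is defined).
#' @export
evannoDeltaK <- function(runs) {
  stopifnot(is.data.frame(runs), all(c("K", "logLik") %in% names(runs)))
  Ks <- sort(unique(runs$K))
  if (!identical(Ks, seq(min(Ks), max(Ks)))) {
    stop("K values must form a contiguous range")
  }
  nReps <- as.integer(table(factor(runs$K, levels = Ks)))
  if (any(nReps < 2L)) stop("at least 2 replicates per K are required")
  meanL <- tapply(runs$logLik, factor(runs$K, levels = Ks), mean)
  sdL <- tapply(runs$logLik, factor(runs$K, levels = Ks), sd)
  m <- length(Ks)
  Lprime <- c(NA, diff(meanL))
  Ldp <- rep(NA_real_, m)
  if (m >= 3L) {
    Ldp[2:(m - 1L)] <- abs(meanL[3:m] - 2 * meanL[2:(m - 1L)] +
                             meanL[1:(m - 2L)])
  }
  deltaK <- ifelse(sdL > 0, Ldp / sdL, NA_real_)
  out <- data.frame(K = Ks, nReps = nReps, meanL = as.numeric(meanL),
                    sdL = as.numeric(sdL), Lprime = as.numeric(Lprime),
                    LdoubleprimeAbs = Ldp, deltaK = as.numeric(deltaK))
  best <- if (all(is.na(out$deltaK))) NA_integer_ else {
    out$K[which.max(out$deltaK)]
  }
  attr(out, "bestK") <- best
  out
}

#' Replicate mixture fits across K with Evanno model selection
#'
#' Runs \code{\link{fitMixtureEM}} for K = 1..Kmax with \code{replicates}
#' independent seeds per K (derived deterministically from the master
#' seed), builds the Evanno delta-K table, and refits/returns the
#' best-likelihood model at the delta-K peak. When no clear peak exists
#' (all delta K undefined or the maximum is small) the result is flagged
#' low-signal.
#'
#' @param x an \code{SSRGenotypes} object.
#' @param Kmax largest K to fit (>= 3 so that at least one interior K has
#'   a defined delta K).
#' @param replicates EM restarts per K (>= 2; default 10).
#' @param seed master seed; the whole procedure is reproducible given it.
#' @param lowSignalDeltaK flag threshold: a maximum delta K below this is
#'   reported as low-signal (default 10).
#' @param ... passed to \code{\link{fitMixtureEM}}.
#' @return list with elements \code{evanno} (table from
#'   \code{\link{evannoDeltaK}}), \code{bestK}, \code{fit} (best
#'   \code{SSRMixtureFit} at bestK), \code{runs} (per-run K, replicate,
#'   seed, logLik) and \code{lowSignal}.
#' @export
inferStructure <- function(x, Kmax = 6L, replicates = 10L, seed = 1L,
                           lowSignalDeltaK = 10, ...) {
  stopifnot(Kmax >= 3L, replicates >= 2L)
  runs <- expand.grid(replicate = seq_len(replicates), K = seq_len(Kmax))
  runs <- runs[, c("K", "replicate")]
  runs$seed <- .derive_seed(seed, runs$K, runs$replicate)
  runs$logLik <- NA_real_
  fits <- vector("list", nrow(runs))
  for (r in seq_len(nrow(runs))) {
    fits[[r]] <- fitMixtureEM(x, K = runs$K[r], seed = runs$seed[r], ...)
    runs$logLik[r] <- fits[[r]]@logLik
  }
  ev <- evannoDeltaK(runs)
  bestK <- attr(ev, "bestK")
  lowSignal <- is.na(bestK) ||
    max(ev$deltaK, na.rm = TRUE) < lowSignalDeltaK
  if (is.na(bestK)) bestK <- ev$K[which.max(ev$meanL)]
  atBest <- which(runs$K == bestK)
  fit <- fits[[atBest[which.max(runs$logLik[atBest])]]]
  list(evanno = ev, bestK = bestK, fit = fit, runs = runs,
       lowSignal = lowSignal)
}

## deterministic replicate seeds from a master seed (counter hashing,
## kept within 32-bit integer range)
.derive_seed <- function(seed, K, replicate) {
  as.integer((as.numeric(seed) %% 65521 + 1) * 7919 +
               K * 104729 + replicate * 1299709) %% 2147483647L
}

## allele-copy count matrix: individuals x (all alleles over all loci)
.allele_count_matrix <- function(x) {
  a1 <- assay(x, "allele1"); a2 <- assay(x, "allele2")
  n <- ncol(a1); L <- nrow(a1)
  blocks <- lapply(seq_len(L), function(l) {
    alleles <- sort(unique(c(a1[l, ], a2[l, ])))
    alleles <- alleles[!is.na(alleles)]
    B <- matrix(0L, n, length(alleles))
    ok <- which(!is.na(a1[l, ]))
    i1 <- cbind(ok, match(a1[l, ok], alleles))
    i2 <- cbind(ok, match(a2[l, ok], alleles))
    B[i1] <- B[i1] + 1L
    B[i2] <- B[i2] + 1L
    B
  })
  C <- do.call(cbind, blocks)
  locus <- rep(seq_len(L), vapply(blocks, ncol, integer(1)))
  list(C = C, locus = locus)
}
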