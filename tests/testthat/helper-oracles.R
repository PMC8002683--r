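# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths (C++ builders, assembleGenerator) so that
# agreement is informative.

# Brute-force one-gene MaxCal transition matrix by exhaustive path
# enumeration (sink appended last).
bruteForceTransitionSGAA <- function(hAlpha, hA, KA, M, nmax) {
  P <- matrix(0, nmax + 1, nmax + 1)
  for (i in 0:(nmax - 1)) {
    g <- expand.grid(la = 0:M, lA = 0:i)
    w <- exp(lchoose(i, g$lA) + hAlpha * g$la + hA * g$lA + KA * g$la * g$lA)
    w <- w / sum(w)
    j <- g$la + g$lA
    for (k in seq_along(j)) {
      if (j[k] < nmax) P[j[k] + 1, i + 1] <- P[j[k] + 1, i + 1] + w[k]
      else P[nmax + 1, i + 1] <- P[nmax + 1, i + 1] + w[k]
    }
  }
  P[nmax + 1, nmax + 1] <- 1
  P
}

# Brute-force toggle-switch MaxCal transition matrix.
bruteForceTransitionTS <- function(hAlpha, hA, KAalpha, KAbeta, M, nmax) {
  dim <- nmax^2 + 1
  P <- matrix(0, dim, dim)
  for (k in 0:(nmax - 1)) for (i in 0:(nmax - 1)) {
    g <- expand.grid(la = 0:M, lA = 0:i, lb = 0:M, lB = 0:k)
    w <- exp(lchoose(i, g$lA) + lchoose(k, g$lB) +
               hAlpha * (g$la + g$lb) + hA * (g$lA + g$lB) +
               KAalpha * (g$la * g$lA + g$lb * g$lB) +
               KAbeta * (g$lb * g$lA + g$la * g$lB))
    w <- w / sum(w)
    j <- g$la + g$lA; l <- g$lb + g$lB
    col <- i + nmax * k + 1
    for (q in seq_along(w)) {
      if (j[q] < nmax && l[q] < nmax)
        P[j[q] + nmax * l[q] + 1, col] <- P[j[q] + nmax * l[q] + 1, col] + w[q]
      else P[dim, col] <- P[dim, col] + w[q]
    }
  }
  P[dim, dim] <- 1
  P
}

# Truncated Taylor series exp(A) = sum A^k/k!, k <= 30.
taylorExpm <- function(A, nTerms = 30) {
  S <- diag(nrow(A)); term <- diag(nrow(A))
  for (k in seq_len(nTerms)) {
    term <- term %*% A / k
    S <- S + term
  }
  S
}

# random small generator matrix (columns sum to zero)
randomGenerator <- function(n, scale = 1) {
  A <- matrix(stats::runif(n * n) * scale, n, n)
  diag(A) <- 0
  diag(A) <- -colSums(A)
  A
}

# wrap a plain generator matrix for propagate()
asGenerator <- function(A) {
  sp <- buildStateSpace(c(A = nrow(A) - 1L))
  new("GeneratorMatrix", W = Matrix::Matrix(A), space = sp)
}

# small birth-death generator over counts 0..nmax-1 + sink
birthDeathGeneratorMatrix <- function(lambda, mu, nmax) {
  sp <- buildStateSpace(c(A = nmax))
  assembleGenerator(list(
    list(delta = c(A = 1L), propensity = function(s) rep(lambda, nrow(s))),
    list(delta = c(A = -1L), propensity = function(s) mu * s[, "A"])), sp)
}
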