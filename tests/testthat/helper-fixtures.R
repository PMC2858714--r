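# Shared fixtures, built in code.

# tiny record table with a known class structure per area
tinyRecords <- function() {
  data.frame(
    area = c(rep("X1A", 6), rep("Y2B", 5)),
    a = c(1, 1, 1, 2, 2, 3, 1, 2, 3, 4, 5),
    b = c(rep(1, 6), rep(9, 5)),
    stringsAsFactors = FALSE
  )
}

tinyPopTable <- function() {
  data.frame(area = c("X1A", "Y2B"), pop = c(30L, 25L),
             stringsAsFactors = FALSE)
}

# small synthetic population reused across tests (generation is cheap)
smallSynth <- function(seed = 7, nAreas = 4, popRange = c(60, 200)) {
  generatePopulation(populationSpec(nAreas = nAreas, popRange = popRange,
                                    seed = seed))
}

# all-pairs AUC oracle: brute-force pair counting with ties counted half
aucAllPairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# brute-force King-Zeng bias oracle: explicit elementwise matrix arithmetic
kzBiasBruteForce <- function(X, pi) {
  n <- nrow(X); k <- ncol(X)
  W <- diag(pi * (1 - pi), n)
  XtWX <- t(X) %*% W %*% X
  A <- solve(XtWX)
  Q <- X %*% A %*% t(X)
  xi <- numeric(n)
  for (i in seq_len(n)) xi[i] <- 0.5 * Q[i, i] * (2 * pi[i] - 1)
  drop(A %*% t(X) %*% W %*% xi)
}
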