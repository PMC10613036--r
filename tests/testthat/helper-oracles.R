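# Independent oracle implementations used to validate the package's own
# algorithms; deliberately written as direct, unoptimised formulas.

# exhaustive between-class-variance maximiser over all 255 thresholds
otsu_oracle <- function(h) {
  n <- sum(h)
  lev <- 0:255
  best <- -Inf
  best_t <- NA_integer_
  for (t in 0:254) {
    w0 <- sum(h[1:(t + 1)])
    w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:(t + 1)] * lev[1:(t + 1)]) / w0
    mu1 <- sum(h[(t + 2):256] * lev[(t + 2):256]) / w1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best + 1e-9) {
      best <- bcv
      best_t <- t
    }
  }
  best_t
}

# greedy Ward agglomeration by direct recomputation of the SSE increase
# for every cluster pair at every step
ward_oracle <- function(x) {
  x <- as.matrix(x)
  clusters <- lapply(seq_len(nrow(x)), identity)
  costs <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf
    bi <- bj <- 0
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        a <- x[clusters[[i]], , drop = FALSE]
        b <- x[clusters[[j]], , drop = FALSE]
        na <- nrow(a); nb <- nrow(b)
        d2 <- sum((colMeans(a) - colMeans(b))^2)
        cost <- na * nb / (na + nb) * d2
        if (cost < best - 1e-12) {
          best <- cost
          bi <- i; bj <- j
        }
      }
    }
    costs <- c(costs, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  costs
}

# Feret dimensions by dense direction-grid search over mesh vertices
feret_oracle <- function(V, k = 4000L) {
  set.seed(7)
  D <- matrix(rnorm(3 * k), k, 3)
  D <- D / sqrt(rowSums(D^2))
  ext <- apply(V %*% t(D), 2, function(p) max(p) - min(p))
  max(ext)
}
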