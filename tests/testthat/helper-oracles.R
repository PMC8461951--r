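# Independent brute-force oracles. These deliberately share no code with the
# package: UPGMA recomputes cluster distances as means over the ORIGINAL
# distance matrix instead of Lance-Williams updates; the Mann-Whitney oracle
# counts concordant pairs instead of summing ranks; the hypergeometric oracle
# sums binomial-coefficient mass.

# O(n^4) UPGMA: clusters as member sets; inter-cluster distance = mean of all
# original pairwise distances; ties broken by the lexicographically smallest
# (min member of first cluster, min member of second cluster).
oracle_upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)   # member index sets
  codes <- -seq_len(n)                        # hclust coding
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        dd <- mean(d[clusters[[a]], clusters[[b]]])
        key <- c(min(clusters[[a]]), min(clusters[[b]]))
        if (key[1L] > key[2L]) key <- rev(key)
        if (is.null(best) || dd < best$d - 1e-12 ||
            (abs(dd - best$d) <= 1e-12 &&
             (key[1L] < best$key[1L] ||
              (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
          best <- list(a = a, b = b, d = dd, key = key)
        }
      }
    }
    pair <- c(codes[best$a], codes[best$b])
    pair <- pair[order(pair >= 0L, abs(pair))]
    merge[step, ] <- pair
    height[step] <- best$d
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    codes[best$a] <- step
    clusters[[best$b]] <- NULL
    codes <- codes[-best$b]
  }
  list(merge = merge, height = height)
}

# Pearson correlation by the textbook sum formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Upper-tail hypergeometric P[X >= k] from binomial coefficients.
oracle_hyper_upper <- function(k, N, K, n) {
  js <- max(k, 0L):min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Same tail by exhaustive enumeration of all n-subsets of a universe whose
# first K elements form the gene set (feasible for N <= 12).
oracle_hyper_enum <- function(k, N, K, n) {
  combos <- utils::combn(N, n)
  mean(colSums(combos <= K) >= k)
}

# Exact two-sided Mann-Whitney p by enumerating labelings and counting
# concordant case/control pairs directly (half for ties).
oracle_mw_exact <- function(v1, v2) {
  n1 <- length(v1); n2 <- length(v2)
  pooled <- c(v1, v2)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    diff <- outer(a, b, `-`)
    sum(diff > 0) + 0.5 * sum(diff == 0)
  }
  u_obs <- u_of(seq_len(n1))
  mid <- n1 * n2 / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2L, u_of)
  mean(abs(u_all - mid) >= abs(u_obs - mid) - 1e-9)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small random symmetric distance matrix generator for property tests.
random_dist <- function(n, seed) {
  set.seed(seed)
  stats::dist(matrix(stats::runif(n * 3L), nrow = n))
}
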