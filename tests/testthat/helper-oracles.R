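# Independent brute-force oracles, deliberately written with naive loops and
# formulas distinct from the package implementation paths.

# Cohen's kappa by explicit pair counting over label vectors.
oracleKappa <- function(la, lb) {
  la <- as.character(la)
  lb <- as.character(lb)
  n <- length(la)
  labs <- sort(unique(c(la, lb)))
  po <- 0
  for (i in seq_len(n)) po <- po + (la[i] == lb[i])
  po <- po / n
  pe <- 0
  for (s in labs) {
    ra <- sum(la == s) / n
    rb <- sum(lb == s) / n
    pe <- pe + ra * rb
  }
  if (abs(1 - pe) < 1e-14) return(NA_real_)
  (po - pe) / (1 - pe)
}

# Subtype-specific kappa via an explicitly constructed 2x2 table.
oracleSubtypeKappa <- function(la, lb, s) {
  tab <- matrix(0, 2, 2)
  for (i in seq_along(la)) {
    r <- if (la[i] == s) 2 else 1
    c <- if (lb[i] == s) 2 else 1
    tab[r, c] <- tab[r, c] + 1
  }
  n <- sum(tab)
  po <- (tab[1, 1] + tab[2, 2]) / n
  pe <- (sum(tab[1, ]) * sum(tab[, 1]) + sum(tab[2, ]) * sum(tab[, 2])) / n^2
  if (abs(1 - pe) < 1e-14) return(NA_real_)
  (po - pe) / (1 - pe)
}

# Percentile by hand: sort and linearly interpolate between order statistics
# at position h = (n - 1) p + 1.
oracleQuantile <- function(x, p) {
  x <- sort(unname(x))
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Signed module score by explicit per-gene accumulation.
oracleModuleScore <- function(exprCol, module) {
  num <- 0
  den <- 0
  for (i in seq_len(nrow(module))) {
    g <- module$gene_id[i]
    if (g %in% names(exprCol)) {
      num <- num + module$weight[i] * exprCol[[g]]
      den <- den + abs(module$weight[i])
    }
  }
  num / den
}

# Bivariate Gaussian density via solve()/det(), independent of the
# Cholesky-based implementation in the package.
oracleDmvnorm2 <- function(x, mu, sigma) {
  xc <- as.numeric(x) - as.numeric(mu)
  q <- as.numeric(t(xc) %*% solve(sigma) %*% xc)
  exp(-q / 2) / (2 * pi * sqrt(det(sigma)))
}

randomAssignmentPair <- function(n, nClasses) {
  labs <- subtypeLevels()[seq_len(nClasses)]
  ids <- sprintf("s%04d", seq_len(n))
  list(a = SubtypeAssignment(ids, sample(labs, n, replace = TRUE), "A"),
       b = SubtypeAssignment(ids, sample(labs, n, replace = TRUE), "B"))
}
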