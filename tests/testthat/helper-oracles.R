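# Independent oracles and fixture builders. Each oracle re-derives its
# quantity from first principles (enumeration / naive set arithmetic) and
# never calls the implementation path it checks.

# Naive set-arithmetic SE: element-by-element membership counting.
oracleSE <- function(lRef, lCmp, convention = "semantic") {
  nI <- sum(vapply(lRef, function(p) any(p == lCmp), logical(1)))
  r1 <- nI / length(lRef)
  r2 <- nI / length(lCmp)
  if (convention == "semantic") r1 - r2 else r2 - r1
}

# Naive C/G/PL partition with membership loops.
oracleClassify <- function(lRef, lCmp) {
  inBoth <- vapply(lRef, function(p) any(p == lCmp), logical(1))
  inRefOnly <- !inBoth
  inCmpOnly <- !vapply(lCmp, function(p) any(p == lRef), logical(1))
  list(consensus = sort(lRef[inBoth]),
       gain = sort(lCmp[inCmpOnly]),
       potential_loss = sort(lRef[inRefOnly]),
       gain_ratio = sum(inCmpOnly) / length(lCmp),
       potential_loss_ratio = sum(inRefOnly) / length(lRef))
}

# Exhaustive two-group partition: minimal within-group sum of squares over
# every bipartition into two non-empty groups. Returns the minimal SS.
oracleMinSplitSS <- function(values) {
  n <- length(values)
  best <- Inf
  for (mask in seq_len(2^n - 2L)) {
    inA <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    a <- values[inA]
    b <- values[!inA]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ss < best) best <- ss
  }
  best
}

withinSS <- function(values, highIdx) {
  a <- values[highIdx]
  b <- values[-highIdx]
  ssA <- if (length(a) > 0L) sum((a - mean(a))^2) else 0
  ssB <- if (length(b) > 0L) sum((b - mean(b))^2) else 0
  ssA + ssB
}

# Exact two-sided signed-rank p-value by full enumeration of all 2^n sign
# assignments (distinct non-zero magnitudes assumed).
oracleSignedRankP <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  V <- as.vector(signs %*% r)
  min(1, 2 * min(mean(V <= v), mean(V >= v)))
}

# Random LR pair universe and subsets for property tests.
randomPairUniverse <- function(n) {
  sprintf("L%02d|R%02d", seq_len(n), seq_len(n))
}

randomSubset <- function(universe, minSize = 1L) {
  size <- sample(seq.int(minSize, length(universe)), 1L)
  sample(universe, size)
}

commKeyRow <- function(df) paste(df$source, df$target, sep = "->")

# Canonical interaction data.frame builder.
makeRecords <- function(source, target, ligand, receptor,
                        lr_mean = 1, pa = 0.01, pb = 0.01) {
  data.frame(source = source, target = target, ligand = ligand,
             receptor = receptor, lr_mean = lr_mean,
             pval_method_a = pa, pval_method_b = pb,
             stringsAsFactors = FALSE)
}

# Writes an InteractionTable to a temp CSV in LIANA naming; returns path.
writeTempTable <- function(tbl) {
  path <- tempfile(fileext = ".csv")
  writeInteractionTable(tbl, path)
  path
}
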