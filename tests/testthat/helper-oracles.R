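# Independent brute-force oracles the implementation is checked
# against. Deliberately written as explicit loops, no vectorization,
# no reuse of package internals.

# --- enrichment score -------------------------------------------------

oracle_es_sub <- function(ranks, r) {
  s <- length(ranks)
  if (s == 0L) return(0)
  V <- sort(ranks)
  a <- -Inf
  b <- -Inf
  for (j in seq_len(s)) {
    a <- max(a, j / s - V[j] / r)
    b <- max(b, V[j] / r - (j - 1) / s)
  }
  if (a >= b) a else -b
}

oracle_es <- function(up_ranks, down_ranks, r) {
  eu <- oracle_es_sub(up_ranks, r)
  ed <- oracle_es_sub(down_ranks, r)
  if (eu != 0 && ed != 0 && sign(eu) == sign(ed)) 0 else eu - ed
}

# --- Moran's I --------------------------------------------------------

oracle_morans_i <- function(values, coords, k) {
  n <- length(values)
  k <- min(k, n - 1L)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  }
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i])
    others <- seq_len(n)[-i]
    for (j in others[ord][seq_len(k)]) {
      W[i, j] <- 1; W[j, i] <- 1
    }
  }
  xbar <- mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + W[i, j] * (values[i] - xbar) * (values[j] - xbar)
  }
  den <- sum((values - xbar)^2)
  (n / sum(W)) * num / den
}

# --- Wilcoxon rank-sum (exact enumeration) ----------------------------

oracle_ranksum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  w_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  labelings <- utils::combn(n1 + n2, n1)
  ws <- apply(labelings, 2, function(idx) {
    sum(rk[idx]) - n1 * (n1 + 1) / 2
  })
  lo <- mean(ws <= w_obs)
  hi <- mean(ws >= w_obs)
  min(1, 2 * min(lo, hi))
}

# --- Kendall tau-b by pair counting -----------------------------------

oracle_kendall_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx_total(x)) * (n0 - tx_total(y)))
}

tx_total <- function(v) {
  tt <- table(v)
  sum(tt * (tt - 1) / 2)
}

# --- small fixtures ---------------------------------------------------

# minimal spatial sample on an nx x ny grid with given counts
toy_sample <- function(counts, technology = "multi_cell",
                       mito_genes = character(), spacing = 1,
                       annotations = NULL) {
  nx <- ceiling(sqrt(ncol(counts)))
  coords <- data.frame(
    location_id = colnames(counts),
    x = ((seq_len(ncol(counts)) - 1) %% nx) * spacing,
    y = ((seq_len(ncol(counts)) - 1) %/% nx) * spacing)
  spatial_sample(counts, coords, technology, mito_genes = mito_genes,
                 annotations = annotations)
}

named_matrix <- function(data, genes, locs) {
  matrix(data, nrow = length(genes), dimnames = list(genes, locs))
}

# tiny profile library with prescribed z-scores (one signature)
toy_library <- function(z, signature_id = "S1", compound = "drugA") {
  profile_library(
    matrix(z, ncol = 1, dimnames = list(names(z), signature_id)),
    data.frame(signature_id = signature_id, compound = compound))
}

# library whose single signature ranks gene g at position rank[g]
library_from_ranks <- function(ranks) {
  toy_library(setNames(as.numeric(ranks), names(ranks)))
}

# profile over genes g01..gr whose ranking is the identity (z = rank)
identity_profile <- function(r) {
  genes <- sprintf("g%02d", seq_len(r))
  rank_profile(library_from_ranks(setNames(seq_len(r), genes)), "S1")
}

genes_at_ranks <- function(ranks) sprintf("g%02d", ranks)

# one-gene-per-count sample: each location has `umis` UMIs spread over
# distinct genes (so detected genes == total UMIs)
umi_ladder_sample <- function(umis, technology = "multi_cell") {
  n_gene <- max(umis)
  m <- sapply(umis, function(u) c(rep(1L, u), rep(0L, n_gene - u)))
  rownames(m) <- sprintf("G%04d", seq_len(n_gene))
  colnames(m) <- sprintf("L%03d", seq_along(umis))
  toy_sample(m, technology = technology)
}
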