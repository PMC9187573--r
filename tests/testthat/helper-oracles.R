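# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: set scans instead of vectorised masking, graph
# components instead of flood fill, full enumeration instead of closed-form
# distributions.

# brute-force masked mean by explicit voxel scan
brute_masked_mean <- function(values, mask) {
  acc <- 0
  n <- 0L
  d <- dim(values)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] && !is.na(values[i, j, k])) {
      acc <- acc + values[i, j, k]
      n <- n + 1L
    }
  }
  acc / n
}

# connected components of a logical array via igraph
igraph_components <- function(mask, connectivity) {
  idx <- which(mask)
  if (!length(idx)) return(array(0L, dim(mask)))
  d <- dim(mask)
  co <- arrayInd(idx, d)
  rank <- array(0L, d)
  rank[idx] <- seq_along(idx)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[r, ], "+")
    okb <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(okb)) next
    li <- nb[okb, 1] + d[1] * (nb[okb, 2] - 1L) + d[1] * d[2] * (nb[okb, 3] - 1L)
    inm <- mask[li]
    edges <- rbind(edges, cbind(which(okb)[inm], rank[li[inm]]))
  }
  g <- igraph::graph_from_edgelist(unique(t(apply(edges, 1, sort))),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out <- array(0L, d)
  out[idx] <- comp[seq_along(idx)]
  out
}

# two component labelings agree up to label renaming
same_partition <- function(a, b) {
  if (!identical(a != 0L, b != 0L)) return(FALSE)
  idx <- which(a != 0L)
  all(tapply(b[idx], a[idx], function(v) length(unique(v))) == 1) &&
    all(tapply(a[idx], b[idx], function(v) length(unique(v))) == 1)
}

# full-enumeration two-sided Mann-Whitney p (no ties)
enum_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  u_all <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# two-sided Fisher p by hypergeometric enumeration
enum_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ])          # margin of row 1
  k <- sum(tab[, 1])          # margin of col 1
  n <- sum(tab)
  xs <- max(0, k - (n - m)):min(k, m)
  pr <- stats::dhyper(xs, m, n - m, k)
  p_obs <- stats::dhyper(a, m, n - m, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# random blobby test mask: union of a few spheres
random_mask <- function(d, n_spheres = 3, spacing = c(1, 1, 1)) {
  m <- array(FALSE, d)
  for (i in seq_len(n_spheres)) {
    cen <- sapply(d, function(k) sample(seq_len(k), 1))
    rad <- runif(1, 1, min(d) / 3)
    x <- slice.index(m, 1); y <- slice.index(m, 2); z <- slice.index(m, 3)
    m <- m | ((x - cen[1])^2 + (y - cen[2])^2 + (z - cen[3])^2 <= rad^2)
  }
  binary_mask(m, spacing)
}
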