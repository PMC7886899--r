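# Meiosis machinery: Haldane (Poisson) crossovers on a genetic map.
#
# A gamete is assembled per chromosome by choosing a starting parental strand
# at random and switching strand at each crossover; crossover counts are
# Poisson with mean length/100 Morgans and positions uniform on the
# chromosome. Strand state at a variant is the parity of the number of
# crossovers before its position.

# Strand indicator matrix for n independent meioses at the given positions
# (cM, one chromosome of length L). TRUE = first parental strand.
# With record = TRUE the raw crossover realisation (start strand, counts,
# sorted-by-owner point positions) is returned too, so downstream code can
# compute exact shared-segment quantities.
meiosis_strands <- function(n, pos, L, record = FALSE) {
  start <- runif(n) < 0.5
  p <- length(pos)
  out <- if (p > 0) matrix(start, n, p) else matrix(FALSE, n, 0)
  if (L <= 0) {
    return(if (record) list(strands = out, start = start,
                            k = integer(n), u = numeric(0)) else
           list(strands = out))
  }
  k <- stats::rpois(n, L / 100)
  K <- sum(k)
  if (K > 0L) {
    u <- runif(K, 0, L)
    o <- rep.int(seq_len(n), k)
    for (j in seq_len(p)) {
      flips <- tabulate(o[u < pos[j]], nbins = n)
      odd <- flips %% 2L == 1L
      out[, j] <- xor(out[, j], odd)
    }
  } else u <- numeric(0)
  if (record) list(strands = out, start = start, k = k, u = u)
  else list(strands = out)
}

# Gametes for a batch of meioses. hapA/hapB: parental haplotypes, one row per
# meiosis (rows repeated for parents contributing several gametes).
# Returns list(gamete, recomb); recomb (when requested) holds the per-
# chromosome crossover realisations for exact IBD computation.
make_gametes <- function(hapA, hapB, position, map, keep_recomb = FALSE) {
  n <- nrow(hapA)
  gam <- matrix(0L, n, ncol(hapA))
  recomb <- if (keep_recomb) vector("list", nrow(map)) else NULL
  for (c in seq_len(nrow(map))) {
    idx <- which(position$chrom == map$chrom[c])
    ms <- meiosis_strands(n, position$pos_cM[idx], map$cM[c], record = keep_recomb)
    if (length(idx)) {
      s <- ms$strands
      g <- hapB[, idx, drop = FALSE]
      a <- hapA[, idx, drop = FALSE]
      g[s] <- a[s]
      gam[, idx] <- g
    }
    if (keep_recomb) recomb[[c]] <- ms[c("start", "k", "u")]
  }
  list(gamete = gam, recomb = recomb)
}

# Exact genome-wide IBD proportion between gamete pairs transmitted by the
# same parent, from recorded crossover realisations. The strand-equality
# indicator along a chromosome flips at every crossover of either meiosis,
# so the shared length is an alternating-segment sum over the merged
# crossover points (the same telegraph computation as the standalone sib
# IBD simulator).
recomb_ibd <- function(recomb, i, j, map) {
  npair <- length(i)
  tot <- sum(map$cM)
  w <- if (tot > 0) map$cM / tot else rep(1 / nrow(map), nrow(map))
  ibd <- numeric(npair)
  for (c in seq_len(nrow(map))) {
    rc <- recomb[[c]]
    L <- map$cM[c]
    eq_start <- rc$start[i] == rc$start[j]
    if (L <= 0) {
      ibd <- ibd + w[c] * as.numeric(eq_start)
      next
    }
    k <- rc$k[i] + rc$k[j]
    # merged crossover points of both meioses, grouped by pair
    off <- c(0, cumsum(rc$k))  # point offsets per meiosis
    take <- function(m) rc$u[sequence(rc$k[m], from = off[m] + 1L)]
    u <- c(take(i), take(j))
    o <- c(rep.int(seq_len(npair), rc$k[i]), rep.int(seq_len(npair), rc$k[j]))
    ibd <- ibd + w[c] * telegraph_shared(eq_start, k, u, o, L) / L
  }
  ibd
}

# Give owner `to` an identical crossover realisation to owner `from`
# (used to make MZ co-twins share gametes exactly).
copy_owner_recomb <- function(r, from, to) {
  ow <- rep.int(seq_along(r$k), r$k)
  pts_from <- r$u[ow == from]
  u_all <- c(r$u[ow != to], pts_from)
  o_all <- c(ow[ow != to], rep.int(to, length(pts_from)))
  ord <- order(o_all)
  r$u <- u_all[ord]
  r$k[to] <- r$k[from]
  r$start[to] <- r$start[from]
  r
}
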