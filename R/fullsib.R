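# Full-sib IBD regression: within-family heritability from the segregation
# variance of realised genome-wide IBD sharing around its expectation of 0.5.

# Length of the "equal" state of a two-state alternating process on [0, L]
# that starts in state eq_start (per owner) and flips at each of the owner's
# points. Owners with k = 0 points hold their start state throughout.
# u: point positions, o: owner index per point (any order). Returns lengths.
telegraph_shared <- function(eq_start, k, u, o, L) {
  N <- length(eq_start)
  shared <- ifelse(eq_start, L, 0)
  nz <- which(k > 0L)
  if (length(nz)) {
    ord <- order(o, u)
    os <- o[ord]; us <- u[ord]
    firsts <- !duplicated(os)
    prev <- c(0, us[-length(us)])
    prev[firsts] <- 0
    d <- us - prev
    j <- sequence(k[nz])
    segstate <- xor(eq_start[os], (j - 1L) %% 2L == 1L)
    inner <- rowsum(d * segstate, os)
    lastu <- us[rev(!duplicated(rev(os)))]
    endstate <- xor(eq_start[nz], k[nz] %% 2L == 1L)
    shared[nz] <- inner[, 1] + (L - lastu) * endstate
  }
  shared
}

# Shared ("equal-strand") length fraction for N independent meiosis pairs on
# one chromosome of length L cM. The equality indicator is a telegraph
# process: it flips at the crossovers of either meiosis (Poisson, combined
# rate 2 per Morgan) and starts in each state with probability 1/2.
shared_length <- function(N, L) {
  start <- runif(N) < 0.5
  if (L <= 0) return(ifelse(start, 1, 0))  # point chromosome: all or nothing
  k <- stats::rpois(N, 2 * L / 100)
  u <- runif(sum(k), 0, L)
  o <- rep.int(seq_len(N), k)
  telegraph_shared(start, k, u, o, L) / L
}

#' Simulate genome-wide IBD proportions for full-sib pairs
#'
#' Maternal and paternal meioses are simulated as Haldane crossover
#' processes (Poisson counts with mean length/100 Morgans per chromosome,
#' uniform positions); the sib pair's shared fraction per parent is the
#' fraction of the genome where both sibs inherited the same parental
#' strand, combined across chromosomes with length weights, and the IBD
#' proportion is the average over the two parents. With the default human
#' autosomal map the distribution has mean 0.50 and SD about 0.037.
#'
#' @param n_pairs Number of sib pairs.
#' @param map Genetic map data.frame (`chrom`, `cM`); default
#'   [default_genetic_map()].
#' @param seed Optional seed applied locally.
#' @return Numeric vector of IBD proportions in \[0, 1\].
#' @export
simulate_sib_ibd <- function(n_pairs, map = default_genetic_map(), seed = NULL) {
  stopifnot(n_pairs >= 1)
  if (is.null(map) || nrow(map) == 0) stop("empty genetic map")
  if (any(map$cM < 0)) stop("negative chromosome length in map")
  if (!is.null(seed)) set.seed(seed)
  tot <- sum(map$cM)
  w <- if (tot > 0) map$cM / tot else rep(1 / nrow(map), nrow(map))
  ibd <- numeric(n_pairs)
  for (c in seq_len(nrow(map))) {
    frac <- shared_length(2L * n_pairs, map$cM[c])
    per_pair <- (frac[seq_len(n_pairs)] + frac[n_pairs + seq_len(n_pairs)]) / 2
    ibd <- ibd + w[c] * per_pair
  }
  ibd
}

new_fullsib_fit <- function(sa, sc, se, ses, method, n_pairs, total,
                            extra = NULL) {
  structure(c(list(sigma2_a = sa, sigma2_c = sc, sigma2_e = se,
                   h2_fs = sa / total, c2_fs = sc / total,
                   se_h2 = unname(ses["h2"]), se_c2 = unname(ses["c2"]),
                   total = total, method = method, n_pairs = n_pairs),
              extra),
            class = "fullsib_fit")
}

#' @export
print.fullsib_fit <- function(x, ...) {
  cat(sprintf("fullsib_fit (%s, %d pairs): h2_fs = %.3f (se %.3f), c2_fs = %.3f (se %.3f)\n",
              x$method, x$n_pairs, x$h2_fs, x$se_h2, x$c2_fs, x$se_c2))
  cat(sprintf("  variance components a/c/e: %.4f / %.4f / %.4f (total %.4f)\n",
              x$sigma2_a, x$sigma2_c, x$sigma2_e, x$total))
  invisible(x)
}

#' Full-sib IBD regression at the pair level
#'
#' Least squares of the sib-pair phenotype cross-product on the realised
#' IBD proportion. The intercept estimates the shared (family) covariance
#' `c2_FS`; the slope estimates the within-family heritability `h2_FS`,
#' which is free of environmental covariance between sibs. MZ pairs
#' (IBD = 1) carry no segregation information and are dropped.
#'
#' @param ibd Realised IBD proportions per pair.
#' @param y1,y2 Prepared phenotypes of the two sibs (or give `xp`).
#' @param xp Cross-products directly (overrides y1/y2).
#' @return A `fullsib_fit` (method "pair-regression").
#' @export
pair_regression <- function(ibd, y1 = NULL, y2 = NULL, xp = NULL) {
  if (is.null(xp)) xp <- y1 * y2
  mz <- ibd >= 1 - 1e-12
  if (any(mz)) message(sum(mz), " MZ pair(s) (IBD = 1) dropped")
  ibd_ <- ibd[!mz]; xp_ <- xp[!mz]
  if (length(ibd_) < 3) stop("need at least 3 pairs with IBD variation")
  if (stats::var(ibd_) == 0) stop("no segregation variance: IBD is constant")
  f <- stats::lm(xp_ ~ ibd_)
  cf <- stats::coef(f)
  sm <- suppressWarnings(summary(f))$coefficients
  total <- if (!is.null(y1)) stats::var(c(y1, y2)) else 1
  sa <- cf[[2]]; sc <- cf[[1]]
  new_fullsib_fit(sa, sc, max(0, total - sa - sc),
                  c(h2 = sm[2, 2] / total, c2 = sm[1, 2] / total),
                  "pair-regression", length(ibd_), total)
}

#' Full-sib variance components by restricted maximum likelihood
#'
#' Individual-level model `y* = 1 mu + a + c + e` with
#' `a ~ N(0, A sigma2_a)`, `c ~ N(0, C sigma2_c)`, `e ~ N(0, I sigma2_e)`;
#' `A` is block diagonal with 1 on the diagonal and realised IBD on sib
#' off-diagonals, `C` likewise with 1 for sib pairs. The restricted
#' likelihood is maximised directly over the three variance components
#' using per-family block decompositions (families are tiny), with a
#' closed-form path for two-member families. Standard errors come from the
#' observed information at the optimum; negative components are constrained
#' at zero.
#'
#' @param y Named phenotype vector (names are ids).
#' @param family Family label per element of `y`.
#' @param ibd Data.frame `id1`, `id2`, `ibd` for within-family sib pairs
#'   (pairs not listed get IBD 0.5; MZ pairs should carry 1).
#' @param tol Convergence tolerance on the restricted log-likelihood.
#' @return A `fullsib_fit` (method "variance-components") with the REML
#'   estimates, delta-method ses for `h2_fs`/`c2_fs`, and the fitted
#'   log-likelihood.
#' @export
fit_variance_components <- function(y, family, ibd = NULL, tol = 1e-8) {
  stopifnot(length(y) == length(family))
  ids <- names(y)
  if (is.null(ids)) ids <- as.character(seq_along(y))
  fams <- split(seq_along(y), family)
  sizes <- lengths(fams)
  if (all(sizes == 1)) {
    warning("all families are singletons: sigma2_a and sigma2_c are not separable")
    v <- stats::var(y)
    return(new_fullsib_fit(0, 0, v, c(h2 = NA_real_, c2 = NA_real_),
                           "variance-components", 0L, v))
  }
  ibd_of <- function(a, b) {
    if (is.null(ibd)) return(0.5)
    hit <- (ibd$id1 == a & ibd$id2 == b) | (ibd$id1 == b & ibd$id2 == a)
    if (any(hit)) ibd$ibd[which(hit)[1]] else 0.5
  }
  # precompute structures
  pair_fams <- fams[sizes == 2]
  if (length(pair_fams)) {
    p1 <- vapply(pair_fams, `[`, 0L, 1); p2 <- vapply(pair_fams, `[`, 0L, 2)
    pibd <- mapply(ibd_of, ids[p1], ids[p2])
    py1 <- y[p1]; py2 <- y[p2]
  }
  single <- unlist(fams[sizes == 1])
  big_fams <- fams[sizes > 2]
  big <- lapply(big_fams, function(ix) {
    k <- length(ix)
    A <- diag(k); C <- matrix(1, k, k)
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      A[a, b] <- A[b, a] <- ibd_of(ids[ix[a]], ids[ix[b]])
    }
    list(y = y[ix], A = A, C = C)
  })

  nll <- function(th) {
    sa <- th[1]; sc <- th[2]; se <- th[3]
    logdet <- 0; xvx <- 0; xvy <- 0; yvy <- 0
    if (length(single)) {
      v <- sa + sc + se
      logdet <- logdet + length(single) * log(v)
      xvx <- xvx + length(single) / v
      xvy <- xvy + sum(y[single]) / v
      yvy <- yvy + sum(y[single]^2) / v
    }
    if (length(pair_fams)) {
      v <- sa + sc + se
      w <- sa * pibd + sc
      det2 <- v^2 - w^2
      if (any(det2 <= 0)) return(1e10)
      logdet <- logdet + sum(log(det2))
      xvx <- xvx + sum((2 * v - 2 * w) / det2)
      xvy <- xvy + sum((py1 + py2) * (v - w) / det2)
      yvy <- yvy + sum((v * (py1^2 + py2^2) - 2 * w * py1 * py2) / det2)
    }
    for (f in big) {
      V <- f$A * sa + f$C * sc + diag(length(f$y)) * se
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      logdet <- logdet + 2 * sum(log(diag(ch)))
      Vi1 <- backsolve(ch, forwardsolve(t(ch), rep(1, length(f$y))))
      Viy <- backsolve(ch, forwardsolve(t(ch), f$y))
      xvx <- xvx + sum(Vi1)
      xvy <- xvy + sum(Viy)
      yvy <- yvy + sum(f$y * Viy)
    }
    if (xvx <= 0) return(1e10)
    0.5 * (logdet + log(xvx) + yvy - xvy^2 / xvx)
  }

  v0 <- stats::var(y)
  opt <- stats::optim(c(v0 / 3, v0 / 3, v0 / 3), nll, method = "L-BFGS-B",
                      lower = c(0, 0, 1e-8), hessian = TRUE,
                      control = list(factr = tol / .Machine$double.eps))
  if (opt$convergence != 0)
    stop("REML did not converge: ", opt$message %||% opt$convergence)
  th <- opt$par
  if (any(th[1:2] < 1e-10))
    message("variance component constrained at the zero boundary")
  vc <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA, 3, 3))
  total <- sum(th)
  # delta method for ratios h2 = sa/total, c2 = sc/total
  gh <- c(total - th[1], -th[1], -th[1]) / total^2
  gc <- c(-th[2], total - th[2], -th[2]) / total^2
  se_h2 <- sqrt(max(0, drop(t(gh) %*% vc %*% gh)))
  se_c2 <- sqrt(max(0, drop(t(gc) %*% vc %*% gc)))
  n_pairs <- length(pair_fams) + sum(vapply(big, function(f) choose(length(f$y), 2), 0))
  new_fullsib_fit(th[1], th[2], th[3], c(h2 = se_h2, c2 = se_c2),
                  "variance-components", as.integer(n_pairs), total,
                  extra = list(logLik = -opt$value, vcov = vc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full-sib phenotypic correlation from regression components
#'
#' `r_FS = c2_FS + 0.5 h2_FS`, with the large-sample approximation
#' `se = sqrt((1 - r_FS^2) / N)`.
#'
#' @param c2_fs,h2_fs Full-sib regression components.
#' @param n_pairs Number of sib pairs.
#' @return List with `r_fs` and `se`.
#' @export
fullsib_correlation <- function(c2_fs, h2_fs, n_pairs) {
  stopifnot(n_pairs >= 2)
  r <- c2_fs + 0.5 * h2_fs
  if (abs(r) >= 1) stop("implied full-sib correlation outside (-1, 1)")
  list(r_fs = r, se = sqrt((1 - r^2) / n_pairs))
}

#' Read a genetic map from a two-column TSV
#'
#' @param path File with header columns `chrom` and `cM`.
#' @return A data.frame usable wherever [default_genetic_map()] is.
#' @export
read_genetic_map <- function(path) {
  map <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("chrom", "cM") %in% names(map)), all(map$cM >= 0))
  map[, c("chrom", "cM")]
}
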