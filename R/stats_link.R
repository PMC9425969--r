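#' Exact two-sided Wilcoxon rank-sum test
#'
#' Exact permutation test of the rank-sum statistic: pooled values receive
#' midranks (so the test remains exact under ties), and the two-sided
#' p-value is the probability, over all `choose(n_a + n_b, n_a)` group
#' assignments, of a rank sum at least as far from its null expectation as
#' the observed one. The full permutation distribution is computed by
#' dynamic programming over doubled midranks (integers), so no explicit
#' enumeration is needed. For groups larger than `exact_max` a normal
#' approximation with tie correction is used, with a message.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param label optional comparison label.
#' @param exact_max largest group size for the exact path, default 12.
#' @return list of class `group_comparison`: `label`, `n_a`, `n_b`,
#'   `statistic` (rank sum of `a`), `p_two_sided`, `method`.
#' @examples
#' wilcoxon_exact(1:5, 6:10)$p_two_sided  # 2/252
#' @export
wilcoxon_exact <- function(a, b, label = NULL, exact_max = 12) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("insufficient data: each group needs >= 2 observations")
  pooled <- c(a, b)
  r <- rank(pooled)                      # midranks
  na <- length(a); nb <- length(b); N <- na + nb
  W <- sum(r[seq_len(na)])
  mu <- na * (N + 1) / 2
  if (na <= exact_max && nb <= exact_max) {
    r2 <- as.integer(round(2 * r))       # midranks doubled are integers
    p <- ranksum_exact_p(r2, na, as.integer(round(2 * W)))
    method <- "exact"
  } else {
    message("group sizes exceed exact enumeration limit; ",
            "using normal approximation with tie correction")
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  structure(list(label = label, n_a = na, n_b = nb, statistic = W,
                 p_two_sided = min(1, p), method = method),
            class = "group_comparison")
}

# Exact two-sided p for the rank-sum of the first group. r2: doubled
# midranks (integers); na: size of group a; w2: doubled observed rank sum.
# Two-sided via symmetric deviation |W - E W| >= |w - E W| (invariant
# under swapping groups). Counts stay exact in doubles up to 2^53.
ranksum_exact_p <- function(r2, na, w2) {
  N <- length(r2)
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(na)])
  # f[k+1, s+1] = number of k-subsets with doubled-rank sum s
  f <- matrix(0, na + 1, smax + 1)
  f[1, 1] <- 1
  for (v in r2) {
    for (k in rev(seq_len(na))) {
      nz <- which(f[k, ] > 0)
      nz <- nz[nz + v <= smax + 1]
      if (length(nz)) f[k + 1, nz + v] <- f[k + 1, nz + v] + f[k, nz]
    }
  }
  dist <- f[na + 1, ]
  total <- sum(dist)
  mu2 <- na * sum(r2) / N
  s_vals <- which(dist > 0) - 1
  extreme <- abs(s_vals - mu2) >= abs(w2 - mu2) - 1e-9
  sum(dist[s_vals + 1][extreme]) / total
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("rank-sum comparison%s: n = %d vs %d, W = %.1f, p = %.4g (%s)\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$n_a, x$n_b, x$statistic, x$p_two_sided, x$method))
  invisible(x)
}

# All permutations of 1..n as an n! x n matrix (n <= 7 here).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Permutation correlation test for one pair of vectors
#'
#' Spearman (default) or Pearson correlation with a two-sided permutation
#' p-value: exact enumeration of all `n!` permutations when `n <= 7`,
#' otherwise `n_perm` seeded random permutations (with the identity
#' included, so p >= 1/(n_perm + 1)). The permutation criterion is
#' `|coefficient| >= |observed|`.
#'
#' @param x,y numeric vectors of equal length >= 4; neither constant.
#' @param method "spearman" or "pearson".
#' @param n_perm Monte Carlo permutations when `n > 7`, default 10000.
#' @param seed RNG seed for the Monte Carlo path.
#' @param perm_idx optional pre-built permutation index matrix
#'   (`n_perm` x `n`); lets [correlation_matrix()] share one set of
#'   permutations across all pairs.
#' @return list with `coefficient`, `p_two_sided`, `method`, `exact`.
#' @examples
#' correlate_pair(1:5, c(2, 3, 1, 5, 4))
#' @export
correlate_pair <- function(x, y, method = c("spearman", "pearson"),
                           n_perm = 10000, seed = 1, perm_idx = NULL) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 4) stop("need at least 4 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant vector")
  xs <- if (method == "spearman") rank(x) else x
  ys <- if (method == "spearman") rank(y) else y
  obs <- cor(xs, ys)
  xc <- (xs - mean(xs)) / sqrt(sum((xs - mean(xs))^2))
  yc <- (ys - mean(ys)) / sqrt(sum((ys - mean(ys))^2))
  if (n <= 7) {
    P <- all_perms(n)
    stats <- as.numeric(matrix(yc[P], nrow(P), n) %*% xc)
    p <- mean(abs(stats) >= abs(obs) - 1e-12)
    exact <- TRUE
  } else {
    if (is.null(perm_idx))
      perm_idx <- with_seed(seed, t(vapply(seq_len(n_perm),
                                           function(i) sample.int(n),
                                           integer(n))))
    stats <- as.numeric(matrix(yc[perm_idx], nrow(perm_idx), n) %*% xc)
    p <- (1 + sum(abs(stats) >= abs(obs) - 1e-12)) / (nrow(perm_idx) + 1)
    exact <- FALSE
  }
  list(coefficient = obs, p_two_sided = p, method = method, exact = exact)
}

#' Taxa-metabolite correlation matrix
#'
#' Correlates every (taxon, metabolite) column pair across shared
#' observation units (typically replicates x time points within one sex),
#' with permutation p-values from [correlate_pair()]. Significance is
#' assessed at `alpha`, uncorrected by default; `adjust = "BH"` recomputes
#' the significant flag on Benjamini-Hochberg adjusted p-values.
#'
#' @param taxa numeric matrix, units x taxa (rownames = unit ids).
#' @param metabolites numeric matrix, units x metabolites, same rownames.
#' @param method "spearman" (default) or "pearson".
#' @param alpha significance level, default 0.05.
#' @param adjust "none" (default) or "BH".
#' @param seed RNG seed for Monte Carlo permutation paths.
#' @return data.frame with columns `taxon`, `metabolite_id`, `method`,
#'   `coefficient`, `p_two_sided`, `significant`, `sign`. Pairs whose
#'   correlation is undefined (constant column) are returned with NA
#'   coefficient and flagged non-significant.
#' @export
correlation_matrix <- function(taxa, metabolites,
                               method = c("spearman", "pearson"),
                               alpha = 0.05, adjust = c("none", "BH"),
                               seed = 1) {
  method <- match.arg(method); adjust <- match.arg(adjust)
  taxa <- as.matrix(taxa); metabolites <- as.matrix(metabolites)
  if (nrow(taxa) != nrow(metabolites) ||
      (!is.null(rownames(taxa)) && !is.null(rownames(metabolites)) &&
       !identical(rownames(taxa), rownames(metabolites))))
    stop("alignment error: taxa and metabolite matrices must share ",
         "identical observation units")
  if (nrow(taxa) < 4) stop("need at least 4 shared observation units")
  n <- nrow(taxa)
  perm_idx <- if (n > 7)
    with_seed(child_seed(seed, "perms"),
              t(vapply(seq_len(10000), function(i) sample.int(n),
                       integer(n))))
  else NULL
  grid <- expand.grid(ti = seq_len(ncol(taxa)),
                      mi = seq_len(ncol(metabolites)))
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    ti <- grid$ti[k]; mi <- grid$mi[k]
    res <- tryCatch(
      correlate_pair(taxa[, ti], metabolites[, mi], method = method,
                     seed = child_seed(seed, paste0("corr", k)),
                     perm_idx = perm_idx),
      error = function(e) NULL)
    data.frame(taxon = colnames(taxa)[ti] %||% paste0("taxon", ti),
               metabolite_id = colnames(metabolites)[mi] %||%
                 paste0("metab", mi),
               method = method,
               coefficient = if (is.null(res)) NA_real_ else res$coefficient,
               p_two_sided = if (is.null(res)) NA_real_ else res$p_two_sided)
  })
  out <- do.call(rbind, rows)
  p_eff <- if (adjust == "BH") stats::p.adjust(out$p_two_sided, "BH")
           else out$p_two_sided
  out$significant <- !is.na(p_eff) & p_eff < alpha
  out$sign <- ifelse(is.na(out$coefficient), NA_character_,
                     ifelse(out$coefficient >= 0, "+", "-"))
  out
}
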