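#' Build a carbon isotopologue correction matrix
#'
#' Constructs the (n+1) x (n+1) matrix `A` whose column `j` is the
#' predicted measured mass-isotopomer distribution of a molecule carrying
#' exactly `j` tracer-labeled carbon positions: the convolution of
#' `Binomial(j, tracer_purity)` (labeled positions that actually are 13C)
#' with `Binomial(n - j, natural_13C)` (unlabeled positions that are 13C by
#' natural abundance). This is the carbon-only correction appropriate for
#' high-resolution acquisition, where isobaric contributions of other
#' elements' isotopes are mass-resolved from the 13C cluster.
#'
#' @param n_carbons number of carbons in the metabolite skeleton (>= 1).
#' @param natural_13C natural 13C abundance, in (0, 0.5). Default 0.0107,
#'   the IUPAC representative isotopic composition of carbon.
#' @param tracer_purity atom fraction 13C of the tracer substrate, in
#'   (0, 1]. Default 0.98, a typical commercial "> 98 atom % 13C" label.
#' @return A list of class `correction_model` with elements `n_carbons`,
#'   `natural_13C`, `tracer_purity` and `matrix`. Every column of `matrix`
#'   sums to 1.
#' @examples
#' m <- build_correction_matrix(3)
#' colSums(m$matrix)
#' @export
build_correction_matrix <- function(n_carbons, natural_13C = 0.0107,
                                    tracer_purity = 0.98) {
  if (length(n_carbons) != 1 || n_carbons < 1 || n_carbons != round(n_carbons))
    stop("n_carbons must be a single integer >= 1")
  if (!is.numeric(natural_13C) || natural_13C <= 0 || natural_13C >= 0.5)
    stop("natural_13C must lie in (0, 0.5)")
  if (!is.numeric(tracer_purity) || tracer_purity <= 0 || tracer_purity > 1)
    stop("tracer_purity must lie in (0, 1]")
  n <- as.integer(n_carbons)
  A <- matrix(0, n + 1, n + 1)
  for (j in 0:n) {
    lab <- dbinom(0:j, j, tracer_purity)
    nat <- dbinom(0:(n - j), n - j, natural_13C)
    A[, j + 1] <- convolve_pmf(lab, nat, n + 1)
  }
  structure(list(n_carbons = n, natural_13C = natural_13C,
                 tracer_purity = tracer_purity, matrix = A),
            class = "correction_model")
}

# Discrete convolution of two pmfs, padded/truncated to length len.
convolve_pmf <- function(p, q, len) {
  out <- numeric(len)
  for (i in seq_along(p)) {
    idx <- i + seq_along(q) - 1L
    out[idx] <- out[idx] + p[i] * q
  }
  out
}

#' Measured isotopologue vector
#'
#' Bundles one metabolite's measured isotopic cluster: raw intensities or
#' mass fractions `M0..Mn` for a carbon skeleton of `n_carbons` atoms.
#'
#' @param metabolite_id metabolite label.
#' @param n_carbons carbon count `n`; `intensities` must have length `n + 1`.
#' @param intensities non-negative numeric vector M0..Mn, not all zero.
#' @return An object of class `isotopologue_vector`.
#' @export
isotopologue_vector <- function(metabolite_id, n_carbons, intensities) {
  n <- as.integer(n_carbons)
  if (n < 1) stop("n_carbons must be >= 1")
  if (length(intensities) != n + 1)
    stop("intensities must have length n_carbons + 1 (M0..Mn)")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (all(intensities == 0)) stop("all-zero intensity vector")
  structure(list(metabolite_id = as.character(metabolite_id),
                 n_carbons = n, intensities = as.numeric(intensities)),
            class = "isotopologue_vector")
}

# Lawson-Hanson active-set non-negative least squares: min ||Ax - b||_2,
# x >= 0. Matrices here are tiny ((n+1)^2, n <= ~20), so a plain R
# implementation is adequate and keeps the solver dependency-free.
nnls_solve <- function(A, b, tol = 1e-12) {
  n <- ncol(A)
  passive <- logical(n)
  x <- numeric(n)
  w <- as.numeric(crossprod(A, b - A %*% x))
  it <- 0L
  while (any(!passive) && max(w[!passive]) > tol && it < 50L * n) {
    it <- it + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      s[passive][is.na(s[passive])] <- 0
      if (all(s[passive] > tol)) { x <- s; break }
      drop_set <- passive & s <= tol
      alpha <- min(x[drop_set] / (x[drop_set] - s[drop_set]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  x
}

#' Correct a measured isotopologue cluster
#'
#' Solves the non-negative least-squares problem `min ||A x - m||` for the
#' labeling distribution `x` (the carbon isotopologue distribution, CID),
#' where `m` is the measured intensity vector normalized to sum 1 and `A`
#' the correction matrix. The solution is renormalized to the simplex and
#' the mean 13C enrichment `sum(j * x_j) / n` is attached. NNLS rather than
#' plain inversion because measured clusters carry noise and unconstrained
#' inversion can return negative isotopologue fractions.
#'
#' @param measured an [isotopologue_vector()].
#' @param model a [build_correction_matrix()] result with matching
#'   `n_carbons`.
#' @return A list of class `corrected_cid` with `metabolite_id`,
#'   `fractions` (x0..xn on the simplex), `mean_enrichment` and `residual`
#'   (L2 norm of the NNLS fit residual, a quality diagnostic).
#' @examples
#' mod <- build_correction_matrix(3, tracer_purity = 1)
#' m <- isotopologue_vector("PEP", 3, as.numeric(mod$matrix[, 1]))
#' correct_cid(m, mod)$mean_enrichment
#' @export
correct_cid <- function(measured, model) {
  stopifnot(inherits(measured, "isotopologue_vector"),
            inherits(model, "correction_model"))
  if (measured$n_carbons != model$n_carbons)
    stop("dimension mismatch: measured n_carbons ", measured$n_carbons,
         " vs model ", model$n_carbons)
  m <- measured$intensities
  if (all(m == 0)) stop("all-zero intensity vector")
  m <- m / sum(m)
  x <- nnls_solve(model$matrix, m)
  if (sum(x) <= 0) stop("degenerate NNLS solution (all-zero fractions)")
  res <- sqrt(sum((model$matrix %*% x - m)^2))
  x <- x / sum(x)
  structure(list(metabolite_id = measured$metabolite_id,
                 fractions = x,
                 mean_enrichment = mean_enrichment(x, model$n_carbons),
                 residual = res),
            class = "corrected_cid")
}

#' Mean 13C enrichment of a labeling distribution
#'
#' `sum_j j * x_j / n`: the average fraction of carbon positions that are
#' labeled, in \[0, 1\].
#'
#' @param fractions simplex vector x0..xn (length `n_carbons + 1`).
#' @param n_carbons carbon count n.
#' @return scalar in \[0, 1\].
#' @examples
#' mean_enrichment(c(0.5, 0, 0, 0.5), 3)
#' @export
mean_enrichment <- function(fractions, n_carbons) {
  n <- as.integer(n_carbons)
  if (length(fractions) != n + 1)
    stop("fractions must have length n_carbons + 1")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  s <- sum(fractions)
  if (abs(s - 1) > 1e-6) stop("fractions must sum to 1")
  sum((0:n) * fractions) / n
}

#' Ratio of two isotopologue fractions
#'
#' `Mi / Mj` of a corrected CID, e.g. the M3/M6 ratio of a hexose
#' phosphate that separates direct incorporation of a fully labeled
#' substrate (M6) from triose-level scrambling (M3).
#'
#' @param cid a [correct_cid()] result.
#' @param i,j isotopologue indices in `0..n`.
#' @return non-negative scalar `fractions[i] / fractions[j]`.
#' @export
isotopologue_ratio <- function(cid, i, j) {
  stopifnot(inherits(cid, "corrected_cid"))
  n <- length(cid$fractions) - 1L
  if (i < 0 || j < 0 || i > n || j > n) stop("indices must lie in 0..n")
  denom <- cid$fractions[j + 1]
  if (denom == 0)
    stop("undefined ratio: M", j, " fraction is zero")
  cid$fractions[i + 1] / denom
}

#' Summarize mean enrichment across replicates
#'
#' Groups corrected CIDs by experimental cell (any combination of grouping
#' columns, typically sex, time and compartment) and metabolite, and reports
#' the mean, sample SD and replicate count of `mean_enrichment`. Groups
#' where a metabolite was measured in only some replicates are kept, with
#' `n` reflecting the available replicates (SD is 0 when n = 1).
#'
#' @param cids data.frame with a `mean_enrichment` column, a
#'   `metabolite_id` column and the grouping columns named in `by`.
#' @param by character vector of grouping column names
#'   (default `c("sex", "time_h", "compartment")`; columns absent from
#'   `cids` are ignored).
#' @return data.frame with one row per (group, metabolite):
#'   grouping columns, `metabolite_id`, `mean`, `sd`, `n`.
#' @examples
#' d <- data.frame(sex = "F", time_h = 4, metabolite_id = "F6P",
#'                 mean_enrichment = c(0.1, 0.2, 0.3))
#' summarize_enrichment(d)
#' @export
summarize_enrichment <- function(cids, by = c("sex", "time_h", "compartment")) {
  cids <- as.data.frame(cids)
  if (nrow(cids) == 0)
    return(data.frame(metabolite_id = character(), mean = numeric(),
                      sd = numeric(), n = integer()))
  by <- intersect(by, names(cids))
  key_cols <- c(by, "metabolite_id")
  key <- interaction(cids[key_cols], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(cids, key), function(g) {
    e <- g$mean_enrichment
    row <- g[1, key_cols, drop = FALSE]
    row$mean <- mean(e)
    row$sd <- if (length(e) > 1) sd(e) else 0
    row$n <- length(e)
    row
  }))
  rownames(out) <- NULL
  out
}

#' Carbon counts for the profiled metabolite panel
#'
#' Editable lookup of carbon skeleton sizes for the central-metabolism
#' panel quantified in the profiled extracts (glycolysis, TCA, pentose
#' phosphate intermediates and the two labeled nucleotides).
#'
#' @return data.frame with columns `metabolite_id`, `n_carbons`.
#' @export
metabolite_carbons <- function() {
  data.frame(
    metabolite_id = c("F6P", "FBP", "Gly3P", "PEP", "Lact", "Cit", "a-KG",
                      "G6P", "6-PG", "Sed7P", "UMP", "GMP", "Man6P", "Succ",
                      "Mala", "2-OHGlu", "2-3PG", "P-Ser"),
    n_carbons = c(6L, 6L, 3L, 3L, 3L, 6L, 5L,
                  6L, 6L, 7L, 9L, 10L, 6L, 4L,
                  4L, 5L, 3L, 3L))
}
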