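test_that("correction matrix matches direct binomial evaluation", {
  # n = 1, pure tracer: only natural abundance acts
  m <- build_correction_matrix(1, natural_13C = 0.0107, tracer_purity = 1)
  expect_equal(m$matrix, matrix(c(0.9893, 0.0107, 0, 1), 2, 2),
               tolerance = 1e-12)
  # fully labeled column is the pure tracer-impurity binomial
  m3 <- build_correction_matrix(3, tracer_purity = 0.98)
  expect_equal(m3$matrix[, 4], dbinom(0:3, 3, 0.98), tolerance = 1e-12)
  expect_equal(m3$matrix[, 4],
               c(0.000008, 0.001176, 0.057624, 0.941192), tolerance = 1e-9)
  # no isotope effects at all: identity
  m2 <- build_correction_matrix(2, natural_13C = 1e-15, tracer_purity = 1)
  expect_equal(m2$matrix, diag(3), tolerance = 1e-12)
})

test_that("correction matrix columns are probability distributions", {
  for (n in c(1, 3, 7, 12, 20)) {
    A <- build_correction_matrix(n)$matrix
    expect_true(all(A >= 0))
    expect_lt(max(abs(colSums(A) - 1)), 1e-12)
  }
})

test_that("correction model parameter domains are enforced", {
  expect_error(build_correction_matrix(0), "n_carbons")
  expect_error(build_correction_matrix(3, natural_13C = 0.6), "natural_13C")
  expect_error(build_correction_matrix(3, tracer_purity = 0), "tracer_purity")
})

test_that("correct_cid inverts the forward model", {
  mod <- build_correction_matrix(3, tracer_purity = 0.98)
  # unlabeled natural envelope -> all mass on M0 (spec-rounded input)
  meas <- isotopologue_vector("x", 3, c(0.96823, 0.03142, 0.00034, 0.0000012))
  cc <- correct_cid(meas, mod)
  expect_equal(cc$fractions, c(1, 0, 0, 0), tolerance = 1e-3)
  expect_equal(cc$mean_enrichment, 0, tolerance = 1e-3)
  # fully labeled at purity 0.98
  full <- isotopologue_vector("x", 3, dbinom(0:3, 3, 0.98))
  cc <- correct_cid(full, mod)
  expect_equal(cc$fractions, c(0, 0, 0, 1), tolerance = 1e-9)
  expect_equal(cc$mean_enrichment, 1, tolerance = 1e-9)
  # errors
  expect_error(isotopologue_vector("x", 3, c(0, 0, 0, 0)), "all-zero")
  expect_error(correct_cid(isotopologue_vector("x", 2, c(1, 0, 0)), mod),
               "mismatch")
})

test_that("round trip recovers random labeling distributions", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(1:10, 1)
    x <- runif_simplex(n + 1)
    mod <- build_correction_matrix(n, tracer_purity = 0.98)
    m <- as.numeric(mod$matrix %*% x)
    cc <- correct_cid(isotopologue_vector("x", n, m), mod)
    expect_lt(max(abs(cc$fractions - x)), 1e-9)
    expect_lt(abs(cc$mean_enrichment - mean_enrichment(x, n)), 1e-9)
  }
})

test_that("NNLS solution matches a simplex grid-search oracle", {
  # constrained LS optimum equals exhaustive search over the simplex;
  # step 1e-3 at n = 2 (full enumeration), coarser at n = 4 where the
  # 1e-3 grid is combinatorially out of reach
  set.seed(7)
  grid_best <- function(A, m, step) {
    best <- NULL; bestv <- Inf
    k <- ncol(A)
    pts <- seq(0, 1, by = step)
    if (k == 3) {
      for (x0 in pts) for (x1 in pts[pts <= 1 - x0 + 1e-12]) {
        x <- c(x0, x1, 1 - x0 - x1)
        v <- sum((A %*% x - m)^2)
        if (v < bestv) { bestv <- v; best <- x }
      }
    } else {
      reps <- as.matrix(expand.grid(rep(list(pts), k - 1)))
      reps <- reps[rowSums(reps) <= 1 + 1e-12, , drop = FALSE]
      X <- cbind(reps, 1 - rowSums(reps))
      v <- colSums((A %*% t(X) - as.numeric(m))^2)
      best <- X[which.min(v), ]
    }
    best
  }
  for (case in 1:3) {
    n <- 2
    mod <- build_correction_matrix(n, tracer_purity = 0.98)
    x <- runif_simplex(n + 1)
    m <- as.numeric(mod$matrix %*% x) + runif(n + 1, 0, 0.01)
    m <- m / sum(m)
    cc <- correct_cid(isotopologue_vector("x", n, m), mod)
    g <- grid_best(mod$matrix, m, 1e-3)
    expect_lt(max(abs(cc$fractions - g / sum(g))), 2e-3)
  }
  n <- 4
  mod <- build_correction_matrix(n, tracer_purity = 0.98)
  x <- runif_simplex(n + 1)
  m <- as.numeric(mod$matrix %*% x) + runif(n + 1, 0, 0.01)
  m <- m / sum(m)
  cc <- correct_cid(isotopologue_vector("x", n, m), mod)
  g <- grid_best(mod$matrix, m, 0.05)
  expect_lt(max(abs(cc$fractions - g / sum(g))), 0.1)
})

test_that("mean enrichment follows the weighted-index formula", {
  expect_identical(mean_enrichment(c(1, 0, 0, 0), 3), 0)
  expect_identical(mean_enrichment(c(0, 0, 0, 1), 3), 1)
  expect_identical(mean_enrichment(c(0.5, 0, 0, 0.5), 3), 0.5)
  expect_error(mean_enrichment(c(-0.1, 1.1, 0, 0), 3), "non-negative")
  # binomial labeling distributions have enrichment exactly p,
  # strictly increasing in p
  ps <- seq(0.05, 0.95, by = 0.1)
  vals <- vapply(ps, function(p) mean_enrichment(dbinom(0:6, 6, p), 6),
                 numeric(1))
  expect_equal(vals, ps, tolerance = 1e-12)
  expect_true(all(diff(vals) > 0))
})

test_that("isotopologue ratios divide corrected fractions", {
  cid <- structure(list(metabolite_id = "F6P",
                        fractions = c(0.1, 0, 0, 0.2, 0.1, 0.2, 0.4),
                        mean_enrichment = NA), class = "corrected_cid")
  expect_equal(isotopologue_ratio(cid, 3, 6), 0.5)
  expect_equal(isotopologue_ratio(cid, 4, 4), 1)
  expect_equal(isotopologue_ratio(cid, 1, 6), 0)
  expect_error(isotopologue_ratio(cid, 0, 1), "undefined ratio")
})

test_that("enrichment summaries aggregate replicates by group", {
  d <- data.frame(sex = rep(c("F", "M"), c(3, 1)),
                  time_h = 4,
                  metabolite_id = "F6P",
                  mean_enrichment = c(0.1, 0.2, 0.3, 0.4))
  s <- summarize_enrichment(d)
  f <- s[s$sex == "F", ]
  expect_equal(f$mean, 0.2)
  expect_equal(f$sd, 0.1)
  expect_equal(f$n, 3L)
  m <- s[s$sex == "M", ]
  expect_equal(m$mean, 0.4)
  expect_equal(m$sd, 0)
  expect_equal(m$n, 1L)
  # identical replicates: zero SD; missing-metabolite groups retained
  d2 <- data.frame(sex = "F", time_h = c(4, 4, 4, 10),
                   metabolite_id = c("Cit", "Cit", "Cit", "Cit"),
                   mean_enrichment = c(0.25, 0.25, 0.25, 0.5))
  s2 <- summarize_enrichment(d2)
  expect_equal(s2$sd[s2$time_h == 4], 0)
  expect_equal(s2$n, c(3L, 1L))
  expect_equal(nrow(summarize_enrichment(d[0, ])), 0)
})
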