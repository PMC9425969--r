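# Fixture builders shared across test files.

# Composite count table with one (sex, time) cell: four composite samples
# (12C/13C x heavy/light) per replicate, counts supplied per OTU as a
# named list of c(h13, l13, h12, l12) vectors (same across replicates).
make_composite_table <- function(per_otu, n_replicates = 3,
                                 sex = "F", time_h = 4) {
  otus <- names(per_otu)
  cols <- list(); meta <- list()
  for (r in seq_len(n_replicates)) {
    for (spec in list(c("13C", "heavy", 1), c("13C", "light", 2),
                      c("12C", "heavy", 3), c("12C", "light", 4))) {
      cnt <- vapply(per_otu, function(v) as.integer(v[as.integer(spec[3])]),
                    integer(1))
      id <- sprintf("%s_%sh_%s_r%d_%s", sex, time_h, spec[1], r, spec[2])
      cols[[id]] <- cnt
      meta[[id]] <- data.frame(sample_id = id, sex = sex, time_h = time_h,
                               treatment = spec[1], fraction_class = spec[2],
                               replicate = r, is_control = FALSE)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- otus
  count_table(m, do.call(rbind, meta))
}

# Brute-force two-sided exact rank-sum p by enumerating all assignments.
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a); N <- length(pooled)
  W <- sum(r[seq_len(na)])
  mu <- na * mean(r)
  sets <- combn(N, na)
  sums <- apply(sets, 2, function(ix) sum(r[ix]))
  mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
}

# Random simplex vector of length k.
runif_simplex <- function(k) {
  x <- -log(runif(k))
  x / sum(x)
}
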