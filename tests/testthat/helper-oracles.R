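# Independent oracles, kept deliberately separate from the package's own
# computation paths.

# Plug-in entropy via the alternative closed form
# H = log2(n) - (1/n) * sum c_i log2 c_i  (exact in count space).
oracle_plugin_entropy <- function(counts) {
  n <- sum(counts)
  cc <- counts[counts > 0]
  log2(n) - sum(cc * log2(cc)) / n
}

# Hausser-Strimmer shrinkage entropy, written from the closed form.
oracle_james_stein <- function(counts) {
  n <- sum(counts)
  k <- length(counts)
  freq <- counts / n
  num <- 1 - sum(freq^2)
  den <- (n - 1) * sum((1 / k - freq)^2)
  lambda <- if (den == 0) 1 else max(0, min(1, num / den))
  p <- lambda / k + (1 - lambda) * freq
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Explicit delete-one jackknife loop.
oracle_jackknife_se <- function(samples, estimator) {
  n <- length(samples)
  loo <- sapply(seq_len(n), function(i) estimator(samples[-i]))
  sqrt((n - 1) / n * sum((loo - mean(loo))^2))
}

entropy_of_calls <- function(calls) binary_entropy(fit_binary_distribution(calls))

# Random valid joint binary distribution with symmetric marginals
# (p01 = p10 forces the two marginals to coincide).
random_symmetric_joint <- function() {
  raw <- stats::runif(3)
  p <- c(raw[1], raw[2], raw[2], raw[3]) / (raw[1] + 2 * raw[2] + raw[3])
  joint_binary_distribution(p[1], p[2], p[3], p[4])
}

# Small labelled binary matrix from a cells-x-genes 0/1 matrix.
make_binary <- function(calls, population = rep("P", nrow(calls))) {
  colnames(calls) <- paste0("g", seq_len(ncol(calls)))
  rownames(calls) <- paste0("c", seq_len(nrow(calls)))
  binary_matrix(calls, population)
}

# Expression fixture written to a temp file for reader tests.
write_fixture_csv <- function(path, sep = ",") {
  lines <- c(paste("cell_id", "population", "gA", "gB", sep = sep),
             paste("c1", "HSC", "0", "3.2", sep = sep),
             paste("c2", "HSC", "0.0001", "0", sep = sep),
             paste("c3", "MPP", "1.5", "2.5", sep = sep))
  writeLines(lines, path)
  path
}
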