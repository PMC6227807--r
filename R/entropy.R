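# Binary and pairwise-joint Shannon entropy, in bits throughout.
# Plug-in (ML) probabilities are never regularized: 0 log 0 := 0.

#' Fit a binary (Bernoulli) distribution by maximum likelihood
#'
#' @param calls Non-empty vector of 0/1 calls.
#' @return A `binary_distribution`: list with `p0`, `p1` and sample size `n`.
#' @export
#' @examples
#' fit_binary_distribution(c(1, 0, 0, 0))  # p1 = 0.25
fit_binary_distribution <- function(calls) {
  if (length(calls) == 0)
    stop("cannot fit a distribution to an empty sample", call. = FALSE)
  if (anyNA(calls) || !all(calls %in% c(0, 1)))
    stop("`calls` must be 0/1 with no missing values", call. = FALSE)
  p1 <- sum(calls) / length(calls)
  binary_distribution(1 - p1, p1, n = length(calls))
}

#' Binary distribution constructor
#'
#' @param p0,p1 Probabilities of the "off" and "on" outcome; must sum to 1.
#' @param n Sample count behind the estimate (0 for an exact distribution).
#' @return A `binary_distribution` object.
#' @export
binary_distribution <- function(p0, p1, n = 0L) {
  if (anyNA(c(p0, p1)) || p0 < 0 || p1 < 0 || abs(p0 + p1 - 1) > 1e-12)
    stop("p0 and p1 must be probabilities summing to 1", call. = FALSE)
  structure(list(p0 = p0, p1 = p1, n = as.integer(n)),
            class = "binary_distribution")
}

#' Joint distribution over a gene pair's on/off states
#'
#' States are ordered lexicographically as (gene A bit, gene B bit):
#' 00, 01, 10, 11. Pairs are unordered; by convention A is the
#' lower-indexed gene.
#'
#' @param p00,p01,p10,p11 State probabilities; must sum to 1.
#' @param n Sample count behind the estimate.
#' @return A `joint_binary_distribution` object.
#' @export
joint_binary_distribution <- function(p00, p01, p10, p11, n = 0L) {
  p <- c(p00, p01, p10, p11)
  if (anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-12)
    stop("joint probabilities must be non-negative and sum to 1",
         call. = FALSE)
  structure(list(p00 = p00, p01 = p01, p10 = p10, p11 = p11,
                 n = as.integer(n)),
            class = "joint_binary_distribution")
}

#' Marginal distributions of a joint binary distribution
#'
#' @param j A [joint_binary_distribution()].
#' @return List of two `binary_distribution`s (gene A, gene B).
#' @export
joint_marginals <- function(j) {
  stopifnot(inherits(j, "joint_binary_distribution"))
  list(a = binary_distribution(j$p00 + j$p01, j$p10 + j$p11, j$n),
       b = binary_distribution(j$p00 + j$p10, j$p01 + j$p11, j$n))
}

# -Σ p log2 p with 0 log 0 := 0, for a bare probability vector
plugin_entropy_bits <- function(p) {
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Binary Shannon entropy
#'
#' `H(P) = -p0 log2 p0 - p1 log2 p1` in bits, with `0 log 0 := 0`.
#' Symmetric in p0/p1, zero iff one outcome is certain, maximal (1 bit) at
#' p0 = p1 = 1/2.
#'
#' @param d A [binary_distribution()], or a single probability `p1`.
#' @return Entropy in bits, in \[0, 1\].
#' @export
#' @examples
#' binary_entropy(0.5)   # 1
#' binary_entropy(0.25)  # 0.811...
binary_entropy <- function(d) {
  if (is.numeric(d)) {
    if (length(d) != 1 || is.na(d) || d < 0 || d > 1)
      stop("`d` must be a binary_distribution or a single probability",
           call. = FALSE)
    d <- binary_distribution(1 - d, d)
  }
  stopifnot(inherits(d, "binary_distribution"))
  plugin_entropy_bits(c(d$p0, d$p1))
}

#' Joint Shannon entropy of a gene pair
#'
#' `H(P12) = -Σ p_ij log2 p_ij` over the four on/off states, in bits.
#'
#' @param j A [joint_binary_distribution()].
#' @return Entropy in bits, in \[0, 2\].
#' @export
joint_entropy <- function(j) {
  stopifnot(inherits(j, "joint_binary_distribution"))
  plugin_entropy_bits(c(j$p00, j$p01, j$p10, j$p11))
}

#' Normalize an entropy by its maximum
#'
#' Divides by `log2(n_states)` so that a marginal (2 states) and a pairwise
#' joint (4 states) entropy are comparable on \[0, 1\].
#'
#' @param h Entropy in bits (>= 0).
#' @param n_states Number of states of the underlying distribution (>= 2).
#' @param allow_excess If `TRUE`, values above 1 (as produced by the
#'   Miller-Madow correction) are returned as-is with a warning instead of
#'   an error.
#' @return Normalized entropy.
#' @export
normalize_entropy <- function(h, n_states, allow_excess = FALSE) {
  if (any(h < 0) || n_states < 2)
    stop("need h >= 0 and n_states >= 2", call. = FALSE)
  hmax <- log2(n_states)
  if (any(h > hmax + 1e-9)) {
    if (!allow_excess)
      stop(sprintf("entropy %.6g exceeds log2(%d) = %.6g",
                   max(h), n_states, hmax), call. = FALSE)
    warning("normalized entropy exceeds 1 (bias-corrected estimator)",
            call. = FALSE)
  }
  h / hmax
}

#' Mutual information of a gene pair
#'
#' `I = H(P1) + H(P2) - H(P12)` in bits; non-negative, zero iff the two
#' genes' on/off states are independent. When the two marginals are equal,
#' the gap between normalized marginal and normalized joint entropy equals
#' `I / 2`.
#'
#' @param j A [joint_binary_distribution()].
#' @return Mutual information in bits (>= 0, tiny negatives from rounding
#'   are clipped to 0).
#' @export
mutual_information <- function(j) {
  m <- joint_marginals(j)
  i <- binary_entropy(m$a) + binary_entropy(m$b) - joint_entropy(j)
  max(0, i)
}

#' Variance of a binary random variable
#'
#' `p0 (1 - p0)`; shares its maximizer (p = 1/2) and zero set with the
#' binary entropy, so it tracks the same qualitative behaviour.
#'
#' @param d A [binary_distribution()] or a single probability `p1`.
#' @return Variance (dimensionless).
#' @export
bernoulli_variance <- function(d) {
  if (is.numeric(d)) d <- binary_distribution(1 - d, d)
  stopifnot(inherits(d, "binary_distribution"))
  d$p0 * (1 - d$p0)
}

check_counts <- function(counts, min_n = 1) {
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be non-negative integers", call. = FALSE)
  n <- sum(counts)
  if (n < min_n)
    stop(sprintf("need at least %d observations, got %d", min_n, n),
         call. = FALSE)
  n
}

#' Plug-in (maximum-likelihood) entropy from counts
#'
#' @param counts Non-negative integer counts per state (total >= 1).
#' @return Entropy in bits.
#' @export
entropy_ml <- function(counts) {
  n <- check_counts(counts, 1)
  plugin_entropy_bits(counts / n)
}

#' Miller-Madow bias-corrected entropy
#'
#' Plug-in entropy plus `(m - 1) / (2 n)` nats, where `m` is the number of
#' occupied (non-zero count) states; the correction is converted to bits.
#' The correction can push small-sample estimates above the `log2(#states)`
#' ceiling (e.g. counts (2,2) give 1.18 bits > 1) — a known overcorrection,
#' reported as-is.
#'
#' @param counts Non-negative integer counts per state (total >= 1).
#' @return Entropy in bits; may exceed `log2(length(counts))`.
#' @export
entropy_miller_madow <- function(counts) {
  n <- check_counts(counts, 1)
  m_hat <- sum(counts > 0)
  entropy_ml(counts) + (m_hat - 1) / (2 * n * log(2))
}

#' James-Stein shrinkage entropy (Hausser-Strimmer)
#'
#' Shrinks the ML frequencies toward the uniform target `t_k = 1/p` with the
#' closed-form optimal intensity
#' `lambda = (1 - sum(theta^2)) / ((n - 1) * sum((t - theta)^2))`,
#' clipped to \[0, 1\] (and set to 1 when the ML estimate already equals the
#' target), then returns the plug-in entropy of the shrunk frequencies.
#'
#' @param counts Non-negative integer counts per state (total >= 2).
#' @return Entropy in bits.
#' @export
entropy_james_stein <- function(counts) {
  n <- check_counts(counts, 2)
  theta <- counts / n
  p <- length(counts)
  target <- rep(1 / p, p)
  denom <- (n - 1) * sum((target - theta)^2)
  lambda <- if (denom == 0) 1 else (1 - sum(theta^2)) / denom
  lambda <- min(1, max(0, lambda))
  plugin_entropy_bits(lambda * target + (1 - lambda) * theta)
}

#' Entropy estimator lookup
#'
#' Maps an estimator id to the counts-based entropy function.
#'
#' @param estimator One of `"ml"`, `"miller_madow"`, `"james_stein"`.
#' @return A function taking a counts vector and returning bits.
#' @export
entropy_estimator <- function(estimator = c("ml", "miller_madow",
                                            "james_stein")) {
  estimator <- match.arg(estimator)
  switch(estimator,
         ml = entropy_ml,
         miller_madow = entropy_miller_madow,
         james_stein = entropy_james_stein)
}
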