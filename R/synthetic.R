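# Seeded generator for single-cell expression data in which each population
# is a mixture of discrete gene-regulatory-network (GRN) substates: a
# substate is a static on/off configuration (with per-gene firing
# probabilities near 0 or 1), and mixing several substates in one population
# produces high per-gene entropy together with correlated gene pairs --
# exactly the statistical structure the entropy pipeline is designed to
# detect. Detection-limit dropout censors "on" calls to zero at a fixed
# false-negative rate; there are no false positives.

#' GRN substate specification
#'
#' @param on_probability Per-gene probability that the gene fires "on" in a
#'   cell occupying this substate (values in \[0, 1\], typically near 0 or 1).
#' @param weight Mixture weight of this substate within its population.
#' @param level_meanlog,level_sdlog Log-normal parameters of the positive
#'   expression level drawn for "on" calls. Binarization erases them; they
#'   exist only to exercise the expression-space transforms.
#' @return A `substate_spec` object.
#' @export
substate_spec <- function(on_probability, weight = 1,
                          level_meanlog = 1.5, level_sdlog = 0.5) {
  if (anyNA(on_probability) || any(on_probability < 0 | on_probability > 1))
    stop("on_probability values must lie in [0, 1]", call. = FALSE)
  if (weight < 0) stop("weight must be non-negative", call. = FALSE)
  structure(list(on_probability = on_probability, weight = weight,
                 level_meanlog = level_meanlog, level_sdlog = level_sdlog),
            class = "substate_spec")
}

#' Population (stage) specification
#'
#' @param label Population label.
#' @param n_cells Number of cells to draw (>= 2).
#' @param substates List of [substate_spec()]s; weights are normalized to
#'   sum to 1 and must all cover the same number of genes.
#' @param dropout Probability that a fired "on" call is censored to 0 by the
#'   detection limit (false negatives only), in \[0, 1).
#' @return A `stage_spec` object.
#' @export
stage_spec <- function(label, n_cells, substates, dropout = 0) {
  if (inherits(substates, "substate_spec")) substates <- list(substates)
  if (!length(substates) ||
      !all(vapply(substates, inherits, logical(1), "substate_spec")))
    stop("`substates` must be a list of substate_spec objects", call. = FALSE)
  g <- unique(vapply(substates, function(s) length(s$on_probability),
                     integer(1)))
  if (length(g) != 1)
    stop("all substates must cover the same number of genes", call. = FALSE)
  w <- vapply(substates, `[[`, numeric(1), "weight")
  if (sum(w) <= 0) stop("substate weights must sum to > 0", call. = FALSE)
  for (i in seq_along(substates)) substates[[i]]$weight <- w[i] / sum(w)
  if (n_cells < 2) stop("n_cells must be >= 2", call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("dropout must lie in [0, 1)", call. = FALSE)
  structure(list(label = as.character(label), n_cells = as.integer(n_cells),
                 substates = substates, dropout = dropout, n_genes = g),
            class = "stage_spec")
}

#' Scenario specification: ordered stages along a differentiation course
#'
#' @param stages List of [stage_spec()]s with unique labels.
#' @param ordering Optional ordering for trajectory analysis: label path or
#'   2-column edge table (default: the stage labels as a linear path).
#' @param convention Output value convention: `"none"` (expression space),
#'   `"guo"` (raw Ct below a background of 28) or `"pina"` (delta-Ct below a
#'   detection limit of 30). Both Ct conventions invert the corresponding
#'   expression transforms exactly.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(stages, ordering = NULL,
                          convention = c("none", "guo", "pina")) {
  convention <- match.arg(convention)
  if (!length(stages) ||
      !all(vapply(stages, inherits, logical(1), "stage_spec")))
    stop("`stages` must be a list of stage_spec objects", call. = FALSE)
  labels <- vapply(stages, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("stage labels must be unique", call. = FALSE)
  if (is.null(ordering)) ordering <- labels
  structure(list(stages = stages, ordering = ordering,
                 convention = convention, labels = labels),
            class = "scenario_spec")
}

#' Sample one population of cells from a stage specification
#'
#' Each cell first draws a substate by mixture weight; each gene then fires
#' independently with that substate's on-probability; dropout independently
#' censors each fired call to 0; surviving "on" calls receive a strictly
#' positive log-normal expression level (capped below the background of the
#' Ct conventions so the transforms invert exactly). Fully reproducible
#' from `seed`.
#'
#' @param spec A [stage_spec()].
#' @param seed Integer seed.
#' @return An [expression_matrix()] (expression-space convention).
#' @export
sample_population <- function(spec, seed) {
  stopifnot(inherits(spec, "stage_spec"))
  set.seed(as.integer(seed))
  n <- spec$n_cells
  g <- spec$n_genes
  w <- vapply(spec$substates, `[[`, numeric(1), "weight")
  state <- sample.int(length(w), n, replace = TRUE, prob = w)
  q <- t(vapply(spec$substates, `[[`, numeric(g), "on_probability"))
  fired <- matrix(stats::runif(n * g) < q[state, , drop = FALSE], n, g)
  if (spec$dropout > 0)
    fired <- fired & matrix(stats::runif(n * g) >= spec$dropout, n, g)
  meanlog <- vapply(spec$substates, `[[`, numeric(1), "level_meanlog")[state]
  sdlog <- vapply(spec$substates, `[[`, numeric(1), "level_sdlog")[state]
  levels <- matrix(stats::rlnorm(n * g, meanlog = rep(meanlog, g),
                                 sdlog = rep(sdlog, g)), n, g)
  levels <- pmin(levels, 27.9)  # keep below the Ct background of 28
  values <- ifelse(fired, levels, 0)
  expression_matrix(values,
                    cell_ids = sprintf("%s_c%04d", spec$label, seq_len(n)),
                    gene_ids = sprintf("g%03d", seq_len(g)),
                    population = rep(spec$label, n))
}

#' Generate a full multi-stage scenario dataset
#'
#' Concatenates per-stage samples (stage seeds derived deterministically
#' from `seed`) and, if requested, converts expression values to one of the
#' qPCR Ct conventions.
#'
#' @param scenario A [scenario_spec()].
#' @param seed Integer seed.
#' @return An [expression_matrix()]. Under `convention = "guo"` the values
#'   are raw Ct (28 = undetected); under `"pina"` they are delta-Ct
#'   (30 = undetected); read such tables back with the matching `transform`.
#' @export
generate_scenario <- function(scenario, seed) {
  stopifnot(inherits(scenario, "scenario_spec"))
  seed <- as.integer(seed)
  mats <- lapply(seq_along(scenario$stages), function(i)
    sample_population(scenario$stages[[i]], seed = (seed + 1013L * i) %% .Machine$integer.max))
  values <- do.call(rbind, lapply(mats, `[[`, "values"))
  population <- unlist(lapply(mats, `[[`, "population"))
  if (scenario$convention == "guo") {
    values <- ifelse(values > 0, 28 - values, 28)
  } else if (scenario$convention == "pina") {
    values <- ifelse(values > 0, 30 - values / log(2), 30)
  }
  m <- structure(list(values = values, population = population),
                 class = "expression_matrix")
  attr(m, "convention") <- scenario$convention
  attr(m, "ordering") <- scenario$ordering
  m
}

#' Exact population entropies implied by a stage specification
#'
#' Analytic oracle for the generator: per-gene on-probabilities follow from
#' total probability over substates, `p_g = sum_k w_k q_kg (1 - dropout)`;
#' pairwise joint probabilities use the conditional independence of genes
#' within a substate. Aggregation matches the pipeline exactly (mean over
#' genes; mean over unordered pairs of `H(P12) / 2`).
#'
#' @param spec A [stage_spec()].
#' @return List with `marginal` (mean per-gene entropy, bits),
#'   `joint` (mean normalized pairwise joint entropy), `p_on` (per-gene
#'   on-probability vector).
#' @export
true_population_entropy <- function(spec) {
  stopifnot(inherits(spec, "stage_spec"))
  w <- vapply(spec$substates, `[[`, numeric(1), "weight")
  q <- t(vapply(spec$substates, `[[`, numeric(spec$n_genes),
                "on_probability"))  # substates x genes
  keep <- 1 - spec$dropout
  q_eff <- q * keep
  p_on <- as.numeric(w %*% q_eff)
  marginal <- mean(vapply(p_on, binary_entropy, numeric(1)))
  g <- spec$n_genes
  joint <- NA_real_
  if (g >= 2) {
    idx <- which(upper.tri(diag(g)), arr.ind = TRUE)
    p11 <- as.numeric(w %*% (q_eff[, idx[, 1], drop = FALSE] *
                               q_eff[, idx[, 2], drop = FALSE]))
    pa <- p_on[idx[, 1]]
    pb <- p_on[idx[, 2]]
    h12 <- vapply(seq_len(nrow(idx)), function(i) {
      p <- c(1 - pa[i] - pb[i] + p11[i], pb[i] - p11[i],
             pa[i] - p11[i], p11[i])
      plugin_entropy_bits(p)
    }, numeric(1))
    joint <- mean(h12) / 2
  }
  list(marginal = marginal, joint = joint, p_on = p_on)
}

#' Default three-stage commitment scenario
#'
#' The stated world of the synthetic tests: a low-high-low entropy course.
#' Stage `pre` is one near-deterministic substate (committed-like pattern A),
#' stage `commit` mixes `n_substates` distinct near-deterministic substates
#' at equal weight (the multiple-entry-points configuration: per-gene
#' on-fractions near 1/2, genes strongly correlated through shared substate
#' identity), and stage `post` is one near-deterministic substate
#' (pattern B). With 20 genes, 100 cells per stage, on-probabilities of
#' 0.95/0.05 and 10% dropout, the commitment stage's true marginal entropy
#' (~0.99) towers over the flanking stages (~0.43), so the trajectory peak
#' identifies it.
#'
#' @param n_cells Cells per stage (default 100).
#' @param n_genes Number of genes (default 20).
#' @param n_substates Number of mixed substates at the commitment stage
#'   (default 2; substates use complementary / rotated on/off patterns).
#' @param dropout Detection-limit false-negative rate (default 0.1).
#' @param q_on,q_off "Near-deterministic" firing probabilities
#'   (defaults 0.95 and 0.05).
#' @param convention Output value convention (see [scenario_spec()]).
#' @return A [scenario_spec()] with stages `pre`, `commit`, `post`.
#' @export
commitment_scenario <- function(n_cells = 100, n_genes = 20,
                                n_substates = 2, dropout = 0.1,
                                q_on = 0.95, q_off = 0.05,
                                convention = "none") {
  pattern <- function(on_mask) ifelse(on_mask, q_on, q_off)
  half_on <- seq_len(n_genes) <= n_genes / 2
  pre <- stage_spec("pre", n_cells,
                    substate_spec(pattern(half_on)), dropout)
  # rotate the on-block so each commitment substate is a distinct pattern
  commit_subs <- lapply(seq_len(n_substates) - 1, function(k) {
    shift <- round(k * n_genes / n_substates)
    mask <- half_on[((seq_len(n_genes) - 1 + shift) %% n_genes) + 1]
    substate_spec(pattern(mask), weight = 1 / n_substates)
  })
  commit <- stage_spec("commit", n_cells, commit_subs, dropout)
  post <- stage_spec("post", n_cells,
                     substate_spec(pattern(!half_on)), dropout)
  scenario_spec(list(pre, commit, post), convention = convention)
}

#' Six-stage branching scenario mirroring the classical haematopoietic tree
#'
#' Root -> intermediate -> two branches, each branch with one further
#' derived stage; the two post-branch stages mix substates so entropy peaks
#' immediately after the branching point.
#'
#' @inheritParams commitment_scenario
#' @return A [scenario_spec()] with a 2-column edge-table ordering.
#' @export
branching_scenario <- function(n_cells = 100, n_genes = 20, dropout = 0.1,
                               q_on = 0.95, q_off = 0.05) {
  pattern <- function(on_mask) ifelse(on_mask, q_on, q_off)
  mask <- function(shift) {
    half <- seq_len(n_genes) <= n_genes / 2
    half[((seq_len(n_genes) - 1 + shift) %% n_genes) + 1]
  }
  pure <- function(label, shift)
    stage_spec(label, n_cells, substate_spec(pattern(mask(shift))), dropout)
  mixed <- function(label, shifts)
    stage_spec(label, n_cells,
               lapply(shifts, function(s)
                 substate_spec(pattern(mask(s)), weight = 1 / length(shifts))),
               dropout)
  stages <- list(pure("root", 0), pure("multipotent", 2),
                 mixed("branchA", c(4, 14)), mixed("branchB", c(8, 18)),
                 pure("leafA", 4), pure("leafB", 8))
  edges <- data.frame(
    parent = c("root", "multipotent", "multipotent", "branchA", "branchB"),
    child = c("multipotent", "branchA", "branchB", "leafA", "leafB"),
    stringsAsFactors = FALSE)
  scenario_spec(stages, ordering = edges)
}

#' Write a scenario specification file
#'
#' Flat key/value serialization readable by [read_scenario()]; covers the
#' scenario shapes constructible with [commitment_scenario()]-style
#' parameters (per-stage label, cell count, dropout and substate
#' on-probability vectors).
#'
#' @param scenario A [scenario_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario_spec"))
  lines <- c(sprintf("convention: %s", scenario$convention),
             sprintf("n_stages: %d", length(scenario$stages)))
  if (is.character(scenario$ordering)) {
    lines <- c(lines, sprintf("ordering: %s",
                              paste(scenario$ordering, collapse = ",")))
  } else {
    lines <- c(lines, sprintf("ordering_edges: %s",
                              paste(paste(scenario$ordering$parent,
                                          scenario$ordering$child, sep = ">"),
                                    collapse = ",")))
  }
  for (i in seq_along(scenario$stages)) {
    s <- scenario$stages[[i]]
    lines <- c(lines,
               sprintf("stage%d.label: %s", i, s$label),
               sprintf("stage%d.n_cells: %d", i, s$n_cells),
               sprintf("stage%d.dropout: %.17g", i, s$dropout),
               sprintf("stage%d.n_substates: %d", i, length(s$substates)))
    for (k in seq_along(s$substates)) {
      sub <- s$substates[[k]]
      lines <- c(lines,
                 sprintf("stage%d.substate%d.weight: %.17g", i, k, sub$weight),
                 sprintf("stage%d.substate%d.on_probability: %s", i, k,
                         paste(sprintf("%.17g", sub$on_probability),
                               collapse = ",")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a scenario specification file written by [write_scenario()]
#'
#' @param path File path.
#' @return A [scenario_spec()].
#' @export
read_scenario <- function(path) {
  cfg <- read_config(path)
  n_stages <- as.integer(cfg$n_stages)
  stages <- lapply(seq_len(n_stages), function(i) {
    key <- function(suffix) cfg[[sprintf("stage%d.%s", i, suffix)]]
    n_subs <- as.integer(key("n_substates"))
    subs <- lapply(seq_len(n_subs), function(k) {
      skey <- function(suffix)
        cfg[[sprintf("stage%d.substate%d.%s", i, k, suffix)]]
      substate_spec(as.numeric(strsplit(skey("on_probability"), ",")[[1]]),
                    weight = as.numeric(skey("weight")))
    })
    stage_spec(key("label"), as.integer(key("n_cells")), subs,
               dropout = as.numeric(key("dropout")))
  })
  ordering <- NULL
  if (!is.null(cfg$ordering)) {
    ordering <- strsplit(cfg$ordering, ",")[[1]]
  } else if (!is.null(cfg$ordering_edges)) {
    pairs <- strsplit(strsplit(cfg$ordering_edges, ",")[[1]], ">")
    ordering <- data.frame(parent = vapply(pairs, `[[`, character(1), 1),
                           child = vapply(pairs, `[[`, character(1), 2),
                           stringsAsFactors = FALSE)
  }
  scenario_spec(stages, ordering = ordering,
                convention = cfg$convention %||% "none")
}
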