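# Per-population entropy aggregation, trajectory peak detection and the
# end-to-end analysis driver.

#' Entropy estimate container
#'
#' @param value Entropy (bits; normalized if `normalized`).
#' @param estimator Estimator id (`"ml"`, `"miller_madow"`, `"james_stein"`).
#' @param se Jackknife standard error, or `NA` if not computed.
#' @param normalized Whether `value` is on the \[0, 1\] normalized scale.
#' @param n Number of cells behind the estimate.
#' @return An `entropy_estimate` object.
#' @export
entropy_estimate <- function(value, estimator, se = NA_real_,
                             normalized = TRUE, n = NA_integer_) {
  structure(list(value = value, estimator = estimator, se = se,
                 normalized = normalized, n = as.integer(n)),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("entropy %.4f%s [%s]%s\n", x$value,
              if (is.na(x$se)) "" else sprintf(" +/- %.4f", x$se),
              x$estimator,
              if (x$normalized) " (normalized)" else " (bits)"))
  invisible(x)
}

# Per-gene entropies (bits) of a 0/1 matrix, vectorized over genes.
gene_entropies_bits <- function(calls, estimator = "ml") {
  n <- nrow(calls)
  n1 <- colSums(calls)
  counts <- cbind(n - n1, n1)
  state_counts_entropy(counts, estimator, n)
}

# Joint entropies (bits) of all unordered gene pairs (a < b, column order of
# `calls`), vectorized via the cross-product of the call matrix.
pair_entropies_bits <- function(calls, estimator = "ml") {
  n <- nrow(calls)
  g <- ncol(calls)
  if (g < 2) stop("need at least 2 genes for pairwise entropies",
                  call. = FALSE)
  x <- calls
  storage.mode(x) <- "double"
  n11 <- crossprod(x)
  n1 <- diag(n11)
  idx <- which(upper.tri(n11), arr.ind = TRUE)
  a <- idx[, 1]; b <- idx[, 2]
  c11 <- n11[idx]
  c10 <- n1[a] - c11
  c01 <- n1[b] - c11
  c00 <- n - n1[a] - n1[b] + c11
  counts <- cbind(c00, c01, c10, c11)
  h <- state_counts_entropy(counts, estimator, n)
  attr(h, "pairs") <- cbind(a = a, b = b)
  h
}

# Rowwise entropy (bits) from a matrix of per-state counts, each row one
# distribution over ncol(counts) states with total n.
state_counts_entropy <- function(counts, estimator, n) {
  theta <- counts / n
  lt <- theta
  lt[lt > 0] <- lt[lt > 0] * log2(lt[lt > 0])
  h_ml <- -rowSums(lt)
  switch(estimator,
    ml = h_ml,
    miller_madow = h_ml + (rowSums(counts > 0) - 1) / (2 * n * log(2)),
    james_stein = {
      if (n < 2) stop("James-Stein shrinkage requires n >= 2", call. = FALSE)
      k <- ncol(counts)
      t_k <- 1 / k
      denom <- (n - 1) * rowSums((t_k - theta)^2)
      lambda <- ifelse(denom == 0, 1,
                       pmin(1, pmax(0, (1 - rowSums(theta^2)) / denom)))
      p <- lambda * t_k + (1 - lambda) * theta
      lp <- p
      lp[lp > 0] <- lp[lp > 0] * log2(lp[lp > 0])
      -rowSums(lp)
    },
    stop(sprintf("unknown estimator '%s'", estimator), call. = FALSE))
}

population_calls <- function(b, population) {
  stopifnot(inherits(b, "binary_matrix"))
  keep <- b$population == population
  if (!any(keep))
    stop(sprintf("unknown population '%s'", population), call. = FALSE)
  b$calls[keep, , drop = FALSE]
}

#' Population marginal entropy
#'
#' The unweighted mean over genes of the per-gene binary Shannon entropy of
#' a population's cells, with a delete-one-cell jackknife standard error.
#' Genes with zero variance contribute entropy 0 and are not excluded.
#' Per-gene binary entropies are already on the \[0, 1\] normalized scale.
#'
#' @param b A [binary_matrix()].
#' @param population Population label to analyse.
#' @param estimator Estimator id (see [entropy_estimator()]).
#' @param se Compute the jackknife standard error (requires >= 2 cells)?
#' @return An [entropy_estimate()].
#' @export
population_marginal_entropy <- function(b, population, estimator = "ml",
                                        se = TRUE) {
  calls <- population_calls(b, population)
  est <- function(m) mean(gene_entropies_bits(m, estimator))
  value <- est(calls)
  se_val <- NA_real_
  if (se) {
    if (nrow(calls) < 2)
      stop("jackknife needs at least 2 cells per population", call. = FALSE)
    se_val <- jackknife(calls, est)$se
  }
  entropy_estimate(value, estimator, se_val, normalized = TRUE,
                   n = nrow(calls))
}

#' Population pairwise joint entropy
#'
#' The unweighted mean over all unordered gene pairs of the normalized joint
#' entropy `H(P12) / 2`, with a delete-one-cell jackknife standard error.
#'
#' @inheritParams population_marginal_entropy
#' @return An [entropy_estimate()] on the normalized \[0, 1\] scale.
#' @export
population_joint_entropy <- function(b, population, estimator = "ml",
                                     se = TRUE) {
  calls <- population_calls(b, population)
  if (ncol(calls) < 2)
    stop("pairwise joint entropy needs at least 2 genes", call. = FALSE)
  est <- function(m) mean(pair_entropies_bits(m, estimator)) / 2
  value <- est(calls)
  se_val <- NA_real_
  if (se) {
    if (nrow(calls) < 2)
      stop("jackknife needs at least 2 cells per population", call. = FALSE)
    se_val <- jackknife(calls, est)$se
  }
  entropy_estimate(value, estimator, se_val, normalized = TRUE,
                   n = nrow(calls))
}

#' Per-population entropy profile
#'
#' Marginal and pairwise-joint normalized entropies, with jackknife
#' standard errors, for every population of a binary call matrix.
#'
#' @param b A [binary_matrix()].
#' @param estimator Estimator id.
#' @param populations Populations to include, in output order (default:
#'   order of first appearance).
#' @param se Compute jackknife standard errors?
#' @return A data frame of class `population_entropy_profile` with columns
#'   `population`, `marginal_entropy`, `marginal_se`, `joint_entropy`,
#'   `joint_se`, `n_cells`, `n_genes`.
#' @export
population_entropy_profile <- function(b, estimator = "ml",
                                       populations = unique(b$population),
                                       se = TRUE) {
  stopifnot(inherits(b, "binary_matrix"))
  rows <- lapply(populations, function(pop) {
    m <- population_marginal_entropy(b, pop, estimator, se = se)
    j <- population_joint_entropy(b, pop, estimator, se = se)
    data.frame(population = pop,
               marginal_entropy = m$value, marginal_se = m$se,
               joint_entropy = j$value, joint_se = j$se,
               n_cells = m$n, n_genes = ncol(b$calls),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "estimator") <- estimator
  class(out) <- c("population_entropy_profile", "data.frame")
  out
}

#' Per-gene, per-population entropy table
#'
#' Binary Shannon entropy for each (gene, population) combination, with a
#' delete-one-cell jackknife standard error and the on-fraction `p1` (so a
#' zero entropy with p1 = 1, always on, is distinguishable from p1 = 0,
#' always off).
#'
#' @param b A [binary_matrix()].
#' @param estimator Estimator id.
#' @param se Compute jackknife standard errors?
#' @return A data frame with columns `gene`, `population`, `entropy`, `se`,
#'   `p1`, `n_cells`.
#' @export
gene_entropy_table <- function(b, estimator = "ml", se = TRUE) {
  stopifnot(inherits(b, "binary_matrix"))
  pops <- unique(b$population)
  genes <- colnames(b$calls)
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(b$calls)))
  fn <- entropy_estimator(estimator)
  rows <- lapply(pops, function(pop) {
    calls <- population_calls(b, pop)
    n <- nrow(calls)
    if (se && n < 2)
      stop("jackknife needs at least 2 cells per population", call. = FALSE)
    k <- colSums(calls)
    h <- gene_entropies_bits(calls, estimator)
    se_vec <- rep(NA_real_, length(genes))
    if (se) {
      # Leave-one-out entropies take only two values per gene: delete an
      # "on" cell (k of them) or an "off" cell (n - k of them).
      se_vec <- vapply(seq_along(genes), function(g) {
        loo_on <- if (k[g] > 0) fn(c(n - k[g], k[g] - 1)) else NA_real_
        loo_off <- if (k[g] < n) fn(c(n - k[g] - 1, k[g])) else NA_real_
        loo <- c(rep(loo_on, k[g]), rep(loo_off, n - k[g]))
        theta_bar <- mean(loo)
        sqrt((n - 1) / n * sum((loo - theta_bar)^2))
      }, numeric(1))
    }
    data.frame(gene = genes, population = pop, entropy = h, se = se_vec,
               p1 = k / n, n_cells = n, stringsAsFactors = FALSE,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "estimator") <- estimator
  out
}

#' Pairwise joint-entropy matrix for one population
#'
#' @param b A [binary_matrix()].
#' @param population Population label.
#' @param estimator Estimator id.
#' @param normalized Divide by 2 (the pairwise maximum)?
#' @return A symmetric genes-by-genes matrix of pairwise joint entropies;
#'   the diagonal holds each gene's marginal entropy.
#' @export
pairwise_joint_matrix <- function(b, population, estimator = "ml",
                                  normalized = TRUE) {
  calls <- population_calls(b, population)
  g <- ncol(calls)
  h <- pair_entropies_bits(calls, estimator)
  idx <- attr(h, "pairs")
  out <- matrix(0, g, g, dimnames = list(colnames(calls), colnames(calls)))
  out[idx] <- h
  out[idx[, c(2, 1), drop = FALSE]] <- h
  diag(out) <- gene_entropies_bits(calls, estimator)
  if (normalized) {
    out[row(out) != col(out)] <- out[row(out) != col(out)] / 2
  }
  out
}

# ---- trajectory ------------------------------------------------------------

# Normalize an ordering (label path or parent/child edge table) into a
# validated edge list plus root-to-leaf paths.
resolve_ordering <- function(ordering, labels) {
  if (is.character(ordering) && is.null(dim(ordering))) {
    if (length(ordering) < 2)
      stop("ordering path needs at least 2 populations", call. = FALSE)
    edges <- data.frame(parent = ordering[-length(ordering)],
                        child = ordering[-1], stringsAsFactors = FALSE)
  } else if ((is.matrix(ordering) || is.data.frame(ordering)) &&
             ncol(ordering) == 2) {
    edges <- data.frame(parent = as.character(ordering[[1]]),
                        child = as.character(ordering[[2]]),
                        stringsAsFactors = FALSE)
  } else {
    stop("ordering must be a label vector (path) or a 2-column edge table",
         call. = FALSE)
  }
  nodes <- unique(c(edges$parent, edges$child))
  missing <- setdiff(nodes, labels)
  if (length(missing))
    stop(sprintf("ordering mentions unknown population(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(edges$child))
    stop("ordering is not a tree: a population has two parents",
         call. = FALSE)
  roots <- setdiff(nodes, edges$child)
  if (length(roots) == 0)
    stop("ordering is cyclic: no root population", call. = FALSE)
  children <- split(edges$child, edges$parent)
  paths <- list()
  walk <- function(node, path) {
    if (node %in% path)
      stop("ordering is cyclic", call. = FALSE)
    path <- c(path, node)
    kids <- children[[node]]
    if (is.null(kids)) {
      paths[[length(paths) + 1]] <<- path
    } else {
      for (k in kids) walk(k, path)
    }
  }
  for (r in roots) walk(r, character(0))
  list(edges = edges, paths = paths, roots = roots, nodes = nodes)
}

#' Entropy trajectory along a differentiation ordering
#'
#' Computes per-edge entropy changes along a user-supplied linear path or
#' branching tree of populations, flags changes larger than `z` combined
#' jackknife standard errors, and reports the entropy peak(s): populations
#' whose entropy exceeds their predecessor and every successor along their
#' root-to-leaf path (falling back to the path argmax when ties leave no
#' strict peak). The differentiation ordering is an input, not inferred.
#'
#' @param profile A [population_entropy_profile()].
#' @param ordering Character vector of population labels (linear path) or a
#'   2-column parent/child edge table (tree).
#' @param metric Which profile entropy to trace: `"marginal"` or `"joint"`.
#' @param z Significance multiplier on the combined jackknife SE
#'   (default 2).
#' @return An `entropy_trajectory`: list with `edges` (parent, child,
#'   delta, se_delta, significant), `peaks` (label vector), `paths`,
#'   `metric` and `z`.
#' @export
entropy_trajectory <- function(profile, ordering,
                               metric = c("marginal", "joint"), z = 2) {
  stopifnot(inherits(profile, "population_entropy_profile"))
  metric <- match.arg(metric)
  ord <- resolve_ordering(ordering, profile$population)
  val_col <- paste0(metric, "_entropy")
  se_col <- paste0(metric, "_se")
  value <- stats::setNames(profile[[val_col]], profile$population)
  se <- stats::setNames(profile[[se_col]], profile$population)
  edges <- ord$edges
  edges$delta <- value[edges$child] - value[edges$parent]
  edges$se_delta <- sqrt(se[edges$child]^2 + se[edges$parent]^2)
  edges$significant <- !is.na(edges$se_delta) &
    abs(edges$delta) > z * edges$se_delta
  rownames(edges) <- NULL
  peaks <- character(0)
  for (path in ord$paths) {
    v <- value[path]
    cand <- which(vapply(seq_along(path), function(i) {
      up <- i == 1 || v[i] > v[i - 1]
      down <- i == length(path) || all(v[i] > v[(i + 1):length(path)])
      up && down
    }, logical(1)))
    if (length(cand) == 0) cand <- which.max(v)
    peaks <- c(peaks, path[cand])
  }
  structure(list(edges = edges, peaks = unique(peaks), paths = ord$paths,
                 metric = metric, z = z),
            class = "entropy_trajectory")
}

#' @export
print.entropy_trajectory <- function(x, ...) {
  cat(sprintf("entropy trajectory (%s, z = %g): peak at %s\n",
              x$metric, x$z, paste(x$peaks, collapse = ", ")))
  print(x$edges)
  invisible(x)
}

# ---- run driver ------------------------------------------------------------

#' Read a population ordering file
#'
#' One column = linear path, two columns = parent/child edge table. Comma,
#' tab or whitespace separated; lines starting with `#` ignored; no header.
#'
#' @param path File path.
#' @return A character vector (path) or a 2-column data frame (edges).
#' @export
read_ordering <- function(path) {
  if (!file.exists(path))
    stop(sprintf("ordering file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[,\t ]+")
  width <- unique(lengths(parts))
  if (length(width) != 1 || !width %in% c(1, 2))
    stop("ordering file must have one column (path) or two (edges)",
         call. = FALSE)
  if (width == 1) {
    vapply(parts, `[[`, character(1), 1)
  } else {
    data.frame(parent = vapply(parts, `[[`, character(1), 1),
               child = vapply(parts, `[[`, character(1), 2),
               stringsAsFactors = FALSE)
  }
}

#' Read a key/value configuration file
#'
#' Minimal flat `key: value` (or `key = value`) syntax, `#` comments.
#'
#' @param path File path.
#' @return Named list of character values.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3)
      stop(sprintf("cannot parse config line: '%s'", ln), call. = FALSE)
    out[[m[2]]] <- trimws(m[3])
  }
  out
}

write_report_table <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full entropy-landscape analysis
#'
#' Reads an expression table, applies the configured Ct transform,
#' binarizes, computes the per-population entropy profile, the per-gene
#' entropy table, one pairwise joint-entropy matrix per population and the
#' trajectory summary, and writes them as tab-separated report files with a
#' commented header recording version, seed and parameters. Deterministic
#' given the configuration.
#'
#' @param config Named list with entries `input` (file path), `dialect`
#'   (`csv`/`tsv`), `transform` (`none`/`guo`/`pina`), `label_col`,
#'   `estimator`, `ordering` (file path, label vector or edge table),
#'   `outdir`, and optionally `id_col`, `seed` (integer), `z` (numeric),
#'   `metric` (`marginal`/`joint`).
#' @return Invisibly, a list with the computed `profile`, `gene_table`,
#'   `trajectory` and the report file `paths`.
#' @export
run_analysis <- function(config) {
  required <- c("input", "outdir", "ordering")
  miss <- setdiff(required, names(config))
  if (length(miss))
    stop(sprintf("config is missing: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  dialect <- config$dialect %||% "csv"
  transform <- config$transform %||% "none"
  estimator <- config$estimator %||% "ml"
  label_col <- config$label_col %||% "population"
  z <- as.numeric(config$z %||% 2)
  metric <- config$metric %||% "marginal"
  seed <- as.integer(config$seed %||% 1L)
  set.seed(seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  m <- stage("read", read_expression_table(
    config$input, dialect = dialect, label_column = label_col,
    id_column = config$id_col, transform = transform))
  b <- stage("binarize", binarize(m))
  ordering <- config$ordering
  if (is.character(ordering) && length(ordering) == 1 &&
      file.exists(ordering))
    ordering <- stage("ordering", read_ordering(ordering))
  profile <- stage("profile", population_entropy_profile(b, estimator))
  if (estimator == "miller_madow" &&
      any(profile$marginal_entropy > 1 | profile$joint_entropy > 1))
    message("note: Miller-Madow bias correction pushed some normalized ",
            "entropies above 1; values reported as-is")
  gene_tab <- stage("gene_table", gene_entropy_table(b, estimator))
  traj <- stage("trajectory",
                entropy_trajectory(profile, ordering, metric = metric, z = z))

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf(
    "entroscape %s | seed=%d dialect=%s transform=%s estimator=%s z=%g metric=%s input=%s",
    as.character(utils::packageVersion("entroscape")), seed, dialect,
    transform, estimator, z, metric, config$input)
  paths <- list(
    profile = file.path(config$outdir, "population_profile.tsv"),
    gene_table = file.path(config$outdir, "gene_entropy.tsv"),
    trajectory = file.path(config$outdir, "trajectory.tsv"),
    params = file.path(config$outdir, "params.txt"))
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
    df
  }
  write_report_table(fmt(as.data.frame(profile)), paths$profile, hdr)
  write_report_table(fmt(gene_tab), paths$gene_table, hdr)
  traj_df <- traj$edges
  traj_df$peak <- traj_df$child %in% traj$peaks
  write_report_table(fmt(traj_df), paths$trajectory,
                     paste0(hdr, " | peaks=",
                            paste(traj$peaks, collapse = ",")))
  for (pop in profile$population) {
    p <- file.path(config$outdir,
                   sprintf("joint_matrix_%s.tsv", gsub("[^A-Za-z0-9_.-]", "_", pop)))
    jm <- pairwise_joint_matrix(b, pop, estimator)
    write_report_table(
      cbind(data.frame(gene = rownames(jm), stringsAsFactors = FALSE),
            fmt(as.data.frame(jm))), p, hdr)
    paths[[paste0("joint_matrix_", pop)]] <- p
  }
  writeLines(c(hdr, paste0(names(config), " = ",
                           vapply(config, function(x)
                             paste(format(x), collapse = " "),
                             character(1)))),
             paths$params)
  invisible(list(profile = profile, gene_table = gene_tab, trajectory = traj,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
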