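# Expression-program and spot-level analysis: NMF (Lee-Seung multiplicative
# updates, squared-Frobenius objective), consensus NMF with local-density
# filtering, gene-set scores against expression-matched controls, regulon
# (TF) activity scores, and deconvolved-abundance spot summaries.

#' Gene-set score with expression-matched control genes
#'
#' Per observation, the mean log-expression of the set genes minus the mean
#' log-expression of control genes drawn from the same average-expression
#' bins. Genes are ranked by their average expression across observations
#' and cut into `n_bins` equal-size bins; each set gene contributes
#' `n_ctrl` control genes sampled without replacement (where possible) from
#' its bin, excluding the set genes themselves. A positive score means the
#' set is expressed above expression-matched background in that
#' observation.
#'
#' @param log_expr observations x genes numeric matrix (log scale), with
#'   column names.
#' @param genes character vector of set genes; genes absent from the matrix
#'   are dropped with a warning, an empty intersection errors.
#' @param n_bins number of average-expression bins (default 24; the matrix
#'   must have at least this many genes).
#' @param n_ctrl control genes sampled per set gene (default 100).
#' @param seed integer seed for the control draw.
#' @param control_genes optional explicit control genes, bypassing the
#'   binned sampling (then `n_bins`, `n_ctrl` and `seed` are ignored).
#' @return numeric score per observation.
#' @export
score_gene_set <- function(log_expr, genes, n_bins = 24L, n_ctrl = 100L,
                           seed = NULL, control_genes = NULL) {
  log_expr <- as.matrix(log_expr)
  if (is.null(colnames(log_expr))) stop("'log_expr' needs column names",
                                        call. = FALSE)
  present <- intersect(genes, colnames(log_expr))
  if (!length(present)) stop("no set gene present in the matrix", call. = FALSE)
  if (length(present) < length(genes)) {
    warning(sprintf("%d set gene(s) absent from the matrix; dropped",
                    length(genes) - length(present)))
  }
  set_score <- rowMeans(log_expr[, present, drop = FALSE])
  if (!is.null(control_genes)) {
    ctrl <- intersect(control_genes, colnames(log_expr))
    if (!length(ctrl)) stop("no control gene present", call. = FALSE)
    return(set_score - rowMeans(log_expr[, ctrl, drop = FALSE]))
  }
  G <- ncol(log_expr)
  if (G < n_bins) stop("fewer genes than bins", call. = FALSE)
  avg <- colMeans(log_expr)
  bin <- ceiling(rank(avg, ties.method = "first") / (G / n_bins))
  names(bin) <- colnames(log_expr)
  ctrl_pool <- .with_seed(seed, {
    unlist(lapply(present, function(g) {
      mates <- names(bin)[bin == bin[g]]
      pool <- setdiff(mates, present)
      if (!length(pool)) pool <- setdiff(mates, g)
      if (length(pool) >= n_ctrl) sample(pool, n_ctrl)
      else sample(pool, n_ctrl, replace = TRUE)
    }))
  })
  set_score - rowMeans(log_expr[, ctrl_pool, drop = FALSE])
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (tab-separated: name, description, genes...).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1L)
  if (any(!lengths(sets))) stop("empty gene set in GMT", call. = FALSE)
  sets
}

#' Transcription-factor activity from regulon target expression
#'
#' Each gene's expression is standardized across cells (z-score); the
#' activity of a TF in a cell is the mean over its regulon targets of
#' `mode-of-regulation * z`. Regulons below the confidence cutoff are
#' excluded (the conventional high-confidence filter keeps classes A--C),
#' as are regulons with no usable target in the matrix (with a warning).
#'
#' @param expr cells x genes numeric matrix with column names.
#' @param regulons data.frame with columns `tf`, `confidence` (A--E),
#'   `target`, `mor` (+1/-1).
#' @param min_confidence weakest confidence class kept (default `"C"`, i.e.
#'   A, B and C are used).
#' @return TF x cell activity matrix.
#' @export
tf_activity <- function(expr, regulons, min_confidence = c("C", "A", "B")) {
  min_confidence <- match.arg(min_confidence)
  expr <- as.matrix(expr)
  if (is.null(colnames(expr))) stop("'expr' needs column names", call. = FALSE)
  keep_classes <- LETTERS[seq_len(match(min_confidence, LETTERS))]
  reg <- regulons[regulons$confidence %in% keep_classes, , drop = FALSE]
  if (!nrow(reg)) stop("no regulon passes the confidence filter", call. = FALSE)
  sds <- apply(expr, 2L, stats::sd)
  z <- scale(expr)
  z[, sds == 0] <- 0  # constant genes carry no activity signal
  tfs <- unique(reg$tf)
  rows <- lapply(tfs, function(tf) {
    r <- reg[reg$tf == tf, , drop = FALSE]
    r <- r[r$target %in% colnames(z), , drop = FALSE]
    if (!nrow(r)) {
      warning(sprintf("regulon '%s' has no usable target; excluded", tf))
      return(NULL)
    }
    colMeans(t(z[, r$target, drop = FALSE]) * r$mor)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("all regulons excluded: no usable targets", call. = FALSE)
  out <- do.call(rbind, rows[keep])
  rownames(out) <- tfs[keep]
  colnames(out) <- rownames(expr)
  out
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the squared Frobenius error `||X - W H||_F^2` over nonnegative
#' `W` (usage, rows x k) and `H` (programs, k x columns) with Lee-Seung
#' multiplicative updates (a small epsilon stabilizes denominators). The
#' objective is recorded after every iteration and is non-increasing; the
#' loop stops at `max_iter` or when the relative objective change drops
#' below `tol`.
#'
#' @param X nonnegative numeric matrix.
#' @param k factorization rank, `1 <= k <= min(dim(X))`.
#' @param seed integer seed for the random nonnegative initialization.
#' @param max_iter maximum iterations (default 200).
#' @param tol relative objective-change stopping tolerance (default 1e-5).
#' @return object of class `nmf_result`: `usage` (W), `programs` (H),
#'   `objective` (per-iteration trace), `k`, `seed`, `iterations`.
#' @export
nmf <- function(X, k, seed = 1L, max_iter = 200L, tol = 1e-5) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("'X' must be nonnegative", call. = FALSE)
  if (k < 1 || k > min(dim(X))) {
    stop(sprintf("'k' must be in 1..%d", min(dim(X))), call. = FALSE)
  }
  n <- nrow(X); m <- ncol(X)
  eps <- 1e-12
  .with_seed(seed, {
    sc <- sqrt(mean(X) / k)
    W <- matrix(stats::runif(n * k), n, k) * sc
    H <- matrix(stats::runif(k * m), k, m) * sc
    obj <- numeric(0)
    prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, X) / (crossprod(W) %*% H + eps))
      W <- W * (X %*% t(H) / (W %*% tcrossprod(H) + eps))
      o <- sum((X - W %*% H)^2)
      obj <- c(obj, o)
      if (is.finite(prev) && abs(prev - o) / max(prev, eps) < tol) break
      prev <- o
    }
    structure(list(usage = W, programs = H, objective = obj, k = k,
                   seed = seed, iterations = length(obj)),
              class = "nmf_result")
  })
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf("nmf_result: k = %d, %d iterations, final objective %.4g\n",
              x$k, x$iterations, utils::tail(x$objective, 1)))
  invisible(x)
}

# refit nonnegative usage with programs H fixed (multiplicative updates)
.refit_usage <- function(X, H, max_iter = 200L, tol = 1e-6) {
  eps <- 1e-12
  W <- matrix(mean(X) / max(mean(H), eps) / nrow(H),
              nrow(X), nrow(H))
  prev <- Inf
  for (it in seq_len(max_iter)) {
    W <- W * (X %*% t(H) / (W %*% tcrossprod(H) + eps))
    o <- sum((X - W %*% H)^2)
    if (is.finite(prev) && abs(prev - o) / max(prev, eps) < tol) break
    prev <- o
  }
  W
}

#' Consensus NMF over repeated seeded runs
#'
#' For each candidate rank K, `n_runs` seeded NMF runs are performed and
#' their L2-normalized program vectors pooled. Outlier components whose
#' mean Euclidean distance to their nearest neighbors (30% of the run
#' count) exceeds `density_threshold` are removed; survivors are k-means
#' clustered into K consensus programs (cluster-wise component medians) and
#' the usage matrix is refit by nonnegative least squares with the
#' consensus programs fixed. Per-K stability is the mean silhouette width
#' of the component clustering; error is the relative Frobenius
#' reconstruction error. With `n_runs = 1` the procedure reduces to a plain
#' NMF per K.
#'
#' @param X nonnegative matrix (e.g. spot x gene counts or merged cell
#'   abundance matrices).
#' @param k_range candidate ranks (default 5:13).
#' @param n_runs seeded runs per K (default 200).
#' @param density_threshold local-density filter cutoff on mean
#'   nearest-neighbor distance (default 0.1); `Inf` disables filtering.
#' @param seed master seed; run seeds derive from it.
#' @param chosen_k rank to report factors for; default the K with maximal
#'   stability among Ks that produced a consensus.
#' @param max_iter,tol passed to [nmf()].
#' @param run_seeds optional explicit vector of `n_runs` seeds (overrides
#'   the derivation from `seed`).
#' @return object of class `consensus_nmf`: `usage`, `programs` (for
#'   `chosen_k`), `per_k` (data.frame k/stability/error/kept), `chosen_k`,
#'   `density_threshold`, `runs` (per-K list of component matrices).
#' @export
consensus_nmf <- function(X, k_range = 5:13, n_runs = 200L,
                          density_threshold = 0.1, seed = 1L,
                          chosen_k = NULL, max_iter = 200L, tol = 1e-5,
                          run_seeds = NULL) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("'X' must be nonnegative", call. = FALSE)
  per_k <- data.frame(k = k_range, stability = NA_real_, error = NA_real_,
                      kept = NA_integer_)
  factors <- list()
  for (ki in seq_along(k_range)) {
    K <- k_range[ki]
    seeds <- run_seeds %||%
      ((seed + 7919L * K + seq_len(n_runs)) %% .Machine$integer.max)
    runs <- lapply(seeds, function(s) {
      nmf(X, K, seed = s, max_iter = max_iter, tol = tol)
    })
    comp <- do.call(rbind, lapply(runs, `[[`, "programs"))
    comp_n <- comp / pmax(sqrt(rowSums(comp^2)), 1e-12)
    if (n_runs == 1L) {
      best <- runs[[1]]
      per_k$error[ki] <- sqrt(sum((X - best$usage %*% best$programs)^2) /
                                sum(X^2))
      per_k$stability[ki] <- NA_real_
      per_k$kept[ki] <- K
      factors[[as.character(K)]] <- list(usage = best$usage,
                                         programs = best$programs)
      next
    }
    d <- as.matrix(stats::dist(comp_n))
    diag(d) <- Inf
    n_nb <- max(1L, floor(0.3 * n_runs))
    dens <- apply(d, 1L, function(row) mean(sort(row)[seq_len(n_nb)]))
    keep <- if (is.infinite(density_threshold)) rep(TRUE, nrow(comp_n))
            else dens <= density_threshold
    per_k$kept[ki] <- sum(keep)
    if (sum(keep) < K) next  # too few survivors: K marked unstable
    surv <- comp_n[keep, , drop = FALSE]
    km <- .with_seed(seed + K, stats::kmeans(surv, centers = K,
                                             nstart = 10L, iter.max = 50L))
    sil <- tryCatch(
      mean(cluster::silhouette(km$cluster,
                               stats::dist(surv))[, "sil_width"]),
      error = function(e) NA_real_)
    H <- do.call(rbind, lapply(seq_len(K), function(cl) {
      apply(surv[km$cluster == cl, , drop = FALSE], 2L, stats::median)
    }))
    H <- pmax(H, 0)
    W <- .refit_usage(X, H)
    per_k$stability[ki] <- sil
    per_k$error[ki] <- sqrt(sum((X - W %*% H)^2) / sum(X^2))
    factors[[as.character(K)]] <- list(usage = W, programs = H)
  }
  if (is.null(chosen_k)) {
    ok <- per_k$k[!is.na(per_k$error)]
    if (!length(ok)) stop("no K produced a consensus", call. = FALSE)
    st <- per_k$stability[match(ok, per_k$k)]
    chosen_k <- if (all(is.na(st))) ok[1] else ok[which.max(st)]
  }
  ch <- factors[[as.character(chosen_k)]]
  if (is.null(ch)) stop(sprintf("K = %d produced no consensus", chosen_k),
                        call. = FALSE)
  structure(list(usage = ch$usage, programs = ch$programs, per_k = per_k,
                 chosen_k = chosen_k, density_threshold = density_threshold,
                 n_runs = n_runs, seed = seed),
            class = "consensus_nmf")
}

#' @export
print.consensus_nmf <- function(x, ...) {
  cat(sprintf("consensus_nmf: chosen K = %d (%d runs per K)\n",
              x$chosen_k, x$n_runs))
  print(x$per_k, row.names = FALSE)
  invisible(x)
}

#' Spot enrichment by deconvolved cell-type abundance
#'
#' A spot is enriched for a cell type when its rounded estimated abundance
#' reaches `min_cells` (rounding is half-to-even on the fractional
#' deconvolution estimates).
#'
#' @param abundance spots x cell-types matrix/data.frame with column names,
#'   or a [generate_spot_dataset()] result.
#' @param cell_type column to threshold.
#' @param min_cells minimum rounded cells per spot (default 1).
#' @return list: `enriched` (logical mask), `n_enriched`,
#'   `mean_abundance_all`, `mean_abundance_enriched`, `cell_type`,
#'   `min_cells`.
#' @export
spot_enrichment <- function(abundance, cell_type, min_cells = 1L) {
  if (inherits(abundance, "spot_dataset")) abundance <- abundance$abundance
  abundance <- as.matrix(abundance)
  if (!cell_type %in% colnames(abundance)) {
    stop(sprintf("unknown cell type '%s'; available: %s", cell_type,
                 paste(colnames(abundance), collapse = ", ")), call. = FALSE)
  }
  a <- unname(abundance[, cell_type])
  .check_positive(a, "abundance", strict = FALSE)
  mask <- round(a) >= min_cells
  list(enriched = mask, n_enriched = sum(mask),
       mean_abundance_all = mean(a),
       mean_abundance_enriched = if (any(mask)) mean(a[mask]) else NaN,
       cell_type = cell_type, min_cells = min_cells)
}

#' Per-group cluster composition percentages
#'
#' @param cluster per-cell cluster labels.
#' @param group per-cell sample/group labels.
#' @return data.frame `group`, `cluster`, `n`, `pct`; percentages sum to
#'   100 within each group. Groups with no cells are excluded with a
#'   warning.
#' @export
cluster_fractions <- function(cluster, group) {
  if (length(cluster) != length(group)) {
    stop("'cluster' and 'group' must have equal length", call. = FALSE)
  }
  if (anyNA(cluster) || anyNA(group)) stop("missing labels", call. = FALSE)
  g <- if (is.factor(group)) group else factor(group)
  empty <- levels(g)[tabulate(g, nlevels(g)) == 0L]
  if (length(empty)) {
    warning("empty group(s) excluded: ", paste(empty, collapse = ", "))
    g <- droplevels(g)
  }
  tab <- table(group = g, cluster = factor(cluster))
  pct <- prop.table(tab, margin = 1L) * 100
  out <- as.data.frame(tab, responseName = "n")
  out$pct <- as.data.frame(pct)$Freq
  out <- out[order(out$group, out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  out
}
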