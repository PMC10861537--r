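# Spatial statistics on segmented, labeled cell maps. Distances are
# Euclidean in the map's coordinate units (micrometres for imaging data);
# everything is 2-D (tissue sections). No edge correction is applied.

#' @importFrom mclust Mclust mclustBIC
NULL

#' Construct a cell map
#'
#' @param x,y coordinates (same units, typically micrometres).
#' @param label per-cell category (character or factor), non-empty.
#' @param intensities optional data.frame/matrix of per-cell stain mean
#'   intensities (one column per stain).
#' @param window bounding rectangle `c(xmin, xmax, ymin, ymax)`; defaults to
#'   the data bounding box. All points must lie inside.
#' @return object of class `cell_map`: list with `cells` (data.frame of x,
#'   y, label and any intensity columns) and `window`.
#' @export
cell_map <- function(x, y, label, intensities = NULL, window = NULL) {
  if (length(x) != length(y) || length(x) != length(label)) {
    stop("x, y and label must have equal length", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  label <- as.character(label)
  if (anyNA(label) || any(!nzchar(label))) {
    stop("labels must be non-empty", call. = FALSE)
  }
  if (is.null(window)) {
    window <- c(min(x), max(x), min(y), max(y))
  }
  stopifnot(length(window) == 4L, window[2] >= window[1], window[4] >= window[3])
  if (any(x < window[1] | x > window[2] | y < window[3] | y > window[4])) {
    stop("points outside the window", call. = FALSE)
  }
  cells <- data.frame(x = x, y = y, label = label)
  if (!is.null(intensities)) {
    intensities <- as.data.frame(intensities)
    stopifnot(nrow(intensities) == length(x))
    cells <- cbind(cells, intensities)
  }
  structure(list(cells = cells, window = window), class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("cell_map: %d cells, %d labels, window [%g, %g] x [%g, %g]\n",
              nrow(x$cells), length(unique(x$cells$label)),
              x$window[1], x$window[2], x$window[3], x$window[4]))
  print(table(x$cells$label))
  invisible(x)
}

#' Read a segmented-cell map from GeoJSON or CSV
#'
#' GeoJSON input must be an RFC 7946 FeatureCollection of Point features;
#' the cell label is taken from `properties[[label_field]]` and any other
#' numeric properties are kept as per-cell intensities. CSV input needs
#' columns `x`, `y` and the label field; extra numeric columns are kept.
#'
#' @param path file path, `.geojson`/`.json` or `.csv`.
#' @param label_field property/column holding the cell label (default
#'   `"label"`).
#' @param window optional bounding rectangle; defaults to the data bounding
#'   box.
#' @return a [cell_map()].
#' @export
read_cellmap <- function(path, label_field = "label", window = NULL) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!identical(gj$type, "FeatureCollection")) {
      stop("GeoJSON root must be a FeatureCollection", call. = FALSE)
    }
    feats <- gj$features
    n <- length(feats)
    xs <- ys <- numeric(n)
    labs <- character(n)
    props <- vector("list", n)
    for (i in seq_len(n)) {
      f <- feats[[i]]
      g <- f$geometry
      if (is.null(g) || !identical(g$type, "Point") ||
          length(g$coordinates) < 2L) {
        stop(sprintf("feature %d: malformed Point geometry", i), call. = FALSE)
      }
      xs[i] <- as.numeric(g$coordinates[[1]])
      ys[i] <- as.numeric(g$coordinates[[2]])
      lab <- f$properties[[label_field]]
      if (is.null(lab)) {
        stop(sprintf("feature %d: missing property '%s'", i, label_field),
             call. = FALSE)
      }
      labs[i] <- as.character(lab)
      pnum <- f$properties[setdiff(names(f$properties), label_field)]
      props[[i]] <- pnum[vapply(pnum, is.numeric, logical(1))]
    }
    inten <- NULL
    keys <- unique(unlist(lapply(props, names)))
    if (length(keys)) {
      inten <- as.data.frame(lapply(keys, function(k) {
        vapply(props, function(p) as.numeric(p[[k]] %||% NA_real_), numeric(1))
      }))
      names(inten) <- keys
    }
    cell_map(xs, ys, labs, intensities = inten, window = window)
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("x", "y", label_field)
    miss <- setdiff(need, names(d))
    if (length(miss)) {
      stop("CSV missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (anyNA(d[[label_field]])) {
      stop(sprintf("row %d: missing label", which(is.na(d[[label_field]]))[1]),
           call. = FALSE)
    }
    extra <- setdiff(names(d), need)
    extra <- extra[vapply(d[extra], is.numeric, logical(1))]
    cell_map(d$x, d$y, d[[label_field]],
             intensities = if (length(extra)) d[extra], window = window)
  }
}

#' Write a cell map to GeoJSON or CSV
#'
#' @param map a [cell_map()].
#' @param path output path; format chosen by extension unless given.
#' @param format `"geojson"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_cellmap <- function(map, path,
                          format = if (grepl("\\.(geojson|json)$", path,
                                             ignore.case = TRUE)) "geojson"
                                   else "csv") {
  stopifnot(inherits(map, "cell_map"))
  format <- match.arg(format, c("geojson", "csv"))
  if (format == "csv") {
    utils::write.csv(map$cells, path, row.names = FALSE)
  } else {
    cells <- map$cells
    extra <- setdiff(names(cells), c("x", "y"))
    feats <- lapply(seq_len(nrow(cells)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(cells$x[i], cells$y[i])),
           properties = as.list(cells[i, extra, drop = FALSE]))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Threshold per-cell stain intensities into positive/negative
#'
#' A cell is positive iff its intensity is `>=` the cut (boundary
#' inclusive). The cut is either fixed, found by Otsu's criterion
#' (exhaustive scan of candidate cuts maximizing between-class variance), or
#' the equal-density crossing of a two-component Gaussian mixture.
#'
#' @param intensity numeric per-cell intensities.
#' @param method `"fixed"`, `"otsu"` or `"gmm2"`.
#' @param cut threshold for `method = "fixed"`.
#' @return list with `positive` (logical), `cut`, `method`.
#' @export
threshold_positivity <- function(intensity, method = c("otsu", "gmm2", "fixed"),
                                 cut = NULL) {
  method <- match.arg(method)
  if (anyNA(intensity)) stop("missing intensities", call. = FALSE)
  if (method == "fixed") {
    if (is.null(cut)) stop("'cut' required for method = 'fixed'", call. = FALSE)
  } else {
    if (length(intensity) < 2L) {
      stop("adaptive thresholding needs >= 2 cells", call. = FALSE)
    }
    if (max(intensity) == min(intensity)) {
      stop("constant intensities: use method = 'fixed' with an explicit cut",
           call. = FALSE)
    }
    if (method == "otsu") {
      v <- sort(unique(intensity))
      cand <- (v[-1] + v[-length(v)]) / 2
      n <- length(intensity)
      bcv <- vapply(cand, function(t) {
        hi <- intensity >= t
        w2 <- mean(hi); w1 <- 1 - w2
        if (w1 == 0 || w2 == 0) return(-Inf)
        w1 * w2 * (mean(intensity[hi]) - mean(intensity[!hi]))^2
      }, numeric(1))
      cut <- cand[which.max(bcv)]
    } else {
      fit <- mclust::Mclust(intensity, G = 2, modelNames = "V",
                            verbose = FALSE)
      mu <- fit$parameters$mean
      sdv <- sqrt(fit$parameters$variance$sigmasq)
      if (length(sdv) == 1L) sdv <- rep(sdv, 2L)
      pi2 <- fit$parameters$pro
      lo <- which.min(mu); hi <- which.max(mu)
      f <- function(t) {
        pi2[lo] * stats::dnorm(t, mu[lo], sdv[lo]) -
          pi2[hi] * stats::dnorm(t, mu[hi], sdv[hi])
      }
      cut <- tryCatch(
        stats::uniroot(f, lower = mu[lo], upper = mu[hi])$root,
        error = function(e) mean(mu))
    }
  }
  list(positive = intensity >= cut, cut = cut, method = method)
}

# squared distance matrix between two point sets (2-D, chunk-free)
.sqdist <- function(ax, ay, bx, by) {
  outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
}

#' Co-occurrence probability-ratio curves between cell labels
#'
#' For a reference label `a`, target label `b` and radius `r`, the ratio is
#' the conditional probability of finding a `b` cell within distance `r` of
#' an `a` cell, divided by the marginal frequency of `b`:
#' `ratio(b | a, r) = [N_ab(r) / N_a.(r)] / (n_b / n)`,
#' where `N_ab(r)` counts ordered pairs (i, j), i != j, with label(i) = a,
#' label(j) = b and dist <= r, and `N_a.(r)` counts all such pairs from `a`
#' cells. A ratio above 1 means `b` cells are over-represented near `a`
#' cells (attraction); below 1, under-represented (exclusion). The marginal
#' uses all cells of the map; self-pairs are excluded. `NaN` where no pair
#' from `a` falls within `r`.
#'
#' @param map a [cell_map()].
#' @param radii increasing positive radius bin upper edges; default 50
#'   equal-width cumulative bins from 0 to a quarter of the window diagonal.
#' @param ref_labels,target_labels restrict the ordered label pairs reported
#'   (statistics are always computed against the full label set; this only
#'   subsets the output). Unknown labels error.
#' @return long data.frame: `ref_label`, `target_label`, `radius`, `ratio`.
#' @export
co_occurrence <- function(map, radii = NULL, ref_labels = NULL,
                          target_labels = NULL) {
  stopifnot(inherits(map, "cell_map"))
  cells <- map$cells
  n <- nrow(cells)
  if (n < 2L) stop("need >= 2 cells", call. = FALSE)
  if (is.null(radii)) {
    diag_len <- sqrt(diff(map$window[1:2])^2 + diff(map$window[3:4])^2)
    radii <- seq(0, diag_len / 4, length.out = 51L)[-1]
  }
  if (is.unsorted(radii, strictly = TRUE) || any(radii <= 0)) {
    stop("radii must be strictly increasing and positive", call. = FALSE)
  }
  labs <- unique(cells$label)
  for (l in c(ref_labels, target_labels)) {
    if (!l %in% labs) stop(sprintf("unknown label '%s'", l), call. = FALSE)
  }
  ref_labels <- ref_labels %||% labs
  target_labels <- target_labels %||% labs
  marg <- table(cells$label)[labs] / n
  idx <- split(seq_len(n), factor(cells$label, levels = labs))

  # per ordered pair (a,b): sorted pair distances, then cumulative counts
  pair_counts <- function(a) {
    ia <- idx[[a]]
    d2 <- .sqdist(cells$x[ia], cells$y[ia], cells$x, cells$y)
    d2[cbind(seq_along(ia), ia)] <- Inf  # drop self-pairs
    res <- vapply(labs, function(b) {
      db <- sqrt(as.vector(d2[, idx[[b]], drop = FALSE]))
      findInterval(radii, sort(db[is.finite(db)]))
    }, numeric(length(radii)))
    if (!is.matrix(res)) res <- matrix(res, nrow = 1L,
                                       dimnames = list(NULL, names(res)))
    res
  }
  out <- list()
  for (a in ref_labels) {
    counts <- pair_counts(a)                 # radii x labels
    n_a_dot <- rowSums(counts)
    for (b in target_labels) {
      cond <- ifelse(n_a_dot > 0, counts[, b] / n_a_dot, NaN)
      out[[paste(a, b, sep = "\r")]] <- data.frame(
        ref_label = a, target_label = b, radius = radii,
        ratio = cond / as.numeric(marg[b]))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# --- Delaunay triangulation (Bowyer-Watson) -------------------------------
# Returns a 2-column edge matrix (i < j), or NULL if the point set is
# degenerate (fewer than 3 distinct non-collinear points).
.delaunay_edges <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(NULL)
  # normalize to unit box for numerical stability
  sc <- max(max(x) - min(x), max(y) - min(y))
  if (sc == 0) return(NULL)
  px <- (x - min(x)) / sc
  py <- (y - min(y)) / sc
  # super-triangle well outside the unit box
  px <- c(px, -10, 10, 0.5)
  py <- c(py, -10, -10, 20)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  circum <- function(i, j, k) {
    ax <- px[i]; ay <- py[i]; bx <- px[j]; by <- py[j]; cx <- px[k]; cy <- py[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-14) return(NULL)  # collinear
    a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
    ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
    uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  tris <- list(c(s1, s2, s3))
  ccs <- list(circum(s1, s2, s3))
  for (p in seq_len(n)) {
    ptx <- px[p]; pty <- py[p]
    bad <- vapply(ccs, function(cc) {
      (ptx - cc[1])^2 + (pty - cc[2])^2 <= cc[3] * (1 + 1e-12)
    }, logical(1))
    if (!any(bad)) next  # duplicate of an existing vertex on a hull edge
    # boundary of the bad-triangle cavity = edges appearing exactly once
    be <- do.call(rbind, lapply(tris[bad], function(t) {
      rbind(sort(t[c(1, 2)]), sort(t[c(2, 3)]), sort(t[c(1, 3)]))
    }))
    key <- paste(be[, 1], be[, 2])
    keep <- be[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    tris <- tris[!bad]
    ccs <- ccs[!bad]
    for (e in seq_len(nrow(keep))) {
      cc <- circum(keep[e, 1], keep[e, 2], p)
      if (is.null(cc)) next
      tris[[length(tris) + 1L]] <- c(keep[e, 1], keep[e, 2], p)
      ccs[[length(ccs) + 1L]] <- cc
    }
  }
  real <- Filter(function(t) all(t <= n), tris)
  if (!length(real)) return(NULL)
  edges <- unique(do.call(rbind, lapply(real, function(t) {
    rbind(sort(t[c(1, 2)]), sort(t[c(2, 3)]), sort(t[c(1, 3)]))
  })))
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

#' Build a spatial neighbor graph over a cell map
#'
#' Three constructions: `knn(k)` (k nearest neighbors, symmetrized by edge
#' union), `delaunay` (edges of the Delaunay triangulation), `radius(r)`
#' (all pairs within distance `r`). The graph is undirected with no
#' self-loops. Degenerate point sets (collinear) make the triangulation
#' impossible; the builder then falls back to a radius graph at 1.5x the
#' median nearest-neighbor distance, with a warning.
#'
#' @param map a [cell_map()].
#' @param method `"knn"` (default, k = 6), `"delaunay"` or `"radius"`.
#' @param k neighbors for `"knn"`.
#' @param r radius for `"radius"`.
#' @return object of class `neighbor_graph`: list with `edges` (2-column
#'   matrix, i < j), `n`, `method`, `params`.
#' @export
build_neighbors <- function(map, method = c("knn", "delaunay", "radius"),
                            k = 6L, r = NULL) {
  stopifnot(inherits(map, "cell_map"))
  method <- match.arg(method)
  cells <- map$cells
  n <- nrow(cells)
  d2 <- .sqdist(cells$x, cells$y, cells$x, cells$y)
  diag(d2) <- Inf
  params <- list()
  if (method == "knn") {
    if (n < k + 1L) stop(sprintf("knn(k=%d) needs >= %d cells", k, k + 1L),
                         call. = FALSE)
    nb <- apply(d2, 1L, function(row) order(row)[seq_len(k)])
    edges <- cbind(rep(seq_len(n), each = k), as.vector(nb))
    params <- list(k = k)
  } else if (method == "radius") {
    if (is.null(r) || r <= 0) stop("radius method needs r > 0", call. = FALSE)
    hit <- which(d2 <= r^2, arr.ind = TRUE)
    edges <- hit
    params <- list(r = r)
  } else {
    edges <- .delaunay_edges(cells$x, cells$y)
    if (is.null(edges)) {
      rfall <- 1.5 * stats::median(sqrt(apply(d2, 1L, min)))
      warning(sprintf(
        "degenerate point set for delaunay; falling back to radius(r=%.3g)",
        rfall))
      return(build_neighbors(map, "radius", r = rfall))
    }
    params <- list()
  }
  edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                        pmax(edges[, 1], edges[, 2])))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  dimnames(edges) <- NULL
  structure(list(edges = edges, n = n, method = method, params = params),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("neighbor_graph: %d nodes, %d edges (%s)\n",
              x$n, nrow(x$edges), x$method))
  invisible(x)
}

# label-pair edge counts for a graph; returns symmetric L x L matrix
.pair_edge_counts <- function(edges, lab_int, L) {
  a <- pmin(lab_int[edges[, 1]], lab_int[edges[, 2]])
  b <- pmax(lab_int[edges[, 1]], lab_int[edges[, 2]])
  m0 <- matrix(tabulate((a - 1L) * L + b, nbins = L * L), L, L)
  m <- m0 + t(m0)
  diag(m) <- diag(m0)
  m
}

#' Neighborhood enrichment of label pairs on a spatial graph
#'
#' For every unordered label pair the observed number of graph edges joining
#' the two labels is compared to its distribution under uniform random
#' shuffles of the label vector (node positions and graph fixed):
#' `z = (observed - mean_perm) / sd_perm`. Positive z means the two labels
#' are neighbors more often than chance (colocalization); negative z,
#' avoidance. The diagonal scores within-label clustering.
#'
#' @param graph a [build_neighbors()] graph.
#' @param labels per-node labels (length `graph$n`).
#' @param n_perms number of label permutations (`>= 100`).
#' @param seed integer seed; the permutation stream is fully determined by
#'   it.
#' @return object of class `nhood_enrichment`: `z`, `observed`,
#'   `perm_mean`, `perm_sd` (label x label matrices), `n_perms`, `seed`.
#'   `z` is `NaN` where the permutation sd is zero (and everywhere, with a
#'   warning, when only one label is present).
#' @export
neighborhood_enrichment <- function(graph, labels, n_perms = 1000L,
                                    seed = NULL) {
  stopifnot(inherits(graph, "neighbor_graph"))
  if (length(labels) != graph$n) {
    stop("labels must have one entry per node", call. = FALSE)
  }
  if (n_perms < 100L) stop("n_perms must be >= 100", call. = FALSE)
  f <- factor(labels)
  L <- nlevels(f)
  lab_int <- as.integer(f)
  obs <- .pair_edge_counts(graph$edges, lab_int, L)
  dimnames(obs) <- list(levels(f), levels(f))
  if (L < 2L) {
    warning("single label: all z-scores undefined")
    z <- obs * NaN
    return(structure(list(z = z, observed = obs, perm_mean = obs * NaN,
                          perm_sd = obs * NaN, n_perms = n_perms, seed = seed),
                     class = "nhood_enrichment"))
  }
  perm <- .with_seed(seed, {
    vapply(seq_len(n_perms), function(i) {
      .pair_edge_counts(graph$edges, sample(lab_int), L)
    }, obs)
  })
  pm <- apply(perm, c(1, 2), mean)
  ps <- apply(perm, c(1, 2), stats::sd)
  z <- ifelse(ps > 0, (obs - pm) / ps, NaN)
  dimnames(z) <- dimnames(pm) <- dimnames(ps) <- dimnames(obs)
  structure(list(z = z, observed = obs, perm_mean = pm, perm_sd = ps,
                 n_perms = n_perms, seed = seed),
            class = "nhood_enrichment")
}

#' @export
print.nhood_enrichment <- function(x, ...) {
  cat(sprintf("neighborhood enrichment (%d permutations)\nz-scores:\n",
              x$n_perms))
  print(round(x$z, 2))
  invisible(x)
}

#' Nearest-distance distribution between two point sets
#'
#' For each query point, the distance to its closest reference point.
#' Distances beyond `max_radius` are flagged as censored but reported, not
#' dropped. A point present in both sets gives distance 0.
#'
#' @param query,reference 2-column matrices/data.frames of coordinates (or
#'   [cell_map()] objects).
#' @param max_radius censoring radius (default `Inf`).
#' @return data.frame with `distance` and `censored` per query point.
#' @export
nearest_distance_distribution <- function(query, reference, max_radius = Inf) {
  as_xy <- function(p) {
    if (inherits(p, "cell_map")) p <- p$cells
    p <- as.data.frame(p)
    if (!all(c("x", "y") %in% names(p))) names(p)[1:2] <- c("x", "y")
    p
  }
  q <- as_xy(query); r <- as_xy(reference)
  if (!nrow(q)) stop("empty query set", call. = FALSE)
  if (!nrow(r)) stop("empty reference set", call. = FALSE)
  # chunked brute force; point sets here are at most a few thousand
  mins <- numeric(nrow(q))
  step <- 512L
  for (s in seq(1L, nrow(q), by = step)) {
    i <- s:min(s + step - 1L, nrow(q))
    d2 <- .sqdist(q$x[i], q$y[i], r$x, r$y)
    mins[i] <- sqrt(apply(d2, 1L, min))
  }
  data.frame(distance = mins, censored = mins > max_radius)
}
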