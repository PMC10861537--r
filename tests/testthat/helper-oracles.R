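# Independent oracles used across test files. These deliberately take the
# naive O(n^2) route so they share no code path with the implementation.

# co-occurrence ratio by direct evaluation of the defining formula
bf_cooccurrence <- function(map, radii, ref, target) {
  cells <- map$cells
  n <- nrow(cells)
  D <- as.matrix(stats::dist(cells[, c("x", "y")]))
  ia <- which(cells$label == ref)
  p_b <- sum(cells$label == target) / n
  vapply(radii, function(r) {
    n_ab <- 0L; n_a <- 0L
    for (i in ia) {
      within <- which(D[i, ] <= r)
      within <- setdiff(within, i)
      n_a <- n_a + length(within)
      n_ab <- n_ab + sum(cells$label[within] == target)
    }
    if (n_a == 0L) NaN else (n_ab / n_a) / p_b
  }, numeric(1))
}

# greedy one-to-one cosine matching of recovered rows to planted rows
greedy_cosine_match <- function(planted, recovered) {
  Pn <- planted / sqrt(rowSums(planted^2))
  Rn <- recovered / sqrt(rowSums(recovered^2))
  cs <- Pn %*% t(Rn)
  k <- nrow(cs)
  best <- numeric(k); used <- integer(0)
  for (i in order(-apply(cs, 1, max))) {
    j <- which.max(replace(cs[i, ], used, -Inf))
    best[i] <- cs[i, j]
    used <- c(used, j)
  }
  best
}

# a small random labeled map under complete spatial randomness
random_map <- function(n, labels = c("A", "B"), probs = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cell_map(runif(n, 0, 100), runif(n, 0, 100),
           sample(labels, n, replace = TRUE, prob = probs),
           window = c(0, 100, 0, 100))
}

# true-label vector aligned with a classify_cohort() call table
cohort_truth_labels <- function(cohort, calls) {
  ifelse(calls$timepoint == "before",
         cohort$truth$pop_before[calls$patient_id],
         cohort$truth$pop_after[calls$patient_id])
}

# thresholds from an independent learning cohort drawn from the same
# generator settings (mirrors the learn-then-apply design)
learned_thresholds <- function(n_learn = 2000, seed = 9090, ...) {
  learn <- generate_cohort(n_learn, seed = seed, ...)
  mk <- learn$markers[learn$markers$timepoint == "before", ]
  learn_thresholds(split(mk$hscore, mk$marker),
                   provenance = "synthetic learning cohort")
}
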