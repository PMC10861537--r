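# Synthetic-data generators. Patient material behind the original cohorts is
# controlled-access; these generators emit every input the pipeline consumes
# with known ground truth, so all downstream stages are testable end-to-end.

#' Default per-population CAF marker H-score profiles
#'
#' Mean H-scores (0--400) per population for the markers the pipeline uses.
#' Levels follow an ordinal grid: Neg = 20, Low = 80, Med = 160,
#' Med-High = 220, High = 280. CAF-S1 is the FAP-high activated
#' (myofibroblast-rich, ANTXR1+, YAP1-active) population; CAF-S4 is the
#' FAP-negative, CD29/SMA-high activated population; CAF-S2 is
#' quadruple-low normal-like and CAF-S3 the FSP1-high normal-like
#' population. CAF-S1's SMA sits at Med-High, below CAF-S4's hallmark High.
#'
#' @return 4 x 6 numeric matrix, rows CAF-S1..CAF-S4, columns FAP, CD29,
#'   SMA, FSP1, ANTXR1, YAP1.
#' @export
caf_marker_profiles <- function() {
  m <- rbind(
    "CAF-S1" = c(FAP = 280, CD29 = 160, SMA = 220, FSP1 = 220,
                 ANTXR1 = 220, YAP1 = 220),
    "CAF-S2" = c(FAP = 20,  CD29 = 80,  SMA = 20,  FSP1 = 20,
                 ANTXR1 = 20,  YAP1 = 80),
    "CAF-S3" = c(FAP = 20,  CD29 = 160, SMA = 80,  FSP1 = 280,
                 ANTXR1 = 20,  YAP1 = 80),
    "CAF-S4" = c(FAP = 20,  CD29 = 280, SMA = 280, FSP1 = 160,
                 ANTXR1 = 80,  YAP1 = 160))
  m
}

# decompose an H-score into (intensity, pct) with intensity * pct == hscore
.hscore_decompose <- function(h) {
  i <- ifelse(h <= 0, 0, pmin(4, ceiling(h / 100)))
  p <- ifelse(i == 0, 0, h / i)
  list(intensity = i, pct = p)
}

#' Generate a paired before/after IHC cohort with known ground truth
#'
#' Emulates a retrospective cohort of matched tumor samples before and after
#' chemotherapy. Each patient draws a true CAF population from `mix_before`;
#' activated patients (CAF-S1/CAF-S4) switch to a normal-like population
#' (CAF-S2/CAF-S3, equal odds) with probability `switch_prob`, and switching
#' patients additionally shrink their FAP/SMA/ANTXR1 means by `shrink`.
#' Marker H-scores are the population means plus truncated-normal noise
#' (clipped to `[0, 400]`). The change in CD8+ TIL density is generated via
#' a Gaussian copula on the ranks of each patient's change in FAP H-score so
#' that the population Spearman correlation of (delta-FAP, delta-CD8
#' density) equals `rho_true`; when delta-FAP is degenerate (e.g. zero
#' noise, no switching) all TIL deltas are exactly zero.
#'
#' @param n_patients number of patients (`>= 2`).
#' @param mix_before named probabilities over CAF-S1..CAF-S4, summing to 1.
#' @param switch_prob probability that an activated patient switches to a
#'   normal-like population after treatment.
#' @param rho_true target Spearman correlation between delta-FAP and
#'   delta-CD8 density, in `[-1, 1]`.
#' @param noise_sd marker noise sd in H-score units (`>= 0`).
#' @param seed integer seed; output is bit-reproducible given it.
#' @param profiles population x marker mean matrix
#'   (default [caf_marker_profiles()]), entries in `[0, 400]`.
#' @param shrink multiplicative factor applied to FAP/SMA/ANTXR1 means of
#'   switching patients after treatment.
#' @param cd8_delta_sd scale (cells/mm^2) of the delta-CD8-density
#'   distribution.
#' @return list of class `caf_cohort`: `markers` (long data.frame:
#'   patient_id, timepoint, marker, compartment, intensity, pct_stained,
#'   hscore), `tils` (patient_id, timepoint, cell_type, count, area_mm2,
#'   compartment), and `truth` (population before/after per patient,
#'   `rho_true`, profiles, parameters).
#' @export
generate_cohort <- function(n_patients, mix_before = c("CAF-S1" = 0.50,
                                                       "CAF-S2" = 0.10,
                                                       "CAF-S3" = 0.15,
                                                       "CAF-S4" = 0.25),
                            switch_prob = 0.42, rho_true = -0.6,
                            noise_sd = 20, seed = 1L,
                            profiles = caf_marker_profiles(),
                            shrink = 0.7, cd8_delta_sd = 60) {
  if (n_patients < 2) stop("'n_patients' must be >= 2", call. = FALSE)
  if (abs(sum(mix_before) - 1) > 1e-8 || any(mix_before < 0)) {
    stop("'mix_before' must be nonnegative and sum to 1", call. = FALSE)
  }
  if (!all(names(mix_before) %in% .caf_populations)) {
    stop("'mix_before' names must be CAF-S1..CAF-S4", call. = FALSE)
  }
  .check_prob(switch_prob, "switch_prob")
  .check_range(rho_true, -1, 1, "rho_true")
  .check_positive(noise_sd, "noise_sd", strict = FALSE)
  .check_range(as.vector(profiles), 0, 400, "profiles")

  markers <- colnames(profiles)
  .with_seed(seed, {
    pop_before <- sample(names(mix_before), n_patients, replace = TRUE,
                         prob = mix_before)
    switches <- pop_before %in% .activated_populations &
      stats::runif(n_patients) < switch_prob
    pop_after <- pop_before
    pop_after[switches] <- sample(c("CAF-S2", "CAF-S3"), sum(switches),
                                  replace = TRUE)

    mean_for <- function(pop, after, switched) {
      m <- profiles[pop, , drop = FALSE]
      if (after) {
        shrunk <- c("FAP", "SMA", "ANTXR1")
        m[switched, intersect(shrunk, markers)] <-
          m[switched, intersect(shrunk, markers), drop = FALSE] * shrink
      }
      m
    }
    mu_b <- mean_for(pop_before, FALSE, switches)
    mu_a <- mean_for(pop_after, TRUE, switches)
    draw <- function(mu) {
      h <- mu + matrix(stats::rnorm(length(mu), sd = noise_sd),
                       nrow(mu), ncol(mu))
      pmin(pmax(h, 0), 400)
    }
    h_b <- draw(mu_b); h_a <- draw(mu_a)

    pid <- sprintf("P%03d", seq_len(n_patients))
    long <- function(h, tp) {
      dec <- .hscore_decompose(as.vector(h))
      data.frame(patient_id = rep(pid, times = length(markers)),
                 timepoint = tp,
                 marker = rep(markers, each = n_patients),
                 compartment = "stroma",
                 intensity = dec$intensity, pct_stained = dec$pct,
                 hscore = as.vector(h))
    }
    marker_tab <- rbind(long(h_b, "before"), long(h_a, "after"))

    # CD8 density delta anti-correlated with delta-FAP via Gaussian copula;
    # Pearson rho on the latent normals chosen so the Spearman equals
    # rho_true: rho_pearson = 2 sin(pi rho_true / 6)
    d_fap <- h_a[, "FAP"] - h_b[, "FAP"]
    if (stats::sd(d_fap) == 0) {
      d_cd8 <- rep(0, n_patients)
    } else {
      z1 <- stats::qnorm(rank(d_fap, ties.method = "average") /
                           (n_patients + 1))
      rho_p <- 2 * sin(pi * rho_true / 6)
      z2 <- rho_p * z1 + sqrt(1 - rho_p^2) * stats::rnorm(n_patients)
      d_cd8 <- cd8_delta_sd * z2
    }
    area <- 5 * 0.105  # five representative fields of 0.105 mm^2
    dens_b <- stats::rgamma(n_patients, shape = 16, scale = 25)
    dens_a <- pmax(dens_b + d_cd8, 0)
    cd3_b <- dens_b * 1.6; cd3_a <- cd3_b + 1.3 * (dens_a - dens_b)
    fox_b <- dens_b * 0.15; fox_a <- fox_b + 0.1 * (dens_a - dens_b)
    til_row <- function(ct, db, da) {
      data.frame(patient_id = rep(pid, 2L),
                 timepoint = rep(c("before", "after"), each = n_patients),
                 cell_type = ct,
                 count = round(c(db, da) * area),
                 area_mm2 = area, compartment = "stroma")
    }
    tils <- rbind(til_row("CD8", dens_b, dens_a),
                  til_row("CD3", cd3_b, cd3_a),
                  til_row("FOXP3", pmax(fox_b, 0), pmax(fox_a, 0)))

    structure(list(
      markers = marker_tab, tils = tils,
      truth = list(pop_before = stats::setNames(pop_before, pid),
                   pop_after = stats::setNames(pop_after, pid),
                   switched = stats::setNames(switches, pid),
                   rho_true = rho_true, profiles = profiles,
                   mix_before = mix_before, switch_prob = switch_prob,
                   noise_sd = noise_sd, shrink = shrink, seed = seed)),
      class = "caf_cohort")
  })
}

#' Write a synthetic cohort to TSV
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed); writes `markers.tsv`
#'   and `tils.tsv`.
#' @return `dir`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "caf_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$markers, file.path(dir, "markers.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$tils, file.path(dir, "tils.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Specify ground truth for a labeled spatial point pattern
#'
#' @param window bounding rectangle `c(xmin, xmax, ymin, ymax)` in
#'   micrometres, positive area.
#' @param intensity named vector of base intensities (points per unit area,
#'   `> 0`) per label. Labels that appear as attraction offspring ignore
#'   their base intensity.
#' @param interactions list of interaction specs:
#'   `list(type = "exclusion", a, b, d_excl)` forbids any `b` point within
#'   `d_excl` of an `a` point; `list(type = "attraction", parent, offspring,
#'   cluster_sd, mean_count)` generates `offspring` as a Thomas cluster
#'   process around `parent` points.
#' @return list of class `spatial_truth`.
#' @export
spatial_truth <- function(window, intensity, interactions = list()) {
  stopifnot(length(window) == 4L)
  if ((window[2] - window[1]) * (window[4] - window[3]) <= 0) {
    stop("'window' must have positive area", call. = FALSE)
  }
  .check_positive(intensity, "intensity", strict = TRUE)
  if (is.null(names(intensity))) stop("'intensity' must be named", call. = FALSE)
  for (sp in interactions) {
    if (!sp$type %in% c("exclusion", "attraction")) {
      stop("interaction 'type' must be exclusion or attraction", call. = FALSE)
    }
    if (sp$type == "exclusion" && sp$d_excl <= 0) {
      stop("'d_excl' must be > 0", call. = FALSE)
    }
    if (sp$type == "attraction" && (sp$cluster_sd <= 0 || sp$mean_count <= 0)) {
      stop("'cluster_sd' and 'mean_count' must be > 0", call. = FALSE)
    }
  }
  structure(list(window = window, intensity = intensity,
                 interactions = interactions), class = "spatial_truth")
}

#' Generate a labeled cell map with planted attraction/exclusion
#'
#' Labels without interactions are homogeneous Poisson at their stated
#' intensity. Exclusion pairs are enforced by rejection sampling (capped at
#' 10,000 rounds; an unsatisfiable constraint errors out). Attraction
#' offspring follow a Thomas process: each parent point spawns a
#' Poisson(`mean_count`) number of offspring displaced by isotropic Gaussian
#' noise of sd `cluster_sd`, resampled to stay inside the window.
#'
#' @param truth a [spatial_truth()].
#' @param seed integer seed.
#' @return list with `map` (a [cell_map()]) and `truth`.
#' @export
generate_cellmap <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "spatial_truth"))
  w <- truth$window
  area <- (w[2] - w[1]) * (w[4] - w[3])
  offspring_of <- list()
  excluded_by <- list()
  for (sp in truth$interactions) {
    if (sp$type == "attraction") offspring_of[[sp$offspring]] <- sp
    if (sp$type == "exclusion") {
      excluded_by[[sp$b]] <- c(excluded_by[[sp$b]], list(sp))
    }
  }
  labs <- names(truth$intensity)
  order_labs <- c(setdiff(labs, names(offspring_of)),
                  intersect(labs, names(offspring_of)))
  .with_seed(seed, {
    pts <- list()
    runi <- function(n) cbind(stats::runif(n, w[1], w[2]),
                              stats::runif(n, w[3], w[4]))
    for (lab in order_labs) {
      att <- offspring_of[[lab]]
      if (!is.null(att)) {
        par <- pts[[att$parent]]
        if (is.null(par)) stop(sprintf("attraction parent '%s' has no points",
                                       att$parent), call. = FALSE)
        kids <- do.call(rbind, lapply(seq_len(nrow(par)), function(i) {
          m <- stats::rpois(1, att$mean_count)
          if (m == 0) return(NULL)
          out <- matrix(0, m, 2)
          for (j in seq_len(m)) {
            repeat {
              p <- par[i, ] + stats::rnorm(2, sd = att$cluster_sd)
              if (p[1] >= w[1] && p[1] <= w[2] &&
                  p[2] >= w[3] && p[2] <= w[4]) break
            }
            out[j, ] <- p
          }
          out
        }))
        pts[[lab]] <- kids %||% matrix(numeric(0), 0, 2)
      } else {
        n_target <- stats::rpois(1, truth$intensity[[lab]] * area)
        excl <- excluded_by[[lab]]
        if (is.null(excl)) {
          pts[[lab]] <- runi(n_target)
        } else {
          acc <- matrix(numeric(0), 0, 2)
          rounds <- 0L
          while (nrow(acc) < n_target) {
            rounds <- rounds + 1L
            if (rounds > 10000L) {
              stop(sprintf(
                "exclusion constraint on label '%s' unsatisfiable after 10000 rejection rounds",
                lab), call. = FALSE)
            }
            cand <- runi(n_target - nrow(acc))
            ok <- rep(TRUE, nrow(cand))
            for (sp in excl) {
              ref <- pts[[sp$a]]
              if (is.null(ref) || !nrow(ref)) next
              d2 <- .sqdist(cand[, 1], cand[, 2], ref[, 1], ref[, 2])
              ok <- ok & apply(d2, 1L, min) >= sp$d_excl^2
            }
            acc <- rbind(acc, cand[ok, , drop = FALSE])
          }
          pts[[lab]] <- acc
        }
      }
    }
    xy <- do.call(rbind, pts[order_labs])
    lab_vec <- rep(order_labs, vapply(pts[order_labs], nrow, integer(1)))
    list(map = cell_map(xy[, 1], xy[, 2], lab_vec, window = w),
         truth = truth)
  })
}

#' Specify planted nonnegative expression programs for spot data
#'
#' @param k_true number of planted programs (`>= 1`).
#' @param n_genes,n_spots matrix dimensions (`>= k_true`).
#' @param noise `"poisson"` or `"nb"` (negative binomial).
#' @param dispersion NB size parameter; the NB converges to Poisson as
#'   `dispersion -> Inf`.
#' @param lib_size_mean mean library size (total counts) per spot.
#' @param n_cell_types number of planted cell types for the abundance
#'   matrix.
#' @return list of class `program_truth` carrying the sampling plan; the
#'   concrete matrices are drawn by [generate_spot_dataset()].
#' @export
program_truth <- function(k_true, n_genes, n_spots,
                          noise = c("poisson", "nb"), dispersion = 10,
                          lib_size_mean = 2000, n_cell_types = 5L) {
  noise <- match.arg(noise)
  if (k_true < 1) stop("'k_true' must be >= 1", call. = FALSE)
  if (n_genes < k_true || n_spots < k_true) {
    stop("'n_genes' and 'n_spots' must be >= k_true", call. = FALSE)
  }
  if (noise == "nb") .check_positive(dispersion, "dispersion")
  structure(list(k_true = k_true, n_genes = n_genes, n_spots = n_spots,
                 noise = noise, dispersion = dispersion,
                 lib_size_mean = lib_size_mean,
                 n_cell_types = n_cell_types), class = "program_truth")
}

#' Generate a spot x gene count matrix from planted programs
#'
#' Programs are sparse nonnegative K x G rows (each with a dominant gene
#' block) normalized to sum 1; usages are Dirichlet rows on the simplex;
#' counts are drawn with mean `libsize * usage %*% programs` under the
#' chosen noise model. Spots sit on a hexagonal-like grid. Planted per-spot
#' cell-type abundances are Poisson counts driven by the usage matrix
#' through a random nonnegative loading, emulating the output of a
#' deconvolution model.
#'
#' @param truth a [program_truth()].
#' @param seed integer seed.
#' @return list of class `spot_dataset`: `counts` (spots x genes, sparse),
#'   `spots` (spot_id, x, y, annotation), `abundance` (spots x cell types),
#'   and `truth` augmented with the drawn `programs`, `usage`, `lib_sizes`,
#'   `abundance_mean`.
#' @export
generate_spot_dataset <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "program_truth"))
  K <- truth$k_true; G <- truth$n_genes; S <- truth$n_spots
  .with_seed(seed, {
    prog <- matrix(stats::rgamma(K * G, shape = 0.3, rate = 1), K, G)
    block <- if (K == 1L) list(seq_len(G)) else
      split(seq_len(G), cut(seq_len(G), K, labels = FALSE))
    for (k in seq_len(K)) {
      prog[k, block[[k]]] <- prog[k, block[[k]]] +
        stats::rgamma(length(block[[k]]), shape = 4, rate = 0.5)
    }
    prog <- prog / rowSums(prog)
    u <- matrix(stats::rgamma(S * K, shape = 0.3, rate = 1), S, K)
    u <- u / rowSums(u)
    lib <- stats::rlnorm(S, log(truth$lib_size_mean), 0.3)
    mu <- lib * (u %*% prog)
    counts <- if (truth$noise == "poisson") {
      matrix(stats::rpois(length(mu), as.vector(mu)), S, G)
    } else {
      matrix(stats::rnbinom(length(mu), size = truth$dispersion,
                            mu = as.vector(mu)), S, G)
    }
    dimnames(counts) <- list(sprintf("spot%04d", seq_len(S)),
                             sprintf("gene%04d", seq_len(G)))
    # hexagonal-like grid
    ncol_grid <- ceiling(sqrt(S))
    row_i <- (seq_len(S) - 1L) %/% ncol_grid
    col_i <- (seq_len(S) - 1L) %% ncol_grid
    xs <- col_i + ifelse(row_i %% 2L == 1L, 0.5, 0)
    ys <- row_i * sqrt(3) / 2
    ann <- sample(c("stroma", "epithelium", "other"), S, replace = TRUE,
                  prob = c(0.5, 0.4, 0.1))
    Tn <- truth$n_cell_types
    load <- matrix(stats::rgamma(Tn * K, shape = 1, rate = 1), Tn, K)
    ab_mean <- 8 * (u %*% t(load)) / mean(load)
    abundance <- matrix(stats::rpois(length(ab_mean), as.vector(ab_mean)),
                        S, Tn)
    dimnames(abundance) <- list(rownames(counts),
                                sprintf("celltype%d", seq_len(Tn)))
    truth$programs <- prog
    truth$usage <- u
    truth$lib_sizes <- lib
    truth$abundance_mean <- ab_mean
    structure(list(
      counts = Matrix::Matrix(counts, sparse = TRUE),
      spots = data.frame(spot_id = rownames(counts), x = xs, y = ys,
                         annotation = ann),
      abundance = abundance, truth = truth, seed = seed),
      class = "spot_dataset")
  })
}

#' Write a spot dataset as MatrixMarket + TSV/CSV files
#'
#' Counts are written gene x spot (features as rows) as `matrix.mtx` with
#' `features.tsv` and `barcodes.tsv`; abundances and spot annotations as
#' CSV.
#'
#' @param dataset a [generate_spot_dataset()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_spot_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "spot_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(dataset$counts), file.path(dir, "matrix.mtx"))
  writeLines(colnames(dataset$counts), file.path(dir, "features.tsv"))
  writeLines(rownames(dataset$counts), file.path(dir, "barcodes.tsv"))
  utils::write.csv(cbind(spot_id = rownames(dataset$abundance),
                         as.data.frame(dataset$abundance)),
                   file.path(dir, "abundance.csv"), row.names = FALSE)
  utils::write.csv(dataset$spots, file.path(dir, "spots.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a spot x gene count matrix from MatrixMarket + TSV files
#'
#' @param dir directory holding `matrix.mtx` (gene x spot), `features.tsv`,
#'   `barcodes.tsv`.
#' @return sparse spot x gene matrix with dimnames.
#' @export
read_spot_counts <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- readLines(file.path(dir, "features.tsv"))
  bars <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(m) != length(feats) || ncol(m) != length(bars)) {
    stop("matrix dimensions do not match features/barcodes", call. = FALSE)
  }
  dimnames(m) <- list(feats, bars)
  Matrix::t(m)
}

#' Specify planted transcription-factor activities and regulons
#'
#' @param n_tfs number of transcription factors.
#' @param targets_per_tf targets per regulon (`>= 1`).
#' @param effect mean absolute effect of a unit of TF activity on a target.
#' @param noise_sd residual expression noise sd.
#' @param prop_repressed probability a target has mode of regulation -1.
#' @param confidence_probs sampling weights over confidence classes A..E.
#' @return list of class `regulon_truth`.
#' @export
regulon_truth <- function(n_tfs = 5L, targets_per_tf = 20L, effect = 1,
                          noise_sd = 0.5, prop_repressed = 0.2,
                          confidence_probs = c(A = 0.3, B = 0.25, C = 0.25,
                                               D = 0.1, E = 0.1)) {
  if (targets_per_tf < 1) stop("each regulon needs >= 1 target", call. = FALSE)
  .check_positive(noise_sd, "noise_sd", strict = FALSE)
  .check_prob(prop_repressed, "prop_repressed")
  stopifnot(identical(names(confidence_probs), c("A", "B", "C", "D", "E")))
  structure(list(n_tfs = n_tfs, targets_per_tf = targets_per_tf,
                 effect = effect, noise_sd = noise_sd,
                 prop_repressed = prop_repressed,
                 confidence_probs = confidence_probs),
            class = "regulon_truth")
}

#' Generate target-gene expression driven by planted TF activities
#'
#' Per-cell TF activities are standard normal; each target gene's expression
#' is `baseline + mode * effect * activity + Gaussian noise`. The regulon
#' table follows the (tf, confidence, target, mor) schema.
#'
#' @param truth a [regulon_truth()].
#' @param n_cells number of cells (`>= 2`).
#' @param seed integer seed.
#' @return list of class `regulon_dataset`: `expr` (cells x genes),
#'   `regulons` (data.frame tf/confidence/target/mor), `truth` augmented
#'   with the planted `activity` (TF x cell) matrix.
#' @export
generate_regulon_dataset <- function(truth, n_cells, seed = 1L) {
  stopifnot(inherits(truth, "regulon_truth"))
  if (n_cells < 2) stop("'n_cells' must be >= 2", call. = FALSE)
  .with_seed(seed, {
    tfs <- sprintf("TF%02d", seq_len(truth$n_tfs))
    activity <- matrix(stats::rnorm(truth$n_tfs * n_cells),
                       truth$n_tfs, n_cells,
                       dimnames = list(tfs, sprintf("cell%04d",
                                                    seq_len(n_cells))))
    reg <- do.call(rbind, lapply(seq_along(tfs), function(i) {
      data.frame(
        tf = tfs[i],
        confidence = sample(names(truth$confidence_probs),
                            truth$targets_per_tf, replace = TRUE,
                            prob = truth$confidence_probs),
        target = sprintf("%s_target%02d", tfs[i],
                         seq_len(truth$targets_per_tf)),
        mor = ifelse(stats::runif(truth$targets_per_tf) <
                       truth$prop_repressed, -1, 1))
    }))
    eff <- stats::runif(nrow(reg), 0.5, 1.5) * truth$effect
    baseline <- stats::rnorm(nrow(reg), 5, 1)
    expr <- sapply(seq_len(nrow(reg)), function(j) {
      baseline[j] + reg$mor[j] * eff[j] * activity[reg$tf[j], ] +
        stats::rnorm(n_cells, sd = truth$noise_sd)
    })
    colnames(expr) <- reg$target
    rownames(expr) <- colnames(activity)
    truth$activity <- activity
    truth$effect_sizes <- eff
    structure(list(expr = expr, regulons = reg, truth = truth, seed = seed),
              class = "regulon_dataset")
  })
}

#' Write a regulon table to TSV
#'
#' @param regulons data.frame with columns tf, confidence, target, mor.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regulon_table <- function(regulons, path) {
  need <- c("tf", "confidence", "target", "mor")
  stopifnot(all(need %in% names(regulons)))
  utils::write.table(regulons[need], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a regulon table from TSV
#'
#' @param path TSV with columns tf, confidence, target, mor.
#' @return data.frame.
#' @export
read_regulon_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tf", "confidence", "target", "mor")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("regulon table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(d$mor %in% c(-1, 1))) stop("'mor' must be +1 or -1", call. = FALSE)
  d
}
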