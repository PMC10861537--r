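.caf_markers <- c("FAP", "CD29", "SMA", "FSP1")
.caf_populations <- c("CAF-S1", "CAF-S2", "CAF-S3", "CAF-S4")
.activated_populations <- c("CAF-S1", "CAF-S4")

#' Learn per-marker quartile thresholds from a reference distribution
#'
#' The CAF decision tree cuts each marker's H-score at the first quartile,
#' median and third quartile of a learning distribution. Quantiles use linear
#' interpolation between order statistics (`stats::quantile` type 7), so
#' thresholds are deterministic and invariant to the order of the values.
#'
#' @param reference either a named list/data.frame of numeric H-score vectors
#'   (one element per marker) or a long data.frame with columns `marker` and
#'   `hscore`.
#' @param markers markers that must be present (default FAP, CD29, SMA, FSP1).
#' @param provenance free-text identifier of the learning set.
#' @return object of class `caf_thresholds`: a named list with one
#'   `c(q1, median, q3)` vector per marker plus a `provenance` attribute.
#' @export
learn_thresholds <- function(reference, markers = .caf_markers,
                             provenance = "unspecified") {
  if (is.data.frame(reference) && all(c("marker", "hscore") %in% names(reference))) {
    reference <- split(reference$hscore, reference$marker)
  }
  if (!is.list(reference)) {
    stop("'reference' must be a named list of values or a marker/hscore data.frame",
         call. = FALSE)
  }
  miss <- setdiff(markers, names(reference))
  if (length(miss)) {
    stop("missing marker(s) in reference: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  th <- lapply(markers, function(m) {
    v <- reference[[m]]
    if (length(v) < 4L || anyNA(v)) {
      stop(sprintf("marker '%s' needs >= 4 complete values", m), call. = FALSE)
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(q1 = q[1], median = q[2], q3 = q[3])
  })
  names(th) <- markers
  structure(th, provenance = provenance, class = "caf_thresholds")
}

#' @export
print.caf_thresholds <- function(x, ...) {
  cat("CAF marker thresholds (", attr(x, "provenance"), ")\n", sep = "")
  print(do.call(rbind, unclass(x)))
  invisible(x)
}

#' Code an H-score into a Neg/Low/Med/High level
#'
#' Cut points are inclusive on the upper side: a value equal to a threshold
#' takes the higher level (value >= q3 is High, >= median is Med, >= q1 is
#' Low, else Neg).
#'
#' @param hscore numeric H-score(s).
#' @param thresholds `c(q1, median, q3)` for the marker, or a
#'   `caf_thresholds` object together with `marker`.
#' @param marker marker name when `thresholds` is a `caf_thresholds` object.
#' @return factor with levels Neg < Low < Med < High.
#' @export
code_levels <- function(hscore, thresholds, marker = NULL) {
  if (inherits(thresholds, "caf_thresholds")) {
    if (is.null(marker)) stop("supply 'marker' with a caf_thresholds object", call. = FALSE)
    thresholds <- thresholds[[marker]]
  }
  stopifnot(length(thresholds) == 3L, !is.unsorted(thresholds))
  lev <- ifelse(hscore >= thresholds[3], "High",
         ifelse(hscore >= thresholds[2], "Med",
         ifelse(hscore >= thresholds[1], "Low", "Neg")))
  factor(lev, levels = c("Neg", "Low", "Med", "High"), ordered = TRUE)
}

#' Classify one tumor into a CAF population by the decision tree
#'
#' Decision tree over the four marker H-scores, using learned quartile
#' thresholds:
#' 1. FAP >= median(FAP): **CAF-S1** (FAP is the CAF-S1-specific marker);
#' 2. else SMA >= q3(SMA) and CD29 >= median(CD29): **CAF-S4**;
#' 3. else FSP1 >= median(FSP1): **CAF-S3**;
#' 4. else: **CAF-S2**.
#'
#' With `cd29_rule = "tiebreak"` the CD29 condition in step 2 is dropped
#' (SMA alone decides) and CD29 only breaks the case where SMA sits exactly
#' at its q3 cut.
#'
#' @param hscores named numeric vector with entries FAP, CD29, SMA, FSP1.
#' @param thresholds a `caf_thresholds` object.
#' @param cd29_rule `"and"` (default) or `"tiebreak"`; see Details.
#' @return list of class `caf_call`: `population`, `levels` (per-marker
#'   Neg/Low/Med/High codes), `activated` (population is CAF-S1 or CAF-S4).
#' @export
classify_sample <- function(hscores, thresholds, cd29_rule = c("and", "tiebreak")) {
  cd29_rule <- match.arg(cd29_rule)
  stopifnot(inherits(thresholds, "caf_thresholds"))
  miss <- setdiff(.caf_markers, names(hscores))
  if (length(miss)) {
    stop("missing marker(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  th <- function(m, q) thresholds[[m]][[q]]
  pop <- if (hscores[["FAP"]] >= th("FAP", "median")) {
    "CAF-S1"
  } else {
    sma_high <- hscores[["SMA"]] >= th("SMA", "q3")
    cd29_ok <- switch(cd29_rule,
      and = hscores[["CD29"]] >= th("CD29", "median"),
      tiebreak = hscores[["SMA"]] > th("SMA", "q3") ||
        hscores[["CD29"]] >= th("CD29", "median"))
    if (sma_high && cd29_ok) {
      "CAF-S4"
    } else if (hscores[["FSP1"]] >= th("FSP1", "median")) {
      "CAF-S3"
    } else {
      "CAF-S2"
    }
  }
  levels <- vapply(.caf_markers, function(m) {
    as.character(code_levels(hscores[[m]], thresholds[[m]]))
  }, character(1))
  structure(
    list(population = pop, levels = levels,
         activated = pop %in% .activated_populations),
    class = "caf_call")
}

#' Classify every sample of a cohort table
#'
#' @param data long data.frame with columns `patient_id`, `timepoint`,
#'   `marker`, `hscore` (extra markers are ignored), or a wide data.frame
#'   with one column per marker plus `patient_id` and `timepoint`.
#' @param thresholds a `caf_thresholds` object; if `NULL`, thresholds are
#'   learned from this cohort's own pooled H-scores (quantile matching when
#'   no external learning set is available).
#' @param cd29_rule passed to [classify_sample()].
#' @return data.frame with one row per (patient, timepoint): `patient_id`,
#'   `timepoint`, `population`, `activated`, and `FAP`/`CD29`/`SMA`/`FSP1`
#'   level codes.
#' @export
classify_cohort <- function(data, thresholds = NULL,
                            cd29_rule = c("and", "tiebreak")) {
  cd29_rule <- match.arg(cd29_rule)
  if (all(c("marker", "hscore") %in% names(data))) {
    data <- data[data$marker %in% .caf_markers, , drop = FALSE]
    wide <- stats::reshape(
      data[c("patient_id", "timepoint", "marker", "hscore")],
      idvar = c("patient_id", "timepoint"), timevar = "marker",
      direction = "wide")
    names(wide) <- sub("^hscore\\.", "", names(wide))
  } else {
    wide <- data
  }
  miss <- setdiff(.caf_markers, names(wide))
  if (length(miss)) {
    stop("missing marker(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(thresholds)) {
    pooled <- lapply(wide[.caf_markers], function(v) v)
    thresholds <- learn_thresholds(pooled, provenance = "cohort self-quantiles")
  }
  calls <- lapply(seq_len(nrow(wide)), function(i) {
    hs <- unlist(wide[i, .caf_markers])
    cl <- classify_sample(hs, thresholds, cd29_rule)
    data.frame(patient_id = wide$patient_id[i],
               timepoint = wide$timepoint[i],
               population = cl$population, activated = cl$activated,
               t(cl$levels), check.names = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Cohort repartition of CAF populations before/after treatment
#'
#' Tabulates population calls per timepoint and collapses them into the
#' activated (CAF-S1/CAF-S4) versus normal-like (CAF-S2/CAF-S3) 2x2 table
#' used to test whether chemotherapy shifts tumors away from activated CAF
#' states.
#'
#' @param calls data.frame from [classify_cohort()] (columns `timepoint`,
#'   `population`).
#' @return list with `counts` (timepoint x population), `percentages` (rows
#'   sum to 100), and `activated_2x2` (rows before/after, columns
#'   activated/normal_like), suitable for [fisher_exact_2x2()].
#' @export
cohort_repartition <- function(calls) {
  stopifnot(all(c("timepoint", "population") %in% names(calls)))
  tp <- factor(calls$timepoint, levels = c("before", "after"))
  pop <- factor(calls$population, levels = .caf_populations)
  counts <- table(timepoint = tp, population = pop)
  pct <- prop.table(counts, margin = 1) * 100
  act <- factor(ifelse(calls$population %in% .activated_populations,
                       "activated", "normal_like"),
                levels = c("activated", "normal_like"))
  two <- table(timepoint = tp, state = act)
  list(counts = counts, percentages = pct, activated_2x2 = unclass(two))
}
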