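#' Histological score (H-score) from staining intensity and percent positivity
#'
#' The H-score of a marker in a tissue compartment is the ordinal staining
#' intensity multiplied by the percentage of stained cells. With intensity on
#' a 0--4 scale and percentages on 0--100, scores range over 0--400. The more
#' common 0--3 intensity convention (max 300) can be selected via
#' `max_intensity`.
#'
#' @param intensity staining intensity, in `[0, max_intensity]`. Non-integer
#'   values are accepted (e.g. intensities averaged across fields).
#' @param pct_stained percentage of stained cells, in `[0, 100]`. Fractions in
#'   `[0, 1]` are *not* rescaled; percentages are required.
#' @param max_intensity top of the intensity scale (default 4).
#' @return numeric H-score(s) in `[0, 100 * max_intensity]`.
#' @examples
#' compute_hscore(4, 100)  # 400
#' compute_hscore(3, 50)   # 150
#' @export
compute_hscore <- function(intensity, pct_stained, max_intensity = 4) {
  .check_range(intensity, 0, max_intensity, "intensity")
  .check_range(pct_stained, 0, 100, "pct_stained")
  intensity * pct_stained
}

#' Nuclear-localization score
#'
#' Combines the percentage of marker-positive cells showing nuclear staining
#' with the percentage of positive cells among all cells of the class:
#' `pct_nuclear_among_positive * pct_positive_among_total / 100`, yielding a
#' score in `[0, 100]`. Used for nuclear YAP1 in CAFs and in cancer cells.
#'
#' @param pct_nuclear_among_positive percentage of positive cells with nuclear
#'   staining, 0--100.
#' @param pct_positive_among_total percentage of positive cells among all
#'   cells of the class, 0--100.
#' @return numeric score(s) in `[0, 100]`.
#' @examples
#' compute_nuclear_score(50, 80)  # 40
#' @export
compute_nuclear_score <- function(pct_nuclear_among_positive,
                                  pct_positive_among_total) {
  .check_range(pct_nuclear_among_positive, 0, 100, "pct_nuclear_among_positive")
  .check_range(pct_positive_among_total, 0, 100, "pct_positive_among_total")
  pct_nuclear_among_positive * pct_positive_among_total / 100
}

#' Tumor-infiltrating lymphocyte density
#'
#' Cell count divided by evaluated area, in cells per mm^2. When counts come
#' from several representative fields, pass the total count over the summed
#' field area (e.g. five fields of 0.105 mm^2 give 0.525 mm^2); density is
#' invariant to how a count is split across fields.
#'
#' @param count number of cells (CD3+, CD8+ or FOXP3+), `>= 0`.
#' @param area_mm2 evaluated area in mm^2, `> 0`. Either the total section
#'   area or a single compartment's (stromal/epithelial) area, depending on
#'   which normalization is wanted.
#' @return density in cells/mm^2.
#' @examples
#' compute_til_density(21, 5 * 0.105)  # 40
#' @export
compute_til_density <- function(count, area_mm2) {
  .check_positive(count, "count", strict = FALSE)
  .check_positive(area_mm2, "area_mm2", strict = TRUE)
  count / area_mm2
}

#' Paired before/after delta scores
#'
#' For each patient and variable with exactly one measurement before and one
#' after treatment, the delta score is `value_after - value_before`. A
#' positive delta means the variable increased under chemotherapy.
#'
#' @param data data.frame with columns `patient_id`, `timepoint` (values
#'   `"before"`/`"after"`) and the value column, plus any grouping columns.
#' @param value name of the value column (default `"hscore"`).
#' @param by character vector of columns that, together with `patient_id`,
#'   identify one variable (default `c("marker", "compartment")`, using
#'   whichever of those are present).
#' @return data.frame with one row per patient x variable: the `by` columns,
#'   `patient_id`, `value_before`, `value_after`, `delta`.
#' @examples
#' d <- data.frame(patient_id = "P1", timepoint = c("before", "after"),
#'                 marker = "FAP", hscore = c(150, 100))
#' compute_delta(d, by = "marker")$delta  # -50
#' @export
compute_delta <- function(data, value = "hscore",
                          by = c("marker", "compartment")) {
  stopifnot(is.data.frame(data))
  need <- c("patient_id", "timepoint", value)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  by <- intersect(by, names(data))
  if (!all(data$timepoint %in% c("before", "after"))) {
    stop("'timepoint' must be 'before' or 'after'", call. = FALSE)
  }
  key <- do.call(paste, c(data[c("patient_id", by)], sep = "\r"))
  split_idx <- split(seq_len(nrow(data)), key)
  rows <- lapply(split_idx, function(idx) {
    tp <- data$timepoint[idx]
    if (sum(tp == "before") != 1L || sum(tp == "after") != 1L) {
      have <- paste(sort(tp), collapse = ", ")
      id <- data$patient_id[idx[1]]
      stop(sprintf(
        "patient '%s' (%s) needs exactly one 'before' and one 'after'; has: %s",
        id, paste(unlist(data[idx[1], by, drop = FALSE]), collapse = "/"),
        have), call. = FALSE)
    }
    out <- data[idx[1], c("patient_id", by), drop = FALSE]
    out$value_before <- data[[value]][idx[tp == "before"]]
    out$value_after <- data[[value]][idx[tp == "after"]]
    out$delta <- out$value_after - out$value_before
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$patient_id), , drop = FALSE]
}
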