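#' Build a perception-expectation gap report from AP/AE trapezoids
#'
#' Defuzzifies the average perception (AP) and average expectation (AE)
#' trapezoids of each row into crisp `P` and `E` and takes `gap = P - E`.
#' The gap is computed on unrounded values; `*_reported` columns carry the
#' half-away-from-zero roundings used for presentation. Taking the gap after
#' defuzzification is equivalent, by linearity, to defuzzifying the fuzzy
#' difference AP - AE.
#'
#' @param AP,AE `n x 4` matrices of trapezoids (congruent rownames/order).
#' @param ids Row identifiers; defaults to `rownames(AP)`.
#' @param names Optional human-readable names.
#' @param l Optional effective respondent counts (carried through).
#' @param digits Decimals for the reported columns (default 3).
#' @return A data frame of class `"gap_report"`: `id`, `name`, AP/AE
#'   components (`ap_a..ap_d`, `ae_a..ae_d`), full-precision `P`, `E`,
#'   `gap`, and `P_reported`, `E_reported`, `gap_reported`.
#' @seealso [indicator_gaps()] for the full pipeline from raw survey rows.
#' @export
gap_report <- function(AP, AE, ids = rownames(AP), names = NULL, l = NULL,
                       digits = 3) {
  AP <- tfn_matrix(AP); AE <- tfn_matrix(AE)
  if (nrow(AP) != nrow(AE))
    stop("AP and AE must have the same number of rows", call. = FALSE)
  if (is.null(ids)) ids <- paste0("row_", seq_len(nrow(AP)))
  P <- defuzzify(AP); E <- defuzzify(AE)
  gap <- P - E
  out <- data.frame(id = ids,
                    name = if (is.null(names)) ids else names,
                    stringsAsFactors = FALSE)
  out[paste0("ap_", c("a", "b", "c", "d"))] <- AP
  out[paste0("ae_", c("a", "b", "c", "d"))] <- AE
  out$P <- P; out$E <- E; out$gap <- gap
  out$P_reported <- round_half_up(P, digits)
  out$E_reported <- round_half_up(E, digits)
  out$gap_reported <- round_half_up(gap, digits)
  if (!is.null(l)) out$l <- l
  rownames(out) <- NULL
  class(out) <- c("gap_report", "data.frame")
  out
}

#' @export
print.gap_report <- function(x, ...) {
  cat("<gap report> ", nrow(x), " rows\n", sep = "")
  show <- data.frame(id = x$id, P = x$P_reported, E = x$E_reported,
                     gap = x$gap_reported)
  print(show, row.names = FALSE)
  invisible(x)
}

#' Perception-expectation gaps per indicator
#'
#' The full evaluation pipeline on raw survey rows: encode every answer,
#' average into AP/AE per indicator ([survey_means()]), defuzzify, and
#' report `gap = P - E`. Indicators are ordered and labelled by the supplied
#' hierarchy when given.
#'
#' @param survey Long-form survey data frame (see [survey_means()]).
#' @param hierarchy Optional [indicator_hierarchy()] restricting and
#'   ordering the report rows; surveys must cover all its indicators.
#' @param termsets Named list of [linguistic_termset()]s.
#' @param missing Missing-data policy, see [survey_means()].
#' @param digits Report rounding, see [gap_report()].
#' @return A `"gap_report"` data frame, one row per indicator.
#' @examples
#' spec <- simulation_spec(seed = 7, n_respondents = 40)
#' rep <- indicator_gaps(generate_survey(spec))
#' head(rep$gap_reported)
#' @export
indicator_gaps <- function(survey, hierarchy = NULL,
                           termsets = default_termsets(),
                           missing = "strict", digits = 3) {
  sm <- survey_means(survey, termsets, missing = missing)
  ids <- rownames(sm$AP)
  nm <- NULL
  if (!is.null(hierarchy)) {
    stopifnot(inherits(hierarchy, "indicator_hierarchy"))
    want <- hierarchy$indicators$indicator_id
    miss <- setdiff(want, ids)
    if (length(miss))
      stop("survey lacks indicator(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    sel <- match(want, ids)
    sm$AP <- sm$AP[sel, , drop = FALSE]
    sm$AE <- sm$AE[sel, , drop = FALSE]
    sm$l <- sm$l[sel]
    ids <- want
    nm <- hierarchy$indicators$name
  }
  gap_report(sm$AP, sm$AE, ids = ids, names = nm, l = sm$l, digits = digits)
}

#' Roll indicator gaps up to dimensions
#'
#' Dimension-level AP and AE are the unweighted componentwise means of the
#' dimension's sub-indicator AP/AE trapezoids; P, E and the gap then follow
#' by defuzzification as for indicators.
#'
#' @param report A `"gap_report"` over indicators.
#' @param hierarchy An [indicator_hierarchy()] whose indicator ids match the
#'   report's `id` column.
#' @param digits Report rounding.
#' @return A `"gap_report"` with one row per dimension.
#' @export
dimension_rollup <- function(report, hierarchy, digits = 3) {
  stopifnot(inherits(hierarchy, "indicator_hierarchy"))
  if (!all(hierarchy$indicators$indicator_id %in% report$id))
    stop("report lacks rows for some indicators in the hierarchy",
         call. = FALSE)
  dims <- hierarchy$dimensions
  apc <- paste0("ap_", c("a", "b", "c", "d"))
  aec <- paste0("ae_", c("a", "b", "c", "d"))
  AP <- AE <- matrix(NA_real_, nrow(dims), 4L)
  for (i in seq_len(nrow(dims))) {
    sub_ids <- hierarchy$indicators$indicator_id[
      hierarchy$indicators$dimension_id == dims$id[i]]
    if (!length(sub_ids)) stop("dimension '", dims$id[i], "' is empty",
                               call. = FALSE)
    rows <- report[match(sub_ids, report$id), ]
    AP[i, ] <- colMeans(as.matrix(rows[apc]))
    AE[i, ] <- colMeans(as.matrix(rows[aec]))
  }
  gap_report(AP, AE, ids = dims$id, names = dims$name, digits = digits)
}

#' Rank key factors by most negative gap
#'
#' Sorts report rows by ascending reported gap (most negative — the largest
#' shortfall of perception below expectation — first). Ranking uses the
#' reported (rounded) gaps, with ties broken by row id, which is the reading
#' under which the published key-factor list is reproduced; positive gaps
#' are strengths and rank last.
#'
#' @param report A `"gap_report"`.
#' @param k Number of rows to return; if larger than the report, all rows
#'   are returned with a warning.
#' @return The top-`k` rows as a data frame `id`, `name`, `gap_reported`,
#'   `gap`, ordered worst-first.
#' @examples
#' t6 <- load_fixture("table6_subindicators")
#' rep <- gap_report(as.matrix(t6[, 5:8]), as.matrix(t6[, 9:12]),
#'                   ids = t6$indicator_code)
#' rank_key_factors(rep, 5)$id
#' @export
rank_key_factors <- function(report, k = 5) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(report)) {
    warning("k exceeds the number of rows; returning all ", nrow(report),
            call. = FALSE)
    k <- nrow(report)
  }
  ord <- order(report$gap_reported, report$id)
  out <- as.data.frame(report)[ord[seq_len(k)],
                               c("id", "name", "gap_reported", "gap")]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}
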