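#' Indicator hierarchy
#'
#' The evaluation index system: dimensions, each holding an ordered list of
#' sub-indicators. Dimension order is the order of first appearance in
#' `indicators`.
#'
#' @param indicators A data frame with columns `indicator_id`, `name`,
#'   `dimension_id` and optionally `dimension_name`.
#' @return An object of class `"indicator_hierarchy"` with fields
#'   `dimensions` (data frame `id`, `name`) and `indicators` (data frame
#'   `indicator_id`, `name`, `dimension_id`).
#' @examples
#' h <- load_fixture("initial_hierarchy")
#' h
#' @export
indicator_hierarchy <- function(indicators) {
  need <- c("indicator_id", "name", "dimension_id")
  if (!all(need %in% names(indicators)))
    stop("indicators needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  indicators <- as.data.frame(indicators, stringsAsFactors = FALSE)
  if (anyDuplicated(indicators$indicator_id))
    stop("duplicated indicator ids", call. = FALSE)
  dim_ids <- unique(indicators$dimension_id)
  dim_names <- if ("dimension_name" %in% names(indicators)) {
    vapply(dim_ids, function(d)
      indicators$dimension_name[match(d, indicators$dimension_id)],
      character(1))
  } else dim_ids
  structure(list(
    dimensions = data.frame(id = dim_ids, name = unname(dim_names),
                            stringsAsFactors = FALSE),
    indicators = indicators[, need]
  ), class = "indicator_hierarchy")
}

#' @export
print.indicator_hierarchy <- function(x, ...) {
  cat("<indicator hierarchy> ", nrow(x$indicators), " indicators in ",
      nrow(x$dimensions), " dimensions\n", sep = "")
  for (i in seq_len(nrow(x$dimensions))) {
    sub <- x$indicators[x$indicators$dimension_id == x$dimensions$id[i], ]
    cat("  ", x$dimensions$name[i], " (", nrow(sub), "): ",
        paste(sub$name, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Positional codes for an optimized hierarchy
#'
#' Assigns codes `C<i><j>` (dimension position i, indicator position j
#' within the dimension) to every indicator, following dimension order.
#' These are the row labels used by the case-study report tables.
#'
#' @param hierarchy An [indicator_hierarchy()].
#' @return A data frame `indicator_id`, `code`, `dimension_code`, `name`.
#' @export
hierarchy_codes <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "indicator_hierarchy"))
  out <- do.call(rbind, lapply(seq_len(nrow(hierarchy$dimensions)), function(i) {
    sub <- hierarchy$indicators[
      hierarchy$indicators$dimension_id == hierarchy$dimensions$id[i], ]
    data.frame(indicator_id = sub$indicator_id,
               code = paste0("C", i, seq_len(nrow(sub))),
               dimension_code = paste0("C", i),
               name = sub$name, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Validate a long-form linguistic cell table and encode each row.
# df needs columns set_id, m, n (or prefixed variants); returns n x 4 matrix.
encode_cells <- function(set_id, m, n, termsets) {
  if (!all(set_id %in% names(termsets)))
    stop("unknown term set id(s): ",
         paste(setdiff(unique(set_id), names(termsets)), collapse = ", "),
         call. = FALSE)
  out <- matrix(NA_real_, length(set_id), 4L,
                dimnames = list(NULL, c("a", "b", "c", "d")))
  for (sid in unique(set_id)) {
    sel <- set_id == sid
    set <- termsets[[sid]]
    top <- termset_max_index(set)
    mm <- as.integer(m[sel]); nn <- as.integer(n[sel])
    if (anyNA(mm) || anyNA(nn) || any(mm < 0L) || any(mm > nn) || any(nn > top))
      stop("invalid term indices on set '", sid, "'", call. = FALSE)
    out[sel, ] <- encode_indices(mm, nn, set$T)
  }
  out
}

check_complete_grid <- function(df, unit_col, what) {
  tab <- table(df[[unit_col]], df$indicator_id)
  if (any(tab != 1L))
    stop(what, " must be a complete grid: every ", unit_col,
         " rates every indicator exactly once", call. = FALSE)
  invisible(TRUE)
}

#' Aggregate an expert importance panel
#'
#' Computes the weighted average encoded trapezoid of each indicator over an
#' expert panel: encode every cell with its own term set's granularity, then
#' take the weighted componentwise mean
#' `sum_k w_k * V_k / sum_k w_k`. With equal crisp weights this reduces
#' exactly to the componentwise mean [tfn_mean()]. Crisp weights preserve
#' ordering, so the result rows are valid trapezoids.
#'
#' @param ratings Long-form data frame with columns `expert_id`,
#'   `indicator_id`, `set_id`, `m`, `n` and optionally `weight` (one crisp
#'   non-negative weight per expert, constant across that expert's rows).
#'   Every expert must rate every indicator exactly once.
#' @param termsets Named list of [linguistic_termset()]s keyed by `set_id`.
#' @return An `n_indicators x 4` matrix of averaged trapezoids, rownames =
#'   indicator ids in order of first appearance.
#' @seealso [expert_mean_linguistic()] for fuzzy linguistic weights,
#'   [screen_indicators()] for the screening step that consumes this.
#' @examples
#' spec <- simulation_spec(seed = 1)
#' panel <- generate_expert_panel(spec)
#' head(expert_mean(panel, default_termsets()))
#' @export
expert_mean <- function(ratings, termsets = default_termsets()) {
  need <- c("expert_id", "indicator_id", "set_id", "m", "n")
  if (!all(need %in% names(ratings)))
    stop("ratings needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(ratings) == 0L) stop("empty ratings table", call. = FALSE)
  check_complete_grid(ratings, "expert_id", "expert ratings")

  if ("weight" %in% names(ratings)) {
    w_by_expert <- tapply(ratings$weight, ratings$expert_id,
                          function(w) unique(as.numeric(w)))
    if (any(lengths(w_by_expert) != 1L))
      stop("an expert's weight must be constant across rows", call. = FALSE)
    w <- setNames(as.numeric(w_by_expert), names(w_by_expert))
    if (any(!is.finite(w)) || any(w < 0))
      stop("crisp weights must be finite and >= 0", call. = FALSE)
    if (sum(w) == 0) stop("total expert weight is zero", call. = FALSE)
  } else {
    ids <- unique(ratings$expert_id)
    w <- setNames(rep(1, length(ids)), ids)
  }

  enc <- encode_cells(ratings$set_id, ratings$m, ratings$n, termsets)
  wr <- w[as.character(ratings$expert_id)]
  ind <- factor(ratings$indicator_id, levels = unique(ratings$indicator_id))
  num <- rowsum(enc * wr, ind)
  den <- as.numeric(rowsum(wr, ind))
  out <- num / den
  colnames(out) <- c("a", "b", "c", "d")
  out
}

#' Expert average with fuzzy linguistic weights
#'
#' Evaluates the weighted average literally on the fuzzy scale: each expert's
#' weight is itself a linguistic value, the numerator is the sum of
#' componentwise products weight x rating, and the result is the
#' componentwise quotient by the fuzzy weight sum. Componentwise division
#' does not preserve trapezoid ordering, so each row comes back as a
#' [signed_tuple()]; inspect [is_ordered()] before treating the result as a
#' trapezoid. Provided for completeness — an equal-weight panel should use
#' [expert_mean()], to which this path reduces only approximately.
#'
#' @inheritParams expert_mean
#' @param weights Named list of [linguistic_value()]s, one per expert id.
#' @return A named list of [signed_tuple()]s, one per indicator.
#' @export
expert_mean_linguistic <- function(ratings, weights,
                                   termsets = default_termsets()) {
  need <- c("expert_id", "indicator_id", "set_id", "m", "n")
  if (!all(need %in% names(ratings)))
    stop("ratings needs columns ", paste(need, collapse = ", "), call. = FALSE)
  experts <- unique(as.character(ratings$expert_id))
  if (!all(experts %in% names(weights)))
    stop("missing linguistic weight for expert(s): ",
         paste(setdiff(experts, names(weights)), collapse = ", "),
         call. = FALSE)
  if (!all(vapply(weights, inherits, logical(1), "linguistic_value")))
    stop("weights must be linguistic values; for crisp weights use ",
         "expert_mean()", call. = FALSE)
  check_complete_grid(ratings, "expert_id", "expert ratings")

  wenc <- lapply(weights[experts], encode)
  wsum <- Reduce(`+`, lapply(wenc, tfn_components))
  enc <- encode_cells(ratings$set_id, ratings$m, ratings$n, termsets)
  wmat <- do.call(rbind, lapply(as.character(ratings$expert_id),
                                function(e) tfn_components(wenc[[e]])))
  ind <- factor(ratings$indicator_id, levels = unique(ratings$indicator_id))
  num <- rowsum(enc * wmat, ind)
  out <- lapply(seq_len(nrow(num)), function(i) signed_tuple(num[i, ] / wsum))
  names(out) <- levels(ind)
  if (!all(vapply(out, is_ordered, logical(1))))
    warning("fuzzy-weighted average produced unordered tuples; ",
            "componentwise division does not preserve trapezoid ordering",
            call. = FALSE)
  out
}

#' Aggregate a perception/expectation survey
#'
#' Encodes every respondent's perception and expectation answer and takes
#' the componentwise mean per indicator, yielding the average perception
#' (AP) and average expectation (AE) trapezoids.
#'
#' @param survey Long-form data frame with columns `respondent_id`,
#'   `indicator_id`, `p_set_id`, `p_m`, `p_n`, `e_set_id`, `e_m`, `e_n`.
#' @param termsets Named list of [linguistic_termset()]s.
#' @param missing `"strict"` (default) requires a complete grid;
#'   `"drop"` drops a respondent from an indicator when either answer is
#'   missing (NA), averaging over the remaining answers.
#' @return A list with `AP` and `AE` (`n_indicators x 4` matrices, rownames
#'   = indicator ids) and `l` (named vector of effective respondent counts).
#' @examples
#' spec <- simulation_spec(seed = 1, n_respondents = 25)
#' sm <- survey_means(generate_survey(spec))
#' sm$AP[1:2, ]
#' @export
survey_means <- function(survey, termsets = default_termsets(),
                         missing = c("strict", "drop")) {
  missing <- match.arg(missing)
  need <- c("respondent_id", "indicator_id", "p_set_id", "p_m", "p_n",
            "e_set_id", "e_m", "e_n")
  if (!all(need %in% names(survey)))
    stop("survey needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(survey) == 0L) stop("empty survey table", call. = FALSE)

  has_na <- is.na(survey$p_m) | is.na(survey$p_n) |
    is.na(survey$e_m) | is.na(survey$e_n)
  if (missing == "strict") {
    if (any(has_na)) stop("missing answers; set missing = \"drop\" to drop ",
                          "a respondent per indicator", call. = FALSE)
    check_complete_grid(survey, "respondent_id", "survey")
  } else {
    survey <- survey[!has_na, , drop = FALSE]
    if (nrow(survey) == 0L) stop("no complete answers left", call. = FALSE)
  }

  ind <- factor(survey$indicator_id, levels = unique(survey$indicator_id))
  encP <- encode_cells(survey$p_set_id, survey$p_m, survey$p_n, termsets)
  encE <- encode_cells(survey$e_set_id, survey$e_m, survey$e_n, termsets)
  l <- as.numeric(table(ind))
  AP <- rowsum(encP, ind) / l
  AE <- rowsum(encE, ind) / l
  colnames(AP) <- colnames(AE) <- c("a", "b", "c", "d")
  list(AP = AP, AE = AE, l = setNames(l, levels(ind)))
}

#' Case-study constants
#'
#' The fixed shape of the teleconsultation case study: 5 initial dimensions,
#' 24 initial indicators, 15 equally weighted experts, and 691 collected /
#' 434 valid questionnaires (validity screening happened upstream of the
#' method; only the counts are carried).
#'
#' @return A list with `n_dimensions`, `n_indicators`, `n_experts`,
#'   `questionnaires_collected`, `questionnaires_valid` and the derived
#'   `recovery_rate_pct` (valid/collected, in percent).
#' @examples
#' case_study_profile()$recovery_rate_pct
#' @export
case_study_profile <- function() {
  collected <- 691L
  valid <- 434L
  list(n_dimensions = 5L, n_indicators = 24L, n_experts = 15L,
       questionnaires_collected = collected, questionnaires_valid = valid,
       recovery_rate_pct = 100 * valid / collected)
}
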