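#' Similarity degree between trapezoidal fuzzy numbers
#'
#' The scaled-L1 similarity `1 - (1/4) * sum_h |f_h - M_h|` over the four
#' components. On tuples normalized to `[0, 1]` the value lies in `[0, 1]`,
#' equals 1 iff the tuples are identical, and `1 - similarity` is a metric.
#'
#' @param f,M Fuzzy numbers ([trapezoid()] or length-4 numerics), normally
#'   both normalized to `[0, 1]`.
#' @return Similarity in `[0, 1]` (a warning is raised, and the value may
#'   leave that range, if the inputs are not normalized).
#' @examples
#' s7 <- default_termsets()$seven
#' f1 <- trapezoid(0.206, 0.301, 0.431, 0.527)
#' similarity(f1, encode(linguistic_value(s7, 2)))  # about 0.9642
#' @export
similarity <- function(f, M) {
  fv <- tfn_components(f); Mv <- tfn_components(M)
  if (any(fv < 0 | fv > 1) || any(Mv < 0 | Mv > 1))
    warning("inputs are not normalized to [0, 1]; similarity may leave [0, 1]",
            call. = FALSE)
  1 - sum(abs(fv - Mv)) / 4
}

#' Similarity profile of an indicator against a reference scale
#'
#' Computes the similarity of an aggregated indicator trapezoid to every
#' point term of a reference term set and locates the most similar term.
#' Two or more maxima within `1e-9` of each other are flagged as a tie.
#'
#' @param f Aggregated trapezoid for one indicator.
#' @param reference_set A [linguistic_termset()] supplying the reference
#'   encodings (see [reference_encodings()]).
#' @return A list of class `"similarity_profile"`: `similarities` (named
#'   vector `S0..ST`), `argmax_term` (index of the most similar term),
#'   `tie` (logical).
#' @examples
#' s7 <- default_termsets()$seven
#' similarity_profile(trapezoid(0.810, 0.905, 1, 1), s7)
#' @export
similarity_profile <- function(f, reference_set) {
  refs <- reference_encodings(reference_set)
  fv <- tfn_components(f)
  y <- 1 - rowSums(abs(sweep(refs, 2, fv))) / 4
  amax <- unname(which.max(y)) - 1L
  tie <- sum(y >= max(y) - 1e-9) > 1L
  structure(list(similarities = y, argmax_term = amax, tie = tie),
            class = "similarity_profile")
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat("<similarity profile> argmax S_", x$argmax_term,
      if (x$tie) " (tie)", "\n", sep = "")
  print(round_half_up(x$similarities, 4))
  invisible(x)
}

#' Default screening zones
#'
#' Partition of reference term indices into remove / review / keep zones.
#' For odd granularity the exact midpoint is the review zone and the scale
#' splits symmetrically around it — for the 7-term importance scale,
#' remove = \{0, 1, 2\}, review = \{3\} ("middle"), keep = \{4, 5, 6\}. For
#' even granularity the lower third is removed, the upper third kept, and
#' the middle indices reviewed.
#'
#' @param T Maximum term index of the reference set (granularity - 1), or a
#'   [linguistic_termset()].
#' @return A list with integer vectors `remove`, `review`, `keep` forming a
#'   partition of `0..T`.
#' @examples
#' default_zones(6)
#' @export
default_zones <- function(T) {
  if (inherits(T, "linguistic_termset")) T <- T$T
  T <- as.integer(T)
  if (T < 2L) stop("need at least 3 terms to form zones", call. = FALSE)
  n <- T + 1L
  if (n %% 2L == 1L) {
    mid <- T %/% 2L
    list(remove = 0:(mid - 1L), review = mid, keep = (mid + 1L):T)
  } else {
    lo <- max(1L, n %/% 3L)
    list(remove = 0:(lo - 1L), review = lo:(T - lo), keep = (T - lo + 1L):T)
  }
}

check_zones <- function(zones, T) {
  if (!is.list(zones) || !all(c("remove", "review", "keep") %in% names(zones)))
    stop("zones must be a list with remove, review, keep", call. = FALSE)
  all_idx <- sort(unlist(zones[c("remove", "review", "keep")]))
  if (!identical(as.integer(all_idx), 0:T))
    stop("zones must partition term indices 0..", T, call. = FALSE)
  invisible(TRUE)
}

#' Screening decision for one indicator
#'
#' Maps a similarity profile to a keep / remove / review decision by the
#' zone holding the most similar reference term. A tie at the maximum always
#' yields "review" (human-in-the-loop), regardless of zones.
#'
#' @param profile A [similarity_profile()].
#' @param zones Zone partition, see [default_zones()].
#' @return A list of class `"screening_decision"`: `decision`,
#'   `argmax_term`, `tie`, `rationale`.
#' @export
decide <- function(profile, zones) {
  stopifnot(inherits(profile, "similarity_profile"))
  T <- length(profile$similarities) - 1L
  check_zones(zones, T)
  amax <- profile$argmax_term
  if (profile$tie) {
    decision <- "review"
    rationale <- "tie at maximum similarity; referred to expert review"
  } else {
    decision <- if (amax %in% zones$keep) "keep"
    else if (amax %in% zones$remove) "remove"
    else "review"
    rationale <- sprintf("most similar to reference term S_%d (%s zone)",
                         amax, decision)
  }
  structure(list(decision = decision, argmax_term = amax, tie = profile$tie,
                 rationale = rationale), class = "screening_decision")
}

#' Screen a set of indicators against a reference importance scale
#'
#' For every indicator, computes the similarity of its aggregated trapezoid
#' to each reference term, the most similar term, and the keep / remove /
#' review decision.
#'
#' @param avg An `n x 4` matrix of aggregated indicator trapezoids, rownames
#'   = indicator ids (as returned by [expert_mean()]).
#' @param reference_set A [linguistic_termset()].
#' @param zones Zone partition; defaults to [default_zones()] of the
#'   reference set.
#' @return A data frame with one row per indicator: `indicator_id`, columns
#'   `Y0..YT` (full-precision similarities), `argmax_term`, `tie`,
#'   `decision`. Attribute `reference_set_id` records the scale used.
#' @examples
#' t3 <- load_fixture("table3_expert_trapezoids")
#' avg <- as.matrix(t3[, c("a", "b", "c", "d")])
#' rownames(avg) <- t3$indicator_id
#' scr <- screen_indicators(avg, default_termsets()$seven_importance)
#' table(scr$decision)
#' @export
screen_indicators <- function(avg, reference_set,
                              zones = default_zones(reference_set)) {
  avg <- tfn_matrix(avg)
  if (is.null(rownames(avg)))
    rownames(avg) <- paste0("indicator_", seq_len(nrow(avg)))
  refs <- reference_encodings(reference_set)
  T <- nrow(refs) - 1L
  check_zones(zones, T)

  # n x (T+1) similarity matrix
  Y <- 1 - vapply(seq_len(nrow(refs)), function(j)
    rowSums(abs(sweep(avg, 2, refs[j, ]))), numeric(nrow(avg))) / 4
  Y <- matrix(Y, nrow = nrow(avg))
  amax <- max.col(Y, ties.method = "first") - 1L
  tie <- apply(Y, 1L, function(y) sum(y >= max(y) - 1e-9) > 1L)
  decision <- ifelse(tie, "review",
              ifelse(amax %in% zones$keep, "keep",
              ifelse(amax %in% zones$remove, "remove", "review")))
  out <- data.frame(indicator_id = rownames(avg), Y,
                    argmax_term = amax, tie = tie, decision = decision,
                    stringsAsFactors = FALSE)
  names(out)[2:(T + 2L)] <- paste0("Y", 0:T)
  rownames(out) <- NULL
  attr(out, "reference_set_id") <- reference_set$id
  out
}

#' Merge plan for index-system optimization
#'
#' A declarative description of how reviewed indicators are integrated:
#' lists of indicator merges (several source indicators replaced by one
#' target) and dimension merges. Merges are expert judgement, not
#' computation, so they enter as configuration.
#'
#' @param indicator_merges List of rules, each a list with `sources`
#'   (character vector of indicator ids) and `target` (list `id`, `name`,
#'   `dimension_id`).
#' @param dimension_merges List of rules, each with `sources` (dimension
#'   ids) and `target` (list `id`, `name`).
#' @return An object of class `"merge_plan"`.
#' @seealso [apply_merge_plan()], [read_merge_plan()]
#' @export
merge_plan <- function(indicator_merges = list(), dimension_merges = list()) {
  src <- unlist(lapply(indicator_merges, `[[`, "sources"))
  if (anyDuplicated(src))
    stop("merge sources must be pairwise disjoint across rules", call. = FALSE)
  structure(list(indicator_merges = indicator_merges,
                 dimension_merges = dimension_merges),
            class = "merge_plan")
}

#' Read a merge plan from JSON
#'
#' @param path Path to a JSON file with fields `indicator_merges` and
#'   `dimension_merges` as in [merge_plan()].
#' @return A [merge_plan()].
#' @export
read_merge_plan <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  merge_plan(indicator_merges = raw$indicator_merges %||% list(),
             dimension_merges = raw$dimension_merges %||% list())
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Apply screening decisions and a merge plan to a hierarchy
#'
#' Produces the optimized index system: indicators decided "remove" are
#' dropped, each indicator-merge rule replaces its source indicators with a
#' single target placed at the first source's position, and dimension merges
#' fold dimensions together (target at the first source's position, member
#' indicators kept in order). Merge sources must be keep- or review-zone
#' indicators; a plan touching removed or unknown ids is an error.
#'
#' @param hierarchy An [indicator_hierarchy()].
#' @param decisions Screening report from [screen_indicators()] (or any data
#'   frame with `indicator_id`, `decision`).
#' @param plan A [merge_plan()]; the empty plan leaves non-removed
#'   indicators untouched.
#' @return A new [indicator_hierarchy()] with deterministic ordering.
#' @examples
#' h <- load_fixture("initial_hierarchy")
#' t3 <- load_fixture("table3_expert_trapezoids")
#' avg <- as.matrix(t3[, c("a", "b", "c", "d")]); rownames(avg) <- t3$indicator_id
#' scr <- screen_indicators(avg, default_termsets()$seven_importance)
#' opt <- apply_merge_plan(h, scr, load_fixture("htcc_merge_plan"))
#' nrow(opt$indicators)  # 19
#' @export
apply_merge_plan <- function(hierarchy, decisions, plan = merge_plan()) {
  stopifnot(inherits(hierarchy, "indicator_hierarchy"),
            inherits(plan, "merge_plan"))
  if (!all(c("indicator_id", "decision") %in% names(decisions)))
    stop("decisions needs columns indicator_id, decision", call. = FALSE)
  ind <- hierarchy$indicators
  unknown <- setdiff(decisions$indicator_id, ind$indicator_id)
  if (length(unknown))
    stop("decisions reference unknown indicators: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  removed <- decisions$indicator_id[decisions$decision == "remove"]
  keepers <- decisions$indicator_id[decisions$decision %in% c("keep", "review")]

  for (rule in plan$indicator_merges) {
    src <- unlist(rule$sources)
    bad <- setdiff(src, ind$indicator_id)
    if (length(bad))
      stop("merge plan references unknown indicators: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (any(src %in% removed))
      stop("merge plan references removed indicators: ",
           paste(intersect(src, removed), collapse = ", "), call. = FALSE)
    if (!all(src %in% keepers))
      stop("merge sources must be keep- or review-zone indicators",
           call. = FALSE)
  }

  ind <- ind[!ind$indicator_id %in% removed, , drop = FALSE]

  for (rule in plan$indicator_merges) {
    src <- unlist(rule$sources)
    pos <- match(src, ind$indicator_id)
    first <- min(pos)
    ind$indicator_id[first] <- rule$target$id
    ind$name[first] <- rule$target$name
    ind$dimension_id[first] <- rule$target$dimension_id
    ind <- ind[-setdiff(pos, first), , drop = FALSE]
  }

  dims <- hierarchy$dimensions
  for (rule in plan$dimension_merges) {
    src <- unlist(rule$sources)
    pos <- match(src, dims$id)
    if (anyNA(pos))
      stop("dimension merge references unknown dimensions: ",
           paste(src[is.na(pos)], collapse = ", "), call. = FALSE)
    first <- min(pos)
    dims$id[first] <- rule$target$id
    dims$name[first] <- rule$target$name
    dims <- dims[-setdiff(pos, first), , drop = FALSE]
    ind$dimension_id[ind$dimension_id %in% src] <- rule$target$id
  }
  if (anyDuplicated(dims$id))
    dims <- dims[!duplicated(dims$id), , drop = FALSE]

  empty <- setdiff(dims$id, ind$dimension_id)
  dims <- dims[!dims$id %in% empty, , drop = FALSE]

  # order indicators by dimension position, then original position
  ind <- ind[order(match(ind$dimension_id, dims$id), seq_len(nrow(ind))), ,
             drop = FALSE]
  rownames(ind) <- rownames(dims) <- NULL
  structure(list(dimensions = dims, indicators = ind),
            class = "indicator_hierarchy")
}
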