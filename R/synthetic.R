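#' Specification for a synthetic evaluation study
#'
#' Describes a simulated study with planted structure: an expert panel
#' rating indicator importance on scales of possibly different granularity,
#' and a respondent survey giving paired perception/expectation answers.
#' Planted true levels are indices on the canonical 7-term scale; cells are
#' perturbed by symmetric one-term ordinal noise (clipped to the scale) and
#' occasionally widen to a hesitant interval `[t, t+1]`, the minimal
#' structure-preserving uncertainty model for Likert-type answers.
#'
#' Defaults mirror the case study's shape: 15 equally weighted experts
#' (alternating 7-term and 5-term scales, reflecting rater preference for
#' different granularities), 434 valid respondents (all on the 7-term scale,
#' as in the case survey), 24 indicators in 5 dimensions.
#'
#' @param seed Integer RNG seed; all generation is reproducible given the
#'   spec.
#' @param hierarchy An [indicator_hierarchy()]; defaults to the initial
#'   24-indicator case-study system.
#' @param n_experts,n_respondents Panel and survey sizes.
#' @param expert_granularities Character vector (recycled to `n_experts`) of
#'   term-set ids from `termsets` used by each expert.
#' @param respondent_set Term-set id used by all respondents.
#' @param planted_importance Named integer vector (canonical-scale term
#'   index per indicator id); defaults to a spread over the scale.
#' @param planted_P,planted_E Named integer vectors of true perception and
#'   expectation levels per indicator.
#' @param noise_prob Probability that a cell is perturbed by one term up or
#'   down (before clipping).
#' @param interval_prob Probability that a cell widens to the hesitant
#'   interval `[t, t+1]` (or `[t-1, t]` at the top of the scale).
#' @param termsets Named list of [linguistic_termset()]s.
#' @return An object of class `"simulation_spec"`.
#' @seealso [generate_expert_panel()], [generate_survey()]
#' @export
simulation_spec <- function(seed,
                            hierarchy = load_fixture("initial_hierarchy"),
                            n_experts = 15L,
                            n_respondents = 434L,
                            expert_granularities = c("seven", "five"),
                            respondent_set = "seven",
                            planted_importance = NULL,
                            planted_P = NULL,
                            planted_E = NULL,
                            noise_prob = 0.1,
                            interval_prob = 0.05,
                            termsets = default_termsets()) {
  stopifnot(inherits(hierarchy, "indicator_hierarchy"))
  seed <- as.integer(seed)
  n_experts <- as.integer(n_experts)
  n_respondents <- as.integer(n_respondents)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  if (n_experts < 1L || n_respondents < 1L)
    stop("need at least one expert and one respondent", call. = FALSE)
  if (noise_prob < 0 || noise_prob > 1 || interval_prob < 0 ||
      interval_prob > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)

  ids <- hierarchy$indicators$indicator_id
  canonical_T <- termsets[[respondent_set]]$T
  default_levels <- function(offset) {
    # deterministic spread across the scale so every zone is exercised
    setNames(((seq_along(ids) - 1L + offset) %% (canonical_T + 1L)), ids)
  }
  planted_importance <- planted_importance %||% default_levels(0L)
  planted_P <- planted_P %||% setNames(rep(4L, length(ids)), ids)
  planted_E <- planted_E %||% setNames(rep(5L, length(ids)), ids)
  for (pl in list(planted_importance, planted_P, planted_E)) {
    if (!all(ids %in% names(pl)))
      stop("planted levels must cover every indicator id", call. = FALSE)
    if (any(pl[ids] < 0L | pl[ids] > canonical_T))
      stop("planted levels must be valid canonical-scale indices",
           call. = FALSE)
  }
  gran <- rep_len(expert_granularities, n_experts)
  if (!all(gran %in% names(termsets)))
    stop("unknown expert term-set id(s)", call. = FALSE)
  if (!respondent_set %in% names(termsets))
    stop("unknown respondent term-set id", call. = FALSE)

  structure(list(seed = seed, hierarchy = hierarchy, n_experts = n_experts,
                 n_respondents = n_respondents, expert_granularities = gran,
                 respondent_set = respondent_set, canonical_T = canonical_T,
                 planted_importance = planted_importance[ids],
                 planted_P = planted_P[ids], planted_E = planted_E[ids],
                 noise_prob = noise_prob, interval_prob = interval_prob,
                 termsets = termsets),
            class = "simulation_spec")
}

#' Map a term index between granularities
#'
#' Proportional index scaling with half-up rounding:
#' `round(t * T_to / T_from)`. Used to express a canonical-scale planted
#' level on a rater's own (coarser or finer) scale.
#'
#' @param t Term index (vector) on the source scale.
#' @param from_T,to_T Maximum indices of source and target scales.
#' @return Integer indices on the target scale.
#' @examples
#' map_term(0:6, 6, 4)  # 7-term levels on the 5-term scale
#' @export
map_term <- function(t, from_T, to_T) {
  as.integer(round_half_up(t * to_T / from_T))
}

# Apply the ordinal noise model to a vector of point indices on scale T:
# with prob noise_prob shift one term (random direction), clip to [0, T];
# with prob interval_prob widen to [t, t+1] ([T-1, T] at the top).
perturb_cells <- function(t, T, noise_prob, interval_prob) {
  n <- length(t)
  shift <- ifelse(stats::runif(n) < noise_prob,
                  ifelse(stats::runif(n) < 0.5, -1L, 1L), 0L)
  t <- pmin(pmax(t + shift, 0L), T)
  widen <- stats::runif(n) < interval_prob
  m <- ifelse(widen & t == T, T - 1L, t)
  n_idx <- ifelse(widen, pmin(t + 1L, T), t)
  data.frame(m = as.integer(m), n = as.integer(n_idx))
}

#' Generate a synthetic expert importance panel
#'
#' Each expert rates every indicator on their own term set: the canonical
#' planted level is mapped to the expert's granularity by [map_term()],
#' then ordinal noise and hesitant-interval widening are applied. Weights
#' are equal and crisp. Deterministic given the spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @return A long-form ratings data frame as consumed by [expert_mean()]:
#'   `expert_id`, `indicator_id`, `set_id`, `m`, `n`, `weight`.
#' @examples
#' panel <- generate_expert_panel(simulation_spec(seed = 1, noise_prob = 0))
#' head(panel)
#' @export
generate_expert_panel <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  ids <- names(spec$planted_importance)
  rows <- lapply(seq_len(spec$n_experts), function(k) {
    sid <- spec$expert_granularities[k]
    Tk <- spec$termsets[[sid]]$T
    base <- map_term(spec$planted_importance, spec$canonical_T, Tk)
    mn <- perturb_cells(base, Tk, spec$noise_prob, spec$interval_prob)
    data.frame(expert_id = sprintf("expert_%02d", k), indicator_id = ids,
               set_id = sid, m = mn$m, n = mn$n, weight = 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic perception/expectation survey
#'
#' Each respondent answers every indicator twice (perception and
#' expectation) on the respondent term set, starting from the planted
#' levels, with the same ordinal noise model as the expert panel.
#' Deterministic given the spec's seed (a distinct stream from the panel's).
#'
#' @param spec A [simulation_spec()].
#' @return A long-form survey data frame as consumed by [survey_means()]:
#'   `respondent_id`, `indicator_id`, `p_set_id`, `p_m`, `p_n`, `e_set_id`,
#'   `e_m`, `e_n`.
#' @examples
#' sv <- generate_survey(simulation_spec(seed = 1, n_respondents = 3,
#'                                       noise_prob = 0))
#' head(sv)
#' @export
generate_survey <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed + 1L)

  ids <- names(spec$planted_P)
  Tr <- spec$termsets[[spec$respondent_set]]$T
  baseP <- map_term(spec$planted_P, spec$canonical_T, Tr)
  baseE <- map_term(spec$planted_E, spec$canonical_T, Tr)
  n_ind <- length(ids)
  resp <- sprintf("respondent_%03d", seq_len(spec$n_respondents))

  p <- perturb_cells(rep(baseP, times = spec$n_respondents), Tr,
                     spec$noise_prob, spec$interval_prob)
  e <- perturb_cells(rep(baseE, times = spec$n_respondents), Tr,
                     spec$noise_prob, spec$interval_prob)
  out <- data.frame(respondent_id = rep(resp, each = n_ind),
                    indicator_id = rep(ids, times = spec$n_respondents),
                    p_set_id = spec$respondent_set, p_m = p$m, p_n = p$n,
                    e_set_id = spec$respondent_set, e_m = e$m, e_n = e$n,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
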