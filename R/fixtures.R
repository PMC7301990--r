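#' Packaged case-study fixtures
#'
#' Typed, invariant-checked transcriptions of the teleconsultation
#' case-study inputs and published summary tables shipped under
#' `inst/extdata/`:
#'
#' * `"table3_expert_trapezoids"` — the 24 averaged expert-importance
#'   trapezoids (two printing typos corrected; see the `note` column).
#' * `"table4_similarity"` — the published 24 x 7 similarity table with the
#'   highlighted (argmax) column per row.
#' * `"table5_dimensions"` — published dimension-level AP/AE/P/E/gap rows.
#' * `"table6_subindicators"` — published sub-indicator rows (19, coded
#'   `C11..C43`); `name_source` records whether a row's identity is named in
#'   the study's discussion or inferred positionally.
#' * `"htcc_merge_plan"` — the case study's index-optimization plan as a
#'   [merge_plan()] (alias: `"paper_merge_plan"`).
#' * `"initial_hierarchy"` — the initial 24-indicator / 5-dimension system
#'   as an [indicator_hierarchy()].
#' * `"termset_5"`, `"termset_7"` — the built-in 5- and 7-term scales.
#'
#' @param name Fixture name, one of the above.
#' @return The parsed object; data frames for tables, typed objects
#'   otherwise.
#' @examples
#' nrow(load_fixture("table3_expert_trapezoids"))  # 24
#' load_fixture("table5_dimensions")$gap
#' @export
load_fixture <- function(name) {
  path <- function(f) system.file("extdata", f, package = "mgliqual",
                                  mustWork = TRUE)
  switch(name,
    table3_expert_trapezoids = {
      df <- read.csv(path("table3_expert_trapezoids.csv"),
                     stringsAsFactors = FALSE)
      stopifnot(nrow(df) == 24L,
                all(df$a <= df$b & df$b <= df$c & df$c <= df$d),
                all(df$a >= 0 & df$d <= 1))
      df
    },
    table4_similarity = {
      df <- read.csv(path("table4_similarity.csv"), stringsAsFactors = FALSE)
      stopifnot(nrow(df) == 24L, all(df$argmax_term %in% 0:6))
      df
    },
    table5_dimensions = {
      df <- read.csv(path("table5_dimensions.csv"), stringsAsFactors = FALSE)
      stopifnot(nrow(df) == 4L)
      df
    },
    table6_subindicators = {
      df <- read.csv(path("table6_subindicators.csv"),
                     stringsAsFactors = FALSE)
      stopifnot(nrow(df) == 19L,
                all(df$dimension_code %in% paste0("C", 1:4)))
      df
    },
    htcc_merge_plan = ,
    paper_merge_plan = read_merge_plan(path("htcc_merge_plan.json")),
    initial_hierarchy = indicator_hierarchy(
      read.csv(path("initial_hierarchy.csv"), stringsAsFactors = FALSE)),
    termset_5 = default_termsets()$five,
    termset_7 = default_termsets()$seven,
    stop("unknown fixture '", name, "'", call. = FALSE)
  )
}
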