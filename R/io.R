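#' Read and write the tabular survey dialects
#'
#' Plain CSV (RFC-4180) dialects tying the pipeline together. Ratings files
#' are long-form with columns `expert_id, indicator_id, set_id, m, n,
#' weight`; survey files with `respondent_id, indicator_id, p_set_id, p_m,
#' p_n, e_set_id, e_m, e_n`. Readers validate column presence and term
#' indices against the supplied term sets and report offending line numbers.
#'
#' @param path File path.
#' @param termsets Named list of [linguistic_termset()]s used for
#'   validation.
#' @return A validated data frame.
#' @export
read_ratings <- function(path, termsets = default_termsets()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("expert_id", "indicator_id", "set_id", "m", "n")
  validate_cells(df, need, path,
                 list(list(set = "set_id", m = "m", n = "n")), termsets)
  df
}

#' @rdname read_ratings
#' @export
read_survey <- function(path, termsets = default_termsets()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("respondent_id", "indicator_id", "p_set_id", "p_m", "p_n",
            "e_set_id", "e_m", "e_n")
  validate_cells(df, need, path,
                 list(list(set = "p_set_id", m = "p_m", n = "p_n"),
                      list(set = "e_set_id", m = "e_m", n = "e_n")),
                 termsets)
  df
}

validate_cells <- function(df, need, path, groups, termsets) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop(path, ": no data rows", call. = FALSE)
  for (g in groups) {
    sid <- df[[g$set]]
    bad_set <- !sid %in% names(termsets) & !is.na(sid)
    if (any(bad_set))
      stop(path, ": unknown term set at line(s) ",
           paste(which(bad_set)[1:min(5, sum(bad_set))] + 1L, collapse = ", "),
           call. = FALSE)
    top <- vapply(sid, function(s)
      if (is.na(s)) NA_integer_ else termset_max_index(termsets[[s]]),
      integer(1))
    m <- df[[g$m]]; n <- df[[g$n]]
    bad <- !is.na(m) & !is.na(n) & (m < 0 | m > n | n > top)
    if (any(bad))
      stop(path, ": invalid term indices at line(s) ",
           paste(which(bad)[1:min(5, sum(bad))] + 1L, collapse = ", "),
           call. = FALSE)
  }
  invisible(df)
}

#' Read an indicator hierarchy from CSV
#'
#' @param path CSV with columns `indicator_id`, `name`, `dimension_id` and
#'   optionally `dimension_name`.
#' @return An [indicator_hierarchy()].
#' @export
read_hierarchy <- function(path) {
  indicator_hierarchy(read.csv(path, stringsAsFactors = FALSE))
}

#' Write an indicator hierarchy to CSV
#'
#' @param hierarchy An [indicator_hierarchy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(hierarchy, path) {
  stopifnot(inherits(hierarchy, "indicator_hierarchy"))
  df <- hierarchy$indicators
  df$dimension_name <- hierarchy$dimensions$name[
    match(df$dimension_id, hierarchy$dimensions$id)]
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Render a screening report for humans
#'
#' Rounds the similarity columns of a [screen_indicators()] report to the
#' conventional 4 decimals (half away from zero) and attaches the reference
#' term labels; the full-precision report should be kept alongside for
#' machine use.
#'
#' @param report A [screen_indicators()] data frame.
#' @param reference_set The [linguistic_termset()] the report was screened
#'   against.
#' @param digits Decimals for similarities (default 4).
#' @return A data frame with rounded `Y*` columns and an `argmax_label`
#'   column.
#' @export
format_screening <- function(report, reference_set, digits = 4) {
  ycols <- grep("^Y[0-9]+$", names(report), value = TRUE)
  out <- report
  out[ycols] <- lapply(report[ycols], round_half_up, digits = digits)
  out$argmax_label <- reference_set$labels[report$argmax_term + 1L]
  out
}
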