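# Shared helpers: term sets and the case-study averaged trapezoids as a
# rownamed matrix, plus a tiny random-trapezoid generator for property tests.

ts_all <- default_termsets()
ts7 <- ts_all$seven
ts7imp <- ts_all$seven_importance
ts5 <- ts_all$five

table3_matrix <- function() {
  t3 <- load_fixture("table3_expert_trapezoids")
  m <- as.matrix(t3[, c("a", "b", "c", "d")])
  rownames(m) <- t3$indicator_id
  m
}

random_trapezoid <- function() {
  trapezoid(sort(stats::runif(4)))
}

# long-form ratings table from a named list expert -> list(set, m, n) per
# indicator vector; all weight 1
ratings_from_values <- function(values, indicator_ids) {
  do.call(rbind, lapply(names(values), function(e) {
    v <- values[[e]]
    data.frame(expert_id = e, indicator_id = indicator_ids,
               set_id = v$set, m = v$m, n = v$n, weight = 1,
               stringsAsFactors = FALSE)
  }))
}
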