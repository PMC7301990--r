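test_that("similarity degree reproduces the published spot checks", {
  refs <- reference_encodings(ts7imp)
  f1 <- trapezoid(0.206, 0.301, 0.431, 0.527)
  expect_equal(similarity(f1, refs["S2", ]), 0.9641, tolerance = 5e-4)
  f17 <- trapezoid(0.810, 0.905, 1.000, 1.000)
  expect_equal(round_half_up(similarity(f17, refs["S6", ]), 4), 0.9864)
  f12 <- trapezoid(0.226, 0.321, 0.462, 0.557)
  expect_equal(round_half_up(similarity(f12, refs["S2", ]), 4), 0.9523)
})

test_that("similarity is symmetric, maximal only at identity, and 1 - Y is a metric", {
  set.seed(41)
  for (i in 1:30) {
    x <- random_trapezoid(); y <- random_trapezoid(); z <- random_trapezoid()
    expect_equal(similarity(x, y), similarity(y, x), tolerance = 1e-12)
    expect_equal(similarity(x, x), 1)
    dxy <- 1 - similarity(x, y); dyz <- 1 - similarity(y, z)
    dxz <- 1 - similarity(x, z)
    expect_gte(dxy, 0)
    expect_lte(dxz, dxy + dyz + 1e-12)              # triangle inequality
    if (any(unclass(x) != unclass(y))) expect_gt(dxy, 0)  # identity of indiscernibles
  }
})

test_that("similarity decreases as a component moves away", {
  M <- unclass(encode(linguistic_value(ts7, 3)))
  f <- M
  steps <- seq(0, 0.3, by = 0.05)
  vals <- vapply(steps, function(s) {
    g <- f; g[4] <- min(g[4] + s, 1); similarity(g, M)
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("similarity warns on non-normalized input", {
  expect_warning(similarity(c(0, 1, 2, 3), c(0, 0.1, 0.2, 0.3)),
                 "not normalized")
})

test_that("profiles locate the most similar reference term and flag ties", {
  p <- similarity_profile(trapezoid(0.226, 0.321, 0.462, 0.557), ts7imp)
  expect_equal(p$argmax_term, 2L)
  expect_equal(round_half_up(max(p$similarities), 4), 0.9523)
  expect_false(p$tie)
  # exact encoding is its own argmax with Y = 1
  p4 <- similarity_profile(encode(linguistic_value(ts7imp, 4)), ts7imp)
  expect_equal(p4$argmax_term, 4L)
  expect_equal(unname(p4$similarities["S4"]), 1)
  # equidistant midpoint between S2 and S3 ties
  mid <- (unclass(encode(linguistic_value(ts7imp, 2))) +
            unclass(encode(linguistic_value(ts7imp, 3)))) / 2
  pm <- similarity_profile(trapezoid(mid), ts7imp)
  expect_true(pm$tie)
  expect_equal(decide(pm, default_zones(ts7imp))$decision, "review")
})

test_that("zone partitions drive keep/remove/review decisions", {
  zones <- default_zones(ts7imp)
  expect_equal(zones$remove, 0:2)
  expect_equal(zones$review, 3L)
  expect_equal(zones$keep, 4:6)
  avg <- table3_matrix()
  scr <- screen_indicators(avg, ts7imp)
  expect_setequal(scr$indicator_id[scr$decision == "remove"],
                  c("network_service_provider", "appointment_channel"))
  expect_setequal(scr$indicator_id[scr$decision == "review"],
                  c("process_convenience", "operational_ease_of_use",
                    "consultation_visitors", "re_consultation_rate"))
  expect_equal(scr$argmax_term[scr$indicator_id == "expert_level"], 6L)
  expect_equal(scr$argmax_term[scr$indicator_id == "process_convenience"], 3L)
  expect_error(mgliqual:::check_zones(list(remove = 0:2, review = 3L,
                                           keep = 4:5), 6),
               "partition")
})

test_that("decisions depend only on the argmax, not the similarity scale", {
  avg <- table3_matrix()
  scr <- screen_indicators(avg, ts7imp)
  # a strictly monotone transform of every Y leaves argmax and decision fixed
  ycols <- paste0("Y", 0:6)
  Y <- as.matrix(scr[ycols])
  amax2 <- max.col(2 * Y^3 + 1, ties.method = "first") - 1L
  expect_equal(amax2, scr$argmax_term)
})

test_that("the case-study merge plan optimizes 24/5 into 19/4 with the expected layout", {
  h <- load_fixture("initial_hierarchy")
  scr <- screen_indicators(table3_matrix(), ts7imp)
  plan <- load_fixture("htcc_merge_plan")
  opt <- apply_merge_plan(h, scr, plan)
  expect_equal(nrow(opt$indicators), 19L)
  expect_equal(nrow(opt$dimensions), 4L)
  codes <- hierarchy_codes(opt)
  t6 <- load_fixture("table6_subindicators")
  expect_equal(codes$code, t6$indicator_code)
  expect_equal(codes$name, t6$name)

  # empty plan: identity up to removals
  opt0 <- apply_merge_plan(h, scr, merge_plan())
  expect_equal(nrow(opt0$indicators), 22L)
  no_removals <- scr; no_removals$decision[no_removals$decision == "remove"] <- "keep"
  ident <- apply_merge_plan(h, no_removals, merge_plan())
  expect_equal(ident$indicators, h$indicators)

  # plans touching removed or unknown ids are rejected
  bad <- merge_plan(indicator_merges = list(list(
    sources = c("appointment_channel", "waiting_time"),
    target = list(id = "x", name = "X", dimension_id = "interaction_quality"))))
  expect_error(apply_merge_plan(h, scr, bad), "removed")
  bad2 <- merge_plan(indicator_merges = list(list(
    sources = c("nope", "waiting_time"),
    target = list(id = "x", name = "X", dimension_id = "interaction_quality"))))
  expect_error(apply_merge_plan(h, scr, bad2), "unknown")
  expect_error(merge_plan(indicator_merges = list(
    list(sources = c("a", "b"), target = list()),
    list(sources = c("b", "c"), target = list()))), "disjoint")
})
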