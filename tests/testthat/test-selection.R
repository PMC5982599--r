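## descriptor-id helpers for compact fixtures (real ids, planted values)
d1 <- "VISNIR.414.R.mean"; d2 <- "VISNIR.477.R.mean"
d3 <- "VISNIR.524.R.mean"; d4 <- "VISNIR.671.R.mean"

test_that("a value flags malignancy only strictly outside the benign interval", {
  r <- threshold_rule("VISNIR.414.R_minus_skin.min", upper = 0.8, lower = -0.33)
  expect_true(flag_malignant(0.9, r))
  expect_false(flag_malignant(0.8, r))    # boundary is benign
  expect_false(flag_malignant(-0.33, r))
  expect_true(flag_malignant(-0.5, r))
  expect_false(flag_malignant(0, r))
  expect_error(threshold_rule(d1, upper = -1, lower = 1), "lower < upper")
  expect_error(threshold_rule("not.a.real.id.x", 1, 0), "malformed")
})

test_that("rules rank by melanomas caught with stable ties", {
  ## 10 melanomas; d1 catches 5, d2 catches 9, d3 catches 2
  vals <- list()
  vals[[d1]] <- c(rep(10, 5), rep(0, 5), rep(0, 4))
  vals[[d2]] <- c(rep(10, 9), 0, rep(0, 4))
  vals[[d3]] <- c(rep(10, 2), rep(0, 8), rep(0, 4))
  tab <- fixture_table(vals, c(rep("melanoma", 10), rep("nevus", 4)))
  rules <- list(threshold_rule(d1, 5, -5), threshold_rule(d2, 5, -5),
                threshold_rule(d3, 5, -5))
  ranked <- rank_rules(tab, rules)
  expect_equal(vapply(ranked, `[[`, "", "descriptor"), c(d2, d1, d3))
  expect_equal(attr(ranked, "melanomas_caught"), c(9, 5, 2))

  zero <- fixture_table(stats::setNames(list(rep(0, 6), rep(0, 6)),
                                        c(d1, d2)),
                        c(rep("melanoma", 3), rep("nevus", 3)))
  rz <- rank_rules(zero, rules[1:2])
  expect_equal(vapply(rz, `[[`, "", "descriptor"), c(d1, d2))  # order kept
  expect_equal(attr(rz, "melanomas_caught"), c(0, 0))
})

test_that("greedy accumulation keeps only rules that catch new melanomas", {
  ## A flags melanomas 1-5, B flags the same 1-5, C flags 6 only
  n_mel <- 6
  vals <- list()
  vals[[d1]] <- c(rep(10, 5), 0, rep(0, 3))
  vals[[d2]] <- c(rep(10, 5), 0, rep(0, 3))
  vals[[d3]] <- c(rep(0, 5), 10, rep(0, 3))
  tab <- fixture_table(vals, c(rep("melanoma", n_mel), rep("nevus", 3)))
  rules <- list(threshold_rule(d1, 5, -5), threshold_rule(d2, 5, -5),
                threshold_rule(d3, 5, -5))
  sel <- greedy_select(tab, rules)
  expect_equal(vapply(sel$selected, `[[`, "", "descriptor"), c(d1, d3))
  expect_length(sel$discarded, 1)
  expect_equal(sel$discarded[[1]]$rule$descriptor, d2)
  expect_match(sel$discarded[[1]]$reason, "redundant")
  expect_equal(sel$cumulative_sensitivity, c(5 / 6, 1))

  single <- greedy_select(tab, rules[1:1])
  expect_equal(single$cumulative_sensitivity, 5 / 6)
  ## benign zone below every observed value: one rule flags everything
  sel_all <- greedy_select(tab, list(threshold_rule(d1, -1, -5)))
  expect_equal(sel_all$cumulative_sensitivity, 1)  # one rule flags all

  expect_error(greedy_select(fixture_table(stats::setNames(list(0), d1),
                                           "nevus"), rules[1]),
               "no melanomas")
})

test_that("eight rules each adding melanomas reach 100% with strictly increasing sensitivity", {
  ## 14 melanomas split over 8 rules (sizes 4,3,2,1,1,1,1,1), like an
  ## eight-row selection trace ending at full sensitivity
  sizes <- c(4, 3, 2, 1, 1, 1, 1, 1)
  ids <- descriptor_ids()[seq(1, 8 * 7, by = 7)]
  starts <- cumsum(c(0, sizes[-8]))
  vals <- list()
  for (j in 1:8) {
    v <- rep(0, 20)
    v[(starts[j] + 1):(starts[j] + sizes[j])] <- 10
    vals[[ids[j]]] <- v
  }
  tab <- fixture_table(vals, c(rep("melanoma", 14), rep("nevus", 6)))
  rules <- lapply(ids, function(d) threshold_rule(d, 5, -5))
  ranked <- rank_rules(tab, rules)
  sel <- greedy_select(tab, ranked)
  expect_length(sel$selected, 8)
  expect_true(all(diff(sel$cumulative_sensitivity) > 0))
  expect_equal(sel$cumulative_sensitivity[8], 1)
  expect_equal(sel$cumulative_sensitivity, cumsum(sizes) / 14)
})

test_that("greedy selection equals an independent forward-search oracle", {
  set.seed(40)
  ids <- descriptor_ids()[1:6]
  for (rep_i in 1:10) {
    n <- 16
    classes <- sample(c(rep("melanoma", 6), rep("nevus", 10)))
    vals <- lapply(stats::setNames(ids, ids), function(d) runif(n, -1, 1))
    tab <- fixture_table(vals, classes)
    rules <- lapply(ids, function(d)
      threshold_rule(d, upper = runif(1, 0, 0.8), lower = runif(1, -0.8, -0.1)))
    ranked <- rank_rules(tab, rules)
    sel <- greedy_select(tab, ranked)
    expect_equal(vapply(sel$selected, `[[`, "", "descriptor"),
                 oracle_greedy(tab, ranked))
  }
})

test_that("rule-set classification is the union of per-rule flags", {
  vals <- stats::setNames(list(c(0, 0.9, 0), c(0, 0, -0.6)), c(d1, d2))
  tab <- fixture_table(vals, c("nevus", "melanoma", "melanoma"))
  rules <- list(threshold_rule(d1, 0.5, -0.5), threshold_rule(d2, 0.5, -0.5))
  expect_equal(classify_by_rules(tab, rules),
               c("benign", "malignant", "malignant"))
  expect_error(classify_by_rules(tab, list()), "no rules")
})

test_that("the shipped default rules resolve to existing descriptors and flag an all-zero lesion", {
  rules <- default_rules()
  expect_length(rules, 8)
  ids <- vapply(rules, `[[`, "", "descriptor")
  expect_true(all(ids %in% descriptor_ids()))
  ## an all-zero descriptor row falls below e.g. the 477 nm absorbance-SD
  ## lower bound (0 < 0.039), so it must be called malignant
  zero <- as.data.frame(stats::setNames(as.list(rep(0, 392)),
                                        descriptor_ids()),
                        check.names = FALSE, optional = TRUE)
  zero <- cbind(data.frame(id = "L1", class = "melanoma"), zero)
  expect_equal(classify_by_rules(zero, rules), "malignant")
})

test_that("adding rules never shrinks the flagged melanoma set", {
  set.seed(41)
  ids <- descriptor_ids()[1:5]
  vals <- lapply(stats::setNames(ids, ids), function(d) runif(12, -1, 1))
  tab <- fixture_table(vals, sample(c(rep("melanoma", 5), rep("nevus", 7))))
  rules <- lapply(ids, function(d) threshold_rule(d, 0.5, -0.5))
  mel <- tab$class == "melanoma"
  prev <- rep(FALSE, sum(mel))
  for (k in seq_along(rules)) {
    fl <- classify_by_rules(tab, rules[1:k])[mel] == "malignant"
    expect_true(all(fl[prev]))
    prev <- fl
  }
})

test_that("fitted rules respect the false-positive budget and catch planted melanomas", {
  set.seed(42)
  vals <- stats::setNames(list(c(rnorm(20, 0, 0.1), rnorm(8, 2, 0.2))), d1)
  tab <- fixture_table(vals, c(rep("nevus", 20), rep("melanoma", 8)))
  rules <- fit_rules(tab, d1, max_nevi_flagged = 2)
  expect_length(rules, 1)
  calls <- classify_by_rules(tab, rules)
  expect_lte(sum(calls[tab$class == "nevus"] == "malignant"), 2)
  expect_equal(sum(calls[tab$class == "melanoma"] == "malignant"), 8)
})

test_that("rule sets survive a JSON round trip", {
  path <- withr::local_tempfile(fileext = ".json")
  write_rules(default_rules(), path)
  back <- read_rules(path)
  expect_equal(back, default_rules())
  ## the shipped JSON copy stays in sync with the in-code defaults
  shipped <- system.file("extdata", "default_rules.json",
                         package = "melspect")
  expect_equal(read_rules(shipped), default_rules())
})
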