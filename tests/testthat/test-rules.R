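test_that("a perfectly separating descriptor yields a depth-1 tree", {
  d <- data.frame(x = c(rep(0, 10), rep(1, 10)), z = rnorm(20))
  cls <- rep(c("active", "inactive"), each = 10)
  tr <- train_activity_tree(d, cls)
  expect_equal(tr$training_accuracy, 1)
  expect_equal(sum(tr$fit$frame$var == "<leaf>"), 2)
  expect_error(train_activity_tree(d, rep("active", 20)), "both")
})

test_that("tree memorizes data whose labels are rule-dominated", {
  cur <- cached_curated()
  d <- cached_descriptors()
  # labels explained >= 90% by descriptor rules, the rest flipped noise
  rule_cls <- ifelse(d$fr_hdrzine > 0 | d$fr_SH > 0 | d$fr_halogen > 0,
                     "active", "inactive")
  set.seed(21)
  flip <- sample(length(rule_cls), round(0.1 * length(rule_cls)))
  cls <- rule_cls
  cls[flip] <- ifelse(rule_cls[flip] == "active", "inactive", "active")
  tr <- train_activity_tree(d, cls)
  expect_gte(tr$training_accuracy, max(table(cls)) / length(cls))
  expect_gte(tr$training_accuracy, 0.85)
  # the real study conditions stay above the majority baseline too
  tr0 <- train_activity_tree(d, cur$compounds$activity_class)
  expect_gte(tr0$training_accuracy,
             max(table(cur$compounds$activity_class)) / nrow(d))
})

test_that("single-condition separable data gives a one-condition rule", {
  set.seed(31)
  d <- data.frame(flag = rep(c(1, 0), c(15, 25)), noise = runif(40))
  cls <- c(rep("active", 15), rep("inactive", 22), rep("active", 3))
  tr <- train_activity_tree(d, cls)
  ru <- extract_rules(tr, d, cls)
  hit <- ru[ru$conditions == "flag > 0", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$predicted_class, "active")
  expect_equal(hit$precision_pct, 100)
})

test_that("dropping rule conditions never decreases coverage", {
  cur <- cached_curated()
  d <- cached_descriptors()
  cls <- cur$compounds$activity_class
  tr <- train_activity_tree(d, cls)
  ru <- extract_rules(tr, d, cls)
  conds <- attr(ru, "condition_list")
  for (k in head(seq_along(conds), 10)) {
    full_cov <- sum(ureascape:::.rule_cover(conds[[k]], d))
    if (length(conds[[k]]) < 2) next
    for (j in seq_along(conds[[k]]))
      expect_gte(sum(ureascape:::.rule_cover(conds[[k]][-j], d)), full_cov)
  }
})

test_that("the planted two-condition regime reduces to its sufficient core", {
  set.seed(5)
  n <- 120
  d <- data.frame(grpA = rbinom(n, 1, 0.5), grpB = rbinom(n, 1, 0.5),
                  mw = runif(n, 100, 500))
  cls <- ifelse(d$grpA > 0 & d$grpB > 0, "active",
                sample(c("active", "inactive"), n, TRUE, c(0.25, 0.75)))
  tr <- train_activity_tree(d, cls)
  ru <- extract_rules(tr, d, cls)
  planted <- ru[ru$predicted_class == "active" &
                  grepl("grpA > 0", ru$conditions) &
                  grepl("grpB > 0", ru$conditions), ]
  expect_gte(nrow(planted), 1)
  # the recovered conjunction is exactly the two planted conditions
  expect_equal(sort(strsplit(planted$conditions[1], "; ")[[1]]),
               c("grpA > 0", "grpB > 0"))
  expect_gte(planted$precision_pct[1], 80)
})

test_that("rule evaluation is order-independent", {
  cur <- cached_curated()
  d <- cached_descriptors()
  cls <- cur$compounds$activity_class
  tr <- train_activity_tree(d, cls)
  ru <- extract_rules(tr, d, cls)
  conds <- attr(ru, "condition_list")[[1]]
  m0 <- rule_metrics(conds, d, cls, ru$predicted_class[1])
  set.seed(2)
  p <- sample(nrow(d))
  m1 <- rule_metrics(conds, d[p, , drop = FALSE], cls[p],
                     ru$predicted_class[1])
  expect_equal(m0, m1)
})

test_that("precision reporting matches the printed one-decimal convention", {
  expect_equal(rule_precision(15, 240, "inactive"), 94.1)
  expect_equal(rule_precision(40, 2, "active"), 95.2)
  expect_equal(rule_precision(1, 31, "inactive"), 96.9)
  expect_equal(rule_precision(6, 19, "inactive"), 76.0)
  expect_true(is.na(rule_precision(0, 0, "active")))   # empty coverage
  m <- rule_metrics(list(list(feature = "x", op = ">=", threshold = 99)),
                    data.frame(x = 1:5), rep("active", 5), "active")
  expect_equal(m$n_total, 0)
  expect_true(is.na(m$precision_pct))
})

test_that("rules at threshold keep precision >= 80 and flags mark the rest", {
  cur <- cached_curated()
  d <- cached_descriptors()
  cls <- cur$compounds$activity_class
  ru <- extract_rules(train_activity_tree(d, cls), d, cls,
                      precision_threshold = 0.80)
  expect_true(all(ru$precision_pct[!ru$below_threshold] >= 80))
  expect_true(all(ru$precision_pct[ru$below_threshold] < 80))
  expect_equal(ru$n_total, ru$n_active + ru$n_inactive)
})

test_that("interaction H is 0 for additive and positive for joint effects", {
  set.seed(8)
  d <- data.frame(x1 = runif(80), x2 = runif(80), x3 = runif(80))
  h_add <- feature_interaction(NULL, d, "x1",
                               predict_fun = function(dd) dd$x1 + 2 * dd$x2)
  expect_lt(h_add, 0.05)
  h_mul <- feature_interaction(NULL, d, "x1",
                               predict_fun = function(dd) dd$x1 * dd$x2)
  expect_gt(h_mul, 0.05)
  expect_lte(h_mul, 1)
  h_const <- feature_interaction(NULL, d, "x1",
                                 predict_fun = function(dd) rep(1, nrow(dd)))
  expect_equal(h_const, 0)
  # a depth-1 tree is a single-feature (hence additive) model
  cls <- ifelse(d$x1 > 0.5, "active", "inactive")
  tr1 <- train_activity_tree(d, cls, max_depth = 1)
  expect_lt(feature_interaction(tr1, d, "x2"), 0.05)
})
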