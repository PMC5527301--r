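# Derangement enumeration/sampling, couple relabeling, and both pairing
# nulls (PERMANOVA F and classifier error).

test_that("derangement counts: enumeration matches the recurrence", {
  # !2..!6 = 1, 2, 9, 44, 265
  expect_equal(nrow(enumerate_incorrect_pairings(2)), 1)
  expect_equal(nrow(enumerate_incorrect_pairings(3)), 2)
  expect_equal(nrow(enumerate_incorrect_pairings(4)), 9)
  expect_equal(nrow(enumerate_incorrect_pairings(5)), 44)
  expect_equal(nrow(enumerate_incorrect_pairings(6)), 265)
  for (n in 2:8)
    expect_equal(nrow(enumerate_incorrect_pairings(n)), derangement_count(n))
  # no pairing keeps any couple, and all rows are distinct permutations
  for (n in c(4, 6)) {
    d <- enumerate_incorrect_pairings(n)
    expect_true(all(d != matrix(1:n, nrow(d), n, byrow = TRUE)))
    expect_true(all(apply(d, 1, function(r) setequal(r, 1:n))))
    expect_equal(anyDuplicated(d), 0)
  }
  # the design-scale count used for 1,000 sampled pairings
  expect_equal(derangement_count(10), 1334961)
  expect_error(enumerate_incorrect_pairings(1), ">= 2")
  expect_error(enumerate_incorrect_pairings(10), "sample_unique_pairings")
})

test_that("sample_unique_pairings: exhaustion, distinctness, determinism, bounds", {
  both <- sample_unique_pairings(3, 2, seed = 1)
  expect_equal(nrow(both), 2)
  expect_equal(anyDuplicated(both), 0)
  expect_error(sample_unique_pairings(3, 3), "derangements exist")
  # deterministic per seed, including the large-n rejection path
  a <- sample_unique_pairings(10, 50, seed = 7)
  b <- sample_unique_pairings(10, 50, seed = 7)
  expect_identical(a, b)
  expect_equal(anyDuplicated(a), 0)
  expect_true(all(a != matrix(1:10, 50, 10, byrow = TRUE)))
})

test_that("sampled pairings are uniform over the derangements", {
  # 1,800 single draws for n = 4 (9 derangements): chi-square GOF
  set.seed(2)
  keys <- replicate(1800, paste(sample_unique_pairings(4, 1), collapse = ""))
  tab <- table(keys)
  expect_equal(length(tab), 9L)
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("relabel_couples: identity, swap, invariant preservation", {
  sim <- small_sim(seed = 37, n_couples = 4)
  meta <- sim$meta
  couples <- sort(unique(meta$couple))
  expect_equal(relabel_couples(meta, 1:4)$couple, meta$couple)
  # 2-couple swap: labels crossed for males only
  sw <- relabel_couples(meta, c(2, 1, 4, 3))
  male <- meta$sex == "male"
  expect_equal(sw$couple[!male], meta$couple[!male])
  expect_equal(sort(unique(sw$couple[male & meta$couple == couples[1]])),
               couples[2])
  # every pseudo-couple has exactly one female and one male, all fields else equal
  for (k in 1:3) {
    pr <- sample_unique_pairings(4, 1, seed = 100 + k)
    rel <- relabel_couples(meta, pr[1, ])
    ps <- unique(rel[, c("participant", "couple", "sex")])
    expect_true(all(table(ps$couple) == 2))
    for (cpl in unique(ps$couple))
      expect_setequal(ps$sex[ps$couple == cpl], c("female", "male"))
    expect_identical(rel[, setdiff(names(rel), "couple")],
                     meta[, setdiff(names(meta), "couple")])
  }
  expect_error(relabel_couples(meta, c(1, 1, 2, 3)), "permutation")
})

test_that("pairing_null_permanova: smoothed p arithmetic and structure", {
  sim <- small_sim(seed = 38, n_couples = 4, sigma_couple = 2)
  dm <- bray_curtis(rarefy(sim$table, 400, seed = 8))
  pairings <- enumerate_incorrect_pairings(4)
  nd <- pairing_null_permanova(dm, sim$meta, pairings)
  expect_s3_class(nd, "null_distribution")
  expect_equal(nd$n_null, 9)
  expect_equal(nd$p, (1 + sum(nd$null_values >= nd$observed)) / 10)
  # single-pairing case: F_null < F_obs -> p = 1/2 exactly
  one <- pairing_null_permanova(dm, sim$meta,
                                pairings[which.min(nd$null_values), ,
                                         drop = FALSE])
  if (one$null_values < one$observed) expect_equal(one$p, 0.5)
  # per-location mode returns one distribution per body location
  per <- pairing_null_permanova(dm, sim$meta, pairings, per_location = TRUE)
  expect_setequal(names(per), unique(sim$meta$body_location))
  expect_true(all(vapply(per, function(x) x$n_null, numeric(1)) == 9))
})

test_that("strong couple effect is detected by the PERMANOVA pairing null", {
  # power at the stated-world defaults (sigma_couple = 2 x sigma_noise):
  # p <= 0.05 in >= 90% of replicates
  hits <- vapply(1:10, function(seed) {
    sim <- simulate_couples_design(seed = 600 + seed)
    filt <- filter_low_depth(sim$table, 5293)
    rare <- rarefy(filt$table, 5293, seed = seed)
    meta <- sim$meta[sim$meta$sample_id %in% sample_ids(rare), ]
    dm <- bray_curtis(rare)
    pairings <- sample_unique_pairings(10, 99, seed = seed)
    pairing_null_permanova(dm, meta, pairings)$p <= 0.05
  }, logical(1))
  expect_gte(sum(hits), 9L)
})

test_that("no couple effect: pairing-null p is spread over (0, 1]", {
  ps <- vapply(1:10, function(seed) {
    sim <- small_sim(seed = 700 + seed, n_couples = 5, sigma_couple = 0)
    dm <- bray_curtis(rarefy(sim$table, 400, seed = seed))
    pairings <- enumerate_incorrect_pairings(5)
    pairing_null_permanova(dm, sim$meta, pairings)$p
  }, numeric(1))
  # not concentrated at either extreme (full uniformity is acceptance-tested)
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps), 0.8)
})

test_that("null evaluations only ever differ from the true run in couple labels", {
  sim <- small_sim(seed = 39, n_couples = 3)
  pairings <- enumerate_incorrect_pairings(3)
  for (k in seq_len(nrow(pairings))) {
    rel <- relabel_couples(sim$meta, pairings[k, ])
    expect_identical(rel[, setdiff(names(rel), "couple")],
                     sim$meta[, setdiff(names(sim$meta), "couple")])
    expect_false(identical(rel$couple, sim$meta$couple))
  }
})

test_that("binned_null_histogram covers all values and flags the observed bin", {
  nd <- structure(list(statistic = "permanova_F", observed = 2.5,
                       null_values = c(1, 1.2, 1.4, 2, 2.2, 3),
                       p = 0.2, n_null = 6), class = "null_distribution")
  h <- binned_null_histogram(nd, n_bins = 5)
  expect_equal(nrow(h), 5L)
  expect_equal(sum(h$count), 6)
  expect_equal(sum(h$contains_observed), 1L)
  obs_bin <- h[h$contains_observed, ]
  expect_true(obs_bin$bin_lo <= 2.5 && 2.5 <= obs_bin$bin_hi)
  # bins span the pooled range
  expect_equal(h$bin_lo[1], 1)
  expect_equal(h$bin_hi[5], 3)
})

test_that("pairing_null_classifier: p arithmetic, order invariance, detection", {
  sim <- small_sim(seed = 40, n_couples = 4, sigma_couple = 3,
                   sigma_noise = 0.1)
  rare <- rarefy(sim$table, 400, seed = 9)
  pairings <- enumerate_incorrect_pairings(4)
  nd <- pairing_null_classifier(rare, sim$meta, pairings, n_trees = 30,
                                n_folds = 2, seed = 10)
  expect_equal(nd$n_null, 9)
  expect_equal(nd$p, (1 + sum(nd$null_values <= nd$observed)) / 10)
  # a huge couple effect separates couples: observed error near zero and
  # below every deranged pairing
  expect_lt(nd$observed, 0.2)
  expect_equal(nd$p, 1 / 10)
  # null distribution invariant to pairing order (same seed, same set)
  nd2 <- pairing_null_classifier(rare, sim$meta, pairings[9:1, ],
                                 n_trees = 30, n_folds = 2, seed = 10)
  expect_equal(sort(nd2$null_values), sort(nd$null_values))
  expect_equal(nd2$p, nd$p)
})
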