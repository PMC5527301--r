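# Hierarchical community simulator: invariants, determinism, effect ordering.

test_that("simulated tables satisfy all data-model invariants", {
  for (seed in 1:3) {
    sim <- small_sim(seed = seed, n_couples = 3)
    expect_s3_class(sim$table, "otu_table")
    expect_s3_class(sim$meta, "sample_frame") # validated at construction
    expect_true(all(sim$table$counts >= 0))
    expect_true(all(sim$table$counts == round(sim$table$counts)))
    expect_true(all(sample_depths(sim$table) > 0))
    expect_equal(sample_ids(sim$table), sim$meta$sample_id)
    # design shape: n_couples x 2 participants x 5 swabs (small map)
    expect_equal(nrow(sim$table$counts), 3 * 2 * 5)
    # one female + one male per couple
    ps <- unique(sim$meta[, c("couple", "sex")])
    expect_true(all(table(ps$couple) == 2))
  }
  # full design shape: 340 samples, 17 swabs per participant
  sim <- simulate_community(sim_config(seed = 5, n_otus = 20,
                                       depth_meanlog = log(300),
                                       depth_floor = 250))
  expect_equal(nrow(sim$table$counts), 340L)
  expect_true(all(table(sim$meta$participant) == 17))
})

test_that("simulation is deterministic per seed and truth dimensions line up", {
  a <- small_sim(seed = 42, n_couples = 2)
  b <- small_sim(seed = 42, n_couples = 2)
  expect_identical(a$table$counts, b$table$counts)
  expect_identical(a$meta, b$meta)
  c <- small_sim(seed = 43, n_couples = 2)
  expect_false(identical(a$table$counts, c$table$counts))
  expect_equal(dim(a$truth$site_effects), c(3L, 60L))
  expect_equal(dim(a$truth$participant_effects), c(4L, 60L))
  expect_equal(dim(a$truth$couple_effects), c(2L, 60L))
  expect_equal(dim(a$truth$probs), dim(a$table$counts))
})

test_that("site-only config: within-site distances below between-site", {
  cfg <- sim_config(n_couples = 3, n_otus = 60,
                    body_locations = small_locations(),
                    sigma_individual = 0, sigma_couple = 0, sigma_sex = 0,
                    sigma_site = 2, sigma_noise = 0.1,
                    sex_effect_sites = "inner thigh",
                    depth_meanlog = log(500), depth_sdlog = 0,
                    depth_floor = 500, dispersion = Inf, seed = 7)
  sim <- simulate_community(cfg)
  dm <- bray_curtis(rarefy(sim$table, 500, seed = 1))
  loc <- sim$meta$body_location
  same <- outer(loc, loc, "==") & upper.tri(dm)
  diff <- outer(loc, loc, "!=") & upper.tri(dm)
  expect_lt(mean(dm[same]), mean(dm[diff]))
})

test_that("degenerate config (no effects, no overdispersion) warns", {
  cfg <- sim_config(n_couples = 2, n_otus = 20,
                    body_locations = small_locations(),
                    baseline_sd = 1, sigma_site = 0, sigma_individual = 0,
                    sigma_couple = 0, sigma_sex = 0, sigma_noise = 0,
                    sex_effect_sites = "inner thigh",
                    depth_meanlog = log(200), depth_floor = 200,
                    dispersion = Inf, seed = 1)
  expect_warning(simulate_community(cfg), "degenerate")
})

test_that("sim_config rejects invalid settings", {
  expect_error(sim_config(n_couples = 1), "n_couples")
  expect_error(sim_config(n_otus = 5), "n_otus")
  expect_error(sim_config(sigma_site = -1), ">= 0")
  expect_error(sim_config(depth_floor = 0), "depth_floor")
  expect_error(sim_config(sex_effect_sites = "elbow"), "declared body")
})

test_that("no couple effect: partner nearest-neighbor rate sits at chance", {
  # P(partner) = 1/(2*n_couples - 2) exactly, by participant exchangeability;
  # pooled over replicate simulations it must land in the 95% binomial CI
  n_couples <- 5
  hits <- 0L; total <- 0L
  for (seed in 1:20) {
    # sigma_sex = 0 too: participant exchangeability (the analytic baseline)
    # additionally requires no sex-driven similarity among non-partners
    sim <- small_sim(seed = 100 + seed, n_couples = n_couples,
                     sigma_couple = 0, sigma_sex = 0)
    dm <- bray_curtis(rarefy(sim$table, 400, seed = seed))
    recs <- nearest_neighbors(dm, sim$meta, scope = "nonself",
                              within_location = TRUE)
    hits <- hits + sum(recs$relation == "partner")
    total <- total + nrow(recs)
  }
  p0 <- 1 / (2 * n_couples - 2)
  ci <- p0 + c(-1.96, 1.96) * sqrt(p0 * (1 - p0) / total)
  expect_gt(hits / total, ci[1])
  expect_lt(hits / total, ci[2])
})

test_that("partner match rate is monotone in sigma_couple (on averages)", {
  rate_at <- function(sigma) {
    mean(vapply(1:6, function(seed) {
      sim <- small_sim(seed = 200 + seed, n_couples = 4,
                       sigma_couple = sigma)
      dm <- bray_curtis(rarefy(sim$table, 400, seed = seed))
      recs <- nearest_neighbors(dm, sim$meta, scope = "nonself",
                                within_location = TRUE)
      mean(recs$relation == "partner")
    }, numeric(1)))
  }
  r0 <- rate_at(0)
  r1 <- rate_at(0.8)
  r2 <- rate_at(2)
  expect_lte(r0, r1 + 0.02) # small slack: trend on averages, finite seeds
  expect_lte(r1, r2 + 0.02)
  expect_gt(r2, r0) # strong couple effect clearly beats none
})

test_that("participant PERMANOVA F exceeds couple F when individuality dominates", {
  fs <- vapply(1:10, function(seed) {
    sim <- small_sim(seed = 300 + seed, n_couples = 3,
                     sigma_individual = 1.5, sigma_couple = 0.3)
    dm <- bray_curtis(rarefy(sim$table, 400, seed = seed))
    c(pseudo_f(dm, sim$meta$participant)$F,
      pseudo_f(dm, sim$meta$couple)$F)
  }, numeric(2))
  # effect-recovery ordering on seed-averaged F values
  expect_gt(mean(fs[1, ]), mean(fs[2, ]))
})

test_that("sim_config round-trips through the flat key=value format", {
  cfg <- sim_config(n_couples = 4, n_otus = 33, sigma_couple = 0.55,
                    body_locations = small_locations(),
                    sex_effect_sites = "inner thigh", dispersion = Inf,
                    seed = 77)
  path <- withr::local_tempfile(fileext = ".txt")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back, cfg)
  # a config restored from file drives an identical simulation
  expect_identical(simulate_community(back)$table$counts,
                   simulate_community(cfg)$table$counts)
})

test_that("ground truth exports as a TSV bundle with consistent shapes", {
  sim <- small_sim(seed = 3, n_couples = 2)
  prefix <- file.path(withr::local_tempdir(), "truth")
  paths <- write_sim_truth(sim$truth, prefix)
  expect_length(paths, 6L)
  expect_true(all(file.exists(paths)))
  site <- read.delim(paste0(prefix, "_site_effects.tsv"), row.names = 1)
  expect_equal(dim(site), dim(sim$truth$site_effects))
  expect_equal(unname(as.matrix(site)), unname(sim$truth$site_effects),
               tolerance = 1e-12)
})

test_that("seed_low_depth_samples degrades exactly n samples deterministically", {
  sim <- small_sim(seed = 4, n_couples = 3, depth = 600)
  out <- seed_low_depth_samples(sim$table, n = 5, below = 300, seed = 9)
  d <- sample_depths(out)
  expect_equal(sum(d < 300), 5L)
  expect_equal(sum(d >= 300), nrow(out$counts) - 5L)
  # untouched samples keep identical counts
  keep <- d >= 300
  expect_identical(out$counts[keep, ], sim$table$counts[keep, ])
  # deterministic per seed
  out2 <- seed_low_depth_samples(sim$table, n = 5, below = 300, seed = 9)
  expect_identical(out$counts, out2$counts)
  # identity and error cases
  expect_identical(seed_low_depth_samples(sim$table, 0, 300), sim$table)
  expect_error(seed_low_depth_samples(sim$table, 30, 300), "smaller")
})
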