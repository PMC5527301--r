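# Data model and I/O: OTU tables, mapping files, filtering, rarefaction,
# relative abundance, taxonomy collapse.

test_that("OTU table round-trips through the canonical TSV dialect", {
  tab <- toy_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, path)
  back <- read_otu_table(path)
  expect_identical(back$counts, tab$counts)

  # byte-identity of write(read(x)) for canonical files
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(back, path2)
  expect_identical(readLines(path), readLines(path2))

  # taxonomy column attaches and survives the round trip
  tab2 <- otu_table(tab$counts,
                    taxonomy = c("k__Bacteria; p__Firmicutes",
                                 "k__Bacteria; p__Actinobacteria"))
  write_otu_table(tab2, path)
  back2 <- read_otu_table(path)
  expect_equal(unname(back2$taxonomy),
               c("k__Bacteria; p__Firmicutes",
                 "k__Bacteria; p__Actinobacteria"))

  # samples-as-rows orientation normalizes to the same table
  writeLines(c("sample\tO1\tO2", "S1\t3\t0", "S2\t1\t2"), path)
  expect_equal(read_otu_table(path)$counts, tab$counts)
})

test_that("OTU table validation names the offender", {
  expect_error(otu_table(matrix(c(1, 2), 2, 1,
                                dimnames = list(c("A", "A"), "O1"))),
               "duplicate sample id: A")
  expect_error(otu_table(matrix(c(1, -2), 1, 2,
                                dimnames = list("S1", c("O1", "O2")))),
               "negative count.*O2")
  expect_error(otu_table(matrix(1.5, 1, 1)), "non-integer")
  expect_error(otu_table(matrix(numeric(0), 0, 0)), "empty")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\tS1\tS1", "O1\t1\t2"), path)
  expect_error(read_otu_table(path), "duplicate sample id: S1")
  writeLines(c("#OTU ID\tS1", "O1\tx"), path)
  expect_error(read_otu_table(path), "non-numeric")
})

test_that("mapping files parse, validate the couples design, and round-trip", {
  meta <- toy_meta()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(meta, path)
  back <- read_metadata(path)
  expect_equal(back$sample_id, meta$sample_id)
  expect_equal(back$participant, meta$participant)
  expect_s3_class(back, "sample_frame")

  # one couple, two participants parses fine
  mini <- meta[meta$couple == "H01", ]
  write_metadata(mini, path)
  got <- read_metadata(path)
  expect_equal(length(unique(got$participant)), 2L)
  expect_equal(length(unique(got$couple)), 1L)

  # two females in one couple is a design violation
  bad <- meta
  bad$sex[bad$participant == "H01B"] <- "female"
  write_metadata(bad, path)
  expect_error(read_metadata(path), "one female and one male")

  # unknown body location
  bad <- meta
  bad$body_location[1] <- "elbow"
  write_metadata(bad, path)
  expect_error(read_metadata(path), "unknown body location")

  # side rules: bilateral needs left/right, single needs none
  bad <- meta
  bad$side[1] <- "none"
  write_metadata(bad, path)
  expect_error(read_metadata(path), "left.*right")

  # lifestyle columns are preserved verbatim
  meta$AlcoholUse <- rep(c("daily", "monthly"), 4)
  write_metadata(meta, path)
  expect_equal(read_metadata(path)$AlcoholUse, meta$AlcoholUse)
})

test_that("full-design synthetic mapping parses: 330 rows, 20 participants, 10 couples", {
  sim <- simulate_community(sim_config(seed = 11, n_otus = 40,
                                       depth_meanlog = log(800),
                                       depth_floor = 700))
  tab <- seed_low_depth_samples(sim$table, n = 10, below = 350, seed = 12)
  # drop the 10 low-depth casualties, as the filter would
  filt <- filter_low_depth(tab, 350)
  meta330 <- sim$meta[sim$meta$sample_id %in% sample_ids(filt$table), ]
  expect_equal(nrow(meta330), 330L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(meta330, path)
  back <- read_metadata(path)
  expect_equal(nrow(back), 330L)
  expect_equal(length(unique(back$participant)), 20L)
  expect_equal(length(unique(back$couple)), 10L)
})

test_that("filter_low_depth applies the threshold and keeps counts intact", {
  tab <- otu_table(matrix(c(6000, 0, 2500, 2500), 2, 2, byrow = TRUE,
                          dimnames = list(c("A", "B"), c("O1", "O2"))))
  res <- filter_low_depth(tab, 5293)
  expect_equal(sample_ids(res$table), "A")
  expect_equal(res$removed, "B")
  expect_equal(res$table$counts["A", ], c(O1 = 6000, O2 = 0))
  # min_depth 1 removes nothing
  res1 <- filter_low_depth(tab, 1)
  expect_equal(res1$removed, character(0))
  expect_error(filter_low_depth(tab, 10000), "all samples")
})

test_that("rarefaction: exact depth, cellwise bound, determinism, errors", {
  set.seed(42)
  m <- matrix(rpois(5 * 20, 40), 5, 20,
              dimnames = list(paste0("S", 1:5), paste0("O", 1:20)))
  tab <- otu_table(m)
  depth <- min(sample_depths(tab)) - 10
  r1 <- rarefy(tab, depth, seed = 7)
  expect_true(all(sample_depths(r1) == depth))
  expect_true(all(r1$counts <= tab$counts))
  expect_identical(rarefy(tab, depth, seed = 7)$counts, r1$counts)
  expect_false(identical(rarefy(tab, depth, seed = 8)$counts, r1$counts))
  # subsample-the-whole is the identity
  d0 <- sum(tab$counts[1, ])
  one <- subset_samples(tab, samples = 1)
  expect_identical(rarefy(one, d0, seed = 1)$counts, one$counts)
  # single-OTU mass
  r2 <- rarefy(otu_table(matrix(c(10, 0), 1, 2,
                                dimnames = list("S", c("a", "b")))), 5,
               seed = 1)
  expect_equal(unname(r2$counts[1, ]), c(5, 0))
  # depth above a row sum names the sample
  expect_error(rarefy(tab, max(sample_depths(tab)) + 1), "filter first")
  # all-zero columns kept by default, dropped on request
  tab0 <- otu_table(matrix(c(50, 1, 50, 1), 2, 2, byrow = TRUE,
                           dimnames = list(c("X", "Y"), c("big", "tiny"))))
  rr <- rarefy(tab0, 2, seed = 3)
  expect_equal(ncol(rr$counts), 2L)
  dropped <- rarefy(tab0, 1, seed = 3, drop_empty_otus = TRUE)
  expect_lte(ncol(dropped$counts), 2L)
})

test_that("rarefaction marginals are hypergeometric (500,500) -> 100", {
  # mean 50; variance 100 * .5 * .5 * (900/999)
  tab <- otu_table(matrix(c(500, 500), 1, 2,
                          dimnames = list("S", c("a", "b"))))
  set.seed(123)
  draws <- vapply(1:10000, function(i) {
    rarefy(tab, 100)$counts[1, 1]
  }, numeric(1))
  mu <- 50
  v <- 100 * 0.5 * 0.5 * (900 / 999)
  expect_lt(abs(mean(draws) - mu), 4 * sqrt(v / 10000))
  expect_lt(abs(var(draws) - v), 0.1 * v)
})

test_that("relative abundance normalizes rows", {
  tab <- otu_table(matrix(c(3, 1), 1, 2, dimnames = list("S", c("a", "b"))))
  expect_equal(unname(relative_abundance(tab)[1, ]), c(0.75, 0.25))
  sim <- small_sim(seed = 2, n_couples = 2)
  ra <- relative_abundance(sim$table)
  expect_true(all(abs(rowSums(ra) - 1) < 1e-12))
  z <- otu_table(matrix(c(1, 0), 2, 1, dimnames = list(c("A", "B"), "o")))
  expect_error(relative_abundance(z), "zero-sum sample: B")
})

test_that("collapse_taxonomy sums within rank prefixes and conserves totals", {
  tab <- otu_table(matrix(c(3, 4, 5,
                            1, 2, 3), 2, 3, byrow = TRUE,
                          dimnames = list(c("S1", "S2"), c("o1", "o2", "o3"))),
                   taxonomy = c(
                     "k__Bacteria; p__Firmicutes; c__Bacilli; o__X; f__Staph",
                     "k__Bacteria; p__Firmicutes; c__Bacilli; o__X; f__Staph",
                     "k__Bacteria; p__Actinobacteria; c__A; o__Y; f__Cory"))
  fam <- collapse_taxonomy(tab, 5)
  expect_equal(ncol(fam$counts), 2L)
  staph <- grep("f__Staph", otu_ids(fam), value = TRUE)
  expect_equal(unname(fam$counts[, staph]), c(7, 3))
  expect_equal(sum(fam$counts), sum(tab$counts))
  phy <- collapse_taxonomy(tab, 2)
  expect_equal(sum(phy$counts), sum(tab$counts))
  expect_error(collapse_taxonomy(tab, 0), "rank")
  expect_error(collapse_taxonomy(tab, 8), "rank")
  # missing taxonomy lands in "unclassified"
  tab2 <- otu_table(tab$counts)
  un <- collapse_taxonomy(tab2, 2)
  expect_equal(otu_ids(un), "unclassified")
  expect_equal(sum(un$counts), sum(tab$counts))
})

test_that("dominant-phyla fixture: three phyla >94% leaves 'other' under 6%", {
  # skin-like composition: three dominant phyla + rare tail
  set.seed(9)
  n_otus <- 50
  phyla <- c(rep("Actinobacteria", 18), rep("Firmicutes", 15),
             rep("Proteobacteria", 12), rep("Bacteroidetes", 3),
             rep("Cyanobacteria", 2))
  weights <- c(rexp(45, 1) + 0.5, rexp(5, 10)) # rare tail for the last 5
  counts <- t(rmultinom(6, 5000, weights / sum(weights)))
  rownames(counts) <- paste0("S", 1:6)
  colnames(counts) <- paste0("o", 1:n_otus)
  tab <- otu_table(counts, taxonomy = paste0("k__Bacteria; p__", phyla))
  phy <- collapse_taxonomy(tab, 2)
  ra <- relative_abundance(phy)
  dom <- c("k__Bacteria; p__Actinobacteria", "k__Bacteria; p__Firmicutes",
           "k__Bacteria; p__Proteobacteria")
  share <- rowSums(ra[, dom])
  expect_true(all(share > 0.94))
  expect_true(all(1 - share < 0.06))
})
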