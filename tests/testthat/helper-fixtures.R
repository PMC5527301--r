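# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

# small OTU table with known counts
toy_table <- function() {
  otu_table(matrix(c(3, 0,
                     1, 2), nrow = 2, byrow = TRUE,
                   dimnames = list(c("S1", "S2"), c("O1", "O2"))))
}

# hand-built 2-couple metadata: 2 couples x 2 participants x 2 foot samples
toy_meta <- function() {
  validate_sample_frame(data.frame(
    sample_id = c("H01A14", "H01A15", "H01B14", "H01B15",
                  "H02A14", "H02A15", "H02B14", "H02B15"),
    participant = rep(c("H01A", "H01B", "H02A", "H02B"), each = 2),
    couple = rep(c("H01", "H02"), each = 4),
    sex = rep(c("female", "male", "female", "male"), each = 2),
    body_location = "foot",
    side = rep(c("left", "right"), 4),
    moisture = "moist", stringsAsFactors = FALSE))
}

# reduced body map: 2 bilateral + 1 single location = 5 swabs/participant
small_locations <- function() {
  bl <- body_locations()
  bl[bl$location %in% c("foot", "inner thigh", "navel"), ]
}

# cheap simulation for property tests
small_sim <- function(seed = 1, n_couples = 5, n_otus = 60,
                      depth = 400, ...) {
  cfg <- sim_config(n_couples = n_couples, n_otus = n_otus,
                    body_locations = small_locations(),
                    depth_meanlog = log(depth), depth_sdlog = 0,
                    depth_floor = depth, dispersion = Inf,
                    sex_effect_sites = "inner thigh", seed = seed, ...)
  simulate_community(cfg)
}

# literal brute-force PERMANOVA decomposition (independent of pseudo_f)
brute_force_pseudo_f <- function(dm, labels) {
  n <- nrow(dm)
  labels <- as.character(labels)
  groups <- unique(labels)
  a <- length(groups)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    ss_total <- ss_total + dm[i, j]^2
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in groups) {
    idx <- which(labels == g)
    if (length(idx) > 1)
      for (ii in seq_along(idx)) for (jj in seq_along(idx))
        if (ii < jj)
          ss_within <- ss_within + dm[idx[ii], idx[jj]]^2 / length(idx)
  }
  ss_among <- ss_total - ss_within
  (ss_among / (a - 1)) / (ss_within / (n - a))
}

# all permutations of a vector (n! rows); for exact-enumeration oracles
all_permutations <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- all_permutations(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# random distance matrix via points in R^k (Euclidean-embeddable)
random_euclidean_dm <- function(n, k = 3) {
  pts <- matrix(rnorm(n * k), n)
  dm <- as.matrix(dist(pts))
  dimnames(dm) <- list(paste0("S", 1:n), paste0("S", 1:n))
  dm
}

# random Bray-Curtis distance matrix from a random count table
random_bc_dm <- function(n, p = 12) {
  m <- matrix(rpois(n * p, 8), n, p,
              dimnames = list(paste0("S", 1:n), paste0("O", 1:p)))
  m[rowSums(m) == 0, 1] <- 1
  suppressWarnings(bray_curtis(m))
}
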