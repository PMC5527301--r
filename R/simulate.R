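## Hierarchical community simulator.
##
## Per-sample OTU log-weights decompose additively:
##   log w = baseline + site + participant + couple + sex (designated sites)
##           + replicate noise
## weights are softmax-normalized, optionally Dirichlet-overdispersed, then
## multinomially sampled at a log-normal sequencing depth. The additive
## decomposition keeps each variance component recoverable downstream
## (site >> individual > couple ~ sex is the expected ordering in skin data).

#' Simulation configuration
#'
#' Defaults reproduce the couples-cohort design: 10 couples x 2 participants
#' x 17 swabs (7 bilateral + 3 midline locations) = 340 samples, with strong
#' body-site and individual effects, a weaker cohabitation (couple) effect,
#' and a sex effect concentrated on designated sites (inner thigh, armpit).
#'
#' @param n_couples number of couples (>= 2); each has one female (member A)
#'   and one male (member B).
#' @param body_locations data.frame like [body_locations()] with columns
#'   `location`, `bilateral`, `moisture`.
#' @param n_otus number of OTUs (>= 10).
#' @param baseline_sd sd of the global per-OTU log-abundance baseline
#'   (log-normal rank-abundance profile).
#' @param sigma_site,sigma_individual,sigma_couple,sigma_sex,sigma_noise
#'   standard deviations of the log-additive effects (dimensionless,
#'   log-abundance scale). `sigma_noise` is per-sample replicate noise.
#' @param sex_effect_sites locations carrying the compositional sex effect.
#' @param sex_evenness_factor multiplier applied to male samples' log-weights
#'   (all sites): values > 1 sharpen male communities, reproducing the
#'   female-higher-Shannon pattern typical of skin surveys; 1 disables it.
#' @param dispersion Dirichlet concentration scaler; finite values add
#'   overdispersion (smaller = noisier), `Inf` disables the Dirichlet layer.
#' @param depth_meanlog,depth_sdlog log-normal sequencing-depth law.
#' @param depth_floor minimum depth (>= 1).
#' @param seed integer seed making the whole draw deterministic.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_couples = 10,
                       body_locations = skinmatch::body_locations(),
                       n_otus = 400,
                       baseline_sd = 1.5,
                       sigma_site = 2.0,
                       sigma_individual = 1.0,
                       sigma_couple = 0.7,
                       sigma_sex = 1.0,
                       sigma_noise = 0.5,
                       sex_effect_sites = c("inner thigh", "armpit"),
                       sex_evenness_factor = 1.1,
                       dispersion = 200,
                       depth_meanlog = log(12000),
                       depth_sdlog = 0.3,
                       depth_floor = 6000,
                       seed = 1) {
  cfg <- list(n_couples = n_couples, body_locations = body_locations,
              n_otus = n_otus, baseline_sd = baseline_sd,
              sigma_site = sigma_site, sigma_individual = sigma_individual,
              sigma_couple = sigma_couple, sigma_sex = sigma_sex,
              sigma_noise = sigma_noise, sex_effect_sites = sex_effect_sites,
              sex_evenness_factor = sex_evenness_factor,
              dispersion = dispersion, depth_meanlog = depth_meanlog,
              depth_sdlog = depth_sdlog, depth_floor = depth_floor,
              seed = seed)
  sig <- c(cfg$sigma_site, cfg$sigma_individual, cfg$sigma_couple,
           cfg$sigma_sex, cfg$sigma_noise, cfg$baseline_sd)
  if (any(sig < 0)) stop("all effect sds must be >= 0")
  if (cfg$n_couples < 2) stop("n_couples must be >= 2")
  if (cfg$n_otus < 10) stop("n_otus must be >= 10")
  if (cfg$depth_floor < 1) stop("depth_floor must be >= 1")
  if (!all(c("location", "bilateral", "moisture") %in% names(body_locations)))
    stop("body_locations needs columns location, bilateral, moisture")
  rownames(cfg$body_locations) <- NULL
  if (!all(cfg$sex_effect_sites %in% body_locations$location))
    stop("sex_effect_sites must be declared body locations")
  if (cfg$dispersion <= 0) stop("dispersion must be positive (Inf allowed)")
  if (cfg$sex_evenness_factor <= 0) stop("sex_evenness_factor must be > 0")
  structure(cfg, class = "sim_config")
}

# swab layout for one participant: location x side rows with 2-digit codes
swab_layout <- function(body_locations) {
  rows <- lapply(seq_len(nrow(body_locations)), function(i) {
    loc <- body_locations[i, ]
    if (loc$bilateral)
      data.frame(location = loc$location, side = c("left", "right"),
                 moisture = loc$moisture, stringsAsFactors = FALSE)
    else
      data.frame(location = loc$location, side = "none",
                 moisture = loc$moisture, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$code <- sprintf("%02d", seq_len(nrow(out)))
  out
}

# arbitrary but skin-shaped lineages so taxonomy collapse has work to do
sim_taxonomy <- function(n_otus) {
  phyla <- c("Actinobacteria", "Firmicutes", "Proteobacteria",
             "Bacteroidetes", "Cyanobacteria")
  probs <- c(0.38, 0.30, 0.22, 0.06, 0.04)
  ph <- sample(phyla, n_otus, replace = TRUE, prob = probs)
  fam <- paste0("Fam", sample.int(3L, n_otus, replace = TRUE))
  sprintf(paste0("k__Bacteria; p__%s; c__%sia; o__%sales; ",
                 "f__%s_%s; g__Gen%d; s__sp%d"),
          ph, ph, ph, ph, fam, sample.int(40L, n_otus, TRUE),
          seq_len(n_otus))
}

#' Simulate a household-structured skin microbiome survey
#'
#' @param config a [sim_config()].
#' @return list with `table` (an `otu_table` with taxonomy), `meta` (a
#'   `sample_frame` including lifestyle columns), and `truth` (the realized
#'   effect matrices and per-sample composition, for parameter-recovery
#'   tests).
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_community_impl(config))
}

simulate_community_impl <- function(cfg) {
  layout <- swab_layout(cfg$body_locations)
  n_sites <- nrow(cfg$body_locations)
  couples <- sprintf("H%02d", seq_len(cfg$n_couples))
  # member A = female, B = male
  meta <- do.call(rbind, lapply(couples, function(cpl) {
    do.call(rbind, lapply(c("A", "B"), function(member) {
      data.frame(sample_id = paste0(cpl, member, layout$code),
                 participant = paste0(cpl, member),
                 couple = cpl,
                 sex = if (member == "A") "female" else "male",
                 body_location = layout$location,
                 side = layout$side,
                 moisture = layout$moisture,
                 stringsAsFactors = FALSE)
    }))
  }))
  participants <- unique(meta$participant)
  # lifestyle categories, constant within a participant
  life <- data.frame(
    participant = participants,
    AlcoholUse = sample(c("monthly", "weekly", "daily"),
                        length(participants), replace = TRUE),
    PetOwnership = sample(c("yes", "no"), length(participants), TRUE),
    HoursOutdoors = sample(c("<1", "1-4", ">4"), length(participants), TRUE),
    stringsAsFactors = FALSE)
  idx <- match(meta$participant, life$participant)
  meta$AlcoholUse <- life$AlcoholUse[idx]
  meta$PetOwnership <- life$PetOwnership[idx]
  meta$HoursOutdoors <- life$HoursOutdoors[idx]

  p <- cfg$n_otus
  baseline <- rnorm(p, 0, cfg$baseline_sd)
  site_eff <- matrix(rnorm(n_sites * p, 0, cfg$sigma_site), n_sites, p,
                     dimnames = list(cfg$body_locations$location, NULL))
  part_eff <- matrix(rnorm(length(participants) * p, 0, cfg$sigma_individual),
                     length(participants), p,
                     dimnames = list(participants, NULL))
  coup_eff <- matrix(rnorm(cfg$n_couples * p, 0, cfg$sigma_couple),
                     cfg$n_couples, p, dimnames = list(couples, NULL))
  sex_eff <- rnorm(p, 0, cfg$sigma_sex)

  n <- nrow(meta)
  depth <- pmax(cfg$depth_floor,
                round(rlnorm(n, cfg$depth_meanlog, cfg$depth_sdlog)))
  counts <- matrix(0, n, p, dimnames = list(meta$sample_id,
                                            sprintf("OTU%04d", seq_len(p))))
  probs <- matrix(0, n, p)
  in_sex_site <- meta$body_location %in% cfg$sex_effect_sites
  sex_sign <- ifelse(meta$sex == "female", 0.5, -0.5)
  for (i in seq_len(n)) {
    lw <- baseline +
      site_eff[meta$body_location[i], ] +
      part_eff[meta$participant[i], ] +
      coup_eff[meta$couple[i], ] +
      (if (in_sex_site[i]) sex_sign[i] * sex_eff else 0) +
      rnorm(p, 0, cfg$sigma_noise)
    # evenness component of the sex effect: sharpen male communities
    if (meta$sex[i] == "male") lw <- lw * cfg$sex_evenness_factor
    w <- exp(lw - max(lw))
    pr <- w / sum(w)
    if (is.finite(cfg$dispersion)) {
      g <- rgamma(p, shape = pr * cfg$dispersion)
      if (sum(g) == 0) g[which.max(pr)] <- 1
      pr <- g / sum(g)
    }
    probs[i, ] <- pr
    counts[i, ] <- rmultinom(1L, depth[i], pr)
  }
  degenerate <- all(c(cfg$sigma_site, cfg$sigma_individual, cfg$sigma_couple,
                      cfg$sigma_sex, cfg$sigma_noise) == 0) &&
    !is.finite(cfg$dispersion)
  if (degenerate)
    warning("degenerate config: all effect sds are 0 and dispersion is ",
            "infinite; samples are exchangeable draws from one composition")
  table <- otu_table(counts, taxonomy = sim_taxonomy(p))
  meta <- validate_sample_frame(meta)
  truth <- list(baseline = baseline, site_effects = site_eff,
                participant_effects = part_eff, couple_effects = coup_eff,
                sex_effect = sex_eff, probs = probs, depth = depth)
  list(table = table, meta = meta, truth = truth)
}

#' Downsample a few samples below a depth cutoff
#'
#' Fixture helper emulating failed/low-biomass libraries so the low-depth
#' filter has work to do: exactly `n` randomly chosen samples are rarefied to
#' depths below `below`; all others are untouched.
#'
#' @param x an `otu_table`.
#' @param n how many samples to degrade (`n = 0` is the identity).
#' @param below depth cutoff the degraded samples must fall under.
#' @param seed integer seed (partition and target depths are deterministic
#'   per seed).
#' @return an `otu_table`.
#' @export
seed_low_depth_samples <- function(x, n, below, seed = NULL) {
  n_samples <- nrow(x$counts)
  if (n >= n_samples) stop("n must be smaller than the number of samples (",
                           n_samples, ")")
  if (n == 0L) return(x)
  with_seed(seed, {
    victims <- sample.int(n_samples, n)
    lo <- max(1L, below %/% 2L)
    target <- sample(seq.int(lo, below - 1L), n, replace = TRUE)
    cnt <- x$counts
    for (k in seq_along(victims)) {
      i <- victims[k]
      d <- min(target[k], sum(cnt[i, ]))
      cnt[i, ] <- rarefy_row(cnt[i, ], d)
    }
    otu_table(cnt, taxonomy = x$taxonomy)
  })
}

#' Serialize / restore a simulation configuration
#'
#' Flat key=value text format; `body_locations` rows are encoded as
#' `location:bilateral:moisture` triplets and `sex_effect_sites` as a
#' comma-joined list, so a config round-trips exactly.
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `path` (write) or the restored `sim_config` (read).
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  bl <- config$body_locations
  kv <- c(
    vapply(setdiff(names(config), c("body_locations", "sex_effect_sites")),
           function(k) paste0(k, "=", format(config[[k]], digits = 17)),
           character(1L)),
    paste0("sex_effect_sites=", paste(config$sex_effect_sites,
                                      collapse = ",")),
    paste0("body_locations=",
           paste(sprintf("%s:%s:%s", bl$location,
                         ifelse(bl$bilateral, "bilateral", "single"),
                         bl$moisture), collapse = ",")))
  writeLines(kv, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- setNames(vapply(kv, function(x)
    paste(x[-1L], collapse = "="), character(1L)),
    vapply(kv, `[[`, character(1L), 1L))
  trip <- strsplit(strsplit(vals[["body_locations"]], ",")[[1L]], ":")
  bl <- data.frame(location = vapply(trip, `[[`, character(1L), 1L),
                   bilateral = vapply(trip, `[[`, character(1L), 2L) ==
                     "bilateral",
                   moisture = vapply(trip, `[[`, character(1L), 3L),
                   stringsAsFactors = FALSE)
  num <- function(k) as.numeric(vals[[k]])
  sim_config(n_couples = num("n_couples"), body_locations = bl,
             n_otus = num("n_otus"), baseline_sd = num("baseline_sd"),
             sigma_site = num("sigma_site"),
             sigma_individual = num("sigma_individual"),
             sigma_couple = num("sigma_couple"),
             sigma_sex = num("sigma_sex"),
             sigma_noise = num("sigma_noise"),
             sex_effect_sites = strsplit(vals[["sex_effect_sites"]],
                                         ",")[[1L]],
             sex_evenness_factor = num("sex_evenness_factor"),
             dispersion = num("dispersion"),
             depth_meanlog = num("depth_meanlog"),
             depth_sdlog = num("depth_sdlog"),
             depth_floor = num("depth_floor"),
             seed = num("seed"))
}

#' Write the simulation ground truth as a TSV bundle
#'
#' One TSV per effect component (`<prefix>_baseline.tsv`,
#' `_site_effects.tsv`, `_participant_effects.tsv`, `_couple_effects.tsv`,
#' `_sex_effect.tsv`, `_depth.tsv`), for parameter-recovery work outside R.
#'
#' @param truth the `truth` element of [simulate_community()].
#' @param prefix path prefix for the bundle.
#' @return the written paths, invisibly.
#' @export
write_sim_truth <- function(truth, prefix) {
  paths <- character(0)
  put <- function(obj, name) {
    p <- paste0(prefix, "_", name, ".tsv")
    df <- as.data.frame(obj)
    write.table(df, p, sep = "\t", quote = FALSE,
                row.names = !is.null(rownames(obj)) &&
                  !identical(rownames(obj), as.character(seq_len(NROW(obj)))))
    paths <<- c(paths, p)
  }
  put(data.frame(otu = seq_along(truth$baseline),
                 baseline = truth$baseline), "baseline")
  put(truth$site_effects, "site_effects")
  put(truth$participant_effects, "participant_effects")
  put(truth$couple_effects, "couple_effects")
  put(data.frame(otu = seq_along(truth$sex_effect),
                 effect = truth$sex_effect), "sex_effect")
  put(data.frame(depth = truth$depth), "depth")
  invisible(paths)
}

#' Simulate the full couples-design dataset, low-depth casualties included
#'
#' Convenience preset: [simulate_community()] with default design (340
#' samples) followed by [seed_low_depth_samples()] degrading 10 samples below
#' the 5,293-read cutoff, so that depth filtering retains 330 samples.
#'
#' @param seed integer seed.
#' @param ... overrides forwarded to [sim_config()].
#' @return list with `table`, `meta`, `truth`, and `config`.
#' @export
simulate_couples_design <- function(seed = 1, ...) {
  cfg <- sim_config(seed = seed, ...)
  sim <- simulate_community(cfg)
  sim$table <- seed_low_depth_samples(sim$table, n = 10L, below = 5293L,
                                      seed = seed + 1L)
  sim$config <- cfg
  sim
}
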