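## Alpha diversity and nonparametric category tests.

#' Shannon diversity of a count vector
#'
#' H = -sum p_i log(p_i) with p_i = counts / total; zero counts contribute
#' nothing. Log base 2 by default (the QIIME-1 convention).
#'
#' @param counts non-negative count (or proportion) vector with at least one
#'   positive entry.
#' @param base 2 or `exp(1)`.
#' @return Shannon index, in `[0, log_base(#positive entries)]`.
#' @export
shannon <- function(counts, base = 2) {
  if (all(counts == 0)) stop("Shannon undefined for an all-zero vector")
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log(p, base = base))
}

#' Number of observed OTUs (richness)
#' @param counts count vector.
#' @return integer count of strictly positive entries.
#' @export
observed_otus <- function(counts) sum(counts > 0)

alpha_metric_fun <- function(metric) {
  switch(metric,
         shannon = function(v) shannon(v),
         observed_otus = function(v) observed_otus(v),
         stop("unknown metric: ", metric))
}

#' Alpha diversity over a multiple-rarefaction sweep
#'
#' Computes `metric` on `reps` independent rarefactions of the table at every
#' depth of the arithmetic grid `seq(min_depth, max_depth, step)`, with
#' `max_depth` always included as the final depth. The canonical full-scale
#' sweep (100 to 5,290 by 100, 10 replicates) therefore evaluates
#' 53 x 10 = 530 rarefaction tables.
#'
#' @param x an `otu_table`; `max_depth` must not exceed the minimum depth.
#' @param min_depth,max_depth,step arithmetic depth grid.
#' @param reps rarefaction replicates per depth.
#' @param metric `"shannon"` or `"observed_otus"`.
#' @param seed integer seed.
#' @return object of class `alpha_result`: list with `values` (long
#'   data.frame sample_id / depth / rep / value), `metric`, `depths`,
#'   `reps`, `n_tables`.
#' @export
multiple_rarefactions_alpha <- function(x, min_depth = 100,
                                        max_depth = 5290, step = 100,
                                        reps = 10,
                                        metric = c("shannon",
                                                   "observed_otus"),
                                        seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(step > 0, reps >= 1)
  if (max_depth > min(sample_depths(x)))
    stop("max_depth exceeds the minimum sample depth; filter/rarefy first")
  if (min_depth > max_depth) stop("empty depth grid")
  depths <- seq.int(min_depth, max_depth, by = step)
  # the grid always includes the max depth (100..5290 by 100 -> 53 depths)
  if (depths[length(depths)] < max_depth) depths <- c(depths, max_depth)
  fun <- alpha_metric_fun(metric)
  values <- with_seed(seed, {
    do.call(rbind, lapply(depths, function(d) {
      do.call(rbind, lapply(seq_len(reps), function(r) {
        tab <- rarefy(x, d)
        data.frame(sample_id = sample_ids(tab), depth = d, rep = r,
                   value = apply(tab$counts, 1L, fun),
                   stringsAsFactors = FALSE, row.names = NULL)
      }))
    }))
  })
  structure(list(values = values, metric = metric, depths = depths,
                 reps = reps, n_tables = length(depths) * reps),
            class = "alpha_result")
}

#' @export
print.alpha_result <- function(x, ...) {
  cat(sprintf("alpha_result: %s over %d depths x %d reps = %d tables\n",
              x$metric, length(x$depths), x$reps, x$n_tables))
  invisible(x)
}

# Welch (unequal-variance) two-sample t statistic; 0 when both groups are
# constant and equal.
welch_t <- function(a, b) {
  va <- var(a); vb <- var(b)
  se2 <- va / length(a) + vb / length(b)
  if (se2 == 0) return(if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf)
  (mean(a) - mean(b)) / sqrt(se2)
}

#' Nonparametric (permutation) two-sample t test
#'
#' Classic unequal-variance t statistic; significance by random relabeling of
#' the pooled values, with the +1-smoothed estimator
#' p = (1 + #\{|t_perm| >= |t_obs|\}) / (1 + n_perms), so p is never 0.
#'
#' @param values_a,values_b numeric vectors (each length >= 2).
#' @param n_perms number of random relabelings (>= 1).
#' @param seed integer seed.
#' @return list with `t` and `p`.
#' @export
nonparametric_t_test <- function(values_a, values_b, n_perms = 999,
                                 seed = NULL) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2, n_perms >= 1)
  # sort so the permutation stream depends only on the value multisets,
  # making results invariant to sample order
  values_a <- sort(values_a)
  values_b <- sort(values_b)
  t_obs <- welch_t(values_a, values_b)
  if (t_obs == 0) return(list(t = 0, p = 1))
  pooled <- c(values_a, values_b)
  na <- length(values_a)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perms), function(i) {
      idx <- sample.int(length(pooled), na)
      abs(welch_t(pooled[idx], pooled[-idx])) >= abs(t_obs)
    }, logical(1L)))
  })
  list(t = t_obs, p = (1 + exceed) / (1 + n_perms))
}

#' Alpha-diversity significance sweep across metadata categories
#'
#' Per-sample alpha is the mean over replicates at the largest depth of the
#' sweep; each category is expanded to all pairwise level contrasts and
#' tested with [nonparametric_t_test()]; the Bonferroni factor is the number
#' of tests actually executed.
#'
#' @param alpha an `alpha_result`.
#' @param meta a `sample_frame` covering the alpha samples.
#' @param categories metadata column names to test.
#' @param n_perms permutations per test.
#' @param seed integer seed.
#' @return data.frame with one row per executed contrast: category, groups,
#'   means, sds, t, raw and Bonferroni-adjusted p, and `n_tests` (the
#'   Bonferroni factor).
#' @export
alpha_category_sweep <- function(alpha, meta, categories, n_perms = 999,
                                 seed = NULL) {
  stopifnot(inherits(alpha, "alpha_result"))
  miss <- setdiff(categories, names(meta))
  if (length(miss)) stop("unknown categories: ", paste(miss, collapse = ", "))
  vals <- alpha$values[alpha$values$depth == max(alpha$depths), ]
  per_sample <- tapply(vals$value, vals$sample_id, mean)
  meta <- meta[meta$sample_id %in% names(per_sample), ]
  y <- per_sample[meta$sample_id]
  rows <- list()
  with_seed(seed, {
    for (cat in categories) {
      lv <- sort(unique(meta[[cat]]))
      sizes <- table(meta[[cat]])
      for (pair in if (length(lv) >= 2) combn(lv, 2L, simplify = FALSE)
           else list()) {
        if (any(sizes[pair] < 2)) {
          warning(sprintf("category '%s': contrast %s vs %s skipped (<2 samples)",
                          cat, pair[1L], pair[2L]))
          next
        }
        a <- y[meta[[cat]] == pair[1L]]
        b <- y[meta[[cat]] == pair[2L]]
        tt <- nonparametric_t_test(a, b, n_perms = n_perms)
        rows[[length(rows) + 1L]] <- data.frame(
          category = cat, group_a = pair[1L], group_b = pair[2L],
          n_a = length(a), n_b = length(b),
          mean_a = mean(a), sd_a = sd(a), mean_b = mean(b), sd_b = sd(b),
          t = tt$t, p_raw = tt$p, stringsAsFactors = FALSE)
      }
    }
  })
  if (!length(rows)) stop("no testable contrasts in the sweep")
  out <- do.call(rbind, rows)
  out$n_tests <- nrow(out)
  out$p_adj <- pmin(1, out$p_raw * nrow(out))
  out[order(out$category, out$group_a, out$group_b), , drop = FALSE]
}
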