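## One-factor PERMANOVA on a distance matrix (Anderson's pseudo-F from
## sums of squared inter-point distances; significance by label permutation).

#' PERMANOVA pseudo-F statistic
#'
#' Anderson's decomposition from squared distances:
#' SS_total = (1/N) sum_\{i<j\} d_ij^2;
#' SS_within = sum_g (1/n_g) sum_\{i<j in g\} d_ij^2;
#' SS_among = SS_total - SS_within;
#' F = (SS_among / (a-1)) / (SS_within / (N-a)); R^2 = SS_among / SS_total.
#'
#' @param dm symmetric distance matrix.
#' @param labels group label per sample (>= 2 groups, each non-empty, N > a).
#' @return list with `F`, `R2`, `df_between` (a-1), `df_within` (N-a),
#'   `ss_among`, `ss_within`, `ss_total`.
#' @export
pseudo_f <- function(dm, labels) {
  n <- nrow(dm)
  if (length(labels) != n) stop("labels length must match dm")
  if (anyNA(labels)) stop("NA labels")
  labels <- as.character(labels)
  groups <- unique(labels)
  a <- length(groups)
  if (a < 2) stop("need at least 2 groups")
  if (n <= a) stop("need more samples than groups")
  d2 <- dm^2
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (g in groups) {
    idx <- labels == g
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * sum(idx))
  }
  ss_among <- ss_total - ss_within
  f <- (ss_among / (a - 1)) / (ss_within / (n - a))
  list(F = f, R2 = ss_among / ss_total, df_between = a - 1, df_within = n - a,
       ss_among = ss_among, ss_within = ss_within, ss_total = ss_total)
}

#' PERMANOVA permutation test
#'
#' Unrestricted random label permutations; the +1-smoothed estimator
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perms) (with 1,000 permutations the
#' minimum achievable p is ~0.001).
#'
#' @param dm symmetric distance matrix.
#' @param labels group labels.
#' @param n_perms number of permutations (>= 1).
#' @param seed integer seed.
#' @return object of class `permanova_result`: `F`, `R2`, `df_between`,
#'   `df_within`, `p`, `n_perms`.
#' @export
permanova_test <- function(dm, labels, n_perms = 999, seed = NULL) {
  stopifnot(n_perms >= 1)
  obs <- pseudo_f(dm, labels)
  labels <- as.character(labels)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perms), function(i) {
      pseudo_f(dm, sample(labels))$F >= obs$F
    }, logical(1L)))
  })
  structure(c(obs[c("F", "R2", "df_between", "df_within")],
              list(p = (1 + exceed) / (1 + n_perms), n_perms = n_perms)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: F_%d,%d = %.3f, R2 = %.4f, p = %.4g (%d perms)\n",
              x$df_between, x$df_within, x$F, x$R2, x$p, x$n_perms))
  invisible(x)
}

#' Per-category PERMANOVA significance sweep
#'
#' Runs a one-factor PERMANOVA for each metadata category, optionally within
#' each body location subset (the heatmap analysis: cells with p >= alpha are
#' flagged non-significant and rendered blank downstream).
#'
#' @param dm symmetric distance matrix.
#' @param meta a `sample_frame` covering dm samples.
#' @param categories metadata column names.
#' @param per_location run within each body_location subset.
#' @param n_perms permutations per test.
#' @param seed integer seed.
#' @param alpha significance threshold for the `significant` flag.
#' @return data.frame: category, location, F, R2, p, significant. Categories
#'   constant within a subset are skipped with a warning.
#' @export
category_sweep <- function(dm, meta, categories, per_location = FALSE,
                           n_perms = 999, seed = NULL, alpha = 0.05) {
  miss <- setdiff(categories, names(meta))
  if (length(miss)) stop("unknown categories: ", paste(miss, collapse = ", "))
  meta <- meta[match(rownames(dm), meta$sample_id), ]
  subsets <- if (per_location)
    split(seq_len(nrow(meta)), meta$body_location)
  else list(`(all)` = seq_len(nrow(meta)))
  rows <- list()
  with_seed(seed, {
    for (loc in names(subsets)) {
      idx <- subsets[[loc]]
      sub_dm <- dm[idx, idx, drop = FALSE]
      for (cat in sort(categories)) {
        lab <- meta[[cat]][idx]
        if (length(unique(lab)) < 2 || length(lab) <= length(unique(lab))) {
          warning(sprintf("category '%s' skipped in '%s' (constant or too few samples)",
                          cat, loc))
          next
        }
        res <- permanova_test(sub_dm, lab, n_perms = n_perms)
        rows[[length(rows) + 1L]] <- data.frame(
          category = cat, location = loc, F = res$F, R2 = res$R2, p = res$p,
          significant = res$p < alpha, stringsAsFactors = FALSE)
      }
    }
  })
  if (!length(rows)) stop("no testable category/location cells")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Heatmap-shaped matrix from a per-location PERMANOVA sweep
#'
#' Pivots [category_sweep()] output into the categories x locations matrix
#' used by the significance heatmap: cells hold the pseudo-F, blanked (NA)
#' where p >= the significance threshold.
#'
#' @param sweep output of [category_sweep()].
#' @return numeric matrix, rows = categories, columns = locations, NA for
#'   non-significant or untested cells.
#' @export
permanova_heatmap <- function(sweep) {
  cats <- sort(unique(sweep$category))
  locs <- sort(unique(sweep$location))
  m <- matrix(NA_real_, length(cats), length(locs),
              dimnames = list(cats, locs))
  sig <- sweep[sweep$significant, , drop = FALSE]
  m[cbind(match(sig$category, cats), match(sig$location, locs))] <- sig$F
  m
}
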