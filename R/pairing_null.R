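## Couple-pairing permutation null: every "incorrect pairing" is a
## derangement of the couple indices (no female keeps her true partner);
## PERMANOVA pseudo-F and classifier error are recomputed under each pairing
## and compared to the true pairing.

#' Derangement count !n
#'
#' Computed by the recurrence !n = (n-1)(!(n-1) + !(n-2)) with !0 = 1,
#' !1 = 0 (never assumed from a lookup table).
#'
#' @param n non-negative integer.
#' @return the number of derangements of n items (double; exact below 2^53).
#' @export
derangement_count <- function(n) {
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(1)
  if (n == 1) return(0)
  d2 <- 1; d1 <- 0 # !0, !1
  for (k in 2:n) {
    d <- (k - 1) * (d1 + d2)
    d2 <- d1; d1 <- d
  }
  d1
}

#' Enumerate all incorrect couple pairings (derangements)
#'
#' A pairing maps the female of couple i to the male of couple `pairing[i]`;
#' "incorrect" means no fixed point. Enumeration is recursive with pruning
#' and is limited to n <= 9 (!9 = 133,496); use [sample_unique_pairings()]
#' for larger designs.
#'
#' @param n_couples integer >= 2.
#' @return integer matrix, one derangement per row.
#' @export
enumerate_incorrect_pairings <- function(n_couples) {
  if (n_couples < 2) stop("n_couples must be >= 2")
  if (n_couples > 9) stop("enumeration limited to n_couples <= 9 (!", n_couples,
                          " = ", format(derangement_count(n_couples),
                                        big.mark = ","),
                          "); use sample_unique_pairings()")
  out <- vector("list", 0L)
  recurse <- function(prefix, remaining) {
    pos <- length(prefix) + 1L
    if (!length(remaining)) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (v in remaining)
      if (v != pos) recurse(c(prefix, v), setdiff(remaining, v))
  }
  recurse(integer(0), seq_len(n_couples))
  do.call(rbind, out)
}

#' Sample distinct incorrect pairings uniformly without replacement
#'
#' For small designs the derangements are enumerated and subsampled; for
#' larger designs uniform random permutations are rejection-sampled until
#' `n_samples` distinct derangements are collected (rejection from the
#' uniform permutation law conditioned on zero fixed points is uniform over
#' derangements; discarding duplicates yields without-replacement sampling).
#'
#' @param n_couples integer >= 2.
#' @param n_samples how many distinct pairings (<= !n_couples).
#' @param seed integer seed.
#' @return integer matrix, one derangement per row.
#' @export
sample_unique_pairings <- function(n_couples, n_samples, seed = NULL) {
  total <- derangement_count(n_couples)
  if (n_samples > total)
    stop(sprintf("requested %s pairings but only !%d = %s derangements exist",
                 format(n_samples, big.mark = ","), n_couples,
                 format(total, big.mark = ",")))
  with_seed(seed, {
    if (n_couples <= 7) {
      all_d <- enumerate_incorrect_pairings(n_couples)
      return(all_d[sample.int(nrow(all_d), n_samples), , drop = FALSE])
    }
    seen <- new.env(hash = TRUE, parent = emptyenv())
    out <- matrix(0L, n_samples, n_couples)
    got <- 0L
    while (got < n_samples) {
      perm <- sample.int(n_couples)
      if (any(perm == seq_len(n_couples))) next
      key <- paste(perm, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      got <- got + 1L
      out[got, ] <- perm
    }
    out
  })
}

#' Apply a couple pairing to sample metadata
#'
#' Builds pseudo-couples: pseudo-couple i is \{female of couple i, male of
#' couple pairing[i]\}. Couple labels are reassigned accordingly (males move,
#' females keep their label); every other field is untouched. The identity
#' pairing returns the metadata unchanged.
#'
#' @param meta a `sample_frame`.
#' @param pairing integer permutation of `seq_along(couples)`.
#' @param couples couple labels defining the index order (default sorted
#'   unique couples of `meta`).
#' @return a `sample_frame` with relabeled couples.
#' @export
relabel_couples <- function(meta, pairing, couples = sort(unique(meta$couple))) {
  n <- length(couples)
  if (length(pairing) != n || !setequal(pairing, seq_len(n)))
    stop("pairing must be a permutation of 1..", n)
  miss <- setdiff(couples, meta$couple)
  if (length(miss)) stop("couple missing from metadata: ", miss[1L])
  male <- meta$sex == "male"
  old_idx <- match(meta$couple, couples)
  inv <- integer(n); inv[pairing] <- seq_len(n) # male of couple j -> pseudo inv[j]
  new_couple <- meta$couple
  new_couple[male] <- couples[inv[old_idx[male]]]
  meta$couple <- new_couple
  meta
}

new_null_distribution <- function(statistic, observed, null_values, p) {
  structure(list(statistic = statistic, observed = observed,
                 null_values = null_values, p = p,
                 n_null = length(null_values)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("pairing null (%s): observed %.4f vs %d null pairings, p = %.4g\n",
              x$statistic, x$observed, x$n_null, x$p))
  invisible(x)
}

#' Couple-pairing null for the PERMANOVA pseudo-F
#'
#' Observed statistic: pseudo-F of the true couple labels. Null: pseudo-F
#' recomputed after relabeling couples under each incorrect pairing
#' (everything else in the metadata identical). Large F for the true pairing
#' indicates partners share community structure beyond chance;
#' p = (1 + #\{F_null >= F_obs\}) / (1 + n_null).
#'
#' @param dm symmetric distance matrix.
#' @param meta a `sample_frame` covering dm samples.
#' @param pairings matrix of derangements (rows), e.g. from
#'   [sample_unique_pairings()].
#' @param per_location if TRUE, one null distribution per body location.
#' @return a `null_distribution`, or a named list of them when
#'   `per_location = TRUE`.
#' @export
pairing_null_permanova <- function(dm, meta, pairings, per_location = FALSE) {
  if (is.null(dim(pairings))) pairings <- matrix(pairings, nrow = 1L)
  if (!nrow(pairings)) stop("need at least one incorrect pairing")
  meta <- meta[match(rownames(dm), meta$sample_id), ]
  couples <- sort(unique(meta$couple))
  run_one <- function(idx) {
    sub_dm <- dm[idx, idx, drop = FALSE]
    sub_meta <- meta[idx, ]
    f_obs <- pseudo_f(sub_dm, sub_meta$couple)$F
    f_null <- vapply(seq_len(nrow(pairings)), function(k) {
      relab <- relabel_couples(sub_meta, pairings[k, ], couples)
      pseudo_f(sub_dm, relab$couple)$F
    }, numeric(1L))
    new_null_distribution("permanova_F", f_obs, f_null,
                          (1 + sum(f_null >= f_obs)) / (1 + length(f_null)))
  }
  if (!per_location) return(run_one(seq_len(nrow(meta))))
  lapply(split(seq_len(nrow(meta)), meta$body_location), run_one)
}

#' Couple-pairing null for the classifier error
#'
#' Observed statistic: cross-validated random-forest error classifying the
#' true couple labels. Null: the error recomputed under each incorrect
#' pairing. Couples sharing microbiota are EASIER to classify than arbitrary
#' male/female groupings, so small errors are extreme:
#' p = (1 + #\{error_null <= error_obs\}) / (1 + n_null).
#'
#' @param x an `otu_table` of rarefied counts.
#' @param meta a `sample_frame` covering the table samples.
#' @param pairings matrix of derangements (rows).
#' @param n_trees,n_folds,n_repeats,mtry classifier configuration; the
#'   full-scale canonical setting is 1,000 trees / 10 folds, tests use
#'   declared scaled-down values.
#' @param seed integer seed.
#' @return a `null_distribution` (statistic `classifier_error`).
#' @export
pairing_null_classifier <- function(x, meta, pairings, n_trees = 1000,
                                    n_folds = 10, n_repeats = 1, mtry = NULL,
                                    seed = NULL) {
  if (is.null(dim(pairings))) pairings <- matrix(pairings, nrow = 1L)
  if (!nrow(pairings)) stop("need at least one incorrect pairing")
  meta <- meta[match(sample_ids(x), meta$sample_id), ]
  couples <- sort(unique(meta$couple))
  err <- function(labels, s)
    suppressWarnings(
      couple_classifier_error(x, labels, n_trees = n_trees,
                              n_folds = n_folds, n_repeats = n_repeats,
                              mtry = mtry, seed = s))$error
  # each pairing draws from a content-derived RNG substream so the null
  # distribution is invariant to the order in which pairings are evaluated
  e_obs <- err(meta$couple, seed)
  e_null <- vapply(seq_len(nrow(pairings)), function(k) {
    s <- if (is.null(seed)) NULL else pairing_seed(seed, pairings[k, ])
    err(relabel_couples(meta, pairings[k, ], couples)$couple, s)
  }, numeric(1L))
  new_null_distribution("classifier_error", e_obs, e_null,
                        (1 + sum(e_null <= e_obs)) / (1 + length(e_null)))
}

#' Binned histogram of a pairing-null distribution
#'
#' Export-ready bar-plot data: equal-width bins spanning the null values and
#' the observed statistic, with the observed bin flagged (the "dotted line"
#' of the shuffled-pairing figures).
#'
#' @param nd a `null_distribution`.
#' @param n_bins number of bins.
#' @return data.frame: bin_lo, bin_hi, count, contains_observed.
#' @export
binned_null_histogram <- function(nd, n_bins = 20) {
  stopifnot(inherits(nd, "null_distribution"), n_bins >= 1)
  rng <- range(c(nd$null_values, nd$observed))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- function(v) pmin(pmax(findInterval(v, breaks,
                                            rightmost.closed = TRUE), 1L),
                          n_bins)
  counts <- tabulate(bin(nd$null_values), nbins = n_bins)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
             count = counts,
             contains_observed = seq_len(n_bins) == bin(nd$observed))
}

# deterministic seed from a pairing's content (polynomial hash, < 2^30)
pairing_seed <- function(seed, pairing) {
  h <- as.integer(seed) %% 1073741789
  for (v in pairing) h <- (h * 131 + v) %% 1073741789
  as.integer(h)
}
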