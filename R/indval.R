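## Dufrene-Legendre indicator species analysis, core OTUs, and the
## sex-enrichment table.

# A (specificity), B (fidelity) and IndVal = A*B for every OTU x group;
# returns list(A, B, iv, means) with groups in rows, OTUs in columns
indval_components <- function(counts, groups) {
  g <- factor(groups)
  means <- rowsum(counts, g) / as.vector(table(g))   # group x OTU mean
  pres <- rowsum((counts > 0) * 1, g) / as.vector(table(g)) # fidelity
  tot <- colSums(means)
  A <- sweep(means, 2L, ifelse(tot > 0, tot, 1), "/")
  A[, tot == 0] <- 0
  iv <- A * pres
  list(A = A, B = pres, iv = iv, means = means)
}

#' Dufrene-Legendre indicator value analysis
#'
#' Per OTU and group: specificity A (the group's share of the OTU's summed
#' group means), fidelity B (fraction of the group's samples containing the
#' OTU) and IndVal = A x B on the 0-1 scale. Significance: group labels are
#' permuted and the max-over-groups IndVal per OTU is compared to its
#' permutation distribution (p = (1 + #\{max_perm >= max_obs\}) / (1 +
#' n_perms)); the OTU-level p is attached to each of its group records.
#'
#' @param x an `otu_table` (rarefied counts) or numeric matrix.
#' @param groups group label per sample (>= 2 groups).
#' @param n_perms label permutations (default 999).
#' @param seed integer seed.
#' @param percent_scale report IndVal on the historical 0-100 scale.
#' @return data.frame of class `indval_result`: otu_id, group, A, B, indval,
#'   mean_abundance (within the group), p.
#' @export
indval <- function(x, groups, n_perms = 999, seed = NULL,
                   percent_scale = FALSE) {
  counts <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  if (length(groups) != nrow(counts)) stop("groups length must match samples")
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  stopifnot(n_perms >= 1)
  obs <- indval_components(counts, groups)
  max_obs <- apply(obs$iv, 2L, max)
  exceed <- with_seed(seed, {
    e <- numeric(ncol(counts))
    for (i in seq_len(n_perms)) {
      perm <- indval_components(counts, sample(groups))
      e <- e + (apply(perm$iv, 2L, max) >= max_obs)
    }
    e
  })
  p_otu <- (1 + exceed) / (1 + n_perms)
  scale <- if (percent_scale) 100 else 1
  grp <- rownames(obs$iv)
  out <- do.call(rbind, lapply(grp, function(g) {
    data.frame(otu_id = colnames(counts), group = g,
               A = obs$A[g, ], B = obs$B[g, ],
               indval = scale * obs$iv[g, ],
               mean_abundance = obs$means[g, ],
               p = p_otu, stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (inherits(x, "otu_table") && !is.null(x$taxonomy))
    out$taxonomy <- unname(x$taxonomy[out$otu_id])
  class(out) <- c("indval_result", "data.frame")
  out
}

#' Filter indicator records by the canonical thresholds
#'
#' Keeps records with IndVal >= 0.7, within-group mean abundance >= 10 reads
#' and permutation p < 0.05 (all three configurable).
#'
#' @param records an `indval_result`.
#' @param indval_min minimum indicator value (0-1 scale).
#' @param mean_min minimum mean abundance within the indicated group.
#' @param alpha significance threshold.
#' @return the filtered records.
#' @export
filter_indicators <- function(records, indval_min = 0.7, mean_min = 10,
                              alpha = 0.05) {
  keep <- records$indval >= indval_min & records$mean_abundance >= mean_min &
    records$p < alpha
  records[keep, , drop = FALSE]
}

#' Core OTUs of a metadata category level
#'
#' OTUs with at least one read in EVERY sample of the level.
#'
#' @param x an `otu_table`.
#' @param meta a `sample_frame`.
#' @param category metadata column.
#' @param level level of the category.
#' @return character vector of OTU ids.
#' @export
core_otus <- function(x, meta, category, level) {
  meta <- meta[match(sample_ids(x), meta$sample_id), ]
  idx <- which(meta[[category]] == level)
  if (!length(idx)) stop("empty level '", level, "' of '", category, "'")
  sub <- x$counts[idx, , drop = FALSE]
  otu_ids(x)[colSums(sub > 0) == length(idx)]
}

#' Sex-enrichment table
#'
#' For each OTU present in at least `prevalence_min` of the samples of its
#' enriched sex, reports the direction and the percent increase in mean
#' abundance, (mean_high / mean_low - 1) x 100. OTUs absent from the
#' depleted sex (mean_low = 0) are flagged infinite and excluded from the
#' ranking by default. The top `top_n` per direction are returned, sorted by
#' decreasing increase.
#'
#' @param x an `otu_table` (rarefied counts).
#' @param meta a `sample_frame`.
#' @param prevalence_min minimum prevalence in the enriched sex (default 0.30).
#' @param top_n rows reported per direction (default 10).
#' @param include_infinite keep mean_low = 0 rows (ranked last).
#' @return data.frame: otu_id, taxonomy (when available), direction
#'   (`female`/`male`), mean_female, mean_male, prevalence in the enriched
#'   sex, percent_increase.
#' @export
sex_enrichment_table <- function(x, meta, prevalence_min = 0.30, top_n = 10,
                                 include_infinite = FALSE) {
  meta <- meta[match(sample_ids(x), meta$sample_id), ]
  sexes <- unique(meta$sex)
  if (!setequal(sexes, c("female", "male"))) stop("need both sexes present")
  cnt <- x$counts
  f <- meta$sex == "female"
  mean_f <- colMeans(cnt[f, , drop = FALSE])
  mean_m <- colMeans(cnt[!f, , drop = FALSE])
  prev_f <- colMeans(cnt[f, , drop = FALSE] > 0)
  prev_m <- colMeans(cnt[!f, , drop = FALSE] > 0)
  dir_f <- mean_f > mean_m
  hi <- ifelse(dir_f, mean_f, mean_m)
  lo <- ifelse(dir_f, mean_m, mean_f)
  prev_hi <- ifelse(dir_f, prev_f, prev_m)
  pct <- ifelse(lo > 0, (hi / lo - 1) * 100, Inf)
  out <- data.frame(otu_id = otu_ids(x),
                    direction = ifelse(dir_f, "female", "male"),
                    mean_female = mean_f, mean_male = mean_m,
                    prevalence = prev_hi, percent_increase = pct,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(x$taxonomy)) out$taxonomy <- unname(x$taxonomy[out$otu_id])
  out <- out[out$prevalence >= prevalence_min & hi > 0, , drop = FALSE]
  if (!include_infinite) out <- out[is.finite(out$percent_increase), ,
                                    drop = FALSE]
  picked <- lapply(c("female", "male"), function(d) {
    sub <- out[out$direction == d, , drop = FALSE]
    sub <- sub[order(-sub$percent_increase), , drop = FALSE]
    utils::head(sub, top_n)
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}
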