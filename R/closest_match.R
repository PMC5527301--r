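## Nearest-neighbor self / partner / other matching with chance baselines.

relation_of <- function(query, match, meta) {
  qi <- match(query, meta$sample_id)
  mi <- match(match, meta$sample_id)
  ifelse(meta$participant[mi] == meta$participant[qi], "self",
         ifelse(meta$couple[mi] == meta$couple[qi], "partner", "other"))
}

#' Closest-sample matching under self/partner/other scopes
#'
#' For each query sample, finds the minimum-distance candidate and labels the
#' relation: `self` (same participant), `partner` (same couple, different
#' participant) or `other`. Scopes restrict the candidate pool: `all`
#' excludes only the query itself; `nonself` excludes every sample of the
#' query's participant; `nonself_opposite_sex` further excludes all same-sex
#' participants. Ties are broken by lexicographic sample id and flagged.
#'
#' @param dm symmetric distance matrix with sample ids.
#' @param meta a `sample_frame` covering all dm samples.
#' @param scope `"all"`, `"nonself"` or `"nonself_opposite_sex"`.
#' @param within_location restrict candidates to the query's body location
#'   (default TRUE, the per-location analysis).
#' @return data.frame of match records: query, match, distance, relation,
#'   scope, body_location, tie. Queries with an empty candidate pool are
#'   skipped with a warning.
#' @export
nearest_neighbors <- function(dm, meta,
                              scope = c("all", "nonself",
                                        "nonself_opposite_sex"),
                              within_location = TRUE) {
  scope <- match.arg(scope)
  ids <- rownames(dm)
  miss <- setdiff(ids, meta$sample_id)
  if (length(miss)) stop("samples missing from metadata: ", miss[1L])
  meta <- meta[match(ids, meta$sample_id), ]
  n <- length(ids)
  rows <- vector("list", n)
  skipped <- 0L
  for (i in seq_len(n)) {
    pool <- rep(TRUE, n)
    pool[i] <- FALSE
    if (scope != "all")
      pool <- pool & meta$participant != meta$participant[i]
    if (scope == "nonself_opposite_sex")
      pool <- pool & meta$sex != meta$sex[i]
    if (within_location)
      pool <- pool & meta$body_location == meta$body_location[i]
    cand <- which(pool)
    if (!length(cand)) { skipped <- skipped + 1L; next }
    d <- dm[i, cand]
    best <- cand[d == min(d)]
    tie <- length(best) > 1L
    j <- best[order(ids[best])][1L]
    rows[[i]] <- data.frame(query = ids[i], match = ids[j],
                            distance = dm[i, j],
                            relation = relation_of(ids[i], ids[j], meta),
                            scope = scope,
                            body_location = meta$body_location[i],
                            within_location = within_location,
                            tie = tie, stringsAsFactors = FALSE)
  }
  if (skipped) warning(skipped, " quer", if (skipped == 1L) "y" else "ies",
                       " skipped: empty candidate pool")
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query = character(), match = character(),
                      distance = numeric(), relation = character(),
                      scope = character(), body_location = character(),
                      within_location = logical(), tie = logical(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Analytic chance baseline for the partner relation
#'
#' Participant-level uniform choice among eligible participants. For `n`
#' participants (n/2 couples): `nonself` and `all` scopes give `1/(n-1)`
#' (the partner is one of n-1 non-query participants; under `all`, self
#' matches are excluded from the partner baseline); `nonself_opposite_sex`
#' gives `1/(n/2)` (the partner is one of n/2 opposite-sex participants).
#'
#' @param n_participants even integer >= 4.
#' @param scope matching scope.
#' @return baseline probability that a random match is the partner.
#' @export
chance_baseline <- function(n_participants,
                            scope = c("all", "nonself",
                                      "nonself_opposite_sex")) {
  scope <- match.arg(scope)
  if (n_participants %% 2 != 0) stop("n_participants must be even")
  if (n_participants < 4) stop("need at least 2 couples")
  switch(scope,
         all = 1 / (n_participants - 1),
         nonself = 1 / (n_participants - 1),
         nonself_opposite_sex = 1 / (n_participants / 2))
}

#' Summarize match records as self/partner/other proportions
#'
#' Per body location (and an `(overall)` pooled row) within each scope:
#' proportions of self, partner, other matches, counts, the analytic
#' participant-level chance baseline for the partner relation, a sample-level
#' empirical baseline (partner samples / eligible samples, averaged over
#' queries) for sensitivity, and fold-over-chance.
#'
#' @param records output of [nearest_neighbors()].
#' @param meta a `sample_frame`.
#' @return data.frame of class `match_summary`.
#' @export
match_proportions <- function(records, meta) {
  if (!nrow(records)) stop("no match records")
  n_participants <- length(unique(meta$participant))
  strata <- split(records, list(records$scope, records$body_location),
                  drop = TRUE)
  pooled <- split(records, records$scope)
  names(pooled) <- paste0(names(pooled), ".(overall)")
  strata <- c(strata, pooled)
  rows <- lapply(names(strata), function(key) {
    rec <- strata[[key]]
    scope <- rec$scope[1L]
    loc <- sub("^[^.]*\\.", "", key)
    base <- chance_baseline(n_participants, scope)
    emp <- empirical_partner_baseline(rec, meta)
    p_partner <- mean(rec$relation == "partner")
    data.frame(scope = scope, body_location = loc, n = nrow(rec),
               p_self = mean(rec$relation == "self"),
               p_partner = p_partner,
               p_other = mean(rec$relation == "other"),
               chance_partner = base,
               chance_partner_sample_level = emp,
               fold_partner = p_partner / base,
               ties = sum(rec$tie), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$scope, out$body_location != "(overall)",
                   out$body_location), ]
  rownames(out) <- NULL
  class(out) <- c("match_summary", "data.frame")
  out
}

# Sample-level baseline: mean over queries of
# (#partner samples in pool) / (#pool samples).
empirical_partner_baseline <- function(records, meta) {
  within_loc <- isTRUE(records$within_location[1L])
  qi <- match(records$query, meta$sample_id)
  vals <- vapply(seq_len(nrow(records)), function(k) {
    i <- qi[k]
    pool <- rep(TRUE, nrow(meta))
    pool[i] <- FALSE
    if (records$scope[k] != "all")
      pool <- pool & meta$participant != meta$participant[i]
    if (records$scope[k] == "nonself_opposite_sex")
      pool <- pool & meta$sex != meta$sex[i]
    if (within_loc)
      pool <- pool & meta$body_location == meta$body_location[i]
    if (!any(pool)) return(NA_real_)
    partner <- pool & meta$couple == meta$couple[i] &
      meta$participant != meta$participant[i]
    sum(partner) / sum(pool)
  }, numeric(1L))
  mean(vals, na.rm = TRUE)
}

#' Same-sex bias among non-partner matches
#'
#' Among `nonself` records whose match is neither self nor partner, the
#' fraction matching a participant of the query's own sex, with a two-sided
#' exact binomial test against the design null (for n participants:
#' (n/2 - 1) same-sex candidates of n - 2 non-partner others; 9/18 = 0.5 for
#' 10 couples).
#'
#' @param records `nonself`-scope match records.
#' @param meta a `sample_frame`.
#' @return list with `rate`, `p`, `n`, `null_prob`.
#' @export
same_sex_nonpartner_rate <- function(records, meta) {
  rec <- records[records$scope == "nonself" & records$relation == "other", ]
  if (!nrow(rec)) stop("no nonself 'other' records")
  n_participants <- length(unique(meta$participant))
  null_prob <- (n_participants / 2 - 1) / (n_participants - 2)
  qs <- meta$sex[match(rec$query, meta$sample_id)]
  ms <- meta$sex[match(rec$match, meta$sample_id)]
  same <- sum(qs == ms)
  bt <- binom.test(same, nrow(rec), p = null_prob)
  list(rate = same / nrow(rec), p = bt$p.value, n = nrow(rec),
       null_prob = null_prob)
}
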