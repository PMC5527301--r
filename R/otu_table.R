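#' @useDynLib skinmatch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rlnorm rnorm rgamma rmultinom sd var ks.test binom.test
#'   chisq.test rpois cor aggregate
#' @importFrom utils read.delim write.table combn
NULL

## Body-location vocabulary of the couples study design: 7 bilateral + 3
## midline sites = 17 swabs per participant.
.BODY_LOCATIONS <- data.frame(
  location  = c("eyelid", "outer nose", "inner nostril", "armpit", "torso",
                "back", "navel", "inner thigh", "foot", "palm"),
  bilateral = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
  moisture  = c("oily", "oily", "moist", "moist", "oily",
                "oily", "moist", "moist", "moist", "dry"),
  stringsAsFactors = FALSE
)

#' Declared body-location vocabulary
#'
#' The ten skin sites of the cohabiting-couples study design, with their
#' bilaterality (left/right swabs versus a single midline swab) and their
#' conventional skin moisture class (dry / moist / oily-sebaceous).
#'
#' @return A data.frame with columns `location`, `bilateral`, `moisture`.
#' @export
body_locations <- function() .BODY_LOCATIONS

# run expr under a temporary RNG state seeded with `seed`; NULL = use current
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

#' Construct an OTU table
#'
#' The universal currency of the pipeline: a samples x OTUs matrix of
#' non-negative integer counts with unique sample and OTU identifiers and an
#' optional Greengenes-style semicolon-ranked taxonomy string per OTU.
#'
#' @param counts numeric matrix, samples in rows, OTUs in columns. Must be
#'   non-negative integers. Row/column names are used as ids when
#'   `sample_ids`/`otu_ids` are not given.
#' @param sample_ids character vector of unique sample identifiers.
#' @param otu_ids character vector of unique OTU identifiers.
#' @param taxonomy optional character vector (one lineage per OTU).
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts), taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("empty OTU table")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (length(sample_ids) != nrow(counts) || length(otu_ids) != ncol(counts))
    stop("id lengths do not match count matrix dimensions")
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop("duplicate sample id: ", dup[1L])
  dup <- otu_ids[duplicated(otu_ids)]
  if (length(dup)) stop("duplicate OTU id: ", dup[1L])
  if (anyNA(counts)) stop("counts contain NA")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer or negative count at sample '%s', OTU '%s'",
                 sample_ids[bad[1L, 1L]], otu_ids[bad[1L, 2L]]))
  storage.mode(counts) <- "double" # exact for counts < 2^53, avoids int overflow
  dimnames(counts) <- list(sample_ids, otu_ids)
  if (!is.null(taxonomy)) {
    if (length(taxonomy) != ncol(counts))
      stop("taxonomy length must equal number of OTUs")
    taxonomy <- as.character(taxonomy)
    names(taxonomy) <- otu_ids
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$taxonomy)) "" else " (with taxonomy)"))
  d <- sample_depths(x)
  cat(sprintf("  depth: min %s / median %s / max %s\n",
              format(min(d)), format(stats::median(d)), format(max(d))))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Sample identifiers of an OTU table
#' @param x an `otu_table`.
#' @return character vector.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' OTU identifiers of an OTU table
#' @param x an `otu_table`.
#' @return character vector.
#' @export
otu_ids <- function(x) colnames(x$counts)

#' Per-sample sequencing depth (row sums)
#' @param x an `otu_table`.
#' @return named numeric vector.
#' @export
sample_depths <- function(x) rowSums(x$counts)

#' Subset an OTU table by sample and/or OTU
#' @param x an `otu_table`.
#' @param samples sample ids or indices (default all).
#' @param otus OTU ids or indices (default all).
#' @return an `otu_table`.
#' @export
subset_samples <- function(x, samples = NULL, otus = NULL) {
  cnt <- x$counts
  if (!is.null(samples)) cnt <- cnt[samples, , drop = FALSE]
  if (!is.null(otus)) cnt <- cnt[, otus, drop = FALSE]
  tax <- if (is.null(x$taxonomy)) NULL else x$taxonomy[colnames(cnt)]
  otu_table(cnt, taxonomy = tax)
}

#' Read a QIIME-classic OTU table
#'
#' Parses the tab-separated OTU-table dialect: header sentinel `#OTU ID`
#' (OTUs as rows) or a plain sample-id header (samples as rows), with an
#' optional trailing `taxonomy` column holding semicolon-ranked lineages.
#'
#' @param path file path.
#' @param orientation `"auto"` (detect from the `#OTU ID` sentinel),
#'   `"otus_as_rows"` or `"samples_as_rows"`.
#' @return an `otu_table`, normalized to samples x OTUs.
#' @export
read_otu_table <- function(path,
                           orientation = c("auto", "otus_as_rows",
                                           "samples_as_rows")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  lines <- lines[!grepl("^# ", lines) | grepl("^#OTU ID", lines)]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty table: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (orientation == "auto")
    orientation <- if (identical(header[1L], "#OTU ID")) "otus_as_rows"
                   else "samples_as_rows"
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  if (!length(body)) stop("empty table: ", path)
  n_col <- length(header)
  if (any(lengths(body) != n_col)) stop("ragged rows in ", path)
  cells <- do.call(rbind, body)
  row_ids <- cells[, 1L]
  col_ids <- header[-1L]
  taxonomy <- NULL
  has_tax <- length(col_ids) > 0L &&
    tolower(col_ids[length(col_ids)]) %in% c("taxonomy", "consensus lineage")
  if (orientation == "otus_as_rows" && has_tax) {
    taxonomy <- cells[, n_col]
    cells <- cells[, -n_col, drop = FALSE]
    col_ids <- col_ids[-length(col_ids)]
  }
  num <- suppressWarnings(
    matrix(as.numeric(cells[, -1L, drop = FALSE]),
           nrow = nrow(cells),
           dimnames = list(row_ids, col_ids)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric count at row '%s', column '%s'",
                 row_ids[bad[1L]], col_ids[bad[2L]]))
  }
  if (orientation == "otus_as_rows") {
    otu_table(t(num), taxonomy = taxonomy)
  } else {
    otu_table(num)
  }
}

#' Write an OTU table in the canonical QIIME-classic dialect
#'
#' One row per OTU, header `#OTU ID`, optional final `taxonomy` column.
#'
#' @param x an `otu_table`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  m <- t(x$counts) # OTUs as rows
  header <- c("#OTU ID", rownames(x$counts))
  rows <- cbind(rownames(m), format_counts(m))
  if (!is.null(x$taxonomy)) {
    header <- c(header, "taxonomy")
    rows <- cbind(rows, unname(x$taxonomy[rownames(m)]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(apply(rows, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

format_counts <- function(m) {
  out <- format(m, trim = TRUE, scientific = FALSE)
  dim(out) <- dim(m)
  out
}

#' Read a QIIME mapping file into a sample frame
#'
#' Tab-separated, first column `#SampleID`; required columns `Participant`,
#' `Couple`, `Sex`, `BodyLocation`, `Side`, `Moisture`. Any extra columns are
#' kept verbatim as lifestyle categories. Validates the couples design: every
#' couple has exactly two participants, one female and one male; body
#' locations belong to the declared vocabulary; bilateral locations carry
#' side left/right and single locations side none.
#'
#' @param path file path.
#' @return a data.frame of class `sample_frame` with canonical lower-case
#'   columns `sample_id`, `participant`, `couple`, `sex`, `body_location`,
#'   `side`, `moisture` plus lifestyle columns.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   comment.char = "")
  if (!ncol(df) || !identical(names(df)[1L], "#SampleID"))
    stop("mapping file must start with a '#SampleID' column")
  req <- c("Participant", "Couple", "Sex", "BodyLocation", "Side", "Moisture")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("mapping file missing column(s): ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), c("#SampleID", req))
  out <- data.frame(sample_id = df[["#SampleID"]],
                    participant = df[["Participant"]],
                    couple = df[["Couple"]],
                    sex = tolower(df[["Sex"]]),
                    body_location = df[["BodyLocation"]],
                    side = tolower(df[["Side"]]),
                    moisture = tolower(df[["Moisture"]]),
                    stringsAsFactors = FALSE)
  for (col in extra) out[[col]] <- df[[col]]
  validate_sample_frame(out)
}

#' Validate a sample frame against the couples study design
#'
#' @param meta data.frame with the canonical columns of [read_metadata()].
#' @return `meta`, classed as `sample_frame`, invisibly usable downstream.
#' @export
validate_sample_frame <- function(meta) {
  req <- c("sample_id", "participant", "couple", "sex", "body_location",
           "side", "moisture")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("sample frame missing column(s): ",
                         paste(miss, collapse = ", "))
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup)) stop("duplicate sample id: ", dup[1L])
  if (!all(meta$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  unknown <- setdiff(meta$body_location, .BODY_LOCATIONS$location)
  if (length(unknown)) stop("unknown body location: ", unknown[1L])
  bilat <- .BODY_LOCATIONS$bilateral[match(meta$body_location,
                                           .BODY_LOCATIONS$location)]
  if (!all(meta$side[bilat] %in% c("left", "right")))
    stop("bilateral locations require side 'left' or 'right'")
  if (!all(meta$side[!bilat] == "none"))
    stop("single locations require side 'none'")
  # participant -> exactly one couple; couple -> one female + one male
  pc <- unique(meta[, c("participant", "couple")])
  bad <- pc$participant[duplicated(pc$participant)]
  if (length(bad)) stop("participant in more than one couple: ", bad[1L])
  ps <- unique(meta[, c("participant", "couple", "sex")])
  for (cpl in unique(ps$couple)) {
    members <- ps[ps$couple == cpl, ]
    if (nrow(members) != 2L)
      stop(sprintf("couple '%s' has %d participant(s), expected 2",
                   cpl, nrow(members)))
    if (!setequal(members$sex, c("female", "male")))
      stop(sprintf("couple '%s' must have one female and one male", cpl))
  }
  class(meta) <- c("sample_frame", "data.frame")
  meta
}

#' Write a sample frame as a QIIME mapping file
#' @param meta a `sample_frame`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  canonical <- c("sample_id", "participant", "couple", "sex", "body_location",
                 "side", "moisture")
  extra <- setdiff(names(meta), canonical)
  out <- data.frame(meta$sample_id, meta$participant, meta$couple, meta$sex,
                    meta$body_location, meta$side, meta$moisture,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("#SampleID", "Participant", "Couple", "Sex", "BodyLocation",
                  "Side", "Moisture")
  for (col in extra) out[[col]] <- meta[[col]]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove samples below a sequencing-depth cutoff
#'
#' @param x an `otu_table`.
#' @param min_depth minimum acceptable row sum (the study used 5,293 reads).
#' @return list with `table` (retained samples, counts untouched) and
#'   `removed` (sample ids, in input order).
#' @export
filter_low_depth <- function(x, min_depth) {
  stopifnot(min_depth >= 1)
  depth <- sample_depths(x)
  keep <- depth >= min_depth
  if (!any(keep)) stop("all samples fall below min_depth = ", min_depth)
  list(table = subset_samples(x, samples = which(keep)),
       removed = sample_ids(x)[!keep])
}

# subsample one count vector without replacement to exactly `depth` reads
rarefy_row <- function(x, depth) {
  total <- sum(x)
  if (depth == total) return(x)
  cs <- cumsum(x)
  picks <- sample.int(total, depth) # read indices, uniform w/o replacement
  tabulate(findInterval(picks - 1L, cs) + 1L, nbins = length(x))
}

#' Rarefy an OTU table to a fixed depth
#'
#' Uniform subsampling WITHOUT replacement (hypergeometric marginals) of each
#' sample's reads to exactly `depth`, the QIIME-1 single_rarefaction
#' behavior. All-zero OTU columns are kept by default so OTU indices stay
#' aligned across replicate rarefactions.
#'
#' @param x an `otu_table`; every sample must have depth >= `depth`.
#' @param depth target reads per sample.
#' @param seed integer seed; identical seeds give identical tables.
#' @param drop_empty_otus drop OTUs with zero total count after rarefaction.
#' @return an `otu_table` whose row sums all equal `depth`.
#' @export
rarefy <- function(x, depth, seed = NULL, drop_empty_otus = FALSE) {
  stopifnot(depth >= 1)
  d <- sample_depths(x)
  low <- which(d < depth)
  if (length(low))
    stop(sprintf("sample '%s' has depth %s < %s; filter first",
                 sample_ids(x)[low[1L]], format(d[low[1L]]), format(depth)))
  cnt <- with_seed(seed, {
    t(apply(x$counts, 1L, rarefy_row, depth = depth))
  })
  dimnames(cnt) <- dimnames(x$counts)
  out <- otu_table(cnt, taxonomy = x$taxonomy)
  if (drop_empty_otus) {
    keep <- colSums(out$counts) > 0
    out <- subset_samples(out, otus = which(keep))
  }
  out
}

#' Relative abundances (rows sum to one)
#' @param x an `otu_table`.
#' @return numeric matrix of proportions, same shape and dimnames.
#' @export
relative_abundance <- function(x) {
  d <- sample_depths(x)
  if (any(d == 0)) stop("zero-sum sample: ", sample_ids(x)[which(d == 0)[1L]])
  x$counts / d
}

#' Collapse an OTU table at a taxonomic rank
#'
#' Sums counts over OTUs sharing the semicolon-lineage prefix at ranks
#' 1 (kingdom) .. 7 (species). OTUs without taxonomy fall into an
#' "unclassified" bucket. Total counts are conserved per sample.
#'
#' @param x an `otu_table` with taxonomy.
#' @param rank integer in 1..7.
#' @return an `otu_table` whose OTU ids are rank-prefix lineages.
#' @export
collapse_taxonomy <- function(x, rank) {
  if (!is.numeric(rank) || length(rank) != 1L || rank < 1 || rank > 7)
    stop("rank must be an integer in 1..7")
  rank <- as.integer(rank)
  tax <- x$taxonomy
  if (is.null(tax)) tax <- rep("", ncol(x$counts))
  key <- vapply(strsplit(tax, ";"), function(parts) {
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    if (!length(parts)) return("unclassified")
    paste(parts[seq_len(min(rank, length(parts)))], collapse = "; ")
  }, character(1L))
  collapsed <- t(rowsum(t(x$counts), group = key))
  otu_table(collapsed)
}
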