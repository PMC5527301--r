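## Bray-Curtis distances and principal-coordinates analysis.

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i), computed on counts. Because
#' the study design computes distances on rarefied tables, a warning is
#' raised when row sums are unequal (with equal depths, count-based and
#' proportion-based Bray-Curtis agree).
#'
#' @param x an `otu_table`, or a numeric matrix (samples x OTUs).
#' @return symmetric numeric matrix with sample ids as dimnames; entries in
#'   `[0, 1]`, zero diagonal.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  rs <- rowSums(m)
  if (any(rs == 0)) stop("zero-sum sample: ", rownames(m)[which(rs == 0)[1L]])
  if (max(rs) - min(rs) > 1e-8)
    warning("unequal sample depths; Bray-Curtis is depth-sensitive - ",
            "rarefy first for the canonical analysis")
  num <- as.matrix(stats::dist(m, method = "manhattan"))
  den <- outer(rs, rs, "+")
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Validate a distance matrix
#' @param dm square numeric matrix.
#' @param tol symmetry tolerance.
#' @return `dm`, invisibly; errors if invalid.
#' @export
validate_distance_matrix <- function(dm, tol = 1e-12) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) stop("not a square matrix")
  if (is.null(rownames(dm))) stop("distance matrix must carry sample ids")
  if (max(abs(dm - t(dm))) > tol) stop("matrix not symmetric within ", tol)
  if (any(abs(diag(dm)) > tol)) stop("nonzero diagonal")
  if (any(dm < -tol)) stop("negative dissimilarity")
  invisible(dm)
}

#' Write / read a square distance matrix as TSV
#'
#' Square dialect: ids as header row and first column.
#' @param dm symmetric matrix with ids.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_distance_matrix <- function(dm, path) {
  out <- cbind(rownames(dm), format(dm, trim = TRUE, scientific = FALSE,
                                    digits = 17))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", colnames(dm)), collapse = "\t"), con)
  writeLines(apply(out, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, row.names = 1L)
  dm <- as.matrix(df)
  dimnames(dm) <- list(rownames(df), colnames(df))
  validate_distance_matrix(dm, tol = 1e-8)
  dm
}

#' Principal-coordinates analysis (classical metric scaling)
#'
#' Double-centers -D^2/2, eigendecomposes, and scales eigenvectors by the
#' square roots of the positive eigenvalues. Negative eigenvalues are
#' reported but their axes dropped (no Lingoes/Cailliez correction); when the
#' distance matrix is Euclidean-embeddable the full positive-axis
#' configuration reproduces the distances exactly.
#'
#' @param dm symmetric distance matrix with sample ids.
#' @param n_axes number of axes to return (capped at the positive rank).
#' @return object of class `pcoa_ordination`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (all, descending), `prop_explained`
#'   (over positive eigenvalues), `negative_eigenvalues`.
#' @export
pcoa <- function(dm, n_axes = 2) {
  validate_distance_matrix(dm, tol = 1e-8)
  if (n_axes < 1) stop("n_axes must be >= 1")
  n <- nrow(dm)
  if (n_axes > n - 1L) stop("n_axes must be <= samples - 1")
  a <- -0.5 * dm^2
  centered <- sweep(sweep(a, 1L, rowMeans(a)), 2L, colMeans(a)) + mean(a)
  eig <- eigen(centered, symmetric = TRUE)
  ev <- eig$values
  pos <- which(ev > max(ev[1L], 0) * 1e-9)
  k <- min(n_axes, length(pos))
  if (k < 1L) stop("no positive eigenvalues; degenerate distance matrix")
  coords <- eig$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(ev[pos[seq_len(k)]]), k)
  dimnames(coords) <- list(rownames(dm), paste0("PCo", seq_len(k)))
  structure(list(coordinates = coords,
                 eigenvalues = ev,
                 prop_explained = ev[pos] / sum(ev[pos]),
                 negative_eigenvalues = ev[ev < 0]),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("pcoa_ordination: %d samples, %d axes (%.1f%% on axis 1)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$prop_explained[1L]))
  if (length(x$negative_eigenvalues))
    cat(sprintf("  %d negative eigenvalues (min %.3g), axes dropped\n",
                length(x$negative_eigenvalues),
                min(x$negative_eigenvalues)))
  invisible(x)
}
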