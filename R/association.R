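#' Spearman rank-correlation matrix
#'
#' Pairwise Spearman correlations (Pearson correlation of average ranks, the
#' standard tie treatment) between all item columns. With 4-category ordinal
#' items ties are pervasive, which is why the rank-based estimator is used
#' rather than Pearson on the raw codes.
#'
#' @param data Numeric matrix (n x p) of complete ordinal responses, e.g. an
#'   `item_matrix`. If entries are missing, pairwise-complete correlations
#'   are used and [nearest_psd()] smoothing becomes mandatory downstream.
#' @return A p x p symmetric correlation matrix with unit diagonal and an
#'   `n_effective` attribute (number of rows).
#' @export
spearman_matrix <- function(data) {
  m <- unclass(data)
  attr(m, "communities") <- NULL
  storage.mode(m) <- "double"
  if (nrow(m) < 3L) stop("need at least 3 observations")
  v <- apply(m, 2, function(x) stats::sd(x, na.rm = TRUE))
  if (any(!is.finite(v) | v == 0)) {
    bad <- colnames(m)[!is.finite(v) | v == 0]
    stop("zero-variance item(s): ", paste(bad, collapse = ", "),
         "; Spearman correlation undefined")
  }
  complete <- !anyNA(m)
  S <- stats::cor(m, method = "spearman",
                  use = if (complete) "everything" else "pairwise.complete.obs")
  S <- (S + t(S)) / 2
  diag(S) <- 1
  attr(S, "n_effective") <- nrow(m)
  S
}

#' Project a symmetric matrix to (near) positive semidefiniteness
#'
#' Pairwise rank-correlation matrices need not be positive semidefinite.
#' This clips negative eigenvalues at zero and rescales the result back to
#' unit diagonal. Inputs already PSD (smallest eigenvalue >= -tol) are
#' returned unchanged.
#'
#' @param S Symmetric matrix with unit diagonal.
#' @param tol Tolerance on the smallest admissible eigenvalue (default 1e-8).
#' @return A symmetric unit-diagonal matrix with smallest eigenvalue
#'   >= -tol; attributes of `S` are preserved.
#' @export
nearest_psd <- function(S, tol = 1e-8) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (max(abs(S - t(S))) > 1e-8) stop("input must be symmetric")
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= -tol) return(S)
  v <- pmax(e$values, 0)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  d[d < .Machine$double.eps] <- 1
  out <- out / tcrossprod(d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  dimnames(out) <- dimnames(S)
  attributes(out)[setdiff(names(attributes(S)), c("dim", "dimnames"))] <-
    attributes(S)[setdiff(names(attributes(S)), c("dim", "dimnames"))]
  out
}

#' Write a correlation (or weight) matrix to delimited text
#'
#' @param S Square matrix with dimnames.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(S, path) {
  utils::write.csv(as.data.frame(S), path, row.names = TRUE)
  invisible(path)
}

#' Read a square labelled matrix written by [write_matrix()]
#' @param path CSV path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",", row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}
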