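#' Train a linear-discriminant EEG feature over BAF space
#'
#' Two-class Fisher discriminant on BAF rows: `w` is proportional to
#' `solve(Sw, mu1 - mu0)` with the pooled within-class covariance ridge
#' regularized to invertibility, unit-normalized, oriented so class 1 scores
#' higher.
#'
#' @param x Numeric matrix of BAF rows (windows x atoms).
#' @param label Binary labels (0/1 or logical), one per row.
#' @param name Feature name (e.g. `"VC9-like"`).
#' @param seed Integer recorded in the metadata.
#' @param ridge Ridge coefficient as a fraction of `trace(Sw)/ncol(x)`.
#' @param transfer `"linear"` (identity) or `"logistic"`.
#' @return A `feature_weights` object: `w`, `name`, `transfer`, `method`,
#'   `seed`.
#' @export
train_lda_feature <- function(x, label, name = "lda", seed = 0L,
                              ridge = 1e-3, transfer = "linear") {
  label <- as.integer(as.logical(label))
  if (length(unique(label)) < 2L) stop("need two classes")
  if (min(table(label)) < 2L) stop("need at least 2 rows per class")
  x0 <- x[label == 0L, , drop = FALSE]
  x1 <- x[label == 1L, , drop = FALSE]
  d <- ncol(x)
  s0 <- stats::cov(x0) * (nrow(x0) - 1)
  s1 <- stats::cov(x1) * (nrow(x1) - 1)
  Sw <- (s0 + s1) / (nrow(x) - 2)
  eps <- ridge * sum(diag(Sw)) / d
  w <- solve(Sw + diag(eps, d), colMeans(x1) - colMeans(x0))
  w <- w / sqrt(sum(w^2))
  structure(list(w = as.numeric(w), name = name, transfer = transfer,
                 method = "LDA", seed = as.integer(seed)),
            class = "feature_weights")
}

#' Train a principal-component EEG feature over BAF space
#'
#' `w` is the eigenvector of the column-centered covariance with the
#' `component_index`-th largest eigenvalue (the pipeline's default, 4, mirrors
#' a difficulty-separating fourth component), sign-fixed so the
#' largest-magnitude entry is positive.
#'
#' @param x Numeric matrix of BAF rows.
#' @param component_index Which component (1-based; default 4).
#' @param name Feature name (e.g. `"ST4-like"`).
#' @param transfer Transfer function label.
#' @return A `feature_weights` object.
#' @export
train_pca_feature <- function(x, component_index = 4L, name = "pca",
                              transfer = "linear") {
  if (nrow(x) < component_index + 1L)
    stop("need more rows than component_index")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pr$sdev > pr$sdev[1] * 1e-8)
  if (component_index > rank)
    stop("component_index exceeds rank (", rank, ")")
  w <- pr$rotation[, component_index]
  if (w[which.max(abs(w))] < 0) w <- -w
  structure(list(w = as.numeric(w), name = name, transfer = transfer,
                 method = sprintf("PCA-%d", component_index), seed = NA_integer_),
            class = "feature_weights")
}

#' @export
print.feature_weights <- function(x, ...) {
  cat(sprintf("<feature_weights> %s (%s, %s transfer), %d weights\n",
              x$name, x$method, x$transfer, length(x$w)))
  invisible(x)
}

#' Apply a linear feature to BAF rows
#'
#' Computes `Psi(w . x)` with `Psi` the identity or the logistic function,
#' per the feature's transfer setting.
#'
#' @param wts A `feature_weights` object.
#' @param x BAF row (vector) or matrix of rows.
#' @return Numeric value per row.
#' @export
apply_feature <- function(wts, x) {
  if (is.matrix(x)) {
    if (ncol(x) != length(wts$w)) stop("dimension mismatch")
    y <- as.numeric(x %*% wts$w)
  } else {
    if (length(x) != length(wts$w)) stop("dimension mismatch")
    y <- sum(wts$w * x)
  }
  if (!all(is.finite(y))) stop("non-finite input")
  if (wts$transfer == "logistic") 1 / (1 + exp(-y)) else y
}

#' Scale a feature series to 0-100 per recording
#'
#' Robust min-max: the 1st percentile maps to 0 and the 99th to 100, with
#' clipping; a constant series maps to 50.
#'
#' @param values Raw feature values of one recording.
#' @return Numeric vector in `[0, 100]`.
#' @export
scale_0_100 <- function(values) {
  if (length(values) < 1L) stop("empty series")
  q <- stats::quantile(values, c(0.01, 0.99), names = FALSE, type = 7)
  if (q[2] <= q[1]) return(rep(50, length(values)))
  pmin(pmax((values - q[1]) / (q[2] - q[1]) * 100, 0), 100)
}

#' Write feature weights to a CSV + JSON sidecar
#' @param wts A `feature_weights`.
#' @param path CSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_weights <- function(wts, path) {
  utils::write.csv(data.frame(atom = seq_along(wts$w),
                              weight = sprintf("%.12g", wts$w)),
                   path, row.names = FALSE, quote = FALSE)
  meta <- wts[c("name", "transfer", "method", "seed")]
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE), paste0(path, ".json"))
  invisible(path)
}

#' Read feature weights written by [write_feature_weights()]
#' @param path CSV path.
#' @return A `feature_weights`.
#' @export
read_feature_weights <- function(path) {
  if (!file.exists(path)) stop("missing weight file: ", path)
  df <- utils::read.csv(path)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  structure(list(w = as.numeric(df$weight), name = meta$name,
                 transfer = meta$transfer, method = meta$method,
                 seed = meta$seed %||% NA_integer_),
            class = "feature_weights")
}
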