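# Key-parameter determination: PCA over a speed dataset, selection of the
# most speed-relevant reflex parameters, restricted optimization problems.

#' Principal component analysis of a speed dataset
#'
#' PCA on the standardized parameter matrix of a speed dataset (each
#' column z-scored; columns with zero variance are centered only). The
#' sign of each component is fixed so its largest-magnitude loading is
#' positive.
#'
#' @param dataset An `rg_speed_dataset` (or plain parameter matrix) with
#'   at least 3 records.
#' @return Object of class `rg_pca`: `loadings` (parameters x components),
#'   `explained` (variance ratios summing to 1), `center`, `scale`.
#' @export
fit_pca <- function(dataset) {
  X <- if (inherits(dataset, "rg_speed_dataset")) dataset$params
       else as.matrix(dataset)
  if (nrow(X) < 3) stop("PCA requires at least 3 records")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(!is.finite(scl))) stop("non-finite column variance")
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  pr <- prcomp(Xs, center = FALSE, scale. = FALSE)
  L <- pr$rotation
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  ev <- pr$sdev^2
  structure(list(loadings = L, explained = ev / sum(ev),
                 center = ctr, scale = scl),
            class = "rg_pca")
}

#' @export
print.rg_pca <- function(x, ...) {
  cat(sprintf("PCA over %d parameters: PC1 explains %.1f%% of variance\n",
              nrow(x$loadings), 100 * x$explained[1]))
  invisible(x)
}

#' Select the key reflex parameters
#'
#' The `n_key` parameters with the largest absolute loadings on the first
#' principal component (ties broken by canonical index order) are the key
#' parameters: the reflex pathways most influential for modulating speed.
#'
#' @param pca An `rg_pca` from [fit_pca()].
#' @param n_key Number of key parameters (the study grid is
#'   `{5, 10, 15, 20, 25, 30}`, but any `1..n_params` is allowed).
#' @return Object of class `rg_keys`: ordered integer `indices` into the
#'   canonical parameter vector, their `names` and parameter `kind`
#'   (`"kL"`, `"kF"` or `"c"`) when names are available.
#' @export
select_keys <- function(pca, n_key) {
  npar <- nrow(pca$loadings)
  if (!isTRUE(n_key >= 1 && n_key <= npar))
    stop(sprintf("n_key must be in 1..%d", npar))
  l1 <- abs(pca$loadings[, 1])
  ord <- order(-l1, seq_along(l1))
  idx <- sort(ord[seq_len(n_key)])
  nms <- rownames(pca$loadings)
  if (is.null(nms)) nms <- colnames(pca$loadings)
  knd <- if (is.null(nms)) rep(NA_character_, n_key)
         else sub("_.*", "", nms[idx])
  structure(list(indices = idx, n_key = as.integer(n_key),
                 names = if (is.null(nms)) NULL else nms[idx],
                 kind = knd),
            class = "rg_keys")
}

#' @export
print.rg_keys <- function(x, ...) {
  cat(sprintf("Key parameters (n = %d): %s\n", x$n_key,
              paste(if (is.null(x$names)) x$indices else x$names,
                    collapse = ", ")))
  invisible(x)
}

as_key_indices <- function(keys, npar) {
  idx <- if (inherits(keys, "rg_keys")) keys$indices else as.integer(keys)
  if (anyDuplicated(idx) || any(idx < 1) || any(idx > npar))
    stop("invalid key indices")
  idx
}

#' Restricted optimization problem over the key parameters
#'
#' Freezes all parameters at their initial values and exposes only the
#' key entries as free variables; `expand()` writes a candidate back into
#' a copy of the initial vector (all other entries bit-equal to it).
#'
#' @param p_init Initial canonical parameter vector.
#' @param keys An `rg_keys` selection or integer indices.
#' @return List with `x0` (initial key values), `dim`, `keys`, and
#'   `expand(z)`.
#' @export
restricted_problem <- function(p_init, keys) {
  p_init <- as.numeric(p_init)
  idx <- as_key_indices(keys, length(p_init))
  list(x0 = p_init[idx], dim = length(idx), keys = idx,
       expand = function(z) {
         stopifnot(length(z) == length(idx))
         p <- p_init
         p[idx] <- z
         p
       })
}
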