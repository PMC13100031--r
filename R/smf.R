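# Speed-modulation function: per-key-parameter polynomial regression over
# a speed dataset, assembly of full parameter vectors for a target speed,
# offline sweep and monotonicity diagnostics.

#' Fit the speed-modulation function
#'
#' For each key parameter, an ordinary least-squares polynomial of degree
#' `d_reg` of the parameter value against the actual velocity of the
#' dataset records:
#' `SMF_k(v) = beta_0k + beta_1k v + beta_2k v^2 + beta_3k v^3`, with
#' `beta_nk = 0` for `n > d_reg`. Coefficients are recomputed per degree.
#'
#' @param dataset An `rg_speed_dataset` (the key-restricted optimization
#'   harvest) with more than `d_reg + 1` records and nonzero speed spread.
#' @param keys Key selection (`rg_keys` or indices).
#' @param d_reg Polynomial degree, 1, 2 or 3.
#' @param p_init Initial canonical parameter vector supplying all non-key
#'   entries (default: the dataset record closest to the median speed).
#' @return Object of class `rg_smf`: coefficient matrix `beta`
#'   (`n_key x 4`, columns `beta0..beta3`), `keys`, `p_init`, the fitted
#'   speed range `v_range`, and (once swept) the stable target range.
#' @export
fit_smf <- function(dataset, keys, d_reg = 3, p_init = NULL) {
  stopifnot(inherits(dataset, "rg_speed_dataset"))
  if (!d_reg %in% 1:3) stop("d_reg must be 1, 2 or 3")
  v <- dataset$v_act
  n <- length(v)
  if (n <= d_reg + 1) stop("dataset too small for the requested degree")
  if (diff(range(v)) < 1e-12) stop("degenerate design: all speeds equal")
  idx <- as_key_indices(keys, ncol(dataset$params))
  if (is.null(p_init)) {
    imed <- which.min(abs(v - median(v)))
    p_init <- dataset$params[imed, ]
  }
  p_init <- as.numeric(p_init)
  if (length(p_init) != ncol(dataset$params))
    stop("p_init length does not match the dataset")
  V <- outer(v, 0:d_reg, `^`)           # Vandermonde design
  beta <- matrix(0, length(idx), 4,
                 dimnames = list(colnames(dataset$params)[idx],
                                 paste0("beta", 0:3)))
  qrV <- qr(V)
  for (j in seq_along(idx)) {
    y <- dataset$params[, idx[j]]
    beta[j, seq_len(d_reg + 1)] <- qr.coef(qrV, y)
  }
  structure(list(beta = beta, keys = idx, d_reg = d_reg, p_init = p_init,
                 v_range = range(v), stable_range = c(NA_real_, NA_real_)),
            class = "rg_smf")
}

#' @export
print.rg_smf <- function(x, ...) {
  cat(sprintf("Speed-modulation function: degree %d over %d key parameters, fitted on v in [%.3f, %.3f] m/s\n",
              x$d_reg, length(x$keys), x$v_range[1], x$v_range[2]))
  if (!anyNA(x$stable_range))
    cat(sprintf("  stable target range [%.3f, %.3f] m/s\n",
                x$stable_range[1], x$stable_range[2]))
  invisible(x)
}

#' Assemble a full parameter vector for a target speed
#'
#' Key entries are the modulation polynomials evaluated at `v_tgt`; all
#' other entries are taken unchanged from the frozen initial vector. The
#' result is polynomial (hence smooth) in `v_tgt`. Targets outside the
#' fitted speed range are allowed (extrapolation) and flagged.
#'
#' @param model An `rg_smf`.
#' @param v_tgt Target speed (m/s).
#' @return Canonical parameter vector with attribute `extrapolated`.
#' @export
assemble_params <- function(model, v_tgt) {
  stopifnot(inherits(model, "rg_smf"))
  p <- model$p_init
  vv <- v_tgt^(0:3)
  p[model$keys] <- as.numeric(model$beta %*% vv)
  attr(p, "extrapolated") <- v_tgt < model$v_range[1] ||
    v_tgt > model$v_range[2]
  p
}

#' Default offline sweep grid
#'
#' Target speeds from 0.5 to 3.5 m/s in steps of 0.025 (121 points).
#'
#' @param from,to,by Grid limits and step (m/s).
#' @return Numeric vector of target speeds.
#' @export
sweep_grid <- function(from = 0.5, to = 3.5, by = 0.025) {
  seq(from, to, by = by)
}

#' Offline sweep of the speed-modulation function
#'
#' Runs one deterministic episode per target speed of the grid with the
#' assembled parameter set and records stability, actual velocity and gait
#' label; the stable target range is recorded into the returned model.
#'
#' @param plant An `rg_plant`.
#' @param model An `rg_smf`.
#' @param grid Target-speed grid (m/s), strictly increasing.
#' @param cfg Episode configuration.
#' @return Object of class `rg_sweep`: data frame `points`
#'   (`v_tgt`, `stable`, `v_act`, `gait`), the stable range, and the
#'   updated `model`.
#' @export
offline_sweep <- function(plant, model, grid = sweep_grid(),
                          cfg = episode_config(plant)) {
  stopifnot(inherits(model, "rg_smf"))
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  res <- data.frame(v_tgt = grid, stable = FALSE, v_act = NA_real_,
                    gait = NA_character_)
  for (i in seq_along(grid)) {
    ep <- run_episode(plant, assemble_params(model, grid[i]), cfg)
    res$stable[i] <- ep$stable
    if (ep$stable) {
      res$v_act[i] <- ep$v_act
      res$gait[i] <- ep$gait
    }
  }
  if (any(res$stable)) {
    stable_range <- range(res$v_tgt[res$stable])
  } else {
    warning("no stable target speeds in the sweep")
    stable_range <- c(NA_real_, NA_real_)
  }
  model$stable_range <- stable_range
  structure(list(points = res, stable_range = stable_range, model = model),
            class = "rg_sweep")
}

#' @export
print.rg_sweep <- function(x, ...) {
  ns <- sum(x$points$stable)
  cat(sprintf("Offline sweep: %d/%d stable grid points", ns,
              nrow(x$points)))
  if (ns > 0)
    cat(sprintf(", stable v_tgt in [%.3f, %.3f] m/s", x$stable_range[1],
                x$stable_range[2]))
  cat("\n")
  invisible(x)
}

#' Monotonicity diagnostics of a sweep
#'
#' Checks whether the actual velocity increases monotonically with the
#' target velocity over the stable grid points, and how far the
#' relationship deviates from the identity line.
#'
#' @param sweep An `rg_sweep` with at least 2 stable points.
#' @param tol Numeric tolerance (m/s): adjacent decreases smaller than
#'   this count as ties, not violations (guards against floating-point
#'   noise between physically identical outcomes).
#' @return List: `n_stable`, `violations` (data frame of decreasing
#'   adjacent pairs), `n_violations`, `longest_monotone_run` (in points),
#'   `max_identity_deviation` and `rms_identity_deviation` (m/s).
#' @export
monotonicity_report <- function(sweep, tol = 1e-9) {
  pts <- sweep$points[sweep$points$stable, ]
  if (nrow(pts) < 2) stop("need at least 2 stable sweep points")
  dv <- diff(pts$v_act)
  viol <- which(dv < -tol)
  runs <- rle(dv >= -tol)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) + 1L else 1L
  dev <- pts$v_act - pts$v_tgt
  list(n_stable = nrow(pts),
       violations = data.frame(v_tgt = pts$v_tgt[viol + 1L],
                               drop = -dv[viol]),
       n_violations = length(viol),
       longest_monotone_run = longest,
       max_identity_deviation = max(abs(dev)),
       rms_identity_deviation = sqrt(mean(dev^2)))
}

#' @importFrom stats median
NULL
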