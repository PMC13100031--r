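# Reflex controller: connection matrix, parameter codec, stimulation law.

#' Muscle names in canonical order
#'
#' The nine musculotendon units per leg, in the fixed order used for all
#' parameter vectors, CSV columns and PCA loadings: gluteus (GLU), iliopsoas
#' (ILI), rectus femoris (RF), hamstrings (HAM), biceps femoris short head
#' (BF), vastus (VAS), gastrocnemius (GAS), tibialis anterior (TA), soleus
#' (SOL).
#'
#' @return Character vector of length 9.
#' @export
muscle_names <- function() {
  c("GLU", "ILI", "RF", "HAM", "BF", "VAS", "GAS", "TA", "SOL")
}

#' Default antagonist map
#'
#' Mutual antagonist pairs derived from joint actions: at the hip the flexors
#' (ILI, RF) oppose the extensors (GLU, HAM); at the knee the extensors
#' (VAS, RF) oppose the flexors (HAM, BF, GAS); at the ankle the dorsiflexor
#' (TA) opposes the plantarflexors (SOL, GAS). Pairs sharing two joints
#' (RF-HAM) are counted once. This yields 11 unique pairs, i.e. 22 directed
#' antagonistic connections, which together with the 9 homonymous
#' connections gives the 31-connection network.
#'
#' @return A two-column character matrix of unordered antagonist pairs.
#' @export
default_antagonist_map <- function() {
  rbind(
    c("ILI", "GLU"), c("ILI", "HAM"), c("RF", "GLU"), c("RF", "HAM"),
    c("VAS", "HAM"), c("VAS", "BF"), c("VAS", "GAS"),
    c("RF", "BF"), c("RF", "GAS"),
    c("TA", "SOL"), c("TA", "GAS")
  )
}

#' Build the reflex connection matrix
#'
#' Constructs the ordered list of reflex connections: one homonymous
#' connection per muscle plus two directed antagonistic connections per
#' antagonist pair. Connections are ordered canonically by target muscle,
#' then relation (homonymous before antagonistic), then source muscle.
#' The same matrix is applied to both legs.
#'
#' @param antagonist_map Two-column character matrix of mutual antagonist
#'   pairs (see [default_antagonist_map()]).
#' @param muscles Character vector of muscle names (canonical order).
#' @param expected_total Expected number of connections; the default human
#'   network has 31. Set to `NA` to skip the check.
#' @return An object of class `rg_connections`: a data frame with columns
#'   `target`, `source`, `relation`.
#' @export
build_connection_matrix <- function(antagonist_map = default_antagonist_map(),
                                    muscles = muscle_names(),
                                    expected_total = 31L) {
  if (!is.null(antagonist_map) && length(antagonist_map)) {
    antagonist_map <- as.matrix(antagonist_map)
    if (ncol(antagonist_map) != 2)
      stop("antagonist_map must have two columns")
    bad <- setdiff(as.vector(antagonist_map), muscles)
    if (length(bad))
      stop("unknown muscles in antagonist map: ", paste(bad, collapse = ", "))
    if (any(antagonist_map[, 1] == antagonist_map[, 2]))
      stop("antagonist map contains a self-pair")
  } else {
    antagonist_map <- matrix(character(0), ncol = 2)
  }
  rows <- list()
  for (m in muscles) {
    rows[[length(rows) + 1L]] <- data.frame(
      target = m, source = m, relation = "homonymous",
      stringsAsFactors = FALSE)
    src <- sort(unique(c(antagonist_map[antagonist_map[, 1] == m, 2],
                         antagonist_map[antagonist_map[, 2] == m, 1])))
    # canonical source order: muscle order, not alphabetical
    src <- muscles[muscles %in% src]
    for (s in src)
      rows[[length(rows) + 1L]] <- data.frame(
        target = m, source = s, relation = "antagonistic",
        stringsAsFactors = FALSE)
  }
  cm <- do.call(rbind, rows)
  # order: target id, relation (homonymous first), source id
  tid <- match(cm$target, muscles)
  sid <- match(cm$source, muscles)
  rel <- ifelse(cm$relation == "homonymous", 0L, 1L)
  cm <- cm[order(tid, rel, sid), , drop = FALSE]
  rownames(cm) <- NULL
  if (!is.na(expected_total) && nrow(cm) != expected_total)
    stop(sprintf(
      "connection topology error: map yields %d connections, expected %d",
      nrow(cm), expected_total))
  structure(cm, class = c("rg_connections", "data.frame"),
            muscles = muscles)
}

#' @export
print.rg_connections <- function(x, ...) {
  cat(sprintf("Reflex connection matrix: %d connections (%d homonymous, %d antagonistic)\n",
              nrow(x), sum(x$relation == "homonymous"),
              sum(x$relation == "antagonistic")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Canonical parameter names
#'
#' Names of the entries of the flat parameter vector in canonical order:
#' all length gains `kL_<target>_<source>` in connection order, then all
#' force gains `kF_<target>_<source>`, then the offsets `c_<muscle>`.
#'
#' @param cm Connection matrix from [build_connection_matrix()].
#' @return Character vector of length `2 * nrow(cm) + n_muscles`.
#' @export
param_names <- function(cm) {
  muscles <- attr(cm, "muscles")
  c(paste0("kL_", cm$target, "_", cm$source),
    paste0("kF_", cm$target, "_", cm$source),
    paste0("c_", muscles))
}

#' Construct a reflex parameter set
#'
#' @param kL,kF Numeric vectors of length/force gains, one per connection
#'   (in canonical connection order).
#' @param c Numeric vector of per-muscle constant offsets.
#' @param cm Connection matrix.
#' @return Object of class `rg_params`.
#' @export
reflex_params <- function(kL, kF, c, cm) {
  nc <- nrow(cm)
  nm <- length(attr(cm, "muscles"))
  if (length(kL) != nc || length(kF) != nc)
    stop(sprintf("kL and kF must each have %d entries", nc))
  if (length(c) != nm)
    stop(sprintf("c must have %d entries", nm))
  structure(list(kL = as.numeric(kL), kF = as.numeric(kF),
                 c = as.numeric(c), cm = cm),
            class = "rg_params")
}

#' @export
print.rg_params <- function(x, ...) {
  cat(sprintf("Reflex parameters: %d length gains + %d force gains + %d offsets = %d\n",
              length(x$kL), length(x$kF), length(x$c),
              length(x$kL) + length(x$kF) + length(x$c)))
  invisible(x)
}

#' Encode a parameter set as a flat vector
#'
#' Flattens an `rg_params` object into the canonical numeric vector
#' (length gains, force gains, offsets); for the default human network this
#' vector has 71 entries. `decode_params()` is the exact inverse.
#'
#' @param p Object of class `rg_params`.
#' @return Named numeric vector.
#' @export
encode_params <- function(p) {
  stopifnot(inherits(p, "rg_params"))
  setNames(c(p$kL, p$kF, p$c), param_names(p$cm))
}

#' Decode a flat vector into a parameter set
#'
#' @param v Numeric vector in canonical order (71 entries for the default
#'   human network).
#' @param cm Connection matrix the vector refers to.
#' @return Object of class `rg_params`.
#' @export
decode_params <- function(v, cm) {
  nc <- nrow(cm)
  nm <- length(attr(cm, "muscles"))
  want <- 2L * nc + nm
  if (length(v) != want)
    stop(sprintf("parameter codec error: expected %d entries, got %d",
                 want, length(v)))
  reflex_params(v[seq_len(nc)], v[nc + seq_len(nc)], v[2L * nc + seq_len(nm)],
                cm)
}

#' Number of free parameters of a connection matrix
#' @param cm Connection matrix.
#' @return Integer: `2 * n_connections + n_muscles`.
#' @export
n_params <- function(cm) 2L * nrow(cm) + length(attr(cm, "muscles"))

#' Normalize muscle sensor signals
#'
#' Normalized contractile-element length and tendon force as used by the
#' reflex law: length is CE length over optimal CE length, force is tendon
#' force over maximum isometric force.
#'
#' @param lce CE length (m).
#' @param force Tendon force (N).
#' @param lopt Optimal CE length (m).
#' @param fmax Maximum isometric force (N).
#' @return List with components `L` and `F` (both unitless, nonnegative).
#' @export
normalize_signals <- function(lce, force, lopt, fmax) {
  list(L = lce / lopt, F = pmax(force, 0) / fmax)
}

#' Sensor history for the delayed reflex pathways
#'
#' Holds uniformly sampled normalized length and force signals per muscle
#' together with each muscle's reflex delay. Lookups earlier than the first
#' sample return the first sample.
#'
#' @param dt Sampling interval (s).
#' @param L,F Numeric matrices (samples x muscles) of normalized CE length
#'   and tendon force.
#' @param delays Per-muscle delay (s).
#' @return Object of class `rg_history`.
#' @export
sensor_history <- function(dt, L, F, delays) {
  L <- as.matrix(L); F <- as.matrix(F)
  stopifnot(nrow(L) == nrow(F), ncol(L) == ncol(F),
            length(delays) == ncol(L), dt > 0)
  if (nrow(L) * dt < max(delays))
    stop("history horizon shorter than the largest delay")
  structure(list(dt = dt, L = L, F = F, delays = delays),
            class = "rg_history")
}

history_lookup <- function(h, t, delay) {
  # nearest-sample lookup at time t - delay; clamp to the first sample
  idx <- round((t - delay) / h$dt) + 1L
  max(1L, min(nrow(h$L), idx))
}

#' Compute reflex stimulations
#'
#' The reflex law: each muscle's stimulation is its constant offset plus the
#' sum over its incoming connections of the length gain times the delayed
#' normalized CE length of the source muscle and the force gain times its
#' delayed normalized tendon force, clipped to `[u_min, u_max]`. The same
#' parameters drive both legs.
#'
#' @param t Time (s) at which to evaluate.
#' @param history Sensor history from [sensor_history()], one column per
#'   muscle in canonical order.
#' @param params Parameter set (`rg_params`).
#' @param u_min,u_max Stimulation bounds.
#' @return Named numeric vector of stimulations, one per muscle.
#' @export
compute_stimulation <- function(t, history, params, u_min = 0, u_max = 1) {
  stopifnot(inherits(history, "rg_history"), inherits(params, "rg_params"))
  cm <- params$cm
  muscles <- attr(cm, "muscles")
  u <- params$c
  names(u) <- muscles
  for (k in seq_len(nrow(cm))) {
    src <- match(cm$source[k], muscles)
    tgt <- match(cm$target[k], muscles)
    i <- history_lookup(history, t, history$delays[src])
    u[tgt] <- u[tgt] + params$kL[k] * history$L[i, src] +
      params$kF[k] * history$F[i, src]
  }
  pmin(pmax(u, u_min), u_max)
}
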