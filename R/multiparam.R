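# Physiological condition and the swelling/pH-indexed multi-parameter model.

#' Physiological test condition
#'
#' The oral-cavity state under which a sweep is measured: absolute
#' temperature, swelling ratio of the adhesive (0 = dry, 1 = saturated) and
#' pH of the medium.
#'
#' @param temperature Absolute temperature, K, `> 0`.
#' @param swelling_ratio Dimensionless fraction in `[0, 1]`.
#' @param ph pH in `[0, 14]`.
#' @return An object of class `rheo_condition`.
#' @export
condition <- function(temperature, swelling_ratio = 0, ph = 7) {
  stopifnot_scalar(temperature, "temperature")
  stopifnot_scalar(swelling_ratio, "swelling_ratio")
  stopifnot_scalar(ph, "ph")
  if (temperature <= 0) {
    rheo_abort("temperature must be > 0 K", "rheo_domain_error")
  }
  if (swelling_ratio < 0 || swelling_ratio > 1) {
    rheo_abort("swelling_ratio must lie in [0, 1]", "rheo_domain_error")
  }
  if (ph < 0 || ph > 14) rheo_abort("ph must lie in [0, 14]",
                                    "rheo_domain_error")
  structure(list(temperature = temperature,
                 swelling_ratio = swelling_ratio, ph = ph),
            class = "rheo_condition")
}

#' Multi-parameter viscoelastic material model
#'
#' A Prony-series material whose branch amplitudes and relaxation times
#' depend on the swelling ratio (and optionally pH) through a grid of fitted
#' nodes, and whose temperature dependence enters through a single shared
#' Arrhenius shift. When pH is among `retained_covariates` the node grid must
#' be a full rectangular (SR x pH) grid; otherwise nodes are keyed by SR
#' alone (the simplified, pH-free form).
#'
#' Between nodes, branch parameters are interpolated piecewise-linearly in
#' log g_i and log tau_i (bilinear when both SR and pH are retained), which
#' preserves positivity; the equilibrium modulus g0 is interpolated linearly
#' (it may legitimately be 0). Evaluation outside the grid hull is a hard
#' error: no extrapolation.
#'
#' @param shift An [arrhenius_shift()].
#' @param nodes A list of nodes, each `list(sr =, ph =, prony =)` with a
#'   [prony_series()]; all nodes must share the same number of branches `n`.
#' @param retained_covariates Character subset of `c("SR", "pH")`; which
#'   covariates index the node table. Temperature is always part of the model
#'   through `shift` and is not listed here.
#' @param interpolation Rule identifier; only `"log-linear"` is defined.
#' @return An object of class `multiparam_model`.
#' @seealso [evaluate_multiparam()]
#' @export
multiparam_model <- function(shift, nodes,
                             retained_covariates = c("SR", "pH"),
                             interpolation = "log-linear") {
  stopifnot(inherits(shift, "arrhenius_shift"))
  if (!is.list(nodes) || length(nodes) == 0L) {
    rheo_abort("model table must contain at least one node",
               "rheo_invalid_model_error")
  }
  retained_covariates <- as.character(retained_covariates)
  if (!all(retained_covariates %in% c("SR", "pH"))) {
    rheo_abort("retained_covariates must be a subset of c('SR', 'pH')",
               "rheo_invalid_model_error")
  }
  if (!identical(interpolation, "log-linear")) {
    rheo_abort("unknown interpolation rule", "rheo_invalid_model_error")
  }
  ph_kept <- "pH" %in% retained_covariates
  for (nd in nodes) {
    if (is.null(nd$sr) || !inherits(nd$prony, "prony_series") ||
        (ph_kept && is.null(nd$ph))) {
      rheo_abort("each node needs fields sr, ph (if retained) and prony",
                 "rheo_invalid_model_error")
    }
  }
  nn <- vapply(nodes, function(nd) nd$prony$n, integer(1))
  if (length(unique(nn)) != 1L) {
    rheo_abort("all node Prony series must share the same n",
               "rheo_inconsistency_error")
  }
  sr <- vapply(nodes, function(nd) as.numeric(nd$sr), numeric(1))
  ph <- vapply(nodes, function(nd) as.numeric(nd$ph %||% 7), numeric(1))
  key <- if (ph_kept) paste(sr, ph) else as.character(sr)
  if (anyDuplicated(key)) {
    rheo_abort("duplicate grid keys in model table",
               "rheo_inconsistency_error")
  }
  if (ph_kept && length(unique(ph)) > 1L) {
    # bilinear interpolation needs the full rectangular grid
    want <- expand.grid(sr = sort(unique(sr)), ph = sort(unique(ph)))
    have <- paste(sr, ph)
    miss <- !(paste(want$sr, want$ph) %in% have)
    if (any(miss)) {
      rheo_abort(sprintf("model grid is not rectangular; missing (SR, pH) = %s",
                         paste(sprintf("(%g, %g)", want$sr[miss],
                                       want$ph[miss]), collapse = ", ")),
                 "rheo_inconsistency_error")
    }
  }
  ord <- order(sr, ph)
  structure(list(shift = shift, nodes = nodes[ord],
                 sr = sr[ord], ph = ph[ord],
                 retained_covariates = retained_covariates,
                 interpolation = interpolation,
                 n = nn[1]),
            class = "multiparam_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 1-D bracketing: index pair and weight, exact at nodes
bracket1d <- function(grid, x, what) {
  if (x < min(grid) - 1e-12 || x > max(grid) + 1e-12) {
    rheo_abort(sprintf("%s = %g is outside the model grid [%g, %g]; no extrapolation",
                       what, x, min(grid), max(grid)),
               "rheo_extrapolation_error")
  }
  hit <- which(grid == x)
  if (length(hit)) return(list(i0 = hit[1], i1 = hit[1], w = 0))
  x <- min(max(x, min(grid)), max(grid))
  i1 <- findInterval(x, grid, rightmost.closed = TRUE) # left index
  list(i0 = i1, i1 = i1 + 1L,
       w = (x - grid[i1]) / (grid[i1 + 1L] - grid[i1]))
}

blend_series <- function(a, b, w) {
  # log-linear on branch parameters, linear on the equilibrium modulus
  if (w == 0) return(a)
  if (w == 1) return(b)
  prony_series(
    g0 = (1 - w) * a$g0 + w * b$g0,
    g = exp((1 - w) * log(a$g) + w * log(b$g)),
    tau = exp((1 - w) * log(a$tau) + w * log(b$tau))
  )
}

#' Interpolate the Prony series at a condition
#'
#' Returns the node Prony series when the condition sits exactly on a grid
#' node, otherwise the log-linear (bilinear if pH is retained) blend of the
#' bracketing nodes.
#'
#' @param model A [multiparam_model()].
#' @param cond A [condition()]; `swelling_ratio` (and `ph`, when retained)
#'   must lie inside the grid hull.
#' @return A [prony_series()].
#' @export
interpolate_series <- function(model, cond) {
  stopifnot(inherits(model, "multiparam_model"),
            inherits(cond, "rheo_condition"))
  ph_kept <- "pH" %in% model$retained_covariates
  sr_grid <- sort(unique(model$sr))
  node_at <- function(s, p) {
    idx <- if (ph_kept) which(model$sr == s & model$ph == p) else
      which(model$sr == s)
    model$nodes[[idx[1]]]$prony
  }
  bs <- bracket1d(sr_grid, cond$swelling_ratio, "swelling_ratio")
  if (!ph_kept) {
    return(blend_series(node_at(sr_grid[bs$i0], NA),
                        node_at(sr_grid[bs$i1], NA), bs$w))
  }
  ph_grid <- sort(unique(model$ph))
  if (length(ph_grid) == 1L) {
    if (abs(cond$ph - ph_grid) > 1e-12) {
      rheo_abort("ph is outside the model grid; no extrapolation",
                 "rheo_extrapolation_error")
    }
    return(blend_series(node_at(sr_grid[bs$i0], ph_grid),
                        node_at(sr_grid[bs$i1], ph_grid), bs$w))
  }
  bp <- bracket1d(ph_grid, cond$ph, "ph")
  lo <- blend_series(node_at(sr_grid[bs$i0], ph_grid[bp$i0]),
                     node_at(sr_grid[bs$i1], ph_grid[bp$i0]), bs$w)
  hi <- blend_series(node_at(sr_grid[bs$i0], ph_grid[bp$i1]),
                     node_at(sr_grid[bs$i1], ph_grid[bp$i1]), bs$w)
  blend_series(lo, hi, bp$w)
}

#' Evaluate the multi-parameter relaxation modulus
#'
#' Interpolates the branch parameters at the condition's swelling ratio (and
#' pH, when retained) and evaluates the temperature-shifted relaxation
#' modulus there. At a grid node this equals the node's
#' [relaxation_modulus()] exactly.
#'
#' @param model A [multiparam_model()].
#' @param t Time(s), s, `>= 0`.
#' @param cond A [condition()] inside the model's grid hull.
#' @return Modulus `G(t, theta, SR[, pH])`, Pa.
#' @export
evaluate_multiparam <- function(model, t, cond) {
  ps <- interpolate_series(model, cond)
  relaxation_modulus(ps, model$shift, t, cond$temperature)
}

#' @export
print.multiparam_model <- function(x, ...) {
  cat(sprintf(
    "Multi-parameter Prony model: %d node(s), n = %d, covariates kept: %s\n",
    length(x$nodes), x$n,
    paste(c("temperature (shift)", x$retained_covariates), collapse = ", ")))
  print(x$shift)
  invisible(x)
}
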