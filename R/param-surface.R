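# Per-condition Prony fitting across the swelling (and optionally pH) grid
# and assembly of the final multi-parameter model.

#' Fit Prony series at every (SR, pH) node of a dataset
#'
#' Splits the dataset by (swelling ratio, pH), assembles each node's master
#' curve with the shared Arrhenius shift (a node measured at the reference
#' temperature only reduces trivially) and fits a Prony series with the same
#' branch count everywhere.
#'
#' @param dataset A [sweep_table()] covering the node grid.
#' @param shift The globally estimated [arrhenius_shift()]; a single shift is
#'   shared across all nodes.
#' @param n Branch count for every node fit (default 3).
#' @param tau_policy Passed to [fit_prony()].
#' @return A `condition_table`: list of nodes `list(sr, ph, prony, fit)`.
#' @export
fit_condition_table <- function(dataset, shift, n = 3,
                                tau_policy = "refined") {
  df <- as.data.frame(dataset)
  if (nrow(df) == 0L) {
    rheo_abort("empty dataset", "rheo_insufficient_data_error")
  }
  keys <- unique(df[c("swelling_ratio", "ph")])
  keys <- keys[order(keys$swelling_ratio, keys$ph), , drop = FALSE]
  nodes <- lapply(seq_len(nrow(keys)), function(i) {
    sr <- keys$swelling_ratio[i]
    ph <- keys$ph[i]
    sub <- df[df$swelling_ratio == sr & df$ph == ph, , drop = FALSE]
    fit <- tryCatch({
      mc <- build_master_curve(sweep_table(sub), shift)
      fit_prony(mc, n = n, tau_policy = tau_policy)
    }, rheoprony_error = function(e) {
      rheo_abort(sprintf("node (SR = %g, pH = %g): %s", sr, ph,
                         conditionMessage(e)), "rheo_node_fit_error")
    })
    list(sr = sr, ph = ph, prony = fit$prony, fit = fit)
  })
  structure(nodes, class = "condition_table")
}

collapse_over_ph <- function(entries) {
  # geometric mean (log-average) of branch parameters over pH levels;
  # keeps positivity and treats pH levels symmetrically
  gmat <- sapply(entries, function(e) e$prony$g)
  tmat <- sapply(entries, function(e) e$prony$tau)
  g0s <- vapply(entries, function(e) e$prony$g0, numeric(1))
  gmat <- matrix(gmat, nrow = entries[[1]]$prony$n)
  tmat <- matrix(tmat, nrow = entries[[1]]$prony$n)
  g0 <- if (all(g0s > 0)) exp(mean(log(g0s))) else mean(g0s)
  prony_series(g0, exp(rowMeans(log(gmat))), exp(rowMeans(log(tmat))))
}

#' Assemble the multi-parameter model from a fitted condition table
#'
#' When pH is not retained but the table is pH-resolved, node parameters are
#' collapsed at each swelling ratio by averaging in log space over the pH
#' levels (geometric mean of each `g_i` and `tau_i`), the documented
#' reduction from the pH-resolved to the pH-free model form.
#'
#' @param table A `condition_table` from [fit_condition_table()].
#' @param shift The shared [arrhenius_shift()].
#' @param retained Character subset of `c("SR", "pH")` (from
#'   [screen_covariates()]'s `retained`, temperature excluded).
#' @return A [multiparam_model()].
#' @export
build_multiparam_model <- function(table, shift, retained = c("SR", "pH")) {
  stopifnot(inherits(table, "condition_table"))
  if (length(table) == 0L) {
    rheo_abort("empty condition table", "rheo_invalid_model_error")
  }
  nn <- vapply(table, function(nd) nd$prony$n, integer(1))
  if (length(unique(nn)) != 1L) {
    rheo_abort("nodes have heterogeneous branch counts n",
               "rheo_inconsistency_error")
  }
  retained <- intersect(c("SR", "pH"), retained)
  if (!("pH" %in% retained)) {
    srs <- vapply(table, `[[`, numeric(1), "sr")
    nodes <- lapply(sort(unique(srs)), function(s) {
      entries <- table[srs == s]
      ps <- if (length(entries) == 1L) entries[[1]]$prony else
        collapse_over_ph(entries)
      list(sr = s, ph = NULL, prony = ps)
    })
    return(multiparam_model(shift, nodes, retained_covariates = "SR"))
  }
  nodes <- lapply(table, function(nd) nd[c("sr", "ph", "prony")])
  multiparam_model(shift, nodes, retained_covariates = retained)
}
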