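# Sweep-table CSV, model JSON and FEM material-card readers/writers.

SWEEP_COLUMNS <- c("frequency_hz", "g_prime_pa", "g_double_prime_pa",
                   "temperature_c", "swelling_ratio", "ph")

#' Frequency-sweep table
#'
#' Tidy records of an oscillatory frequency sweep: one row per
#' (frequency, condition) cell with storage and loss moduli. Temperatures are
#' stored in degrees Celsius (the unit rheometer reports print); frequency in
#' Hz. Duplicate (frequency, condition) keys are rejected.
#'
#' @param records A data.frame with columns `frequency_hz`, `g_prime_pa`,
#'   `g_double_prime_pa`, `temperature_c`, `swelling_ratio`, `ph`.
#' @param provenance Free-text metadata (instrument id or synthetic seed).
#' @return A `sweep_table` (a data.frame subclass with a `provenance`
#'   attribute).
#' @export
sweep_table <- function(records, provenance = "") {
  if (!is.data.frame(records)) {
    rheo_abort("records must be a data.frame", "rheo_schema_error")
  }
  miss <- setdiff(SWEEP_COLUMNS, names(records))
  if (length(miss)) {
    rheo_abort(sprintf("missing required column(s): %s",
                       paste(miss, collapse = ", ")), "rheo_schema_error")
  }
  records <- as.data.frame(records)[SWEEP_COLUMNS]
  for (cl in SWEEP_COLUMNS) {
    if (!is.numeric(records[[cl]])) {
      rheo_abort(sprintf("column '%s' must be numeric", cl),
                 "rheo_schema_error")
    }
  }
  if (nrow(records)) {
    finite <- Reduce(`&`, lapply(records, is.finite))
    bad <- !stats::complete.cases(records) | !finite
    if (any(bad)) {
      rheo_abort(sprintf("row(s) %s contain missing or non-finite fields",
                         paste(which(bad), collapse = ", ")),
                 "rheo_schema_error")
    }
    if (any(records$frequency_hz <= 0)) {
      rheo_abort("frequency_hz must be strictly positive",
                 "rheo_schema_error")
    }
  }
  key <- do.call(paste, records[c("frequency_hz", "temperature_c",
                                  "swelling_ratio", "ph")])
  if (anyDuplicated(key)) {
    rheo_abort(sprintf("duplicate (frequency, condition) key at row(s) %s",
                       paste(which(duplicated(key)), collapse = ", ")),
               "rheo_integrity_error")
  }
  ord <- order(records$temperature_c, records$swelling_ratio, records$ph,
               records$frequency_hz)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  structure(records, provenance = provenance,
            class = c("sweep_table", "data.frame"))
}

#' Read and write sweep tables (CSV)
#'
#' Comma-separated, UTF-8, '.' decimal separator, mandatory header with the
#' exact column names of [sweep_table()]. `write_sweep_table()` then
#' `read_sweep_table()` is the identity on records to well below 1e-9
#' relative tolerance (doubles are printed at 15 significant digits).
#'
#' @param path File path.
#' @param table A [sweep_table()].
#' @return `read_sweep_table()` returns a [sweep_table()];
#'   `write_sweep_table()` returns `path` invisibly.
#' @export
read_sweep_table <- function(path) {
  if (!file.exists(path)) {
    rheo_abort(sprintf("input file not found: %s", path),
               "rheo_missing_input_error")
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(SWEEP_COLUMNS, names(raw))
  if (length(miss)) {
    rheo_abort(sprintf("missing required column(s): %s",
                       paste(miss, collapse = ", ")), "rheo_schema_error")
  }
  num <- raw[SWEEP_COLUMNS]
  for (cl in SWEEP_COLUMNS) {
    v <- suppressWarnings(as.numeric(num[[cl]]))
    bad <- which(is.na(v) & !(num[[cl]] %in% c("", "NA")))
    if (length(bad)) {
      rheo_abort(sprintf("non-numeric value '%s' in column '%s' at row %d",
                         num[[cl]][bad[1]], cl, bad[1]), "rheo_parse_error")
    }
    num[[cl]] <- v
  }
  prov <- attr(raw, "provenance")
  sweep_table(num, provenance = prov %||% "")
}

#' @rdname read_sweep_table
#' @export
write_sweep_table <- function(table, path) {
  stopifnot(inherits(table, "sweep_table"))
  df <- as.data.frame(table)
  df[] <- lapply(df, function(x) format(x, digits = 15, trim = TRUE,
                                        scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

MODEL_FORMAT_VERSION <- 1L

#' Serialize and restore a multi-parameter model (JSON)
#'
#' Versioned structured-text serialization of the shift, the node table, the
#' retained covariates and the interpolation rule. Numbers are written at
#' full double precision, so read-back equals the original field-by-field to
#' better than 1e-12 relative.
#'
#' @param model A [multiparam_model()].
#' @param path File path.
#' @return `read_model_json()` returns a [multiparam_model()];
#'   `write_model_json()` returns `path` invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "multiparam_model"))
  obj <- list(
    format_version = MODEL_FORMAT_VERSION,
    shift = list(ea = model$shift$ea, t_ref = model$shift$t_ref),
    retained_covariates = as.list(model$retained_covariates),
    interpolation = model$interpolation,
    nodes = lapply(model$nodes, function(nd) list(
      sr = nd$sr, ph = nd$ph %||% NULL,
      g0 = nd$prony$g0, g = nd$prony$g, tau = nd$prony$tau))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) {
    rheo_abort(sprintf("input file not found: %s", path),
               "rheo_missing_input_error")
  }
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  ver <- obj$format_version
  if (is.null(ver) || !identical(as.integer(ver), MODEL_FORMAT_VERSION)) {
    rheo_abort(sprintf("unsupported model format version: %s",
                       ver %||% "<absent>"), "rheo_version_error")
  }
  nodes <- lapply(obj$nodes, function(nd) list(
    sr = as.numeric(nd$sr),
    ph = if (is.null(nd$ph)) NULL else as.numeric(nd$ph),
    prony = prony_series(as.numeric(nd$g0),
                         vapply(nd$g, as.numeric, numeric(1)),
                         vapply(nd$tau, as.numeric, numeric(1)))))
  multiparam_model(
    shift = arrhenius_shift(as.numeric(obj$shift$ea),
                            as.numeric(obj$shift$t_ref)),
    nodes = nodes,
    retained_covariates = unlist(obj$retained_covariates),
    interpolation = obj$interpolation
  )
}

#' Export a solver-neutral FEM Prony material card
#'
#' Writes a plain-text card with the branch count `n`, relative amplitudes
#' `alpha_i = g_i / (g0 + sum(g))`, relaxation times `tau_i`, the
#' instantaneous modulus (so absolute moduli are reconstructable) and the
#' Arrhenius shift parameters. By construction `sum(alpha) <= 1`, with
#' equality exactly when the equilibrium modulus is zero. The format is
#' documented, not a bit-exact commercial-solver deck.
#'
#' @param prony A [prony_series()] with `g0 + sum(g) > 0`.
#' @param shift An [arrhenius_shift()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
export_fem_card <- function(prony, shift, path) {
  stopifnot(inherits(prony, "prony_series"),
            inherits(shift, "arrhenius_shift"))
  total <- instantaneous_modulus(prony)
  if (total <= 0) {
    rheo_abort("cannot export a card with all-zero moduli",
               "rheo_export_error")
  }
  alpha <- prony$g / total
  num <- function(x) format(x, digits = 17, trim = TRUE)
  lines <- c(
    "# Prony viscoelastic material card (solver-neutral)",
    "prony_card_version 1",
    sprintf("n %d", prony$n),
    sprintf("g_instantaneous_pa %s", num(total)),
    sprintf("ea_j_per_mol %s", num(shift$ea)),
    sprintf("t_ref_k %s", num(shift$t_ref)),
    sprintf("alpha_%d %s", seq_len(prony$n), num(alpha)),
    sprintf("tau_%d %s", seq_len(prony$n), num(prony$tau))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname export_fem_card
#' @return `read_fem_card()` returns a list with fields `n`, `alpha`, `tau`,
#'   `g_instantaneous`, `prony` (the reconstructed [prony_series()]) and
#'   `shift`.
#' @export
read_fem_card <- function(path) {
  if (!file.exists(path)) {
    rheo_abort(sprintf("input file not found: %s", path),
               "rheo_missing_input_error")
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(trimws(lines), "\\s+")
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, `[[`, character(1), 2)
  get1 <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) rheo_abort(sprintf("card field '%s' missing", k),
                             "rheo_parse_error")
    as.numeric(vals[i])
  }
  if (get1("prony_card_version") != 1) {
    rheo_abort("unsupported material-card version", "rheo_version_error")
  }
  n <- as.integer(get1("n"))
  alpha <- vapply(sprintf("alpha_%d", seq_len(n)), get1, numeric(1))
  tau <- vapply(sprintf("tau_%d", seq_len(n)), get1, numeric(1))
  total <- get1("g_instantaneous_pa")
  prony <- prony_series(total * (1 - sum(alpha)), total * alpha, tau)
  list(n = n, alpha = unname(alpha), tau = unname(tau),
       g_instantaneous = total, prony = prony,
       shift = arrhenius_shift(get1("ea_j_per_mol"), get1("t_ref_k")))
}
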