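#' Read a SMILES dataset
#'
#' Reads delimited datasets with columns `id`, `smiles` and (optionally)
#' `endpoint`.  CSV and TSV files carry a header (column names are matched
#' case-insensitively, so `SMILES` works); `.smi` files are whitespace
#' delimited without header, in the conventional order
#' `smiles id [endpoint]`.  Lines starting with `#` are ignored.  Rows whose
#' SMILES fail to tokenize are reported with their row numbers and either
#' abort the read (`on_error = "fatal"`, default) or are dropped with a
#' warning (`"skip"`).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"smi"`.
#' @param on_error `"fatal"` or `"skip"` for unparseable SMILES rows.
#' @return Data frame with columns `id`, `smiles`, `endpoint` (NA when
#'   absent).
#' @export
read_smiles_dataset <- function(path, format = c("auto", "csv", "tsv", "smi"),
                                on_error = c("fatal", "skip")) {
  format <- match.arg(format)
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", smi = "smi",
                     txt = "tsv", "csv")
  }
  if (format == "smi") {
    df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                            comment.char = "#", fill = TRUE)
    if (ncol(df) < 2L) stop("a .smi file needs at least smiles and id columns")
    names(df)[1:2] <- c("smiles", "id")
    if (ncol(df) >= 3L) names(df)[3L] <- "endpoint"
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, comment.char = "#")
    names(df) <- tolower(names(df))
  }
  if (!all(c("id", "smiles") %in% names(df)))
    stop("dataset must have columns 'id' and 'smiles' (got: ",
         paste(names(df), collapse = ", "), ")")
  if (is.null(df$endpoint)) df$endpoint <- NA_real_
  df <- df[, c("id", "smiles", "endpoint")]
  df$id <- as.character(df$id)
  df$smiles <- as.character(df$smiles)
  df$endpoint <- as.numeric(df$endpoint)
  if (nrow(df) == 0L) stop("empty dataset: ", path)
  if (anyDuplicated(df$id))
    stop("duplicate compound id: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  bad <- which(vapply(df$smiles, function(s)
    inherits(try(attribute_profile(s), silent = TRUE), "try-error"),
    logical(1L)))
  if (length(bad)) {
    msg <- paste0("unparseable SMILES at row(s) ",
                  paste(bad, collapse = ", "))
    if (on_error == "fatal") stop(msg)
    warning(msg, "; rows dropped")
    df <- df[-bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_smiles_dataset
#' @param data Data frame with columns `id`, `smiles`, `endpoint`.
#' @param meta Optional character line (without leading `#`) embedded as a
#'   comment header, typically [run_meta()].
#' @export
write_smiles_dataset <- function(data, path, format = c("csv", "tsv"),
                                 meta = NULL) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(data, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Provenance line for output artifacts
#'
#' Every tabular artifact written by the package embeds the package version,
#' the seed and a fingerprint of the optimization settings, so a result file
#' can always be traced to the configuration that produced it.
#'
#' @param control A [cw_control()] (or `NULL`).
#' @param seed Seed to record (defaults to `control$seed`).
#' @return A single character line.
#' @export
run_meta <- function(control = NULL, seed = control$seed) {
  sprintf("cwqsar %s seed=%s config=%s",
          as.character(utils::packageVersion("cwqsar")),
          if (is.null(seed)) "NA" else seed,
          if (is.null(control)) "none" else config_fingerprint(control))
}

# order-independent decimal fingerprint of a control list
config_fingerprint <- function(control) {
  s <- paste(names(control)[order(names(control))],
             vapply(control[order(names(control))],
                    function(v) paste(format(v, digits = 15), collapse = ","),
                    character(1L)),
             sep = "=", collapse = ";")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) h <- ((h * 16777619) %% 4294967296 + b) %% 4294967296
  sprintf("%.0f", h)
}

#' Save or load a fitted model as JSON
#'
#' The JSON artifact stores everything needed to predict: the correlation
#' weights, blocked attributes, calibration coefficients, optimization
#' settings, and the applicability-domain statistics, plus the package
#' version and seed.  Numbers are written with 17 significant digits so the
#' round trip is bit-exact: a model saved and re-loaded produces identical
#' predictions.
#'
#' @param model A fitted [cw_fit()] model.
#' @param path File path for the JSON artifact.
#' @return `load_cw_model` returns an object of class `"cw_model"` (without
#'   the training data and history); `save_cw_model` returns `path`
#'   invisibly.
#' @export
save_cw_model <- function(model, path) {
  stopifnot(inherits(model, "cw_model"))
  payload <- list(
    format = "cwqsar-model",
    format_version = 1L,
    version = model$version,
    control = unclass(model$control),
    weights = as.list(model$weights),
    blocked = model$blocked,
    c0 = model$c0,
    c1 = model$c1,
    domain = list(defects = model$domain$defects,
                  dj = as.list(model$domain$dj),
                  dbar = model$domain$dbar),
    split_id = attr(model$split, "split_id")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_cw_model
#' @export
load_cw_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e)
                        stop("corrupted model file: ", conditionMessage(e)))
  if (!identical(payload$format, "cwqsar-model"))
    stop("not a cwqsar model file: ", path)
  if (!identical(as.integer(payload$format_version), 1L))
    stop("unsupported model format version: ", payload$format_version)
  control <- payload$control
  control$init_range <- as.numeric(control$init_range)
  class(control) <- "cw_control"
  structure(list(
    weights = unlist(payload$weights),
    blocked = as.character(payload$blocked),
    c0 = payload$c0,
    c1 = payload$c1,
    domain = list(defects = payload$domain$defects,
                  dj = unlist(payload$domain$dj),
                  dbar = payload$domain$dbar),
    control = control,
    split_id = payload$split_id,
    version = payload$version
  ), class = "cw_model")
}

#' Write the optimization history as CSV
#'
#' One row per epoch with the target-function value and the per-set
#' determination coefficients, the data behind overtraining-diagnosis plots.
#'
#' @param model A fitted [cw_fit()] model.
#' @param path File path.
#' @export
write_history <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", run_meta(model$control)), con)
  utils::write.table(model$history, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write the per-set statistics table as TSV
#'
#' Emits the standard report shape: one row per set (A/P/C/V) with columns
#' n, R2, CCC, IIC, Q2, RMSE, MAE, F, plus target and split labels so
#' multiple runs can be concatenated and aggregated with [cw_report()].
#'
#' @param model A fitted [cw_fit()] model.
#' @param path File path.
#' @export
write_stats_table <- function(model, path) {
  s <- as.data.frame(summary(model))
  s <- cbind(target = model$control$target,
             split = attr(model$split, "split_id"), s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", run_meta(model$control)), con)
  utils::write.table(s, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the applicability-domain report as TSV
#'
#' Two tables: per attribute (frequencies in the three modelling sets and
#' the statistical defect dk) and per compound (defect Dj and the in-domain
#' flag).
#'
#' @param model A fitted [cw_fit()] model.
#' @param attr_path,compound_path File paths for the two tables.
#' @export
write_domain_report <- function(model, attr_path, compound_path) {
  meta <- paste0("# ", run_meta(model$control))
  con <- file(attr_path, "w")
  writeLines(meta, con)
  utils::write.table(model$domain$defects, con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  close(con)
  dj <- model$domain$dj
  comp <- data.frame(id = names(dj), dj = unname(dj),
                     in_domain = unname(in_domain(dj, model$domain$dbar)),
                     stringsAsFactors = FALSE)
  con <- file(compound_path, "w")
  writeLines(meta, con)
  utils::write.table(comp, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(attr_path)
}

#' Write the promoter classification table as TSV
#'
#' @param promoters A [classify_promoters()] result.
#' @param path File path.
#' @param meta Optional provenance line (see [run_meta()]).
#' @export
write_promoter_table <- function(promoters, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(as.data.frame(promoters), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate statistics across splits and target functions
#'
#' Summarizes per-split model statistics into a comparison report: for each
#' (target function, set) pair the mean determination coefficient and its
#' dispersion, computed both as the population standard deviation (divide by
#' k) and as the sample standard deviation (divide by k - 1).  RMSE is
#' aggregated the same way when present.
#'
#' @param x Either a list of fitted [cw_fit()] models or a data frame with
#'   columns `target`, `split`, `set`, `r2` (and optionally `rmse`), e.g.
#'   concatenated [write_stats_table()] outputs.
#' @return Data frame with one row per (target, set): `k`, `mean_r2`,
#'   `sd_pop_r2`, `sd_r2`, and the RMSE analogues when available.
#' @export
cw_report <- function(x) {
  if (is.list(x) && !is.data.frame(x) &&
      all(vapply(x, inherits, logical(1L), "cw_model"))) {
    x <- do.call(rbind, lapply(x, function(m) {
      s <- as.data.frame(summary(m))
      cbind(target = m$control$target, split = attr(m$split, "split_id"), s)
    }))
  }
  if (!all(c("target", "set", "r2") %in% names(x)))
    stop("need columns target, set, r2")
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  groups <- unique(x[, c("target", "set")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- x[x$target == groups$target[i] & x$set == groups$set[i], ]
    out <- data.frame(target = groups$target[i], set = groups$set[i],
                      k = nrow(g), mean_r2 = mean(g$r2),
                      sd_pop_r2 = sd_pop(g$r2),
                      sd_r2 = if (nrow(g) > 1L) stats::sd(g$r2) else NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.null(g$rmse) && !anyNA(g$rmse)) {
      out$mean_rmse <- mean(g$rmse)
      out$sd_pop_rmse <- sd_pop(g$rmse)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
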