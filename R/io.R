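# File I/O and the orchestration layer behind the command-line interface.

#' Read prediction sets from a delimited file
#'
#' Reads a comma-separated file (header row required, `.` decimal) holding
#' a binary outcome column and one or more columns of predicted
#' probabilities, and returns one [prediction_set()] per probability
#' column, all sharing the outcome vector.  Rows with a missing value in
#' any required column are dropped (complete-case rule) and the dropped
#' count is logged as a warning.
#'
#' @param path path to a CSV file.
#' @param outcome_column name of the 0/1 outcome column.
#' @param probability_columns character vector of probability column names.
#' @return A named list of `prediction_set` objects.
#' @export
read_predictions <- function(path, outcome_column, probability_columns) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  if (length(probability_columns) < 1L) {
    stop_config("at least one probability column is required")
  }
  df <- utils::read.csv(path)
  needed <- c(outcome_column, probability_columns)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop_config("column(s) not found in ", path, ": ",
                paste(missing_cols, collapse = ", "))
  }
  keep <- stats::complete.cases(df[needed])
  if (any(!keep)) {
    log_msg("warning", sprintf("dropped %d row(s) with missing values in %s",
                               sum(!keep), path))
  }
  df <- df[keep, , drop = FALSE]
  y <- df[[outcome_column]]
  if (!all(y %in% c(0, 1))) {
    bad <- unique(y[!y %in% c(0, 1)])
    stop_input("outcome column '", outcome_column, "' must be 0/1; ",
               "offending values: ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  stats::setNames(
    lapply(probability_columns, function(col) prediction_set(y, df[[col]], col)),
    probability_columns
  )
}

fmt12 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.12g", x))
}

#' Write and read decision-curve tables
#'
#' Long-format tab-separated text with a header row.  Numeric columns are
#' written as decimal text with 12 significant digits, so a write-read
#' round trip reproduces the file byte for byte.
#'
#' @param curves a `decision_curve` data frame (curves may be combined with
#'   `rbind`), or any data frame with numeric and character columns.
#' @param path output file path.
#' @return `write_curve_tsv` returns `path` invisibly; `read_curve_tsv`
#'   returns the table as a data frame.
#' @export
write_curve_tsv <- function(curves, path) {
  out <- as.data.frame(curves)
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt12(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_curve_tsv
#' @export
read_curve_tsv <- function(path) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Parse a prevalence specification string
#'
#' Accepts a single number (`"0.3"`), a comma-separated list
#' (`"0.15,0.3,0.45"`), or a range (`"start:stop:step"`, e.g.
#' `"0.1:0.5:0.05"`).
#'
#' @param spec character scalar.
#' @return Numeric vector of prevalences in (0, 1).
#' @export
parse_pi0_spec <- function(spec) {
  spec <- trimws(as.character(spec))
  vals <- if (grepl(":", spec, fixed = TRUE)) {
    parts <- as.numeric(strsplit(spec, ":", fixed = TRUE)[[1]])
    if (length(parts) != 3L || anyNA(parts)) {
      stop_config("range spec must be start:stop:step, got '", spec, "'")
    }
    seq(parts[1], parts[2], by = parts[3])
  } else {
    as.numeric(strsplit(spec, ",", fixed = TRUE)[[1]])
  }
  if (anyNA(vals) || any(vals <= 0) || any(vals >= 1)) {
    stop_config("prevalence values must lie strictly inside (0, 1): '", spec, "'")
  }
  vals
}

#' Configuration for a decision-curve run
#'
#' Bundles the inputs of [run_dca()]: which file and columns to read, which
#' benefit kinds and threshold grid to evaluate, an optional set of assumed
#' true prevalences for a case-control analysis, and output options.
#'
#' @param input_path CSV file of subjects, see [read_predictions()].
#' @param outcome_column,probability_columns column names.
#' @param kinds subset of `c("treated", "untreated", "overall")`.
#' @param grid a [threshold_grid()].
#' @param pi0 optional numeric vector of assumed true prevalences (or a
#'   string accepted by [parse_pi0_spec()]).
#' @param output_prefix path prefix for written artifacts.
#' @param plot logical; also write one PNG per benefit kind.
#' @param log_level one of `"info"`, `"warning"`, `"error"`.
#' @return An object of class `dca_config`.
#' @export
dca_config <- function(input_path, outcome_column, probability_columns,
                       kinds = c("treated", "untreated", "overall"),
                       grid = threshold_grid(), pi0 = NULL,
                       output_prefix = "dca", plot = FALSE,
                       log_level = "info") {
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (is.character(pi0)) pi0 <- parse_pi0_spec(pi0)
  structure(
    list(input_path = input_path, outcome_column = outcome_column,
         probability_columns = probability_columns, kinds = kinds,
         grid = as_threshold_grid(grid), pi0 = pi0,
         output_prefix = output_prefix, plot = isTRUE(plot),
         log_level = log_level),
    class = "dca_config"
  )
}

#' Run a full decision-curve analysis
#'
#' Reads the input file, computes the decision curves of every model
#' column together with the treat-none, treat-all and perfect reference
#' strategies for each requested benefit kind, and writes them as a
#' long-format TSV (`<prefix>_curves.tsv`).  If assumed true prevalences
#' are configured, a case-control table (`<prefix>_casecontrol.tsv`) is
#' also written, with references recomputed at each assumed prevalence.
#' Optionally writes one plot per kind in the classic five-curve layout.
#' On any error, partially written outputs are removed before the error is
#' propagated.
#'
#' @param config a [dca_config()].
#' @return Invisibly, a character vector of the paths written.
#' @export
run_dca <- function(config) {
  stopifnot(inherits(config, "dca_config"))
  old <- options(netbenefit.log_level = config$log_level)
  on.exit(options(old), add = TRUE)
  written <- character(0)
  on_failure <- function(e) {
    file.remove(written[file.exists(written)])
    stop(e)
  }
  tryCatch({
    preds <- read_predictions(config$input_path, config$outcome_column,
                              config$probability_columns)
    pi <- prevalence(preds[[1]])
    grid <- config$grid

    cohort_block <- function(kind) {
      curves <- lapply(preds, decision_curve, grid = grid, kind = kind)
      refs <- lapply(c("treat_none", "treat_all", "perfect"),
                     function(s) reference_curve(pi, grid, s, kind))
      do.call(rbind, c(curves, refs))
    }
    tab <- do.call(rbind, lapply(config$kinds, cohort_block))
    curves_path <- paste0(config$output_prefix, "_curves.tsv")
    write_curve_tsv(tab, curves_path)
    written <- c(written, curves_path)
    log_msg("info", "wrote ", curves_path)

    if (!is.null(config$pi0)) {
      cc_block <- function(pi0, kind) {
        curves <- lapply(preds, case_control_curve, pi0 = pi0,
                         grid = grid, kind = kind)
        refs <- lapply(c("treat_none", "treat_all", "perfect"), function(s) {
          rc <- reference_curve(pi0, grid, s, kind)
          rc$pi0 <- pi0
          rc
        })
        do.call(rbind, c(curves, refs))
      }
      cc <- do.call(rbind, lapply(config$pi0, function(pi0) {
        do.call(rbind, lapply(config$kinds, cc_block, pi0 = pi0))
      }))
      cc_path <- paste0(config$output_prefix, "_casecontrol.tsv")
      write_curve_tsv(cc, cc_path)
      written <- c(written, cc_path)
      log_msg("info", "wrote ", cc_path)
    }

    if (config$plot) {
      for (kind in config$kinds) {
        png_path <- sprintf("%s_%s.png", config$output_prefix, kind)
        grDevices::png(png_path, width = 800, height = 600)
        plot(tab[tab$kind == kind, ],
             main = sprintf("Decision curves (%s)", kind))
        grDevices::dev.off()
        written <- c(written, png_path)
        log_msg("info", "wrote ", png_path)
      }
    }
    invisible(written)
  }, error = on_failure)
}
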