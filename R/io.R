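#' Archive a run or report to a directory
#'
#' Writes every numeric trace as full-precision CSV and everything scalar
#' (report fields, configuration echo) as JSON, so a run can be restored or
#' inspected with standard tools. The layout is one directory per run:
#' `report.json` (typed scalar fields + class tag), plus one CSV per matrix
#' trace (`proj_k.csv`, `weight_traces.csv`, `spectrum.csv`, ...).
#'
#' @param x a report or `network_run` produced by this package.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalars <- list(class = class(x)[1])
  for (nm in names(x)) {
    val <- x[[nm]]
    if (is.null(val)) next
    if (nm %in% c("snaps_real", "reports", "eigvecs")) next
    if (is.matrix(val)) {
      .write_matrix_csv(val, file.path(dir, paste0(nm, ".csv")))
    } else if (is.list(val) && length(val) > 0 && all(vapply(val, is.matrix, logical(1)))) {
      for (k in seq_along(val)) {
        .write_matrix_csv(val[[k]], file.path(dir, sprintf("%s_%03d.csv", nm, k)))
      }
      scalars[[paste0("n_", nm)]] <- length(val)
    } else if (is.atomic(val) || (is.list(val) && !is.object(val)) || inherits(val, "contribution_report")) {
      scalars[[nm]] <- if (is.object(val)) unclass(val) else val
    }
  }
  jsonlite::write_json(scalars, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(dir)
}

.write_matrix_csv <- function(m, path) {
  df <- as.data.frame(m)
  if (is.null(colnames(m))) names(df) <- paste0("c", seq_len(ncol(m)))
  utils::write.csv(.format_full(df), path, row.names = FALSE, quote = FALSE)
}

.renumber <- function(x) {
  # jsonlite writes non-finite numerics as strings; undo that on read
  if (is.list(x)) return(lapply(x, .renumber))
  if (is.character(x) && length(x) > 0 &&
      all(x %in% c("Inf", "-Inf", "NA", "NaN"))) {
    return(as.numeric(x))
  }
  x
}

#' @rdname write_run
#' @param dir archived run directory.
#' @return for `read_run`, a list with `report` (scalar fields) and one
#'   numeric matrix per archived CSV trace.
#' @export
read_run <- function(dir) {
  rp <- file.path(dir, "report.json")
  if (!file.exists(rp)) {
    stop("missing artifact: ", rp, call. = FALSE)
  }
  out <- list(report = .renumber(jsonlite::read_json(rp, simplifyVector = TRUE)))
  for (f in list.files(dir, pattern = "\\.csv$", full.names = TRUE)) {
    nm <- sub("\\.csv$", "", basename(f))
    df <- utils::read.csv(f, check.names = FALSE)
    out[[nm]] <- as.matrix(df)
  }
  out
}
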