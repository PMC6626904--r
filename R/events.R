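#' Single-cell event table
#'
#' An events x channels matrix plus sample metadata. Values are raw ion
#' counts until [arcsinh_transform()] is applied, which flips the
#' `transformed` flag exactly once.
#'
#' @param values numeric matrix, events x channels, with column names equal
#'   to the panel channel names (any order; columns are aligned by name).
#' @param panel a `panel_definition`.
#' @param individual_id,group,condition sample metadata.
#' @param transformed logical; `TRUE` once marker channels are on the
#'   arcsinh scale.
#' @return An object of class `event_table`.
#' @export
event_table <- function(values, panel, individual_id, group, condition,
                        transformed = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  want <- panel_channels(panel)
  if (is.null(colnames(values)))
    stop("event matrix must carry channel names as column names")
  missing <- setdiff(want, colnames(values))
  if (length(missing))
    stop("MissingChannel: ", paste(missing, collapse = ", "))
  values <- values[, want, drop = FALSE]
  if (anyNA(values)) stop("event table must not contain missing values")
  if (!transformed && any(values < 0))
    stop("raw event values must be non-negative")
  structure(list(values = values, panel = panel,
                 individual_id = as.character(individual_id),
                 group = as.character(group),
                 condition = as.character(condition),
                 transformed = isTRUE(transformed)),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("event_table: %d events x %d channels [%s, %s, %s, %s]\n",
              nrow(x$values), ncol(x$values), x$individual_id, x$group,
              x$condition, if (x$transformed) "arcsinh" else "raw"))
  invisible(x)
}

#' Number of events in a table
#' @param table an `event_table`.
#' @return integer event count.
#' @export
n_events <- function(table) nrow(table$values)

#' Arcsinh-transform marker channels
#'
#' Replaces every marker value x by `asinh(x / cofactor)`. QC channels are
#' left raw: cleanup operates on mean-variance scaled QC channels, not on
#' the arcsinh scale. Applying the transform twice is an error.
#'
#' @param table a raw `event_table`.
#' @param cofactor positive scaling divisor; defaults to the panel cofactor.
#' @return The transformed `event_table`.
#' @export
arcsinh_transform <- function(table, cofactor = table$panel$cofactor) {
  if (table$transformed) stop("event table is already arcsinh-transformed")
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0)
    stop("cofactor must be a single positive number")
  marker_ch <- panel_channels(table$panel, c("phenotyping", "functional"))
  table$values[, marker_ch] <- asinh(table$values[, marker_ch] / cofactor)
  table$transformed <- TRUE
  table
}

#' Invert the arcsinh transform
#'
#' @param table a transformed `event_table`.
#' @param cofactor the cofactor used in the forward transform.
#' @return A raw-scale `event_table`.
#' @export
arcsinh_invert <- function(table, cofactor = table$panel$cofactor) {
  if (!table$transformed) stop("event table is not transformed")
  marker_ch <- panel_channels(table$panel, c("phenotyping", "functional"))
  table$values[, marker_ch] <- sinh(table$values[, marker_ch]) * cofactor
  table$transformed <- FALSE
  table
}
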