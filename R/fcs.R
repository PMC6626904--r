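# Minimal FCS 3.1 reader/writer: list-mode float32 data, one data segment,
# no analysis segment. Sufficient for cytometry event matrices; not a
# general-purpose FCS implementation.

FCS_DELIM <- "/"

build_fcs_text <- function(keywords) {
  if (any(grepl(FCS_DELIM, unlist(keywords), fixed = TRUE)))
    stop("FCS keyword values must not contain the delimiter '", FCS_DELIM, "'")
  paste0(FCS_DELIM,
         paste(rbind(names(keywords), unlist(keywords)), collapse = FCS_DELIM),
         FCS_DELIM)
}

#' Write an event matrix as FCS 3.1
#'
#' Writes list-mode single-precision float data with the channel names as
#' `$PnN` keywords.
#'
#' @param values numeric events x channels matrix with column names.
#' @param path output file path.
#' @param extra_keywords named character vector of additional TEXT keywords.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(values, path, extra_keywords = NULL) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(colnames(values)))
  if (nrow(values) == 0L) stop("refusing to write an empty event table")
  n <- nrow(values); p <- ncol(values)
  data_len <- 4L * n * p
  kw <- c(
    list("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
         "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
         "$BEGINDATA" = "0", "$ENDDATA" = "0",
         "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
         "$NEXTDATA" = "0", "$PAR" = as.character(p),
         "$TOT" = as.character(n)))
  for (j in seq_len(p)) {
    kw[[sprintf("$P%dN", j)]] <- colnames(values)[j]
    kw[[sprintf("$P%dB", j)]] <- "32"
    kw[[sprintf("$P%dE", j)]] <- "0,0"
    kw[[sprintf("$P%dR", j)]] <- as.character(max(1, ceiling(max(values[, j]))))
  }
  if (!is.null(extra_keywords))
    for (k in names(extra_keywords)) kw[[k]] <- as.character(extra_keywords[[k]])

  header_len <- 58L  # "FCS3.1" + 4 spaces + 6 fields of 8 chars
  # data offsets depend on TEXT length, which depends on the offsets; iterate
  # until the byte layout is stable (converges in <= 3 passes).
  repeat {
    text <- build_fcs_text(kw)
    text_begin <- header_len
    text_end <- text_begin + nchar(text, type = "bytes") - 1L
    data_begin <- text_end + 1L
    data_end <- data_begin + data_len - 1L
    if (identical(kw[["$BEGINDATA"]], as.character(data_begin)) &&
        identical(kw[["$ENDDATA"]], as.character(data_end))) break
    kw[["$BEGINDATA"]] <- as.character(data_begin)
    kw[["$ENDDATA"]] <- as.character(data_end)
  }
  header <- paste0("FCS3.1    ",
                   paste(formatC(c(text_begin, text_end, data_begin, data_end,
                                   0L, 0L), width = 8, format = "d"),
                         collapse = ""))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(header, text), con, eos = NULL)
  writeBin(as.vector(t(values)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an FCS 3.0/3.1 file
#'
#' Supports list-mode data of type `F` (float32) or `D` (float64), little or
#' big endian, with data offsets in the header or in the TEXT segment.
#'
#' @param path file path.
#' @return list with `values` (events x channels matrix, `$PnN` column
#'   names) and `keywords` (named character vector of the TEXT segment).
#' @export
read_fcs <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(raw) < 58L) stop("not an FCS file (too short): ", path)
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version '", version, "' in ", path)
  field <- function(i) {
    start <- 10L + (i - 1L) * 8L
    as.integer(trimws(rawToChar(raw[(start + 1L):(start + 8L)])))
  }
  text_begin <- field(1); text_end <- field(2)
  data_begin <- field(3); data_end <- field(4)
  text <- rawToChar(raw[(text_begin + 1L):(text_end + 1L)])
  delim <- substr(text, 1L, 1L)
  parts <- strsplit(substring(text, 2L), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L != 0L)
    parts <- parts[seq_len(length(parts) - 1L)]
  keywords <- stats::setNames(parts[seq(2L, length(parts), 2L)],
                              parts[seq(1L, length(parts), 2L)])
  if (is.na(data_begin) || data_begin == 0L) {
    data_begin <- as.integer(keywords[["$BEGINDATA"]])
    data_end <- as.integer(keywords[["$ENDDATA"]])
  }
  p <- as.integer(keywords[["$PAR"]])
  n <- as.integer(keywords[["$TOT"]])
  dtype <- keywords[["$DATATYPE"]]
  if (!dtype %in% c("F", "D"))
    stop("unsupported FCS $DATATYPE '", dtype, "'")
  size <- if (dtype == "F") 4L else 8L
  endian <- if (identical(keywords[["$BYTEORD"]], "4,3,2,1")) "big" else "little"
  bits <- unique(vapply(seq_len(p), function(j)
    keywords[[sprintf("$P%dB", j)]], ""))
  if (!identical(bits, as.character(size * 8L)))
    stop("unsupported FCS $PnB widths: ", paste(bits, collapse = ", "))
  vals <- readBin(raw[(data_begin + 1L):(data_end + 1L)], what = "numeric",
                  n = n * p, size = size, endian = endian)
  m <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  colnames(m) <- vapply(seq_len(p), function(j)
    keywords[[sprintf("$P%dN", j)]], "")
  list(values = m, keywords = keywords)
}

#' Does a file start with the FCS magic bytes?
#'
#' @param path file path.
#' @return Logical.
#' @export
looks_like_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, what = "raw", n = 3L)
  length(magic) == 3L && identical(rawToChar(magic), "FCS")
}

#' Read a sample's events
#'
#' Reads an FCS 3.0/3.1 file or a delimited text table (TSV/CSV with a
#' header row of channel names) and resolves channels by name against the
#' panel, so column order in the file is irrelevant.
#'
#' @param path file path.
#' @param panel a `panel_definition`.
#' @param meta list or one-row data.frame with `individual_id`, `group`,
#'   `condition` (e.g. one manifest record).
#' @param aliases optional named character vector mapping file channel names
#'   to panel channel names (e.g. `c("p-p38" = "156Gd_p-p38")`).
#' @return A raw `event_table`.
#' @export
read_events <- function(path, panel, meta, aliases = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.info(path)$size == 0L) stop("empty event file: ", path)
  if (looks_like_fcs(path)) {
    values <- read_fcs(path)$values
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    if (nrow(df) == 0L) stop("empty event file: ", path)
    values <- as.matrix(df)
    if (!is.numeric(values)) stop("non-numeric event data in ", path)
  }
  if (!is.null(aliases)) {
    hit <- colnames(values) %in% names(aliases)
    colnames(values)[hit] <- aliases[colnames(values)[hit]]
  }
  event_table(values, panel,
              individual_id = meta$individual_id, group = meta$group,
              condition = meta$condition)
}

#' Write a sample's events
#'
#' Persists raw (untransformed) event data, as FCS 3.1 if `path` ends in
#' `.fcs` and as tab-separated text otherwise.
#'
#' @param table a raw `event_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path) {
  if (table$transformed)
    stop("only raw (untransformed) event tables are persisted")
  if (n_events(table) == 0L) stop("refusing to write an empty event table")
  if (grepl("\\.fcs$", path, ignore.case = TRUE)) {
    write_fcs(table$values, path)
  } else {
    utils::write.table(table$values, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
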