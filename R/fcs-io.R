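# Event-table I/O: a plain CSV schema (with metadata header comments)
# and minimal FCS 3.0 (list mode, 32-bit float, single dataset) for
# interchange with standard cytometry parsers.

fcs_channel_name <- function(col) {
  switch(col,
    fsc_a = "FSC-A", fl1_a = "FL1-A", mcherry_a = "mCherry-A",
    t_acquire = "Time", toupper(col))
}

col_from_channel <- function(ch) {
  switch(ch,
    "FSC-A" = "fsc_a", "FL1-A" = "fl1_a", "mCherry-A" = "mcherry_a",
    "Time" = "t_acquire", tolower(gsub("-", "_", ch)))
}

#' Write an event table to CSV or FCS 3.0
#'
#' CSV files carry acquisition metadata as `#key=value` header comment
#' lines and round-trip losslessly through [read_events()]. FCS output
#' is minimal FCS 3.0: list mode, one dataset, 32-bit little-endian
#' floats, linear amplification, channel names in `$PnN` (`FSC-A`,
#' `FL1-A`, `Time`, ...).
#'
#' @param table an `event_table` with at least one row.
#' @param path output file path.
#' @param format `"csv"` or `"fcs"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "event_table"))
  if (nrow(table) == 0L) stop_param("refusing to write an empty event table")
  if (format == "csv") write_events_csv(table, path) else write_events_fcs(table, path)
  invisible(path)
}

write_events_csv <- function(table, path) {
  meta <- events_metadata(table)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    v <- meta[[k]]
    if (length(v) == 1L && !is.na(v)) writeLines(sprintf("#%s=%s", k, v), con)
  }
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(unname(df), sep = ",")), con)
}

write_events_fcs <- function(table, path) {
  df <- as.data.frame(table)
  num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  dat <- as.matrix(df[num_cols])
  n <- nrow(dat); p <- ncol(dat)
  meta <- events_metadata(table)

  kw <- c("$DATATYPE" = "F", "$MODE" = "L", "$BYTEORD" = "1,2,3,4",
          "$NEXTDATA" = "0", "$PAR" = as.character(p), "$TOT" = as.character(n),
          "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$BEGINDATA" = "@@@@@@@@@@", "$ENDDATA" = "##########")
  for (i in seq_len(p)) {
    rng <- max(1, ceiling(max(dat[, i], 0, na.rm = TRUE)))
    kw[sprintf("$P%dN", i)] <- fcs_channel_name(num_cols[i])
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- as.character(rng)
  }
  for (k in c("strain", "alpha", "aba", "timepoint", "dialect")) {
    v <- meta[[k]]
    if (length(v) == 1L && !is.na(v)) kw[toupper(k)] <- as.character(v)
  }
  delim <- "/"
  text <- paste0(delim, paste(rbind(names(kw), unname(kw)), collapse = delim),
                 delim)
  header_len <- 58L
  text_start <- header_len
  text_end <- text_start + nchar(text) - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n * p - 1L
  text <- sub("@@@@@@@@@@", sprintf("%010d", data_start), text, fixed = TRUE)
  text <- sub("##########", sprintf("%010d", data_end), text, fixed = TRUE)
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end, data_start, data_end, 0L, 0L)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(dat)), con, size = 4L, endian = "little")
}

#' Read an event table from CSV or FCS
#'
#' @param path input file; format inferred from the extension unless
#'   given.
#' @param format `"csv"`, `"fcs"`, or `NULL` to infer.
#' @return An `event_table`.
#' @export
read_events <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "fcs") "fcs" else "csv"
  }
  format <- match.arg(format, c("csv", "fcs"))
  if (format == "csv") read_events_csv(path) else read_events_fcs(path)
}

read_events_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#", "", ln)
    k <- sub("=.*$", "", kv)
    v <- sub("^[^=]*=", "", kv)
    vn <- suppressWarnings(as.numeric(v))
    meta[[k]] <- if (!is.na(vn)) vn else v
  }
  df <- read.csv(text = paste(lines[!startsWith(lines, "#")], collapse = "\n"))
  event_table(df, meta)
}

read_events_fcs <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  header <- rawToChar(raw[1:58])
  if (!startsWith(header, "FCS3")) stop_param("not an FCS 3.x file: %s", path)
  offs <- as.integer(substring(header, 10 + 8 * (0:3) + 1, 10 + 8 * (1:4)))
  text <- rawToChar(raw[(offs[1] + 1):(offs[2] + 1)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1L) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- setNames(trimws(vals), trimws(keys))
  if (!identical(kw[["$DATATYPE"]], "F")) {
    stop_param("only $DATATYPE F (float) FCS data is supported")
  }
  endian <- if (identical(kw[["$BYTEORD"]], "4,3,2,1")) "big" else "little"
  p <- as.integer(kw[["$PAR"]]); n <- as.integer(kw[["$TOT"]])
  dstart <- as.integer(kw[["$BEGINDATA"]] %||% offs[3])
  vals <- readBin(raw[(dstart + 1):length(raw)], "numeric",
                  n = n * p, size = 4L, endian = endian)
  mat <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  cols <- vapply(seq_len(p),
                 function(i) col_from_channel(kw[[sprintf("$P%dN", i)]]),
                 character(1))
  df <- as.data.frame(mat)
  names(df) <- cols
  meta <- list()
  for (k in c("strain", "alpha", "aba", "timepoint", "dialect")) {
    v <- unname(kw[toupper(k)])
    if (!is.na(v)) {
      vn <- suppressWarnings(as.numeric(v))
      meta[[k]] <- if (!is.na(vn)) vn else v
    }
  }
  event_table(df, meta)
}
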