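# Event-table input/output: delimited text (CSV/TSV with a header of
# channel names) and a minimal FCS 3.0/3.1 reader/writer (list mode,
# float or double data, either byte order). Optional per-channel
# transforms are explicit, never applied silently.

apply_transform <- function(x, transform = c("none", "asinh", "log10"),
                            cofactor = 150, floor = 1) {
  transform <- match.arg(transform)
  switch(transform,
    none = x,
    asinh = asinh(x / cofactor),
    log10 = log10(pmax(x, floor)))
}

#' Read an event table from FCS or delimited text
#'
#' The format is detected from the file's magic bytes (`FCS3.0` /
#' `FCS3.1`) or treated as delimited text with a header row of channel
#' names (comma or tab separated, detected from the header).
#'
#' @param path File path.
#' @param channels Optional character vector restricting (and ordering)
#'   the channels.
#' @param transform `"none"` (default), `"asinh"` (with `cofactor`) or
#'   `"log10"` (with `floor`).
#' @param cofactor Cofactor of the asinh transform.
#' @param floor Lower clamp of the log10 transform.
#' @return An [event_table()].
#' @export
read_events <- function(path, channels = NULL,
                        transform = c("none", "asinh", "log10"),
                        cofactor = 150, floor = 1) {
  transform <- match.arg(transform)
  if (!file.exists(path)) stop("file not found: ", path)
  magic <- rawToChar(readBin(path, "raw", 6L))
  tab <- if (startsWith(magic, "FCS3")) read_fcs(path) else read_delim_events(path)
  if (!is.null(channels)) {
    missing <- setdiff(channels, tab$channel_names)
    if (length(missing))
      stop("channel(s) ", paste(missing, collapse = ", "),
           " not in file; available: ",
           paste(tab$channel_names, collapse = ", "))
    tab <- event_table(tab$values[, channels, drop = FALSE], channels)
  }
  if (transform != "none")
    tab <- event_table(apply_transform(tab$values, transform,
                                       cofactor, floor),
                       tab$channel_names)
  message("read ", n_events(tab), " events x ", n_channels(tab),
          " channels (", paste(tab$channel_names, collapse = ", "), ")")
  tab
}

read_delim_events <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  event_table(as.matrix(df), colnames(df))
}

#' Write an event table as delimited text
#'
#' Comma-separated with a header row of channel names and no index
#' column.
#'
#' @param data An [event_table()].
#' @param path Output path.
#' @export
write_events <- function(data, path) {
  stopifnot(inherits(data, "event_table"))
  utils::write.table(data$values, path, sep = ",", row.names = FALSE,
                     col.names = data$channel_names, quote = FALSE)
  invisible(path)
}

# ---- minimal FCS 3.0/3.1 support ----------------------------------------

fcs_delim <- "/"

#' Write an event table as a minimal FCS 3.0 file
#'
#' List-mode, single-precision float, little-endian; enough structure for
#' round-tripping fixtures through [read_events()] and for ingestion by
#' standard cytometry tools.
#'
#' @param data An [event_table()].
#' @param path Output path.
#' @export
write_fcs <- function(data, path) {
  stopifnot(inherits(data, "event_table"))
  x <- data$values
  n_par <- ncol(x)
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0",
          "$PAR", as.character(n_par), "$TOT", as.character(nrow(x)))
  for (p in seq_len(n_par)) {
    kw <- c(kw,
            paste0("$P", p, "N"), data$channel_names[p],
            paste0("$P", p, "B"), "32",
            paste0("$P", p, "E"), "0,0",
            paste0("$P", p, "R"), format(ceiling(max(abs(x[, p])) + 1),
                                         scientific = FALSE))
  }
  # placeholder offsets, fixed width so the header can be written first
  mk_text <- function(b_data, e_data) {
    paste0(fcs_delim,
           paste0("$BEGINDATA", fcs_delim, sprintf("%012d", b_data),
                  fcs_delim, "$ENDDATA", fcs_delim, sprintf("%012d", e_data),
                  fcs_delim),
           paste(kw, collapse = fcs_delim), fcs_delim)
  }
  text0 <- mk_text(0, 0)
  b_text <- 58L
  e_text <- b_text + nchar(text0, type = "bytes") - 1L
  b_data <- e_text + 1L
  e_data <- b_data + 4L * length(x) - 1L
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    b_text, e_text, b_data, e_data, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(mk_text(b_data, e_data), con, eos = NULL)
  writeBin(as.numeric(t(x)), con, size = 4L, endian = "little")
  invisible(path)
}

read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58L))
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version '", version, "' (offset 0)")
  off <- suppressWarnings(as.integer(substring(header,
                                               10 + 8 * (0:5) + 1,
                                               10 + 8 * (1:6))))
  b_text <- off[1]; e_text <- off[2]
  if (is.na(b_text) || is.na(e_text) || e_text <= b_text)
    stop("malformed FCS header: bad TEXT segment offsets (offset 10)")
  seek(con, b_text)
  text <- rawToChar(readBin(con, "raw", e_text - b_text + 1L))
  delim <- substr(text, 1L, 1L)
  parts <- strsplit(substring(text, 2L), delim, fixed = TRUE)[[1L]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1, length(parts), 2)]))
  vals <- trimws(parts[seq(2, length(parts), 2)])
  kw <- stats::setNames(vals, keys)
  need <- function(k) {
    if (!k %in% names(kw)) stop("malformed FCS TEXT segment: missing ", k)
    kw[[k]]
  }
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  dtype <- need("$DATATYPE")
  if (!dtype %in% c("F", "D"))
    stop("unsupported FCS $DATATYPE '", dtype, "' (only F and D)")
  byteord <- need("$BYTEORD")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  size <- if (dtype == "F") 4L else 8L
  b_data <- as.numeric(if ("$BEGINDATA" %in% names(kw)) kw[["$BEGINDATA"]]
                       else off[3])
  if (is.na(b_data) || b_data <= 0) b_data <- off[3]
  chans <- vapply(seq_len(n_par), function(p) {
    k <- paste0("$P", p, "N")
    if (k %in% names(kw)) kw[[k]] else paste0("P", p)
  }, "")
  seek(con, b_data)
  raw_vals <- readBin(con, "numeric", n = n_par * n_tot, size = size,
                      endian = endian)
  if (length(raw_vals) < n_par * n_tot)
    stop("malformed FCS DATA segment at offset ", b_data,
         ": expected ", n_par * n_tot, " values, got ", length(raw_vals))
  event_table(matrix(raw_vals, nrow = n_tot, ncol = n_par, byrow = TRUE),
              chans)
}
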