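# Minimal FCS 3.0/3.1 list-mode reader and writer. Scope: DATATYPE F/D/I,
# MODE L, byte order 1,2,3,4 or 4,3,2,1, single data set ($NEXTDATA 0).
# Inputs are assumed compensated; no spillover handling.

FCS_HEADER_LEN <- 58L

fcs_parse_text <- function(txt) {
  delim <- substr(txt, 1L, 1L)
  body <- substr(txt, 2L, nchar(txt))
  parts <- strsplit(body, delim, fixed = TRUE)[[1L]]
  # An empty part signals an escaped (doubled) delimiter inside a value:
  # fold it back into the previous token.
  tokens <- character(0)
  i <- 1L
  while (i <= length(parts)) {
    tok <- parts[i]
    while (i < length(parts) && parts[i + 1L] == "" && i + 2L <= length(parts)) {
      tok <- paste0(tok, delim, parts[i + 2L])
      i <- i + 2L
    }
    tokens <- c(tokens, tok)
    i <- i + 1L
  }
  if (length(tokens) %% 2L == 1L) tokens <- tokens[-length(tokens)]
  kw <- tokens[seq(2L, length(tokens), by = 2L)]
  names(kw) <- toupper(trimws(tokens[seq(1L, length(tokens), by = 2L)]))
  kw
}

fcs_keyword <- function(kw, name, required = TRUE) {
  v <- unname(kw[match(toupper(name), names(kw))])
  if (is.na(v)) {
    if (required) stop("FCS file lacks required keyword ", name, call. = FALSE)
    return(NULL)
  }
  v
}

# Resolve requested marker names to channel indices. Priority: exact $PnS,
# then exact $PnN, then case-insensitive over both; ambiguity is an error.
fcs_resolve_markers <- function(panel, pnn, pns) {
  resolve_one <- function(marker) {
    for (cand in list(which(pns == marker),
                      which(pnn == marker),
                      which(toupper(pns) == toupper(marker) |
                            toupper(pnn) == toupper(marker)))) {
      if (length(cand) == 1L) return(cand)
      if (length(cand) > 1L) {
        stop("marker '", marker, "' matches several channels: ",
             paste(pnn[cand], collapse = ", "), call. = FALSE)
      }
    }
    stop("marker '", marker, "' not found; available channels: ",
         paste(unique(c(pnn[nzchar(pnn)], pns[nzchar(pns)])), collapse = ", "),
         call. = FALSE)
  }
  vapply(panel, resolve_one, integer(1))
}

#' Read one sample's events from an FCS 3.0/3.1 file
#'
#' Reads list-mode data and returns the requested markers in panel order.
#' Marker names are resolved against the file's channel keywords, preferring
#' the stain name (`$PnS`) over the detector name (`$PnN`), with a
#' case-insensitive fallback; an ambiguous match is an error, never a guess.
#'
#' @param path Path to an FCS 3.0/3.1 file.
#' @param panel A [marker_panel()] naming the markers to extract.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return An [event_table()] with `transformed = FALSE` and exactly `$TOT`
#'   events.
#' @export
read_fcs <- function(path, panel, sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  panel <- marker_panel(panel)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < FCS_HEADER_LEN) stop("file too short to be FCS: ", path, call. = FALSE)
  header <- rawToChar(raw[1:FCS_HEADER_LEN])
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version '", version, "' in ", path, call. = FALSE)
  }
  off <- function(a, b) suppressWarnings(as.numeric(trimws(substr(header, a, b))))
  text_start <- off(11, 18); text_end <- off(19, 26)
  data_start <- off(27, 34); data_end <- off(35, 42)
  if (anyNA(c(text_start, text_end)) || text_end <= text_start ||
      text_end + 1 > length(raw)) {
    stop("corrupt FCS header segment offsets in ", path, call. = FALSE)
  }
  kw <- fcs_parse_text(rawToChar(raw[(text_start + 1):(text_end + 1)]))

  if (is.na(data_start) || is.na(data_end) || data_end == 0) {
    data_start <- as.numeric(fcs_keyword(kw, "$BEGINDATA"))
    data_end <- as.numeric(fcs_keyword(kw, "$ENDDATA"))
  }
  if (data_end + 1 > length(raw) || data_end <= data_start) {
    stop("corrupt FCS data segment offsets in ", path, call. = FALSE)
  }
  mode <- fcs_keyword(kw, "$MODE")
  if (toupper(mode) != "L") stop("only list-mode ($MODE L) FCS is supported", call. = FALSE)
  dtype <- toupper(fcs_keyword(kw, "$DATATYPE"))
  byteord <- fcs_keyword(kw, "$BYTEORD")
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little"
            else if (byteord %in% c("4,3,2,1", "2,1")) "big"
            else stop("unsupported $BYTEORD '", byteord, "'", call. = FALSE)
  n_par <- as.integer(fcs_keyword(kw, "$PAR"))
  n_tot <- as.integer(fcs_keyword(kw, "$TOT"))
  pnn <- vapply(seq_len(n_par), function(i)
    fcs_keyword(kw, sprintf("$P%dN", i)), character(1))
  pns <- vapply(seq_len(n_par), function(i) {
    v <- fcs_keyword(kw, sprintf("$P%dS", i), required = FALSE)
    if (is.null(v)) "" else v
  }, character(1))
  pnb <- vapply(seq_len(n_par), function(i)
    as.integer(fcs_keyword(kw, sprintf("$P%dB", i))), integer(1))

  data_raw <- raw[(data_start + 1):(data_end + 1)]
  values <- switch(dtype,
    "F" = {
      if (any(pnb != 32L)) stop("$DATATYPE F requires $PnB 32", call. = FALSE)
      readBin(data_raw, "numeric", n = n_par * n_tot, size = 4L, endian = endian)
    },
    "D" = {
      if (any(pnb != 64L)) stop("$DATATYPE D requires $PnB 64", call. = FALSE)
      readBin(data_raw, "numeric", n = n_par * n_tot, size = 8L, endian = endian)
    },
    "I" = {
      if (length(unique(pnb)) != 1L || !pnb[1L] %in% c(16L, 32L)) {
        stop("$DATATYPE I supported for uniform $PnB 16 or 32 only", call. = FALSE)
      }
      readBin(data_raw, "integer", n = n_par * n_tot, size = pnb[1L] / 8L,
              signed = pnb[1L] == 32L, endian = endian)
    },
    stop("unsupported $DATATYPE '", dtype, "'", call. = FALSE)
  )
  if (length(values) != n_par * n_tot) {
    stop("FCS data segment shorter than $TOT x $PAR in ", path, call. = FALSE)
  }
  mat <- matrix(as.numeric(values), nrow = n_tot, ncol = n_par, byrow = TRUE)
  idx <- fcs_resolve_markers(unclass(panel), pnn, pns)
  mat <- mat[, idx, drop = FALSE]
  colnames(mat) <- unclass(panel)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  event_table(mat, sample_id = sample_id, transformed = FALSE)
}

#' Write an event table as an FCS 3.1 file
#'
#' Emits single-precision (`$DATATYPE F`) list-mode data, little-endian, with
#' marker names stored in both `$PnN` and `$PnS`. Intended for fixtures and
#' for exporting simulations; values round-trip through [read_fcs()] at
#' float32 precision.
#'
#' @param table An [event_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  mat <- table$intensities
  n <- nrow(mat); p <- ncol(mat)
  delim <- "/"
  if (any(grepl(delim, colnames(mat), fixed = TRUE))) {
    stop("marker names may not contain the keyword delimiter '/'", call. = FALSE)
  }
  rng <- vapply(seq_len(p), function(j)
    format(ceiling(max(1, max(mat[, j]))), scientific = FALSE), character(1))
  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$BEGINDATA" = "0000000000", "$ENDDATA" = "0000000000",
          "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0",
          "$PAR" = as.character(p), "$TOT" = as.character(n))
  for (j in seq_len(p)) {
    kw[[sprintf("$P%dB", j)]] <- "32"
    kw[[sprintf("$P%dE", j)]] <- "0,0"
    kw[[sprintf("$P%dR", j)]] <- rng[j]
    kw[[sprintf("$P%dN", j)]] <- colnames(mat)[j]
    kw[[sprintf("$P%dS", j)]] <- colnames(mat)[j]
  }
  build_text <- function(kw) {
    paste0(delim, paste0(names(kw), delim, unname(kw), delim, collapse = ""))
  }
  text <- build_text(kw)
  text_start <- FCS_HEADER_LEN
  text_end <- text_start + nchar(text) - 1L
  data_start <- text_start + nchar(text)
  data_end <- data_start + 4L * n * p - 1L
  if (data_end > 99999999) {
    stop("event table too large for a single-segment FCS write", call. = FALSE)
  }
  kw[["$BEGINDATA"]] <- sprintf("%010d", data_start)
  kw[["$ENDDATA"]] <- sprintf("%010d", data_end)
  text <- build_text(kw)  # same length: widths fixed

  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end, data_start, data_end, 0L, 0L)
  stopifnot(nchar(header) == FCS_HEADER_LEN)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}
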