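#' Write an event table as an FCS 3.1 file
#'
#' Standard-conformant single-dataset FCS 3.1: list-mode float32
#' little-endian data, `$PnN` set to the panel channel identifier and
#' `$PnS` to the marker name.  Ground-truth labels are never emitted into
#' FCS channels; when present they are written to a `<path>.truth.csv`
#' sidecar table.
#'
#' @param events A non-empty `ctc_events` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_fcs <- function(events, path) {
  stopifnot(inherits(events, "ctc_events"))
  x <- events$exprs
  if (nrow(x) == 0) stop("refusing to write an empty event table")
  pan <- events$panel
  chan_id <- function(mk) {
    hit <- match(mk, pan$marker)
    if (is.na(hit)) mk else pan$channel[hit]
  }
  pnn <- vapply(colnames(x), chan_id, "")
  pns <- colnames(x)
  n_par <- ncol(x); n_tot <- nrow(x)

  delim <- "/"
  kw <- c(
    "$FCSversion" = "3.1", "$MODE" = "L", "$DATATYPE" = "F",
    "$BYTEORD" = "1,2,3,4", "$NEXTDATA" = "0",
    "$TOT" = as.character(n_tot), "$PAR" = as.character(n_par),
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$CYT" = "synthetic", "$FIL" = basename(path),
    "$SRC" = as.character(events$sample_id)
  )
  for (i in seq_len(n_par)) {
    kw[paste0("$P", i, "N")] <- pnn[i]
    kw[paste0("$P", i, "S")] <- pns[i]
    kw[paste0("$P", i, "B")] <- "32"
    kw[paste0("$P", i, "E")] <- "0,0"
    kw[paste0("$P", i, "R")] <- as.character(max(1, ceiling(max(x[, i]))))
  }
  data_bytes <- 4L * n_par * n_tot
  # fixed-width offsets so the TEXT segment length is independent of the
  # values it contains
  fmt_off <- function(v) formatC(v, width = 10, flag = "0", format = "d")
  build_text <- function(bd, ed) {
    kw2 <- c(kw, "$BEGINDATA" = fmt_off(bd), "$ENDDATA" = fmt_off(ed))
    paste0(delim, paste0(names(kw2), delim, unname(kw2), delim,
                         collapse = ""))
  }
  probe <- build_text(0, 0)
  text_start <- 256L
  data_start <- text_start + nchar(probe, type = "bytes")
  text <- build_text(data_start, data_start + data_bytes - 1L)
  stopifnot(nchar(text, type = "bytes") == nchar(probe, type = "bytes"))

  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_start, data_start - 1L,
                    data_start, data_start + data_bytes - 1L, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(strrep(" ", text_start - nchar(header, type = "bytes")), con,
            eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(x)), con, size = 4, endian = "little")

  if (!is.null(events$truth)) {
    utils::write.csv(data.frame(event = seq_len(n_tot), truth = events$truth),
                     paste0(path, ".truth.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read an FCS file into an event table
#'
#' Parses FCS 3.0/3.1 single-dataset files (list mode, float or double
#' data).  Channels whose `$PnN` matches a panel channel identifier are
#' renamed to the panel marker; unknown channels are retained under
#' their `$PnS` (or `$PnN`) name and left untransformed.  A
#' `<path>.truth.csv` sidecar written by [write_fcs()] is reattached when
#' present.
#'
#' @param path FCS file.
#' @param panel Panel used to map channels (default [hn_panel()]).
#' @return A `ctc_events` object with raw intensities.
#' @export
read_fcs <- function(path, panel = hn_panel()) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  if (!grepl("^FCS3\\.[01]", header))
    stop("malformed FCS header (expected FCS 3.x): ", substr(header, 1, 6))
  offs <- suppressWarnings(as.integer(substring(
    header, seq(11, 51, 8), seq(18, 58, 8))))
  if (any(is.na(offs[1:4]))) stop("malformed FCS header offsets")
  text_start <- offs[1]; text_end <- offs[2]
  seek(con, text_start)
  text <- readChar(con, text_end - text_start + 1L, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), 2)]
  vals <- parts[seq(2, length(parts), 2)]
  names(vals) <- toupper(trimws(keys))
  need <- c("$TOT", "$PAR", "$DATATYPE", "$BYTEORD")
  if (any(!need %in% names(vals)))
    stop("missing mandatory FCS keyword(s): ",
         paste(setdiff(need, names(vals)), collapse = ", "))

  n_tot <- as.integer(vals["$TOT"])
  n_par <- as.integer(vals["$PAR"])
  dtype <- vals["$DATATYPE"]
  if (!dtype %in% c("F", "D"))
    stop("unsupported $DATATYPE: ", dtype)
  endian <- if (startsWith(vals["$BYTEORD"], "1")) "little" else "big"
  data_start <- as.integer(vals["$BEGINDATA"])
  if (is.na(data_start) || data_start == 0) data_start <- offs[3]
  size <- if (dtype == "F") 4L else 8L
  seek(con, data_start)
  raw <- readBin(con, "numeric", n = n_tot * n_par, size = size,
                 endian = endian)
  x <- matrix(raw, nrow = n_tot, ncol = n_par, byrow = TRUE)

  pnn <- vals[paste0("$P", seq_len(n_par), "N")]
  pns <- vals[paste0("$P", seq_len(n_par), "S")]
  nm <- character(n_par)
  for (i in seq_len(n_par)) {
    hit <- match(pnn[i], panel$channel)
    nm[i] <- if (!is.na(hit)) panel$marker[hit]
    else if (!is.na(pns[i]) && nzchar(pns[i])) pns[i] else pnn[i]
  }
  colnames(x) <- nm
  truth_path <- paste0(path, ".truth.csv")
  truth <- if (file.exists(truth_path))
    utils::read.csv(truth_path, stringsAsFactors = FALSE)$truth
  new_events(x, panel,
             sample_id = if ("$SRC" %in% names(vals)) vals[["$SRC"]]
             else basename(path),
             truth = truth)
}
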