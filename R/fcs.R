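# Minimal FCS 3.1 list-mode support: single data set, float32 values,
# little-endian. Enough to interoperate on the four channels this assay
# uses; spillover matrices, log-amplified integer data and multi-segment
# files are out of scope.

FCS_DELIM <- "/"

write_fcs_text <- function(kw) {
  paste0(FCS_DELIM,
         paste0(names(kw), FCS_DELIM, unname(kw), collapse = FCS_DELIM),
         FCS_DELIM)
}

#' Write an event table as an FCS 3.1 file
#'
#' Emits a single-dataset list-mode file with 32-bit float values,
#' little-endian byte order, and `$PnN` short names taken from the column
#' names with an `-A` (area) suffix appended, matching common cytometer
#' exports (`FSC-A`, `SSC-A`, `FITC-A`, `PI-A`).
#'
#' @param events Data frame of per-event values, numeric columns only
#'   (metadata columns `patient_id`, `dose_gy`, `time_h` are dropped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path) {
  mat <- as.matrix(dplyr::select(
    as.data.frame(events),
    -dplyr::any_of(c("patient_id", "dose_gy", "time_h"))
  ))
  if (!is.numeric(mat) || nrow(mat) == 0L) {
    abort("`events` must contain at least one row of numeric channel values.")
  }
  npar <- ncol(mat)
  tot <- nrow(mat)
  pnames <- paste0(colnames(mat), "-A")
  kw <- c("$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0", "$PAR" = as.character(npar),
          "$TOT" = as.character(tot))
  for (i in seq_len(npar)) {
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- format(2^ceiling(log2(max(mat[, i], 1) + 1)),
                                      scientific = FALSE)
    kw[sprintf("$P%dN", i)] <- pnames[i]
  }
  n_data <- 4L * npar * tot
  # Offsets depend on the text length, which depends on the offsets; the
  # placeholder widths below are fixed so one pass resolves them.
  header_len <- 58L
  fmt <- function(x) formatC(x, width = 8, flag = " ")
  build <- function(b0, e0, bd, ed) {
    kw2 <- c(kw, "$BEGINDATA" = as.character(bd),
             "$ENDDATA" = as.character(ed))
    write_fcs_text(kw2)
  }
  # iterate to a fixed point on segment offsets (converges immediately for
  # these sizes)
  text_begin <- header_len
  txt <- build(0, 0, 0, 0)
  for (i in 1:3) {
    text_end <- text_begin + nchar(txt, type = "bytes") - 1L
    data_begin <- text_end + 1L
    data_end <- data_begin + n_data - 1L
    txt <- build(text_begin, text_end, data_begin, data_end)
  }
  header <- paste0("FCS3.1    ", fmt(text_begin), fmt(text_end),
                   fmt(data_begin), fmt(data_end), fmt(0), fmt(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.vector(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}

read_fcs_keywords <- function(raw, begin, end) {
  txt <- rawToChar(raw[(begin + 1):(end + 1)])
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  setNames(parts[seq(2, length(parts), 2)], parts[seq(1, length(parts), 2)])
}

#' Read a list-mode FCS file
#'
#' Supports FCS 3.0/3.1 single-dataset files with `$DATATYPE F` (float) or
#' `D` (double) and `$MODE L`. Channel columns are named from `$PnN` with a
#' trailing `-A`/`-H`/`-W` suffix stripped, so files written by [write_fcs()]
#' round-trip to the CSV dialect's `FSC,SSC,FITC,PI` names.
#'
#' @param path Path to the FCS file.
#' @return Tibble of per-event values in file order.
#' @export
read_fcs <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  magic <- rawToChar(raw[1:6])
  if (!grepl("^FCS3", magic)) {
    abort(sprintf("not an FCS 3.x file: %s", path))
  }
  off <- function(i) {
    as.integer(trimws(rawToChar(raw[(11 + 8 * (i - 1)):(10 + 8 * i)])))
  }
  kw <- read_fcs_keywords(raw, off(1), off(2))
  data_begin <- off(3); data_end <- off(4)
  if (is.na(data_begin) || data_begin == 0L) {
    data_begin <- as.integer(kw[["$BEGINDATA"]])
    data_end <- as.integer(kw[["$ENDDATA"]])
  }
  if (!identical(kw[["$MODE"]], "L")) abort("only list-mode ($MODE L) supported")
  type <- kw[["$DATATYPE"]]
  if (!type %in% c("F", "D")) {
    abort(sprintf("unsupported $DATATYPE %s (only F/D)", type))
  }
  size <- if (type == "F") 4L else 8L
  endian <- if (grepl("^1", kw[["$BYTEORD"]])) "little" else "big"
  npar <- as.integer(kw[["$PAR"]])
  tot <- as.integer(kw[["$TOT"]])
  if (is.na(npar) || is.na(tot) || tot < 1L) abort("zero events or bad $TOT")
  vals <- readBin(raw[(data_begin + 1):(data_end + 1)], "numeric",
                  n = npar * tot, size = size, endian = endian)
  mat <- matrix(vals, nrow = tot, ncol = npar, byrow = TRUE)
  nms <- vapply(seq_len(npar),
                function(i) kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i),
                character(1))
  colnames(mat) <- sub("-[AHW]$", "", nms)
  tibble::as_tibble(mat)
}
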