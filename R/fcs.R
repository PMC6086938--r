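# Minimal FCS 3.0 writer: HEADER + TEXT segment + little-endian float32 DATA,
# one event per row, one parameter per column. Covers the keywords standard
# cytometry parsers require ($PnN/$PnB/$PnE/$PnR, $DATATYPE F, $BYTEORD,
# $BEGINDATA/$ENDDATA, $TOT, $PAR, $MODE L).
write_fcs <- function(mat, path) {
  stopifnot(is.matrix(mat))
  if (!is.numeric(mat)) storage.mode(mat) <- "double"
  n_par <- ncol(mat)
  n_evt <- nrow(mat)
  delim <- "/"
  kw <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", as.character(n_par), "$TOT", as.character(n_evt),
          "$NEXTDATA", "0")
  rng <- if (n_evt > 0) pmax(1, ceiling(apply(mat, 2, max))) else
    rep(1, n_par)
  for (p in seq_len(n_par)) {
    kw <- c(kw,
            sprintf("$P%dN", p), colnames(mat)[p] %||% sprintf("P%d", p),
            sprintf("$P%dB", p), "32",
            sprintf("$P%dE", p), "0,0",
            sprintf("$P%dR", p), as.character(rng[p]))
  }
  # TEXT segment length depends on the data offsets it quotes; iterate until
  # the offsets are self-consistent.
  data_len <- 4L * n_par * n_evt
  begin_text <- 58L
  begin_data <- 0L; end_data <- 0L
  for (iter in 1:5) {
    kv <- c(rbind(kw[seq(1, length(kw), 2)], kw[seq(2, length(kw), 2)]))
    text <- paste0(delim,
                   paste0("$BEGINDATA", delim, begin_data, delim,
                          "$ENDDATA", delim, end_data, delim),
                   paste(kv, collapse = delim), delim)
    end_text <- begin_text + nchar(text, type = "bytes") - 1L
    new_begin_data <- end_text + 1L
    new_end_data <- if (data_len > 0) new_begin_data + data_len - 1L else 0L
    if (new_begin_data == begin_data && new_end_data == end_data) break
    begin_data <- new_begin_data; end_data <- new_end_data
  }
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    begin_text, end_text,
                    if (end_data <= 99999999) begin_data else 0L,
                    if (end_data <= 99999999) end_data else 0L,
                    0L, 0L)
  stopifnot(nchar(header, type = "bytes") == 58L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (n_evt > 0)
    writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}

# Companion reader used for round-trip validation of exports.
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (substr(header, 1, 6) != "FCS3.0") stop("not an FCS 3.0 file")
  begin_text <- as.integer(substr(header, 11, 18))
  end_text <- as.integer(substr(header, 19, 26))
  seek(con, begin_text)
  text <- readChar(con, end_text - begin_text + 1L, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  keys <- parts[seq(1, length(parts), 2)]
  vals <- parts[seq(2, length(parts), 2)]
  kw <- setNames(vals, keys)
  n_par <- as.integer(kw[["$PAR"]])
  n_evt <- as.integer(kw[["$TOT"]])
  begin_data <- as.integer(kw[["$BEGINDATA"]])
  seek(con, begin_data)
  raw <- readBin(con, "numeric", n = n_par * n_evt, size = 4L,
                 endian = "little")
  mat <- matrix(raw, nrow = n_evt, ncol = n_par, byrow = TRUE)
  colnames(mat) <- vapply(seq_len(n_par),
                          function(p) kw[[sprintf("$P%dN", p)]], character(1))
  list(data = mat, keywords = kw)
}
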