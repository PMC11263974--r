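# Minimal STAR (metadata table) writer/parser: a single data block with
# one loop, which is all a particle stack needs. Numeric formatting uses
# %.12g so files are deterministic.

#' Write a one-block STAR file
#'
#' @param df data.frame; column names become STAR tags (they should carry
#'   the `_rln` / `_cs` prefix already).
#' @param path output path.
#' @param block_name data block name (without the `data_` prefix).
#' @return `path`, invisibly.
#' @export
write_star <- function(df, path, block_name = "particles") {
  fmt <- function(col) {
    if (is.numeric(col)) sprintf("%.12g", col) else as.character(col)
  }
  cols <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cols <- matrix(cols, nrow = 1)
  lines <- c(
    paste0("data_", block_name),
    "",
    "loop_",
    paste0(names(df), " #", seq_along(df)),
    apply(cols, 1, paste, collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-block STAR file
#'
#' Parses the first `loop_` of the first data block; numeric-looking
#' columns are converted to numeric.
#'
#' @param path STAR file path.
#' @return data.frame with the loop's columns.
#' @export
read_star <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  loop_at <- which(lines == "loop_")[1]
  if (is.na(loop_at)) stop("no loop_ block in STAR file ", path)
  i <- loop_at + 1
  tags <- character(0)
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    tags <- c(tags, sub("\\s+#\\d+$", "", lines[i]))
    i <- i + 1
  }
  rows <- lines[seq.int(i, length(lines))]
  rows <- rows[nzchar(rows) & !startsWith(rows, "data_")]
  parts <- strsplit(rows, "\\s+")
  bad <- which(lengths(parts) != length(tags))
  if (length(bad) > 0) {
    stop(
      "STAR row ", bad[1], " has ", lengths(parts)[bad[1]],
      " fields, expected ", length(tags)
    )
  }
  mat <- do.call(rbind, parts)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- tags
  for (j in seq_along(df)) {
    num <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(num)) df[[j]] <- num
  }
  df
}
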