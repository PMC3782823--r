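#' Read an 8-bit grayscale image
#'
#' Reads PGM (P2 ASCII or P5 binary) directly, and PNG through the \pkg{png}
#' package. Colour PNGs are converted to grayscale by channel averaging.
#' Images are returned as integer matrices with origin at the top-left,
#' indexed `[row, col]`.
#'
#' @param path Path to a `.pgm` or `.png` file.
#' @return Integer matrix with values in 0..255.
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- apply(a[, , 1:3, drop = FALSE], c(1, 2), mean)
    return(matrix(as.integer(round(a * 255)), nrow(a), ncol(a)))
  }
  stop("unsupported image format: .", ext)
}

#' Write an 8-bit grayscale image
#'
#' @param image Numeric matrix, values 0..255.
#' @param path Output path ending in `.pgm` or `.png`.
#' @param ascii For PGM, write P2 (ASCII) instead of P5 (binary).
#' @return `path`, invisibly.
#' @export
write_gray <- function(image, path, ascii = FALSE) {
  check_gray(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(write_pgm(image, path, ascii = ascii))
  if (ext == "png") {
    png::writePNG(image / 255, path)
    return(invisible(path))
  }
  stop("unsupported image format: .", ext)
}

# PGM is a trivial textual header plus raster; no installed package reads it,
# so the package carries its own minimal P2/P5 codec.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- pgm_tokens(con, 4)
  magic <- tok[1]
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); maxval <- as.integer(tok[4])
  if (is.na(w) || is.na(h) || w < 1 || h < 1) stop("bad PGM dimensions")
  if (is.na(maxval) || maxval < 1 || maxval > 255)
    stop("only 8-bit PGM supported (maxval <= 255)")
  n <- w * h
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n))
  } else {
    vals <- integer(0)
    while (length(vals) < n) {
      chunk <- readLines(con, n = 1)
      if (length(chunk) == 0) break
      chunk <- sub("#.*", "", chunk)
      vals <- c(vals, as.integer(strsplit(trimws(chunk), "[[:space:]]+")[[1]]))
    }
    vals <- vals[!is.na(vals)]
    if (length(vals) < n) stop("truncated PGM raster")
    vals <- vals[seq_len(n)]
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(image, path, ascii = FALSE, maxval = 255L) {
  vals <- as.integer(round(image))
  if (any(vals < 0 | vals > maxval)) stop("pixel values outside [0, maxval]")
  h <- nrow(image); w <- ncol(image)
  con <- file(path, "wb")
  on.exit(close(con))
  if (ascii) {
    writeLines(c("P2", paste(w, h), as.character(maxval)), con)
    rows <- apply(matrix(vals, h, w), 1, paste, collapse = " ")
    writeLines(rows, con)
  } else {
    writeLines(c("P5", paste(w, h), as.character(maxval)), con)
    writeBin(as.raw(t(matrix(vals, h, w))), con)
  }
  invisible(path)
}

# skip comments/whitespace and pull n header tokens from a PGM stream
pgm_tokens <- function(con, n) {
  tok <- character(0)
  cur <- ""
  while (length(tok) < n) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0) stop("unexpected end of PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(cur)) { tok <- c(tok, cur); cur <- "" }
    } else cur <- paste0(cur, ch)
  }
  tok
}

#' Write a label map as PGM plus a JSON legend
#'
#' The raster holds raw integer label ids; the legend file (`<stem>.json`)
#' maps each id to its region name so the raster is self-describing.
#'
#' @param labels Integer matrix of label ids.
#' @param path Output PGM path; the legend goes to the same stem with
#'   extension `.json`.
#' @return Named list with elements `pgm` and `legend` (the two paths).
#' @export
write_labelmap <- function(labels, path) {
  ids <- sort(unique(as.integer(labels)))
  legend <- as.list(stats::setNames(label_name(ids), as.character(ids)))
  write_pgm(labels, path)
  legend_path <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(legend, legend_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(pgm = path, legend = legend_path))
}

#' Read a label map written by [write_labelmap()]
#'
#' @param path Path to the label PGM; the legend is looked up at the same
#'   stem with extension `.json` (its ids are validated against the scheme).
#' @return Integer matrix of label ids.
#' @export
read_labelmap <- function(path) {
  labels <- read_pgm(path)
  legend_path <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(legend_path)) {
    legend <- jsonlite::read_json(legend_path)
    declared <- label_id(unlist(legend))
    stated <- as.integer(names(legend))
    if (!identical(stated, declared))
      stop("legend ids disagree with the region scheme")
    extra <- setdiff(unique(as.integer(labels)), stated)
    if (length(extra) > 0)
      stop("label map contains ids missing from legend: ",
           paste(extra, collapse = ", "))
  }
  labels
}

#' Write a label map as a colour PNG
#'
#' Uses the fixed palette of [label_palette()], mirroring the usual
#' colour-coded presentation of multi-label segmentations.
#'
#' @param labels Integer matrix of label ids.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_png <- function(labels, path) {
  pal <- label_palette()
  cols <- grDevices::col2rgb(pal[label_name(as.integer(labels))]) / 255
  h <- nrow(labels); w <- ncol(labels)
  arr <- array(0, c(h, w, 3))
  arr[, , 1] <- matrix(cols[1, ], h, w)
  arr[, , 2] <- matrix(cols[2, ], h, w)
  arr[, , 3] <- matrix(cols[3, ], h, w)
  png::writePNG(arr, path)
  invisible(path)
}

#' Read a seed file
#'
#' Seeds are hard constraints for the graph cut: pixel coordinates with an
#' assigned region label. On disk coordinates are 0-based (row, col) as is
#' conventional for image tooling; in R they are converted to 1-based matrix
#' indices.
#'
#' Accepted formats: CSV with header `row,col,label`, or a JSON array of
#' objects with those fields. Labels are region names.
#'
#' @param path Path to a `.csv` or `.json` seed file.
#' @return Data frame with integer columns `row`, `col` (1-based) and
#'   character column `label`.
#' @export
read_seeds <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (ext == "json") {
    df <- as.data.frame(do.call(rbind, lapply(jsonlite::read_json(path),
                                              as.data.frame)))
  } else stop("unsupported seed format: .", ext)
  if (!all(c("row", "col", "label") %in% names(df)))
    stop("seed file must have columns row, col, label")
  out <- data.frame(row = as.integer(df$row) + 1L,
                    col = as.integer(df$col) + 1L,
                    label = as.character(df$label),
                    stringsAsFactors = FALSE)
  label_id(out$label)  # validates names
  out
}

#' Write a seed set as CSV (0-based coordinates)
#'
#' @param seeds Data frame with 1-based `row`, `col` and `label` columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_seeds <- function(seeds, path) {
  utils::write.csv(data.frame(row = seeds$row - 1L, col = seeds$col - 1L,
                              label = seeds$label),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: validate a seed data frame against image dims and the scheme;
# returns seeds with an `id` column attached
check_seeds <- function(seeds, dims) {
  if (!is.data.frame(seeds) || !all(c("row", "col", "label") %in% names(seeds)))
    stop("seeds must be a data frame with columns row, col, label")
  if (nrow(seeds) == 0) stop("seed set is empty")
  if (any(seeds$row < 1 | seeds$row > dims[1] |
          seeds$col < 1 | seeds$col > dims[2]))
    stop("seed coordinates out of image bounds")
  seeds$id <- label_id(seeds$label)
  key <- paste(seeds$row, seeds$col)
  conflict <- tapply(seeds$id, key, function(v) length(unique(v)) > 1)
  if (any(conflict))
    stop("conflicting seed labels at pixel(s): ",
         paste(names(conflict)[conflict], collapse = "; "))
  seeds[!duplicated(key), , drop = FALSE]
}
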