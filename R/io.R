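#' Read a long-format Ct table
#'
#' Reads the comma-delimited Ct dialect (header mandatory; columns
#' `gene,role,genotype,hormone,animal,rep,ct`) and validates it:
#' unknown factor levels, non-numeric or non-finite Ct values (e.g.
#' `"Undetermined"` non-detects) and duplicate
#' `(gene, role, animal, rep)` keys are rejected with the offending row
#' numbers. No imputation of non-detects is attempted.
#'
#' @param path CSV file path.
#' @return Validated `data.frame` of Ct observations.
#' @seealso [write_ct_table()], [generate_ct_dataset()]
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("gene", "role", "genotype", "hormone", "animal", "rep", "ct")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ct_num <- suppressWarnings(as.numeric(df$ct))
  bad <- which(!is.finite(ct_num))
  if (length(bad)) {
    stop("non-numeric or non-finite ct at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " of ", path, " (e.g. '", df$ct[bad[1]],
         "'); non-detects are not supported", call. = FALSE)
  }
  df$ct <- ct_num
  key <- paste(df$gene, df$role, df$animal, df$rep)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (gene, role, animal, rep) key at row(s) ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  validate_ct_data(df)
  df
}

#' Write a Ct table in the package's CSV dialect
#'
#' @param data Ct observations ([generate_ct_dataset()] shape).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ct_table <- function(data, path) {
  validate_ct_data(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an expression matrix with its sample sheet
#'
#' The matrix is tab-delimited with probes as rows and samples as
#' columns; the sample sheet is a two-column `sample,group` CSV.
#'
#' @param path TSV matrix path.
#' @return Numeric matrix with dimnames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' @rdname read_expression_matrix
#' @param m Matrix to write.
#' @export
write_expression_matrix <- function(m, path) {
  utils::write.table(data.frame(probe = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_expression_matrix
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df))) {
    stop("sample sheet needs columns sample and group", call. = FALSE)
  }
  df
}

#' Read / write 8-bit RGB images
#'
#' Thin wrappers over [EBImage::readImage()]/[EBImage::writeImage()]
#' converting between files (TIFF/PNG) and the `height x width x 3`
#' integer arrays (0..255) used throughout the densitometry module.
#'
#' @param path Image file path (`.png` or `.tif`/`.tiff`).
#' @return `height x width x 3` integer array in 0..255.
#' @export
read_rgb_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) < 3 || d[3] < 3) {
    stop("not an RGB image: ", path, call. = FALSE)
  }
  # EBImage stores x (width) first; transpose to row = y
  arr <- array(0L, c(d[2], d[1], 3))
  dat <- EBImage::imageData(img)
  for (k in 1:3) arr[, , k] <- as.integer(round(t(dat[, , k]) * 255))
  arr
}

#' @rdname read_rgb_image
#' @param img `height x width x 3` array, 0..255.
#' @export
write_rgb_image <- function(img, path) {
  d <- dim(img)
  dat <- array(0, c(d[2], d[1], 3))
  for (k in 1:3) dat[, , k] <- t(img[, , k]) / 255
  EBImage::writeImage(EBImage::Image(dat, colormode = "Color"), path)
  invisible(path)
}
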