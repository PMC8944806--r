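## Reading and writing force-distance curves and reports.

#' Write a force-distance curve to disk
#'
#' Delimited text with header columns `separation_nm`, `force_pN`, `cycle`,
#' `direction` (CSV or TSV), or a binary Feather table via the arrow
#' package.
#'
#' @param fdc An `fdc` tibble.
#' @param path Output file.
#' @param format `"csv"`, `"tsv"` or `"arrow"`.
#' @return `path`, invisibly.
#' @export
write_fdc <- function(fdc, path, format = c("csv", "tsv", "arrow")) {
  format <- match.arg(format)
  cols <- c("separation_nm", "force_pN", "cycle", "direction")
  out <- as_tibble(fdc)[, intersect(cols, names(fdc))]
  switch(format,
    csv = readr::write_csv(out, path),
    tsv = readr::write_tsv(out, path),
    arrow = {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        abort("The arrow package is required for format = 'arrow'.")
      }
      arrow::write_feather(out, path)
    })
  invisible(path)
}

#' Read a force-distance curve
#'
#' @param path File written by [write_fdc()] (format inferred from the
#'   extension: `.csv`, `.tsv`, `.feather`/`.arrow`).
#' @return An `fdc` tibble.
#' @export
read_fdc <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    csv = readr::read_csv(path, show_col_types = FALSE),
    tsv = readr::read_tsv(path, show_col_types = FALSE),
    feather = ,
    arrow = {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        abort("The arrow package is required to read Feather files.")
      }
      arrow::read_feather(path)
    },
    abort(sprintf("Unknown FDC file extension '%s'.", ext)))
  as_fdc(x)
}
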