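#' Read and write the package's CSV tables
#'
#' Plain-CSV readers for the two input schemas (perimeter records and
#' species trait tables) with column validation, and a writer for any of the
#' package's tabular outputs.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_perimeter_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("species", "individual", "eye", "elevation", "margin_azimuth",
            "apparatus_radius", "eye_separation")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("perimeter CSV is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  df
}

#' @rdname read_perimeter_csv
#' @export
read_trait_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!"species" %in% names(df)) abort("trait CSV needs a `species` column.")
  prepare_traits(df)
}

#' @rdname read_perimeter_csv
#' @param x A data frame to write.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write outlines as blank-line-separated coordinate blocks
#'
#' Each species block starts with a `# name` comment line followed by
#' `x,y` rows; blocks are separated by blank lines.
#'
#' @param outlines Named list of outline tibbles.
#' @param path Output file.
#' @export
write_outlines <- function(outlines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(outlines)) {
    writeLines(paste0("# ", nm), con)
    o <- outlines[[nm]]
    writeLines(sprintf("%.10g,%.10g", o$x, o$y), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_outlines
#' @return `read_outlines()` returns a named list of outline tibbles.
#' @export
read_outlines <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL
  name <- NULL
  flush_block <- function(out, name, cur) {
    if (is.null(name) || !length(cur)) return(out)
    parts <- do.call(rbind, strsplit(cur, ","))
    out[[name]] <- tibble::tibble(x = as.numeric(parts[, 1]),
                                  y = as.numeric(parts[, 2]))
    out
  }
  for (ln in lines) {
    if (grepl("^#", ln)) {
      out <- flush_block(out, name, cur)
      name <- trimws(sub("^#", "", ln))
      cur <- character(0)
    } else if (nzchar(trimws(ln))) {
      cur <- c(cur, trimws(ln))
    }
  }
  flush_block(out, name, cur)
}
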