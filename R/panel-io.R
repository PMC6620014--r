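## Delimited-text readers and writers for subject-level panel tables,
## with validation and a key-value metadata sidecar.

#' Read a subject-level panel table
#'
#' Reads a comma-separated panel file (header row, '.' decimal, UTF-8)
#' with validation: an empty table, a missing or non-unique header,
#' ragged rows, and non-numeric cells in numeric columns are all
#' explicit errors naming the offending row and column.  When age,
#' period and cohort columns are all present, the identity
#' cohort = period - age is checked per record and violations raise a
#' warning listing the offending rows.
#'
#' @param path file path.
#' @param schema optional named character vector of column types
#'   (`"numeric"`, `"integer"`, `"character"`, `"factor"`) overriding
#'   type inference.
#' @return a data.frame.
#' @export
read_panel <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(nf) == 0) stop("empty file: ", path, call. = FALSE)
  if (length(unique(nf)) != 1)
    stop("ragged rows in ", path, ": row(s) ",
         paste(utils::head(which(nf != nf[1]), 5), collapse = ", "),
         " have ", paste(unique(nf[nf != nf[1]]), collapse = "/"),
         " fields, expected ", nf[1], call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) == 0)
    stop("table in ", path, " has a header but no data rows",
         call. = FALSE)
  hdr <- names(raw)
  if (any(hdr == "") || anyDuplicated(hdr) ||
      all(!is.na(suppressWarnings(as.numeric(hdr)))))
    stop("missing or invalid header row in ", path, call. = FALSE)

  out <- raw
  for (col in hdr) {
    type <- if (!is.null(schema) && col %in% names(schema))
      schema[[col]]
    else {
      conv <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- is.na(conv) & raw[[col]] != "NA"
      if (any(bad) && !all(bad)) {
        ## mixed column: mostly numeric with stray non-numeric cells
        w <- which(bad)
        stop("non-numeric value in numeric column '", col,
             "', row(s) ", paste(utils::head(w, 5), collapse = ", "),
             " (e.g. \"", raw[[col]][w[1]], "\")", call. = FALSE)
      }
      if (any(bad)) "character" else "numeric"
    }
    if (type %in% c("numeric", "integer")) {
      conv <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(is.na(conv) & raw[[col]] != "NA")
      if (length(bad))
        stop("non-numeric value in numeric column '", col,
             "', row(s) ", paste(utils::head(bad, 5), collapse = ", "),
             " (e.g. \"", raw[[col]][bad[1]], "\")", call. = FALSE)
      out[[col]] <- if (type == "integer") as.integer(conv) else conv
    } else if (type == "factor") {
      out[[col]] <- factor(raw[[col]])
    }
  }
  if (all(c("age", "period", "cohort") %in% hdr) &&
      all(vapply(out[c("age", "period", "cohort")], is.numeric,
                 logical(1)))) {
    off <- which(abs(out$cohort - (out$period - out$age)) > 1e-8)
    if (length(off))
      warning("cohort != period - age in ", length(off), " row(s): ",
              paste(utils::head(off, 10), collapse = ", "),
              if (length(off) > 10) ", ...", call. = FALSE)
  }
  out
}

#' Write a subject-level panel table
#'
#' Writes a panel data frame as comma-separated text (header row, '.'
#' decimal, UTF-8, no row names).  Writing, reading back and writing
#' again is byte-stable.  If the data frame carries a `"condition"` or
#' `"generator"` attribute (as the simulators attach) or `meta` is
#' given, a `<path>.meta` sidecar with `key: value` lines records it
#' together with the package version.
#'
#' @param data a data.frame.
#' @param path output file path.
#' @param meta optional named list of extra metadata.
#' @return `path`, invisibly.
#' @export
write_panel <- function(data, path, meta = NULL) {
  stopifnot(is.data.frame(data))
  utils::write.csv(data, path, row.names = FALSE, quote = TRUE)
  info <- c(as.list(attr(data, "condition")),
            as.list(attr(data, "generator")), meta)
  info <- Filter(function(x) !is.null(x) && length(x) > 0, info)
  if (length(info)) {
    fmt <- function(x) paste(format(unlist(x), digits = 15,
                                    trim = TRUE), collapse = ",")
    writeLines(c(paste0("writer: rpcohort ",
                        as.character(utils::packageVersion("rpcohort"))),
                 paste0(names(info), ": ", vapply(info, fmt,
                                                  character(1)))),
               paste0(path, ".meta"))
  }
  invisible(path)
}
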