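# Delimited-text I/O for lesion cohorts. Missing values are empty cells;
# headers are matched case-insensitively with an alias map accepting the
# verbose source-style column names.

#' Read a lesion cohort from a delimited text file
#'
#' Parses a delimited cohort file into a validated [as_lesion_cohort()]
#' table. Header names are canonicalized case-insensitively and an alias map
#' accepts the verbose clinical column headings (e.g. `"SRS Dose (Gy)"` for
#' `dose_gy`). Unparseable or out-of-range values in non-mandatory fields
#' become missing with a consolidated warning; `time_months` and `event` are
#' mandatory and rows with missing or non-positive follow-up (or an event
#' flag other than 0/1) are rejected with an error listing the row indices.
#' Extra columns are preserved unparsed as an `annotations` attribute.
#'
#' @param path Path to the file.
#' @param sep Field delimiter (default comma).
#' @return A `lesion_cohort`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, sep = ",") {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- read.csv(path, sep = sep, colClasses = "character",
                  check.names = FALSE, na.strings = NULL,
                  stringsAsFactors = FALSE)
  canon <- .canon_header(names(raw))
  schema <- .schema_names()
  canon_schema <- .canon_header(schema)
  mapped <- ifelse(canon %in% canon_schema,
                   schema[match(canon, canon_schema)],
                   ifelse(canon %in% names(.schema_aliases),
                          .schema_aliases[canon], NA_character_))
  # Verbose aliases may carry trailing level descriptions, e.g.
  # "Anatomic localization (1: frontal, ...)" -- match on the alias prefix.
  for (i in which(is.na(mapped))) {
    hit <- which(startsWith(canon[i], names(.schema_aliases)))
    if (length(hit) > 0) mapped[i] <- .schema_aliases[hit[1]]
  }
  missing_cols <- setdiff(.schema_names(), mapped)
  if (length(missing_cols) > 0)
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))

  extra <- raw[, is.na(mapped), drop = FALSE]
  out <- list()
  warnings <- character()
  for (f in .schema_fields()) {
    col <- raw[[which(mapped == f$name)[1]]]
    col[col == ""] <- NA_character_
    parsed <- .parse_field(col, f)
    out[[f$name]] <- parsed$value
    if (length(parsed$bad_rows) > 0 && !isTRUE(f$mandatory))
      warnings <- c(warnings, sprintf("%s: rows %s set to missing",
                                      f$name, paste(parsed$bad_rows, collapse = ",")))
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)

  bad_time <- which(is.na(out$time_months) | out$time_months <= 0)
  bad_event <- which(is.na(out$event) | !(out$event %in% c(0L, 1L)))
  reject <- sort(unique(c(bad_time, bad_event)))
  if (length(reject) > 0)
    stop("rows with time-to-event or event status missing or non-positive/invalid: ",
         paste(reject, collapse = ", "))
  if (length(warnings) > 0)
    warning("values coerced to missing -- ", paste(warnings, collapse = "; "))

  cohort <- as_lesion_cohort(out, provenance = path)
  if (ncol(extra) > 0) attr(cohort, "annotations") <- extra
  cohort
}

.parse_field <- function(col, f) {
  n <- length(col)
  bad <- integer(0)
  if (f$type == "id") {
    return(list(value = as.character(col), bad_rows = integer(0)))
  }
  if (f$type %in% c("numeric", "grid", "event")) {
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (f$type == "numeric") {
      lo <- f$min %||% -Inf
      hi <- f$max %||% Inf
      too_low <- if (isTRUE(f$open_min)) num <= lo else num < lo
      bad <- union(bad, which(!is.na(num) & (too_low | num > hi)))
    }
    if (f$type == "grid") bad <- union(bad, which(!is.na(num) & !(num %in% f$levels)))
    if (f$type == "event") bad <- union(bad, which(!is.na(num) & !(num %in% c(0, 1))))
    if (!isTRUE(f$mandatory)) num[bad] <- NA_real_
    val <- if (f$type == "event") as.integer(num) else num
    return(list(value = val, bad_rows = sort(bad)))
  }
  # category
  v <- as.character(col)
  bad <- which(!is.na(v) & !(v %in% f$levels))
  v[bad] <- NA_character_
  list(value = v, bad_rows = sort(bad))
}

#' Write a lesion cohort to a delimited text file
#'
#' Serializes a cohort with canonical column names, missing values as empty
#' cells, and full-precision numerics so that
#' `read_cohort(write_cohort(x, p))` reproduces `x` field-for-field.
#'
#' @param cohort A `lesion_cohort`.
#' @param path Output path.
#' @param sep Field delimiter (default comma).
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  validate_cohort(cohort)
  out <- as.data.frame(cohort, stringsAsFactors = FALSE)
  out <- out[, .schema_names(), drop = FALSE]
  for (f in .schema_fields()) {
    if (f$type %in% c("numeric", "grid")) {
      v <- out[[f$name]]
      out[[f$name]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
    }
  }
  tryCatch(
    utils::write.table(out, path, sep = sep, row.names = FALSE, na = "",
                       quote = TRUE, qmethod = "double"),
    error = function(e) stop("cannot write cohort file '", path, "': ",
                             conditionMessage(e)))
  invisible(path)
}
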