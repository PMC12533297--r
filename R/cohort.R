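#' Read a per-patient survival cohort table
#'
#' Reads a delimited text file of patient survival records. Required
#' columns (after mapping) are `patient_id`, `os_time` (days) and
#' `os_event` (0/1); `dfs_time`/`dfs_event` are optional, and every
#' other column is retained as a covariate. Rows with a missing
#' mandatory field or a non-binary event flag are rejected, reported
#' row-by-row via `message()`, and returned in the `"rejected"`
#' attribute; the reader never repairs data silently. A negative
#' survival time or a duplicated `patient_id` is a hard error.
#'
#' @param path path to a delimited text file with a header row.
#' @param columns named character vector mapping the canonical names
#'   (`patient_id`, `os_time`, `os_event`, `dfs_time`, `dfs_event`) to
#'   the column names used in the file.
#' @param sep field separator.
#' @return A `data.frame` of class `cohort_table` with canonical column
#'   names; attribute `"rejected"` holds the rejected rows (with a
#'   `reason` column), possibly empty.
#' @export
read_cohort_table <- function(path,
                              columns = c(patient_id = "patient_id",
                                          os_time = "os_time",
                                          os_event = "os_event",
                                          dfs_time = "dfs_time",
                                          dfs_event = "dfs_event"),
                              sep = ",") {
  if (!file.exists(path)) stop("cohort table not found: ", path)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  canonical <- c("patient_id", "os_time", "os_event", "dfs_time", "dfs_event")
  map <- columns[intersect(canonical, names(columns))]
  required <- c("patient_id", "os_time", "os_event")
  miss <- setdiff(map[required], names(raw))
  if (length(miss))
    stop("required column(s) absent from file: ", paste(miss, collapse = ", "))
  present <- map[map %in% names(raw)]

  df <- raw
  for (canon in names(present)) names(df)[names(df) == present[canon]] <- canon
  has_dfs <- all(c("dfs_time", "dfs_event") %in% names(df))

  time_cols <- intersect(c("os_time", "dfs_time"), names(df))
  event_cols <- intersect(c("os_event", "dfs_event"), names(df))
  for (cc in c(time_cols, event_cols)) df[[cc]] <- as.numeric(df[[cc]])

  if (any(unlist(df[time_cols]) < 0, na.rm = TRUE))
    stop("negative survival time in ", path)

  mandatory <- c(required, if (has_dfs) c("dfs_time", "dfs_event"))
  reason <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    vals <- df[i, mandatory]
    if (any(is.na(vals)) || !nzchar(as.character(df$patient_id[i]))) {
      reason[i] <- "missing mandatory field"
    } else {
      ev <- unlist(df[i, event_cols])
      if (!all(ev %in% c(0, 1)))
        reason[i] <- sprintf("event flag not in {0,1} (%s)",
                             paste(ev[!ev %in% c(0, 1)], collapse = ","))
    }
  }
  bad <- which(nzchar(reason))
  if (length(bad)) {
    for (i in bad)
      message(sprintf("%s row %d rejected: %s", basename(path), i, reason[i]))
    rejected <- cbind(raw[bad, , drop = FALSE], reason = reason[bad])
  } else {
    rejected <- cbind(raw[0, , drop = FALSE], reason = character(0))
  }
  df <- df[setdiff(seq_len(nrow(df)), bad), , drop = FALSE]

  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id in ", path, ": ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]),
               collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  for (cc in event_cols) df[[cc]] <- as.integer(df[[cc]])
  rownames(df) <- NULL
  structure(df, rejected = rejected,
            class = c("cohort_table", "data.frame"))
}

#' Write a cohort table as CSV
#' @param cohort a `cohort_table` (or plain data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
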