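.mandatory_columns <- c("id", "age_years", "sex")

#' Read a cohort file
#'
#' Reads a delimited cohort table (comma or tab, auto-detected from the
#' header line) in the canonical schema: `id`, `age_years`, `sex` (F/M),
#' optional `black` (0/1), `height_cm`, `weight_kg`, exactly one of
#' `scr_umol_l` / `scr_mg_dl`, `scys_mg_l`, `valine_umol_l`,
#' `myo_inositol_umol_l`, optional `mgfr_ml_min_173` and `tracer`. Unknown
#' columns are preserved. Creatinine given in mg/dL is converted to umol/L
#' (factor 88.42). Row-level validation problems are collected and reported
#' with line numbers. Markers a downstream equation needs but the file
#' lacks raise their error at estimation time, not at load time.
#'
#' @param path Path to the file.
#' @return Validated, unit-normalized data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, warn = FALSE)
  if (!nzchar(header)) stop("cannot parse header of ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  # read everything as character first: type.convert would otherwise turn a
  # single-sex column of "F" values into logicals
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "\"",
                    colClasses = "character", fileEncoding = "UTF-8")
  for (col in setdiff(names(tab), c("id", "sex", "tracer", "indication"))) {
    tab[[col]] <- utils::type.convert(tab[[col]], as.is = TRUE)
  }
  missing_cols <- setdiff(.mandatory_columns, names(tab))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  has_umol <- "scr_umol_l" %in% names(tab)
  has_mgdl <- "scr_mg_dl" %in% names(tab)
  if (has_umol && has_mgdl) {
    stop("ambiguous creatinine: both scr_umol_l and scr_mg_dl present")
  }
  if (!has_umol && !has_mgdl) {
    stop("missing mandatory column(s): scr_umol_l (or scr_mg_dl)")
  }
  if (has_mgdl) {
    tab$scr_umol_l <- tab$scr_mg_dl * 88.42
    tab$scr_mg_dl <- NULL
  }

  problems <- character(0)
  note <- function(rows, msg) {
    # +1 for the header line
    if (length(rows)) {
      problems <<- c(problems,
                     paste0("line ", paste(rows + 1L, collapse = ","), ": ", msg))
    }
  }
  s <- tolower(as.character(tab$sex))
  note(which(!s %in% c("f", "m", "female", "male")), "sex must be F/M")
  note(which(is.na(tab$age_years) | tab$age_years <= 0),
       "age_years must be positive")
  for (col in intersect(c("scr_umol_l", "scys_mg_l", "valine_umol_l",
                          "myo_inositol_umol_l", "height_cm", "weight_kg",
                          "mgfr_ml_min_173"), names(tab))) {
    note(which(!is.na(tab[[col]]) & tab[[col]] <= 0),
         paste0(col, " must be positive"))
  }
  if (length(problems)) {
    stop("invalid cohort rows:\n  ", paste(problems, collapse = "\n  "))
  }
  tab$sex <- toupper(substr(as.character(tab$sex), 1, 1))
  if (any(tab$age_years < 18)) {
    warning("cohort contains ages below 18: equations were developed on adults",
            call. = FALSE)
  }
  tab
}

#' Write a cohort (or any report table) to delimited text
#'
#' @param x Data frame.
#' @param path Output path; a `.tsv` extension selects tab separation,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
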