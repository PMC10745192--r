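# CSV schemas, typed read/write round-trip, and dataset validation.
# All artifacts are plain CSV with a one-line schema-version header
# comment; dates are ISO-8601 and decimals use '.'.

SCHEMAS <- list(
  plots = list(
    cols = c(plot_id = "character", year = "integer",
             enrolled = "character", shrub_cover = "numeric",
             gpp_mean = "numeric", lai_mean = "numeric",
             precip_mean = "numeric", temp_max = "numeric",
             temp_min = "numeric"),
    enums = list(enrolled = c("SGI", "non-SGI")),
    ranges = list(shrub_cover = c(0, 1))),
  nest_detections = list(
    cols = c(plot_id = "character", year = "integer",
             species = "character", round = "integer",
             transect_id = "character", distance_m = "numeric",
             opportunistic = "logical", nest_id = "character"),
    ranges = list(distance_m = c(0, Inf))),
  effort = list(
    cols = c(plot_id = "character", year = "integer",
             transect_id = "character", length_m = "numeric",
             rounds = "integer"),
    ranges = list(length_m = c(0, Inf), rounds = c(1, Inf))),
  nest_visits = list(
    cols = c(nest_id = "character", plot_id = "character",
             species = "character", year = "integer",
             visit_date = "Date", day = "numeric", stage = "character",
             status = "character", cause = "character"),
    enums = list(stage = c("egg", "nestling"),
                 status = c("active", "fledged", "failed"))),
  ddo_counts = list(
    cols = c(plot_id = "character", year = "integer", visit = "integer",
             species = "character", observer_primary = "character",
             observer_secondary = "character", x1 = "integer",
             x2 = "integer", enrolled = "character"),
    enums = list(enrolled = c("SGI", "non-SGI")),
    ranges = list(x1 = c(0, Inf), x2 = c(0, Inf))),
  truth = list(
    cols = c(plot_id = "character", year = "integer",
             species = "character", quality = "numeric",
             nest_density = "numeric", adult_density = "numeric",
             dsr_egg = "numeric", dsr_nestling = "numeric"),
    ranges = list(nest_density = c(0, Inf), adult_density = c(0, Inf),
                  dsr_egg = c(0, 1), dsr_nestling = c(0, 1)))
)

#' Write a survey table as schema-versioned CSV
#'
#' @param df the table.
#' @param path output file.
#' @param schema schema name (one of `names(nestdemog:::SCHEMAS)`);
#'   `NULL` writes plain CSV without a header comment.
#' @return `path`, invisibly.
#' @export
write_demog_csv <- function(df, path, schema = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(schema)) {
    stopifnot(schema %in% names(SCHEMAS))
    writeLines(paste0("# nestdemog schema v1: ", schema), con)
  }
  for (col in names(df))
    if (inherits(df[[col]], "Date"))
      df[[col]] <- format(df[[col]], "%Y-%m-%d")
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a schema-versioned survey CSV with typed columns
#'
#' @param path CSV file.
#' @param schema schema name; `NULL` infers from the header comment.
#' @return a typed data.frame.
#' @export
read_demog_csv <- function(path, schema = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(schema) && startsWith(first, "# nestdemog schema"))
    schema <- sub(".*: ", "", first)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  if (!is.null(schema) && schema %in% names(SCHEMAS)) {
    types <- SCHEMAS[[schema]]$cols
    for (col in names(types)) {
      if (!col %in% names(df)) next
      df[[col]] <- switch(types[[col]],
        character = as.character(df[[col]]),
        integer = as.integer(df[[col]]),
        numeric = as.numeric(df[[col]]),
        logical = as.logical(df[[col]]),
        Date = as.Date(df[[col]]))
    }
  }
  df
}

check_one <- function(df, schema_name, file_label) {
  sc <- SCHEMAS[[schema_name]]
  v <- list()
  add <- function(row, column, problem)
    v[[length(v) + 1L]] <<- data.frame(file = file_label, row = row,
                                       column = column, problem = problem,
                                       stringsAsFactors = FALSE)
  for (col in names(sc$cols))
    if (!col %in% names(df)) add(NA_integer_, col, "missing column")
  for (col in intersect(names(sc$cols), names(df))) {
    want <- sc$cols[[col]]
    bad_type <- switch(want,
      numeric = !is.numeric(df[[col]]),
      integer = !(is.numeric(df[[col]]) &&
                  all(df[[col]] == round(df[[col]]), na.rm = TRUE)),
      character = FALSE, logical = !is.logical(df[[col]]),
      Date = anyNA(as.Date(as.character(df[[col]]),
                           optional = TRUE)) && !all(is.na(df[[col]])))
    if (isTRUE(bad_type)) add(NA_integer_, col, paste("not", want))
  }
  for (col in intersect(names(sc$ranges), names(df))) {
    rg <- sc$ranges[[col]]
    bad <- which(!is.na(df[[col]]) & (df[[col]] < rg[1] | df[[col]] > rg[2]))
    for (b in bad) add(b, col, paste0("out of range [", rg[1], ", ",
                                      rg[2], "]: ", df[[col]][b]))
  }
  for (col in intersect(names(sc$enums), names(df))) {
    ok <- sc$enums[[col]]
    bad <- which(!is.na(df[[col]]) & !df[[col]] %in% ok)
    for (b in bad) add(b, col, paste0("not in {", paste(ok, collapse = ", "),
                                      "}: ", df[[col]][b]))
  }
  v
}

#' Validate a survey dataset against the package schemas
#'
#' Schema check (columns, types, ranges, enumerated values) plus
#' referential integrity: every detection, visit and count row must
#' reference a known plot. The report lists every violation with its row
#' number.
#'
#' @param tables named list of data.frames (names among `plots`,
#'   `nest_detections`, `effort`, `nest_visits`, `ddo_counts`, `truth`),
#'   or a named list/vector of file paths.
#' @param strict error (nonzero condition) on any violation (default
#'   FALSE: return the report).
#' @return data.frame of violations (`file`, `row`, `column`, `problem`);
#'   zero rows when the dataset is clean.
#' @export
validate_dataset <- function(tables, strict = FALSE) {
  if (is.character(tables))
    tables <- lapply(tables, read_demog_csv)
  if (length(tables) && all(vapply(tables, is.character, logical(1))))
    tables <- lapply(tables, read_demog_csv)
  stopifnot(!is.null(names(tables)))
  v <- list()
  for (nm in names(tables)) {
    if (!nm %in% names(SCHEMAS)) next
    v <- c(v, check_one(tables[[nm]], nm, nm))
  }
  if (!is.null(tables$plots)) {
    known <- unique(tables$plots$plot_id)
    for (nm in c("nest_detections", "nest_visits", "ddo_counts")) {
      t2 <- tables[[nm]]
      if (is.null(t2) || is.null(t2$plot_id)) next
      bad <- which(!t2$plot_id %in% known)
      for (b in bad)
        v[[length(v) + 1L]] <- data.frame(
          file = nm, row = b, column = "plot_id",
          problem = paste("unknown plot", t2$plot_id[b]),
          stringsAsFactors = FALSE)
    }
  }
  report <- if (length(v)) do.call(rbind, v) else
    data.frame(file = character(0), row = integer(0),
               column = character(0), problem = character(0))
  if (strict && nrow(report) > 0L)
    stop("dataset validation failed with ", nrow(report), " violation(s)")
  report
}

#' Write a full synthetic survey bundle to CSV
#'
#' @param sim a `demog_sim` from [simulate_demography()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths.
#' @export
write_survey_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "demog_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    plots = write_demog_csv(sim$plots, file.path(dir, "plots.csv"), "plots"),
    nest_detections = write_demog_csv(
      sim$detections, file.path(dir, "nest_detections.csv"),
      "nest_detections"),
    effort = write_demog_csv(sim$effort, file.path(dir, "effort.csv"),
                             "effort"),
    nest_visits = write_demog_csv(
      sim$visits, file.path(dir, "nest_visits.csv"), "nest_visits"),
    ddo_counts = write_demog_csv(
      sim$ddo_counts, file.path(dir, "ddo_counts.csv"), "ddo_counts"),
    truth = write_demog_csv(sim$truth, file.path(dir, "truth.csv"),
                            "truth"))
  paths
}
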