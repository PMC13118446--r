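#' Read one FAERS-dialect quarterly ASCII table
#'
#' FAERS quarterly files are '$'-delimited, unquoted, UTF-8, with a
#' single header row. Columns are matched by name (case-insensitive);
#' columns beyond the table's standard set are preserved untouched.
#' Blank fields become `NA`. Embedded '$' inside a value is not
#' representable in this dialect and is not handled.
#'
#' @param path File path.
#' @param table_kind One of `"demo"`, `"drug"`, `"reac"`, `"outc"`,
#'   `"indi"`.
#' @return A tibble, one row per data line. `demo` tables get typed
#'   `fda_dt` (integer yyyymmdd, `NA` with a warning when unparseable)
#'   and normalised `sex`; code columns keep their FAERS vocabulary.
#' @export
read_faers_table <- function(path, table_kind = c("demo", "drug", "reac",
                                                  "outc", "indi")) {
  table_kind <- match.arg(table_kind)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) abort(paste0("empty file: ", path))
  header <- tolower(strsplit(lines[1], "$", fixed = TRUE)[[1]])
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "$", fixed = TRUE)
  ncol_h <- length(header)
  tbl <- if (length(parts) == 0) {
    as_tibble(setNames(rep(list(character(0)), ncol_h), header),
              .name_repair = "minimal")
  } else {
    mat <- vapply(parts, function(p) {
      length(p) <- ncol_h
      p
    }, character(ncol_h))
    mat <- matrix(mat, nrow = ncol_h)
    out <- as_tibble(as.data.frame(t(mat), stringsAsFactors = FALSE),
                     .name_repair = "minimal")
    names(out) <- header
    out
  }
  tbl[tbl == ""] <- NA_character_
  mandatory <- switch(table_kind,
    demo = c("primaryid", "caseid", "fda_dt"),
    drug = c("primaryid", "role_cod"),
    reac = c("primaryid", "pt"),
    outc = c("primaryid", "outc_cod"),
    indi = c("primaryid", "indi_pt")
  )
  missing_col <- setdiff(mandatory, names(tbl))
  if (length(missing_col) > 0) {
    abort(paste0("format error in ", basename(path), ": missing column(s) ",
                 paste(missing_col, collapse = ", ")))
  }
  if (table_kind == "demo") {
    tbl$fda_dt <- parse_faers_date(tbl$fda_dt)
    if ("sex" %in% names(tbl)) {
      tbl$sex <- dplyr::if_else(tbl$sex %in% c("M", "F"), tbl$sex, NA_character_)
    }
    if ("age" %in% names(tbl)) {
      suppressWarnings(tbl$age <- as.numeric(tbl$age))
    }
  }
  inform(sprintf("%s: read %d row(s) from %s", toupper(table_kind),
                 nrow(tbl), basename(path)))
  tbl
}

# yyyymmdd integers; anything that does not parse as a calendar date
# becomes NA with a row-level warning.
parse_faers_date <- function(x) {
  suppressWarnings(num <- as.integer(x))
  parsed <- as.Date(as.character(num), format = "%Y%m%d")
  bad <- !is.na(x) & is.na(parsed)
  if (any(bad)) {
    warn(sprintf("%d unparseable fda_dt value(s) set to missing", sum(bad)))
    num[bad] <- NA_integer_
  }
  num
}

#' Write a table back to the FAERS '$'-delimited dialect
#'
#' Inverse of [read_faers_table()]: writes a single '$'-separated header
#' line then one line per row, `NA` as the empty string, no quoting.
#' Round-tripping a file produced by this writer is byte-identical.
#'
#' @param tbl Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(tbl, path) {
  mat <- vapply(tbl, function(col) {
    out <- as.character(col)
    out[is.na(out)] <- ""
    out
  }, character(nrow(tbl)))
  if (nrow(tbl) == 1) mat <- matrix(mat, nrow = 1)
  lines <- c(paste(names(tbl), collapse = "$"),
             apply(mat, 1, paste, collapse = "$"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Normalise a FAERS age to years
#'
#' FAERS records age together with a unit code: `DEC` decades, `YR`
#' years, `MON` months, `WK` weeks, `DY` days, `HR` hours. A present age
#' with a missing unit code is taken as years (the FAERS convention),
#' with a warning. Negative ages become missing with a warning.
#'
#' @param age Numeric age value(s).
#' @param age_cod Unit code(s), `NA` allowed.
#' @return Age in years (numeric, `NA` where unrecoverable).
#' @examples
#' age_in_years(6, "MON")
#' age_in_years(7, "DEC")
#' @export
age_in_years <- function(age, age_cod) {
  stopifnot(length(age) == length(age_cod) || length(age_cod) == 1)
  age <- as.numeric(age)
  neg <- !is.na(age) & age < 0
  if (any(neg)) {
    warn(sprintf("%d negative age(s) set to missing", sum(neg)))
    age[neg] <- NA_real_
  }
  factor_map <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
                  DY = 1 / 365.25, HR = 1 / 8766)
  cod <- toupper(as.character(age_cod))
  no_unit <- !is.na(age) & (is.na(cod) | !cod %in% names(factor_map))
  if (any(no_unit)) {
    warn(sprintf("%d age(s) with missing/unknown unit treated as years",
                 sum(no_unit)))
    cod[no_unit] <- "YR"
  }
  mult <- unname(factor_map[cod])
  age * mult
}

#' Write a report bundle as FAERS quarterly files
#'
#' Writes the five tables of a bundle (see [generate_reports()]) as
#' `DEMOyyQq.txt`, `DRUGyyQq.txt`, ... in `dir`, using a single nominal
#' quarter label, plus a `ground_truth.json`-style sidecar when the
#' bundle carries one and `jsonlite` is installed.
#'
#' @param bundle A `faers_bundle` (list with tibbles `demo`, `drug`,
#'   `reac`, `outc`, `indi`).
#' @param dir Output directory (created if needed).
#' @param quarter Label like `"24Q4"` used in file names.
#' @return Named character vector of the files written, invisibly.
#' @export
write_faers_bundle <- function(bundle, dir, quarter = "24Q4") {
  stopifnot(inherits(bundle, "faers_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(demo = "DEMO", drug = "DRUG", reac = "REAC",
             outc = "OUTC", indi = "INDI")
  paths <- character(0)
  for (nm in names(files)) {
    p <- file.path(dir, paste0(files[[nm]], quarter, ".txt"))
    write_faers_table(bundle[[nm]], p)
    paths[nm] <- p
  }
  gt <- attr(bundle, "ground_truth")
  if (!is.null(gt) && requireNamespace("jsonlite", quietly = TRUE)) {
    gp <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(gt, gp, auto_unbox = TRUE, digits = NA)
    paths["ground_truth"] <- gp
  }
  invisible(paths)
}

#' Read a directory of FAERS quarterly files into a bundle
#'
#' Collects every `DEMO*.txt`, `DRUG*.txt`, `REAC*.txt`, `OUTC*.txt`,
#' `INDI*.txt` under `dir` (any number of quarters) and row-binds each
#' kind into one tibble.
#'
#' @param dir Directory containing FAERS-dialect files.
#' @return A `faers_bundle` list of five tibbles.
#' @export
read_faers_bundle <- function(dir) {
  kinds <- c(demo = "DEMO", drug = "DRUG", reac = "REAC",
             outc = "OUTC", indi = "INDI")
  out <- purrr::imap(kinds, function(prefix, kind) {
    fs <- list.files(dir, pattern = paste0("^", prefix, ".*\\.txt$"),
                     full.names = TRUE)
    if (length(fs) == 0) abort(paste0("no ", prefix, "*.txt files in ", dir))
    purrr::map(sort(fs), read_faers_table, table_kind = kind) |> bind_rows()
  })
  structure(out, class = "faers_bundle")
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat("<faers_bundle>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %d rows\n", toupper(nm), nrow(x[[nm]])))
  }
  invisible(x)
}
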