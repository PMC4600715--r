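#' Plate geometry
#'
#' Describes the physical well layout of the assay plates. The default is a
#' 384-well plate: rows A-P, columns 1-24.
#'
#' @param rows Number of rows (lettered A, B, ...; at most 26).
#' @param cols Number of columns (numbered from 1).
#' @return An object of class `screen_geometry`.
#' @examples
#' screen_geometry()        # 384-well
#' screen_geometry(8, 12)   # 96-well
#' @export
screen_geometry <- function(rows = 16L, cols = 24L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || rows < 1L || rows > 26L)
    stop("'rows' must be an integer in 1..26")
  if (is.na(cols) || cols < 1L)
    stop("'cols' must be a positive integer")
  structure(list(rows = rows, cols = cols), class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d-well plate (rows A-%s, columns 1-%d)\n",
              x$rows * x$cols, LETTERS[x$rows], x$cols))
  invisible(x)
}

#' Parse well labels
#'
#' Converts plate-reader style well labels ("A1".."P24") into row/column
#' indices, validating against a plate geometry. Labels are a row letter
#' followed by a 1-based column number, with no zero padding required
#' ("A1" and "A01" both parse).
#'
#' @param well Character vector of well labels.
#' @param geometry A [screen_geometry()].
#' @return A data frame with columns `row` and `col` (integer indices).
#' @export
parse_well <- function(well, geometry = screen_geometry()) {
  well <- as.character(well)
  u <- unique(well)
  m <- regmatches(u, regexec("^([A-Za-z])([0-9]{1,2})$", u))
  bad <- lengths(m) != 3L
  row <- rep(NA_integer_, length(u)); col <- rep(NA_integer_, length(u))
  ok <- which(!bad)
  if (length(ok)) {
    row[ok] <- match(toupper(vapply(m[ok], `[`, "", 2L)), LETTERS)
    col[ok] <- as.integer(vapply(m[ok], `[`, "", 3L))
  }
  invalid <- bad | is.na(row) | row > geometry$rows |
    is.na(col) | col < 1L | col > geometry$cols
  if (any(invalid)) {
    first <- u[which(invalid)[1L]]
    at <- which(well == first)[1L]
    stop(sprintf(
      "invalid well label '%s' (entry %d) for %dx%d plate geometry",
      first, at, geometry$rows, geometry$cols))
  }
  i <- match(well, u)
  data.frame(row = row[i], col = col[i])
}

.WELL_TYPES <- c("sample", "negative_control", "positive_control", "empty")

.required_cols <- c("screen", "cell_line", "plate", "well",
                    "sirna", "gene", "well_type", "intensity")

#' Construct a screen dataset
#'
#' Bundles a long-format table of well measurements with its plate geometry
#' and control declaration, and validates the screening-design invariants:
#' positive intensities for non-empty wells, well labels inside the declared
#' geometry, unique (screen, plate, well) coordinates, a shared library
#' layout across screens, at least one negative-control well on every plate
#' of every screen, and at least one screen per cell line.
#'
#' @param wells Data frame with columns `screen`, `cell_line`, `plate`,
#'   `well`, `sirna`, `gene`, `well_type`, `intensity`. `well_type` must be
#'   one of `"sample"`, `"negative_control"`, `"positive_control"`,
#'   `"empty"`. `intensity` may be `NA` only for empty wells.
#' @param geometry A [screen_geometry()].
#' @param validate Run [validate_screen_dataset()] (default `TRUE`).
#' @return An object of class `screen_dataset`: a list with elements
#'   `wells`, `geometry` and `groups` (named character vector mapping each
#'   screen id to its cell line).
#' @seealso [read_screen_table()], [simulate_screen()]
#' @export
screen_dataset <- function(wells, geometry = screen_geometry(),
                           validate = TRUE) {
  if (!is.data.frame(wells))
    stop("'wells' must be a data frame")
  missing_cols <- setdiff(.required_cols, names(wells))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  wells <- as.data.frame(wells)[.required_cols]
  for (cc in c("screen", "cell_line", "plate", "well", "sirna", "gene",
               "well_type"))
    wells[[cc]] <- as.character(wells[[cc]])
  wells$intensity <- as.numeric(wells$intensity)
  rownames(wells) <- NULL
  scr <- unique(wells[c("screen", "cell_line")])
  groups <- stats::setNames(scr$cell_line, scr$screen)
  x <- structure(list(wells = wells, geometry = geometry, groups = groups),
                 class = "screen_dataset")
  if (validate) validate_screen_dataset(x)
  x
}

#' Validate a screen dataset
#'
#' Checks every `screen_dataset` invariant and stops with an informative
#' error naming the first offending row or (plate, well) on failure.
#'
#' @param x A [screen_dataset()].
#' @return `x`, invisibly, when all checks pass.
#' @export
validate_screen_dataset <- function(x) {
  if (!inherits(x, "screen_dataset")) stop("not a screen_dataset")
  w <- x$wells
  if (anyNA(w$well_type) || !all(w$well_type %in% .WELL_TYPES))
    stop("well_type must be one of: ", paste(.WELL_TYPES, collapse = ", "))
  if (any(duplicated(w[c("screen", "cell_line")])[duplicated(w$screen)] &
          FALSE)) NULL # screens map to a single cell line, checked below
  scr <- unique(w[c("screen", "cell_line")])
  if (anyDuplicated(scr$screen))
    stop("screen '", scr$screen[duplicated(scr$screen)][1L],
         "' is assigned to more than one cell line")
  # intensity domain
  nonempty <- w$well_type != "empty"
  bad <- which(nonempty & (is.na(w$intensity) | w$intensity <= 0))
  if (length(bad))
    stop(sprintf(
      "non-positive or missing intensity in non-empty well (row %d: screen %s, plate %s, well %s)",
      bad[1L], w$screen[bad[1L]], w$plate[bad[1L]], w$well[bad[1L]]))
  # geometry
  parse_well(w$well, x$geometry)
  # coordinate uniqueness
  coord <- paste(w$screen, w$plate, w$well, sep = "\r")
  dup <- which(duplicated(coord))
  if (length(dup))
    stop(sprintf(
      "duplicated coordinate (row %d: screen %s, plate %s, well %s)",
      dup[1L], w$screen[dup[1L]], w$plate[dup[1L]], w$well[dup[1L]]))
  # shared library layout: identical sirna and well_type per (plate, well)
  pw <- paste(w$plate, w$well, sep = "\r")
  first <- !duplicated(pw)
  ref <- match(pw, pw[first])
  mismatch <- which(w$sirna != w$sirna[first][ref] |
                      w$well_type != w$well_type[first][ref])
  if (length(mismatch)) {
    i <- mismatch[1L]
    stop(sprintf(
      "library layout differs across screens at plate %s, well %s (screen %s)",
      w$plate[i], w$well[i], w$screen[i]))
  }
  # negative controls on every plate of every screen
  sp <- paste(w$screen, w$plate, sep = "\r")
  has_neg <- unique(sp[w$well_type == "negative_control"])
  missing_neg <- setdiff(unique(sp), has_neg)
  if (length(missing_neg)) {
    parts <- strsplit(missing_neg[1L], "\r", fixed = TRUE)[[1L]]
    stop(sprintf("plate %s in screen %s has no negative-control well",
                 parts[2L], parts[1L]))
  }
  if (length(unique(scr$cell_line)) < 1L || nrow(scr) < 1L)
    stop("dataset contains no screens")
  invisible(x)
}

#' @export
print.screen_dataset <- function(x, ...) {
  w <- x$wells
  cat(sprintf("<screen_dataset> %d wells, %d plates, %d screens (%s)\n",
              nrow(w), length(unique(w$plate)), length(x$groups),
              paste(sprintf("%s: %d", names(table(x$groups)),
                            as.integer(table(x$groups))), collapse = ", ")))
  cat(sprintf("  geometry: %d x %d; well types: %s\n",
              x$geometry$rows, x$geometry$cols,
              paste(sprintf("%s=%d", names(table(w$well_type)),
                            as.integer(table(w$well_type))), collapse = " ")))
  invisible(x)
}

#' Read a long-format screen table
#'
#' Reads a delimited one-row-per-well table (the canonical on-disk format)
#' into a validated [screen_dataset()]. Column names in the file can be
#' remapped with `col_map`.
#'
#' @param path Path to a CSV (default) or TSV file.
#' @param geometry A [screen_geometry()].
#' @param sep Field delimiter, `","` or `"\t"`.
#' @param col_map Optional named character vector mapping canonical column
#'   names (`screen`, `cell_line`, `plate`, `well`, `sirna`, `gene`,
#'   `well_type`, `intensity`) to the names used in the file.
#' @return A [screen_dataset()].
#' @export
read_screen_table <- function(path, geometry = screen_geometry(),
                              sep = ",", col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      j <- match(col_map[[canon]], names(tab))
      if (is.na(j)) stop("column '", col_map[[canon]], "' not found in ", path)
      names(tab)[j] <- canon
    }
  }
  screen_dataset(tab, geometry = geometry)
}

#' Read a wide per-plate matrix
#'
#' Convenience importer for plate-reader exports shaped as a rows x columns
#' intensity matrix for a single (screen, plate). Converts to the canonical
#' long form; annotation (siRNA, gene, well type) must be joined afterwards
#' or supplied via `annotation`.
#'
#' @param path Path to a headerless delimited matrix (`rows x cols`).
#' @param screen,cell_line,plate Labels for the plate being read.
#' @param geometry A [screen_geometry()]; the matrix must match it.
#' @param annotation Optional data frame with columns `well`, `sirna`,
#'   `gene`, `well_type` describing the shared library layout.
#' @param sep Field delimiter.
#' @return A long-format data frame of well records.
#' @export
read_plate_matrix <- function(path, screen, cell_line, plate,
                              geometry = screen_geometry(),
                              annotation = NULL, sep = ",") {
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
  if (nrow(m) != geometry$rows || ncol(m) != geometry$cols)
    stop(sprintf("matrix is %dx%d but geometry declares %dx%d",
                 nrow(m), ncol(m), geometry$rows, geometry$cols))
  long <- data.frame(
    screen = screen, cell_line = cell_line, plate = plate,
    well = paste0(rep(LETTERS[seq_len(geometry$rows)], geometry$cols),
                  rep(seq_len(geometry$cols), each = geometry$rows)),
    intensity = as.numeric(m), stringsAsFactors = FALSE)
  if (is.null(annotation)) {
    long$sirna <- long$well
    long$gene <- NA_character_
    long$well_type <- "sample"
  } else {
    i <- match(long$well, annotation$well)
    if (anyNA(i)) stop("annotation missing well ",
                       long$well[which(is.na(i))[1L]])
    long$sirna <- as.character(annotation$sirna[i])
    long$gene <- as.character(annotation$gene[i])
    long$well_type <- as.character(annotation$well_type[i])
  }
  long[c("screen", "cell_line", "plate", "well", "sirna", "gene",
         "well_type", "intensity")]
}

# Deterministic row order for on-disk tables: differential tables sort by
# (q, p), everything else lexicographically over all columns.
.result_order <- function(df) {
  if (!nrow(df)) return(integer(0))
  if (all(c("q", "p") %in% names(df))) {
    rest <- df[setdiff(names(df), c("q", "p"))]
    do.call(order, c(list(df$q, df$p), unname(rest)))
  } else {
    do.call(order, unname(df))
  }
}

# Format numeric columns at full double precision so write/read round-trips
# are lossless.
.format_full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- sprintf("%.17g", df[[j]])
      v[is.na(df[[j]])] <- NA_character_
      v[is.infinite(df[[j]])] <- ifelse(df[[j]][is.infinite(df[[j]])] > 0,
                                        "Inf", "-Inf")
      df[[j]] <- v
    }
  }
  df
}

#' Write pipeline result tables
#'
#' Writes each table of a named list to `<path>/<name>.csv` with a
#' deterministic column order and row sort (differential-result tables sort
#' ascending by q then p), numeric fields at full double precision, and a
#' JSON manifest listing file name, row count and MD5 checksum.
#'
#' @param tables Named list of data frames (a `screen_dataset` may be passed
#'   directly and contributes its `wells` table).
#' @param path Output directory; created if absent.
#' @param manifest_file Name of the manifest written inside `path`.
#' @return The manifest, invisibly (a data frame: `name`, `file`, `rows`,
#'   `md5`).
#' @export
write_results <- function(tables, path, manifest_file = "manifest.json") {
  if (inherits(tables, "screen_dataset")) tables <- list(screen = tables$wells)
  if (is.data.frame(tables)) tables <- list(result = tables)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("'tables' must be a named list of data frames")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  entries <- vector("list", length(tables))
  for (k in seq_along(tables)) {
    df <- tables[[k]]
    if (inherits(df, "screen_dataset")) df <- df$wells
    if (!is.data.frame(df)) stop("table '", names(tables)[k],
                                 "' is not a data frame")
    df <- as.data.frame(df)
    df <- df[.result_order(df), , drop = FALSE]
    file <- file.path(path, paste0(names(tables)[k], ".csv"))
    utils::write.table(.format_full_precision(df), file, sep = ",",
                       row.names = FALSE, quote = TRUE, na = "NA",
                       fileEncoding = "UTF-8")
    entries[[k]] <- data.frame(name = names(tables)[k],
                               file = basename(file),
                               rows = nrow(df),
                               md5 = unname(tools::md5sum(file)),
                               stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, entries)
  jsonlite::write_json(manifest, file.path(path, manifest_file),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read back a result table written by [write_results()]
#'
#' @param file Path to a CSV written by [write_results()].
#' @return A data frame with numeric columns restored at full precision.
#' @export
read_results <- function(file) {
  utils::read.table(file, header = TRUE, sep = ",", quote = "\"",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
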