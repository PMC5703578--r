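#' Read a network model from tabular files
#'
#' Accepts either a two-sheet workbook (`.xlsx`, first sheet `species`,
#' second sheet `reactions`; read via the readxl package) or a pair of CSV
#' files. Expected columns are `species(id, name, y_init, y_max, tau)` and
#' `reactions(id, rule, weight, n, ec50)`; blank parameter cells fall back
#' to the defaults (`y_init = 0`, `y_max = 1`, `tau = 1`, `weight = 0.9`
#' for non-input reactions, `n = 1.4`, `ec50 = 0.5`). Released model
#' workbooks do not always use these exact headers, so `col_map` lets the
#' caller remap them.
#'
#' @param source Path to the workbook, or to the species CSV when
#'   `reactions` is given.
#' @param reactions Path to the reactions CSV (CSV dialect only).
#' @param col_map Optional list with elements `species` and/or `reactions`,
#'   each a named character vector mapping canonical column names to the
#'   names used in the file, e.g.
#'   `list(species = c(id = "ID", tau = "timeConstant"))`.
#' @param sheets Length-2 character or integer vector naming the workbook
#'   sheets (default `c("species", "reactions")`, falling back to sheets
#'   1 and 2 when those names are absent).
#' @return A `network_model`.
#' @seealso [write_model_table()], [network_model()]
#' @export
parse_model_table <- function(source, reactions = NULL, col_map = NULL,
                              sheets = c("species", "reactions")) {
  if (is.null(reactions) && grepl("\\.xlsx?$", source, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading workbooks requires the 'readxl' package")
    have <- readxl::excel_sheets(source)
    pick <- function(want, idx) if (want %in% have) want else have[idx]
    sp_raw <- as.data.frame(readxl::read_excel(source, sheet = pick(sheets[1], 1),
                                               col_types = "text"))
    rx_raw <- as.data.frame(readxl::read_excel(source, sheet = pick(sheets[2], 2),
                                               col_types = "text"))
  } else {
    if (is.null(reactions))
      stop("CSV dialect needs both a species file and a reactions file")
    sp_raw <- utils::read.csv(source, colClasses = "character",
                              check.names = FALSE)
    rx_raw <- utils::read.csv(reactions, colClasses = "character",
                              check.names = FALSE)
  }
  sp_raw <- remap_columns(sp_raw, col_map$species)
  rx_raw <- remap_columns(rx_raw, col_map$reactions)
  if (!"id" %in% names(sp_raw))
    stop("species sheet lacks an 'id' column (use col_map to remap headers)")
  if (!all(c("id", "rule") %in% names(rx_raw)))
    stop("reactions sheet lacks 'id'/'rule' columns (use col_map to remap headers)")

  sp <- data.frame(id = trimws(sp_raw$id), stringsAsFactors = FALSE)
  sp$name <- if ("name" %in% names(sp_raw)) sp_raw$name else sp$id
  for (col in c("y_init", "y_max", "tau"))
    sp[[col]] <- coerce_numeric_col(sp_raw[[col]], "species", col, nrow(sp))

  rx <- data.frame(id = trimws(rx_raw$id), rule = rx_raw$rule,
                   stringsAsFactors = FALSE)
  rx$weight <- coerce_numeric_col(rx_raw$weight, "reactions", "weight",
                                  nrow(rx))
  rx$hill_n <- coerce_numeric_col(rx_raw[["n"]], "reactions", "n", nrow(rx))
  rx$ec50 <- coerce_numeric_col(rx_raw$ec50, "reactions", "ec50", nrow(rx))

  network_model(sp, rx, metadata = list(source = as.character(source)))
}

remap_columns <- function(df, map) {
  if (is.null(map)) return(df)
  for (canon in names(map)) {
    if (!map[[canon]] %in% names(df))
      stop("col_map refers to absent column ", sQuote(map[[canon]]))
    names(df)[names(df) == map[[canon]]] <- canon
  }
  df
}

coerce_numeric_col <- function(x, sheet, col, n) {
  if (is.null(x)) return(rep(NA_real_, n))
  x <- trimws(as.character(x))
  blank <- is.na(x) | x == ""
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!blank & is.na(out))
  if (length(bad))
    stop(sprintf("non-numeric value %s in sheet '%s', column '%s', row %d",
                 sQuote(x[bad[1]]), sheet, col, bad[1]))
  out
}

#' Write a network model as paired CSV tables
#'
#' Serializes to the paired-CSV dialect read by [parse_model_table()]:
#' `<basename>_species.csv` and `<basename>_reactions.csv`. Numeric
#' parameters are written with 17 significant digits so the round trip
#' through [parse_model_table()] reproduces them bit-exactly.
#'
#' @param model A valid `network_model`.
#' @param basename Output path prefix (directories must exist).
#' @return Invisibly, the two file paths written.
#' @export
write_model_table <- function(model, basename) {
  check_model(model, warn_orphans = FALSE)
  if (nrow(model$species) == 0L)
    stop("refusing to serialize a degenerate model with no species")
  num <- function(x) sprintf("%.17g", x)
  sp <- model$species
  sp_out <- data.frame(id = sp$id, name = sp$name, y_init = num(sp$y_init),
                       y_max = num(sp$y_max), tau = num(sp$tau),
                       stringsAsFactors = FALSE)
  rx <- model$reactions
  rx_out <- data.frame(id = rx$id, rule = rx$rule, weight = num(rx$weight),
                       n = num(rx$hill_n), ec50 = num(rx$ec50),
                       stringsAsFactors = FALSE)
  paths <- paste0(basename, c("_species.csv", "_reactions.csv"))
  utils::write.csv(sp_out, paths[1], row.names = FALSE, quote = TRUE)
  utils::write.csv(rx_out, paths[2], row.names = FALSE, quote = TRUE)
  invisible(paths)
}
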