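#' Read long-format production, import or population records
#'
#' Parses a delimited text file of production-style records
#' (`country, product, year, tonnes`) or population records
#' (`country, year, persons`). Column names are configurable; the
#' delimiter is inferred from the file extension (`.csv` comma,
#' anything else tab) unless given explicitly. Labels are
#' whitespace-trimmed; no fuzzy harmonization is attempted.
#'
#' @param path Path to an existing CSV/TSV file with a header row.
#' @param dialect One of `"production"`, `"import"` (same shape) or
#'   `"population"`.
#' @param columns Optional named character vector remapping the expected
#'   logical column names (`country`, `product`, `year`, `tonnes` /
#'   `persons`) to the names actually present in the header, e.g.
#'   `c(tonnes = "Value")`.
#' @param sep Field separator; default inferred from the extension.
#' @return A validated `data.frame` with canonical column names:
#'   `country, product, year, tonnes` for production/import records or
#'   `country, year, persons` for population records.
#'
#' Malformed rows raise an error naming the offending file line
#' (the header is line 1). Negative tonnage and non-positive population
#' counts are hard errors.
#' @export
read_records <- function(path,
                         dialect = c("production", "import", "population"),
                         columns = NULL, sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  wanted <- if (dialect == "population") {
    c("country", "year", "persons")
  } else {
    c("country", "product", "year", "tonnes")
  }
  have <- wanted
  if (!is.null(columns)) {
    bad <- setdiff(names(columns), wanted)
    if (length(bad)) stop("unknown column mapping(s): ",
                          paste(bad, collapse = ", "))
    have[match(names(columns), wanted)] <- unname(columns)
  }
  missing_cols <- setdiff(have, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  out <- raw[have]
  names(out) <- wanted
  if (nrow(out) == 0) {
    out$country <- character(0)
    num_cols <- setdiff(wanted, c("country", "product"))
    for (cc in num_cols) out[[cc]] <- numeric(0)
    out$year <- integer(0)
    return(out)
  }
  out$country <- trimws(out$country)
  if ("product" %in% wanted) out$product <- trimws(out$product)

  # data row i sits on physical line i + 1 (header is line 1)
  line_of <- function(i) i + 1L
  check_numeric <- function(col, what) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) | !nzchar(trimws(out[[col]])))
    if (length(bad)) {
      stop("non-numeric ", what, " on line(s) ",
           paste(line_of(utils::head(bad, 5)), collapse = ", "),
           " of ", path)
    }
    v
  }
  out$year <- as.integer(check_numeric("year", "year"))
  if (dialect == "population") {
    out$persons <- check_numeric("persons", "persons")
    bad <- which(out$persons <= 0)
    if (length(bad)) {
      stop("non-positive persons on line ", line_of(bad[1]), " of ", path)
    }
  } else {
    out$tonnes <- check_numeric("tonnes", "tonnes")
    bad <- which(out$tonnes < 0)
    if (length(bad)) {
      stop("negative tonnes on line ", line_of(bad[1]), " of ", path)
    }
  }
  rownames(out) <- NULL
  out
}

#' Restrict production records to sufficiently populous countries
#'
#' Keeps only records whose country has a population strictly greater
#' than `min_pop` persons in `year`. Countries absent from the
#' population table are dropped with a warning. The operation is total
#' (never errors) and idempotent.
#'
#' @param records Production/import records as from [read_records()].
#' @param population Population records as from
#'   `read_records(dialect = "population")`.
#' @param min_pop Population threshold (strict inequality); default
#'   500,000 persons.
#' @param year Year to evaluate the threshold at.
#' @return The filtered records `data.frame`.
#' @export
filter_countries <- function(records, population, min_pop = 5e5, year) {
  pop_y <- population[population$year == year, , drop = FALSE]
  pop <- stats::setNames(pop_y$persons, pop_y$country)
  known <- records$country %in% names(pop)
  if (any(!known)) {
    warning("dropping ", length(unique(records$country[!known])),
            " country(ies) absent from the population table: ",
            paste(utils::head(sort(unique(records$country[!known])), 5),
                  collapse = ", "))
  }
  keep <- known & pop[records$country] > min_pop
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a bipartite country-product panel for one year
#'
#' Builds the binary adjacency matrix `M` (`M[c, p] = 1` iff country `c`
#' reports strictly positive summed tonnage of product `p` in `year`)
#' and the per-capita weighted matrix `W = tonnes / persons` in tons
#' per person per year. Duplicate `(country, product, year)` rows are
#' summed. Countries and products appearing in the records are retained
#' even if their row/column ends up all zero; such labels are flagged in
#' the returned object rather than dropped.
#'
#' @param records Filtered production or import records.
#' @param population Population records covering every retained country
#'   in `year`; a missing country is a hard error.
#' @param year Year to build.
#' @return A `bipartite_panel` object: a list with elements `year`,
#'   `countries`, `products`, binary `M`, weighted `W`, and character
#'   vectors `zero_countries` / `zero_products` flagging all-zero lines.
#' @export
build_panel <- function(records, population, year) {
  rec <- records[records$year == year, , drop = FALSE]
  countries <- sort(unique(rec$country))
  products <- sort(unique(rec$product))
  pop_y <- population[population$year == year, , drop = FALSE]
  pop <- stats::setNames(pop_y$persons, pop_y$country)
  missing_pop <- setdiff(countries, names(pop))
  if (length(missing_pop)) {
    stop("no population record for year ", year, ": ",
         paste(missing_pop, collapse = ", "))
  }
  tot <- matrix(0, length(countries), length(products),
                dimnames = list(countries, products))
  if (nrow(rec)) {
    agg <- stats::aggregate(tonnes ~ country + product, data = rec, FUN = sum)
    tot[cbind(agg$country, agg$product)] <- agg$tonnes
  }
  W <- tot / pop[countries]
  M <- (tot > 0) + 0L
  storage.mode(M) <- "integer"
  new_bipartite_panel(year, countries, products, M, W)
}

new_bipartite_panel <- function(year, countries, products, M, W) {
  stopifnot(!anyDuplicated(countries), !anyDuplicated(products))
  panel <- structure(list(
    year = as.integer(year),
    countries = countries,
    products = products,
    M = M,
    W = W,
    zero_countries = countries[rowSums(M) == 0],
    zero_products = products[colSums(M) == 0]
  ), class = "bipartite_panel")
  validate_panel(panel)
  panel
}

#' Validate the internal invariants of a bipartite panel
#'
#' Checks that `M` is binary, `W` non-negative, the supports of `M` and
#' `W` coincide, dimensions agree with the label lists, and labels are
#' unique. Errors on the first violation.
#'
#' @param panel A `bipartite_panel`.
#' @return `panel`, invisibly.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "bipartite_panel"))
  M <- panel$M; W <- panel$W
  if (!all(M %in% c(0L, 1L))) stop("M is not binary")
  if (any(W < 0)) stop("W has negative entries")
  if (!identical(dim(M), dim(W))) stop("M and W dimensions differ")
  if (nrow(M) != length(panel$countries) ||
      ncol(M) != length(panel$products)) stop("label/dimension mismatch")
  if (!identical(unname(W > 0), unname(M == 1L))) {
    stop("support mismatch: W > 0 must coincide with M == 1")
  }
  invisible(panel)
}

#' @export
print.bipartite_panel <- function(x, ...) {
  cat(sprintf("bipartite_panel: year %d, %d countries x %d products, %d links (fill %.3f)\n",
              x$year, length(x$countries), length(x$products), sum(x$M),
              mean(x$M)))
  if (length(x$zero_countries) || length(x$zero_products)) {
    cat(sprintf("  all-zero: %d countries, %d products\n",
                length(x$zero_countries), length(x$zero_products)))
  }
  invisible(x)
}

#' Write a panel matrix to labeled text
#'
#' Writes the binary or weighted matrix of a panel either as a dense
#' labeled TSV (first column holds country labels) or as a sparse
#' coordinate-format file with a MatrixMarket-style header. Weighted
#' values are written with 17 significant digits so a write/read
#' round-trip reproduces the matrix bit-exactly.
#'
#' @param panel A `bipartite_panel`.
#' @param path Output file path.
#' @param form `"binary"` (matrix `M`) or `"weighted"` (matrix `W`).
#' @param sparse Write sparse coordinate text instead of dense TSV.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(panel, path, form = c("binary", "weighted"),
                         sparse = FALSE) {
  form <- match.arg(form)
  X <- if (form == "binary") panel$M else panel$W
  fmt <- function(v) {
    if (form == "binary") as.character(as.integer(v)) else sprintf("%.17g", v)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (sparse) {
    nz <- which(X != 0, arr.ind = TRUE)
    writeLines(c("%%MatrixMarket matrix coordinate real general",
                 paste0("% rows: ", paste(panel$countries, collapse = "\t")),
                 paste0("% cols: ", paste(panel$products, collapse = "\t")),
                 paste(nrow(X), ncol(X), nrow(nz))), con)
    if (nrow(nz)) {
      ord <- order(nz[, 1], nz[, 2])
      nz <- nz[ord, , drop = FALSE]
      writeLines(paste(nz[, 1], nz[, 2], fmt(X[nz])), con)
    }
  } else {
    writeLines(paste(c("country", panel$products), collapse = "\t"), con)
    for (i in seq_along(panel$countries)) {
      writeLines(paste(c(panel$countries[i], fmt(X[i, ])), collapse = "\t"),
                 con)
    }
  }
  invisible(path)
}

#' Read a labeled matrix written by [write_matrix()]
#'
#' Handles both the dense labeled TSV and the sparse coordinate format
#' (detected from the MatrixMarket header line).
#'
#' @param path File path.
#' @return A numeric matrix with country row names and product column
#'   names.
#' @export
read_matrix <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "%%MatrixMarket")) {
    lines <- readLines(path)
    rows <- strsplit(sub("^% rows: ?", "", lines[2]), "\t")[[1]]
    cols <- strsplit(sub("^% cols: ?", "", lines[3]), "\t")[[1]]
    dims <- scan(text = lines[4], quiet = TRUE)
    X <- matrix(0, dims[1], dims[2], dimnames = list(rows, cols))
    if (dims[3] > 0) {
      trip <- utils::read.table(text = lines[5:(4 + dims[3])], sep = " ")
      X[cbind(trip[[1]], trip[[2]])] <- trip[[3]]
    }
    return(X)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE, colClasses = "character")
  X <- as.matrix(tab)
  storage.mode(X) <- "double"
  X
}
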