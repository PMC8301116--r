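#' Construct a single NMR spectrum
#'
#' A spectrum is a chemical-shift axis (ppm) paired with an intensity vector.
#' The ppm axis is stored in descending order, following the NMR display
#' convention; ascending input is reversed (together with the intensities).
#'
#' @param ppm Numeric vector of chemical shifts (ppm), strictly monotone.
#' @param intensity Numeric vector of intensities, same length as `ppm`.
#' @param sample_id Sample identifier.
#' @param meta Optional named list of metadata (title, nucleus, ...).
#' @return An object of class `nmr_spectrum` with fields `sample_id`, `ppm`
#'   (descending), `intensity` and `meta`.
#' @export
nmr_spectrum <- function(ppm, intensity, sample_id = "spectrum", meta = list()) {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity))
    stop("ppm and intensity must have equal length (", length(ppm), " vs ",
         length(intensity), ")")
  if (length(ppm) < 2L)
    stop("a spectrum needs at least 2 points")
  if (any(!is.finite(intensity)))
    stop("non-finite intensity at index ", which(!is.finite(intensity))[1L])
  d <- diff(ppm)
  if (any(!is.finite(ppm)) || any(d == 0) || !(all(d > 0) || all(d < 0))) {
    bad <- which(d * sign(d[1L]) <= 0)[1L]
    stop("ppm axis not strictly monotone at index ", bad + 1L)
  }
  if (d[1L] > 0) {        # ascending input: flip to descending
    ppm <- rev(ppm)
    intensity <- rev(intensity)
  }
  structure(list(sample_id = as.character(sample_id), ppm = ppm,
                 intensity = intensity, meta = meta),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s: %d points, %.2f ... %.2f ppm\n",
              x$sample_id, length(x$ppm), x$ppm[1L], x$ppm[length(x$ppm)]))
  invisible(x)
}

#' Read a spectrum from file
#'
#' Supports two plain-text dialects: `"xy-delimited"` (two columns, ppm and
#' intensity, whitespace or comma separated, `#` comments allowed) and
#' `"jcamp-dx"` (the `XYPOINTS=(XY..XY)` and AFFN `XYDATA=(X++(Y..Y))`
#' forms). The returned spectrum always has a descending ppm axis.
#'
#' @param source Path to the file.
#' @param dialect `"xy-delimited"` or `"jcamp-dx"`.
#' @param sample_id Identifier for the spectrum; defaults to the JCAMP TITLE
#'   when present, otherwise the file name.
#' @return An [nmr_spectrum].
#' @export
read_spectrum <- function(source, dialect = c("xy-delimited", "jcamp-dx"),
                          sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(source)) stop("cannot read '", source, "': no such file")
  lines <- readLines(source, warn = FALSE)
  if (dialect == "xy-delimited") {
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) < 2L) stop("'", source, "': fewer than 2 data lines")
    parts <- strsplit(lines, "[,;[:space:]]+")
    n_tok <- lengths(parts)
    if (any(n_tok < 2L))
      stop("'", source, "': line ", which(n_tok < 2L)[1L], " has fewer than 2 fields")
    ppm <- as.numeric(vapply(parts, `[[`, "", 1L))
    intensity <- as.numeric(vapply(parts, `[[`, "", 2L))
    if (anyNA(ppm) || anyNA(intensity))
      stop("'", source, "': non-numeric field")
    if (is.null(sample_id))
      sample_id <- sub("\\.[^.]*$", "", basename(source))
    return(nmr_spectrum(ppm, intensity, sample_id = sample_id))
  }
  parse_jcamp(lines, source, sample_id)
}

# Minimal JCAMP-DX parser: XYPOINTS=(XY..XY) pairs or AFFN XYDATA=(X++(Y..Y)).
parse_jcamp <- function(lines, source, sample_id = NULL) {
  get_field <- function(name) {
    hit <- grep(paste0("^##", name, "="), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(paste0("^##", name, "="), "", hit[1L]))
  }
  title <- get_field("TITLE")
  nucleus <- get_field("\\.OBSERVE NUCLEUS")
  xfac <- as.numeric(get_field("XFACTOR") %||% "1")
  yfac <- as.numeric(get_field("YFACTOR") %||% "1")

  i_xy <- grep("^##(XYPOINTS|XYDATA)=", lines)
  if (!length(i_xy)) stop("'", source, "': no XYPOINTS/XYDATA block")
  i_xy <- i_xy[1L]
  is_tabular <- grepl("X\\+\\+\\(Y\\.\\.Y\\)", lines[i_xy])
  i_end <- grep("^##END", lines)
  i_end <- if (length(i_end)) min(i_end[i_end > i_xy]) else length(lines) + 1L
  body <- lines[seq(i_xy + 1L, i_end - 1L)]
  body <- trimws(body[nzchar(trimws(body))])
  if (!length(body)) stop("'", source, "': empty data block")

  if (is_tabular) {
    # each line: X Y1 Y2 ... ; X of subsequent Ys advances by the implied step
    firstx <- as.numeric(get_field("FIRSTX"))
    lastx <- as.numeric(get_field("LASTX"))
    npt <- as.numeric(get_field("NPOINTS"))
    toks <- strsplit(body, "[[:space:]]+")
    ys <- unlist(lapply(toks, function(tk) as.numeric(tk[-1L])))
    if (anyNA(ys)) stop("'", source, "': non-numeric Y value in XYDATA")
    if (is.na(npt)) npt <- length(ys)
    if (length(ys) != npt)
      stop("'", source, "': NPOINTS=", npt, " but ", length(ys), " Y values")
    ppm <- seq(firstx, lastx, length.out = npt) * xfac
    intensity <- ys * yfac
  } else {
    toks <- unlist(strsplit(body, "[,;[:space:]]+"))
    toks <- toks[nzchar(toks)]
    vals <- as.numeric(toks)
    if (anyNA(vals)) stop("'", source, "': non-numeric value in XYPOINTS")
    if (length(vals) %% 2L != 0L)
      stop("'", source, "': odd number of values in XYPOINTS")
    ppm <- vals[seq(1L, length(vals), by = 2L)] * xfac
    intensity <- vals[seq(2L, length(vals), by = 2L)] * yfac
  }
  meta <- list()
  if (!is.null(title)) meta$title <- title
  if (!is.null(nucleus)) meta$nucleus <- nucleus
  if (is.null(sample_id))
    sample_id <- title %||% sub("\\.[^.]*$", "", basename(source))
  nmr_spectrum(ppm, intensity, sample_id = sample_id, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a spectrum to file
#'
#' Values are written with 17 significant digits so that a read/write
#' round-trip is lossless to within double-precision representation.
#'
#' @param s An [nmr_spectrum].
#' @param sink Output file path.
#' @param dialect `"xy-delimited"` or `"jcamp-dx"`.
#' @export
write_spectrum <- function(s, sink, dialect = c("xy-delimited", "jcamp-dx")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(s, "nmr_spectrum"))
  # revalidate: objects may have been edited after construction
  nmr_spectrum(s$ppm, s$intensity, s$sample_id %||% "spectrum")
  num <- function(v) sprintf("%.17g", v)
  if (dialect == "xy-delimited") {
    out <- paste(num(s$ppm), num(s$intensity))
  } else {
    out <- c(
      paste0("##TITLE=", s$meta$title %||% s$sample_id),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=NMR SPECTRUM",
      paste0("##.OBSERVE NUCLEUS=", s$meta$nucleus %||% "^13C"),
      "##XUNITS=PPM",
      "##YUNITS=ARBITRARY UNITS",
      paste0("##NPOINTS=", length(s$ppm)),
      paste0("##FIRSTX=", num(s$ppm[1L])),
      paste0("##LASTX=", num(s$ppm[length(s$ppm)])),
      "##XYPOINTS=(XY..XY)",
      paste0(num(s$ppm), ", ", num(s$intensity)),
      "##END="
    )
  }
  ok <- tryCatch({ writeLines(out, sink); TRUE },
                 error = function(e) stop("cannot write '", sink, "': ",
                                          conditionMessage(e)))
  invisible(ok)
}

#' Assemble spectra into a samples-by-ppm matrix
#'
#' All spectra are linearly interpolated onto a shared descending ppm grid.
#' With `grid = "intersection"` the grid of the input spectrum with the most
#' points is used, restricted to the ppm span common to all spectra. Grid
#' points outside a spectrum's own span are an error — no extrapolation.
#'
#' @param spectra List of [nmr_spectrum] objects (>= 2, unique sample ids).
#' @param grid Numeric ppm vector, or `"intersection"`.
#' @return A `spectra_matrix`: list with `sample_ids`, `grid` (descending ppm)
#'   and `X` (n x p intensity matrix, rows in input order).
#' @export
assemble_matrix <- function(spectra, grid = "intersection") {
  if (length(spectra) < 2L) stop("need at least 2 spectra")
  stopifnot(all(vapply(spectra, inherits, TRUE, "nmr_spectrum")))
  ids <- vapply(spectra, `[[`, "", "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample_ids: ", ids[duplicated(ids)][1L])
  his <- vapply(spectra, function(s) max(s$ppm), 0)
  los <- vapply(spectra, function(s) min(s$ppm), 0)
  hi <- min(his); lo <- max(los)
  if (hi <= lo) stop("spectra have disjoint ppm ranges")
  if (identical(grid, "intersection")) {
    densest <- spectra[[which.max(vapply(spectra, function(s) length(s$ppm), 0L))]]
    grid <- densest$ppm[densest$ppm <= hi & densest$ppm >= lo]
  }
  grid <- as.numeric(grid)
  if (length(grid) < 2L) stop("grid has fewer than 2 points")
  if (is.unsorted(rev(grid), strictly = TRUE)) grid <- sort(grid, decreasing = TRUE)
  if (max(grid) > hi + 1e-9 || min(grid) < lo - 1e-9)
    stop("grid extends beyond the common ppm span [", signif(lo, 6), ", ",
         signif(hi, 6), "]; extrapolation is not performed")
  X <- t(vapply(spectra, function(s) {
    stats::approx(s$ppm, s$intensity, xout = grid, rule = 1)$y
  }, numeric(length(grid))))
  if (anyNA(X)) stop("interpolation produced missing values")
  dimnames(X) <- list(ids, NULL)
  structure(list(sample_ids = ids, grid = grid, X = X),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix> %d samples x %d points, %.2f ... %.2f ppm\n",
              nrow(x$X), ncol(x$X), x$grid[1L], x$grid[length(x$grid)]))
  invisible(x)
}

# internal constructor used by transforms: reuse ids/grid, swap X
spectra_matrix_like <- function(template, X) {
  structure(list(sample_ids = template$sample_ids, grid = template$grid, X = X),
            class = "spectra_matrix")
}

#' Write / read a spectra matrix as CSV
#'
#' The header row carries the ppm grid; each subsequent row is one sample
#' (first column = sample id).
#'
#' @param m A `spectra_matrix`.
#' @param sink,source File path.
#' @return `read_matrix_csv` returns a `spectra_matrix`.
#' @export
write_matrix_csv <- function(m, sink) {
  stopifnot(inherits(m, "spectra_matrix"))
  hdr <- paste(c("sample_id", sprintf("%.17g", m$grid)),
               collapse = ",")
  rows <- vapply(seq_len(nrow(m$X)), function(i) {
    paste(c(m$sample_ids[i], sprintf("%.17g", m$X[i, ])),
          collapse = ",")
  }, "")
  writeLines(c(hdr, rows), sink)
  invisible(TRUE)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(source) {
  lines <- readLines(source, warn = FALSE)
  if (length(lines) < 3L) stop("'", source, "': need header + >= 2 samples")
  hdr <- strsplit(lines[1L], ",")[[1L]]
  grid <- as.numeric(hdr[-1L])
  if (anyNA(grid)) stop("'", source, "': non-numeric ppm in header")
  cells <- strsplit(lines[-1L], ",")
  ids <- vapply(cells, `[[`, "", 1L)
  X <- t(vapply(cells, function(ce) as.numeric(ce[-1L]), numeric(length(grid))))
  if (anyNA(X)) stop("'", source, "': non-numeric intensity")
  dimnames(X) <- list(ids, NULL)
  structure(list(sample_ids = ids, grid = grid, X = X),
            class = "spectra_matrix")
}

#' Load a reference table of pollen properties
#'
#' Reads a CSV with one row per sample and the ten property columns
#' `tp` (mg GAE/g), `abts` (uM TE/g), `reducing_sugars`, `protein`, `fat`,
#' `nhcs`, `c`, `n`, `s` (all %), and `ph`. The default is the packaged
#' 35-sample bee pollen table. Invariants validated on load: all values
#' positive; protein equals 6.25 x N within 0.006 (Kjeldahl conversion at
#' two-decimal print precision); NHCS sum at least C + N + S.
#'
#' @param source CSV path; default = packaged fixture.
#' @return A data.frame of class `reference_table` with a `sample_id` column
#'   (character) and the ten numeric property columns.
#' @export
load_reference_table <- function(source = system.file("extdata",
                                                      "table1_bee_pollen.csv",
                                                      package = "nmrcal")) {
  d <- utils::read.csv(source, check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("sample_id", reference_properties())
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("reference table missing column(s): ", paste(miss, collapse = ", "))
  d$sample_id <- as.character(d$sample_id)
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample_id: ", d$sample_id[duplicated(d$sample_id)][1L])
  validate_reference_table(d)
  class(d) <- c("reference_table", "data.frame")
  d
}

#' Property columns of a reference table
#' @return Character vector of the ten property column names.
#' @export
reference_properties <- function() {
  c("tp", "abts", "reducing_sugars", "protein", "fat",
    "nhcs", "c", "n", "s", "ph")
}

validate_reference_table <- function(d) {
  for (p in reference_properties()) {
    v <- d[[p]]
    if (!is.numeric(v) || anyNA(v))
      stop("column '", p, "' must be numeric without missing values")
    if (any(v <= 0))
      stop("row ", which(v <= 0)[1L], ": property '", p, "' must be positive")
  }
  kj <- abs(d$protein - 6.25 * d$n)
  if (any(kj > 0.006))
    stop("row ", which(kj > 0.006)[1L],
         ": protein is not 6.25 x N within 0.006 (Kjeldahl conversion)")
  hs <- d$nhcs - (d$c + d$n + d$s)
  if (any(hs < 0))
    stop("row ", which(hs < 0)[1L],
         ": NHCS sum below C + N + S (negative hydrogen share)")
  invisible(TRUE)
}
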