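#' Write a spectra set as wide CSV
#'
#' Dialect: header `sample_id,replicate,<lambda1>,...,<lambdaP>` with
#' wavelengths printed to 2 decimals; one row per spectrum; UTF-8, comma
#' separators, `.` decimal mark. Absorbances are written with 12 significant
#' digits so a write/read round trip is lossless at that precision.
#'
#' @param spectra A `spectra_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_set"))
  header <- c("sample_id", "replicate", sprintf("%.2f", spectra$wavelengths))
  vals <- apply(spectra$absorbance, 1, function(r) {
    paste(sprintf("%.12g", r), collapse = ",")
  })
  lines <- c(paste(header, collapse = ","),
             paste(spectra$sample_id, spectra$replicate, vals, sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a spectra set from wide CSV
#'
#' Parses the dialect written by [write_spectra()]; wavelengths come from the
#' header. Ragged rows, non-numeric cells and non-monotone wavelength headers
#' are rejected with the offending row/column named.
#'
#' @param path Input CSV file.
#' @return A `spectra_set`.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2) stop("parse error: no spectra rows")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 4 || header[1] != "sample_id" || header[2] != "replicate") {
    stop("parse error: header must start with sample_id,replicate and >= 2 wavelengths")
  }
  wl <- suppressWarnings(as.numeric(header[-(1:2)]))
  if (anyNA(wl)) {
    stop(sprintf("parse error: non-numeric wavelength in header column %d",
                 which(is.na(wl))[1] + 2L))
  }
  if (any(diff(wl) <= 0)) {
    stop("parse error: header wavelengths must be strictly increasing")
  }
  p <- length(wl)
  n <- length(lines) - 1L
  A <- matrix(NA_real_, n, p)
  sample_id <- character(n)
  replicate <- integer(n)
  for (i in seq_len(n)) {
    cells <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1]]
    if (length(cells) != p + 2L) {
      stop(sprintf("parse error: row %d has %d fields, expected %d",
                   i, length(cells), p + 2L))
    }
    v <- suppressWarnings(as.numeric(cells[-(1:2)]))
    if (anyNA(v)) {
      stop(sprintf("parse error: non-numeric absorbance at row %d, column %d",
                   i, which(is.na(v))[1] + 2L))
    }
    sample_id[i] <- cells[1]
    replicate[i] <- as.integer(cells[2])
    A[i, ] <- v
  }
  rownames(A) <- sprintf("%s_r%d", sample_id, replicate)
  structure(list(wavelengths = wl, absorbance = A,
                 sample_id = sample_id, replicate = replicate),
            class = "spectra_set")
}

#' Write a reference table as CSV
#' @param refs A `reference_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reference_table <- function(refs, path) {
  stopifnot(is.data.frame(refs))
  out <- refs
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.12g", x))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference table from CSV
#' @param path CSV with columns `sample_id`, `power_density_W_per_L`,
#'   `time_min`, `SH_umol_g`, `SS_umol_g`.
#' @return A `reference_table` data frame.
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  refs <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "power_density_W_per_L", "time_min",
            "SH_umol_g", "SS_umol_g")
  miss <- setdiff(need, names(refs))
  if (length(miss)) {
    stop(sprintf("parse error: missing columns: %s", paste(miss, collapse = ", ")))
  }
  if (any(refs$SH_umol_g <= 0) || any(refs$SS_umol_g <= 0)) {
    stop("parse error: SH and SS must be > 0")
  }
  key <- paste(refs$power_density_W_per_L, refs$time_min)
  if (anyDuplicated(key)) {
    stop("parse error: duplicated (power density, time) pair")
  }
  class(refs) <- c("reference_table", "data.frame")
  refs
}

#' Align spectra with reference chemistry into a modeling dataset
#'
#' Joins a `spectra_set` with its `reference_table`. By default the replicate
#' spectra of each sample are averaged so the dataset has one row per
#' chemistry value (the calibration is over samples, not replicate spectra);
#' with `average_replicates = FALSE` the reference values are repeated per
#' replicate instead.
#'
#' @param spectra A `spectra_set`.
#' @param refs A `reference_table`; every `sample_id` present in `spectra`
#'   must appear here.
#' @param average_replicates Average replicate spectra per sample (default).
#' @return A `nir_dataset`: list with `X` (matrix), `y_SH`, `y_SS`,
#'   `wavelengths`, `meta` (one row per row of `X`).
#' @export
build_dataset <- function(spectra, refs, average_replicates = TRUE) {
  stopifnot(inherits(spectra, "spectra_set"), is.data.frame(refs))
  missing_ids <- setdiff(unique(spectra$sample_id), refs$sample_id)
  if (length(missing_ids)) {
    stop(sprintf("alignment error: sample ids missing from reference table: %s",
                 paste(missing_ids, collapse = ", ")))
  }
  keep <- refs$sample_id %in% spectra$sample_id
  refs <- refs[keep, , drop = FALSE]
  if (average_replicates) {
    X <- matrix(0, nrow(refs), ncol(spectra$absorbance))
    for (i in seq_len(nrow(refs))) {
      rows <- spectra$sample_id == refs$sample_id[i]
      X[i, ] <- colMeans(spectra$absorbance[rows, , drop = FALSE])
    }
    rownames(X) <- refs$sample_id
    meta <- refs[, c("sample_id", "power_density_W_per_L", "time_min")]
    y_sh <- refs$SH_umol_g
    y_ss <- refs$SS_umol_g
  } else {
    idx <- match(spectra$sample_id, refs$sample_id)
    X <- spectra$absorbance
    meta <- cbind(refs[idx, c("sample_id", "power_density_W_per_L", "time_min")],
                  replicate = spectra$replicate)
    y_sh <- refs$SH_umol_g[idx]
    y_ss <- refs$SS_umol_g[idx]
  }
  rownames(meta) <- NULL
  structure(
    list(X = X, y_SH = y_sh, y_SS = y_ss,
         wavelengths = spectra$wavelengths, meta = meta),
    class = "nir_dataset"
  )
}

#' @export
print.nir_dataset <- function(x, ...) {
  cat(sprintf("<nir_dataset> %d samples x %d channels (%.1f-%.1f nm)\n",
              nrow(x$X), ncol(x$X), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}
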