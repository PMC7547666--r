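#' Construct a spectra dataset
#'
#' Bundles an absorbance matrix with its wavenumber axis and per-sample
#' reference concentrations. This is the universal input object consumed by
#' every wavelength-selection method in the package.
#'
#' @param wavenumbers Numeric vector of length `p`, strictly increasing, in
#'   reciprocal centimetres.
#' @param absorbance Numeric `n x p` matrix of absorbance values; row `i` is
#'   the spectrum of sample `i`.
#' @param concentration Numeric vector of length `n` of reference analyte
#'   concentrations (mmol/L), all non-negative.
#' @param sample_ids Character vector of length `n` of sample identifiers.
#'   Defaults to `"s1" ... "sn"`.
#'
#' @return An object of class `spectra_dataset`: a list with elements
#'   `wavenumbers`, `absorbance`, `concentration`, `sample_ids`.
#' @examples
#' ds <- spectra_dataset(c(1000, 1001), matrix(runif(6), 3), c(0, 1, 2))
#' ds
#' @export
spectra_dataset <- function(wavenumbers, absorbance, concentration,
                            sample_ids = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- assert_matrix(absorbance, "absorbance")
  concentration <- as.numeric(concentration)
  p <- length(wavenumbers)
  n <- length(concentration)
  if (p < 2L || n < 2L)
    stop("a spectra_dataset needs at least 2 samples and 2 wavenumbers",
         call. = FALSE)
  if (anyNA(wavenumbers) || anyNA(concentration))
    stop("missing values are not allowed", call. = FALSE)
  if (any(diff(wavenumbers) <= 0))
    stop("`wavenumbers` must be strictly increasing", call. = FALSE)
  if (any(concentration < 0))
    stop("`concentration` must be non-negative", call. = FALSE)
  if (nrow(absorbance) != n || ncol(absorbance) != p)
    stop(sprintf("`absorbance` must be %d x %d to match concentration and wavenumbers",
                 n, p), call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n)
    stop("`sample_ids` must have one entry per sample", call. = FALSE)
  dimnames(absorbance) <- NULL
  structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance,
         concentration = concentration, sample_ids = sample_ids),
    class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf("spectra_dataset: %d samples x %d wavenumbers (%.6g-%.6g cm-1)\n",
              length(x$concentration), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  cat(sprintf("  concentration range: %.6g-%.6g mmol/L\n",
              min(x$concentration), max(x$concentration)))
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$absorbance)

# CSV dialect: header `sample_id,concentration_mmol_L,<wn1>,<wn2>,...`,
# one row per sample, UTF-8, numeric fields printed to 10 significant digits.

#' Read a spectra dataset from CSV
#'
#' The expected layout is one header row
#' `sample_id,concentration_mmol_L,<wn1>,<wn2>,...` where `<wnK>` are
#' wavenumbers in reciprocal centimetres, followed by one row per sample.
#'
#' @param path Path to the CSV file.
#' @return A [spectra_dataset].
#' @seealso [write_spectra_csv()]
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) < 2L || ncol(raw) < 4L)
    stop("malformed spectra CSV: need a header plus >= 2 samples and >= 2 wavenumber columns",
         call. = FALSE)
  header <- as.character(raw[1L, ])
  if (header[1L] != "sample_id" || header[2L] != "concentration_mmol_L")
    stop("malformed header: expected columns `sample_id,concentration_mmol_L,...`",
         call. = FALSE)
  wn <- suppressWarnings(as.numeric(header[-(1:2)]))
  if (anyNA(wn))
    stop(sprintf("non-numeric wavenumber in header column %d",
                 2L + which(is.na(wn))[1L]), call. = FALSE)
  if (anyDuplicated(wn))
    stop(sprintf("duplicated wavenumber in header: %g",
                 wn[duplicated(wn)][1L]), call. = FALSE)
  if (any(diff(wn) <= 0))
    stop("wavenumber header is not strictly increasing", call. = FALSE)
  body <- raw[-1L, , drop = FALSE]
  num <- suppressWarnings(
    vapply(seq_len(ncol(body) - 1L) + 1L,
           function(j) as.numeric(body[[j]]), numeric(nrow(body))))
  num <- matrix(num, nrow = nrow(body))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at data row %d, column %d",
                 bad[1L], bad[2L] + 1L), call. = FALSE)
  }
  spectra_dataset(wavenumbers = wn,
                  absorbance = num[, -1L, drop = FALSE],
                  concentration = num[, 1L],
                  sample_ids = body[[1L]])
}

fmt10 <- function(x) formatC(x, digits = 10, format = "g", width = 1)

#' Write a spectra dataset to CSV
#'
#' Numeric values are printed to 10 significant digits, which is lossless for
#' absorbance and concentration magnitudes in this domain; a write/read
#' round trip reproduces the dataset exactly at that precision.
#'
#' @param ds A [spectra_dataset].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_spectra_csv <- function(ds, path) {
  stopifnot(inherits(ds, "spectra_dataset"))
  header <- paste(c("sample_id", "concentration_mmol_L", fmt10(ds$wavenumbers)),
                  collapse = ",")
  rows <- vapply(seq_along(ds$concentration), function(i) {
    paste(c(ds$sample_ids[i], fmt10(ds$concentration[i]),
            fmt10(ds$absorbance[i, ])), collapse = ",")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, useBytes = TRUE)
  invisible(path)
}

# splits -------------------------------------------------------------------

# Draw one index per block from the concentration-sorted sample order using
# the current RNG stream. Blocks are contiguous after sorting; sizes differ
# by at most one with larger blocks first; concentration ties break by
# ascending original index.
block_split_ <- function(concentration, n_v) {
  n <- length(concentration)
  ord <- order(concentration, seq_len(n))
  base <- n %/% n_v
  extra <- n %% n_v
  sizes <- rep(base, n_v)
  if (extra > 0L) sizes[seq_len(extra)] <- base + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-n_v] + 1L)
  val <- integer(n_v)
  for (b in seq_len(n_v)) {
    block <- ord[starts[b]:ends[b]]
    val[b] <- if (length(block) == 1L) block else block[sample.int(length(block), 1L)]
  }
  list(calibration = sort(setdiff(seq_len(n), val)), validation = sort(val))
}

#' Block-stratified calibration/validation split
#'
#' Samples are sorted by concentration and partitioned into `n_v` contiguous
#' blocks whose sizes differ by at most one (larger blocks first); one index
#' is drawn uniformly at random from each block into the validation set. This
#' guarantees the validation set spans the calibration range, which matters
#' when only tens of samples are available.
#'
#' @param concentration Numeric vector of reference concentrations.
#' @param n_v Number of validation samples (= number of blocks), `1 <= n_v <= n`.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A `split_indices` object: list with sorted integer vectors
#'   `calibration` and `validation` (1-based indices into the input).
#' @examples
#' block_stratified_split(c(5, 1, 3, 2, 6, 4), n_v = 2, seed = 1)
#' @export
block_stratified_split <- function(concentration, n_v, seed) {
  n <- length(concentration)
  n_v <- assert_count(n_v, "n_v")
  if (n_v > n) stop("`n_v` cannot exceed the number of samples", call. = FALSE)
  s <- with_seed(seed, block_split_(concentration, n_v))
  structure(s, class = "split_indices")
}

#' Representative held-out test split
#'
#' Identical mechanics to [block_stratified_split()]: the returned
#' `validation` component is the test set, chosen so that its `n_t` samples
#' are spread across the concentration range. The test set is intended to be
#' held out from all selection and cross-validation steps.
#'
#' @param ds A [spectra_dataset].
#' @param n_t Test-set size.
#' @param seed Integer seed.
#' @return A `split_indices` object; `validation` holds the test indices.
#' @export
representative_test_split <- function(ds, n_t, seed) {
  stopifnot(inherits(ds, "spectra_dataset"))
  s <- block_stratified_split(ds$concentration, n_t, seed)
  if (length(s$calibration) == 0L)
    warning("test split consumed every sample; calibration set is empty")
  s
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("split_indices: %d calibration / %d validation\n",
              length(x$calibration), length(x$validation)))
  invisible(x)
}

#' Serialize split indices to JSON
#'
#' Indices are written 0-based for interoperability with external tooling;
#' [read_split_json()] restores the 1-based R representation.
#'
#' @param split A `split_indices` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_split_json <- function(split, path) {
  stopifnot(inherits(split, "split_indices"))
  jsonlite::write_json(
    list(calibration = split$calibration - 1L,
         validation = split$validation - 1L),
    path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_split_json
#' @export
read_split_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(calibration = as.integer(x$calibration) + 1L,
                 validation = as.integer(x$validation) + 1L),
            class = "split_indices")
}
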