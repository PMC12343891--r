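#' Build a unit-scale event matrix
#'
#' Applies per-dimension display transforms to a raw event table, censors
#' events with any retained value outside the closed interval `[0, 1]` (or
#' any non-finite value), and attaches the dimension metadata that the
#' gating engine needs: which dimensions are phenotyping dimensions and
#' which transform produced each column.
#'
#' Censoring is row-wise: an event is dropped if any of its declared
#' dimensions is out of range, and the number of dropped events is recorded
#' in the `n_censored` attribute, so that `nrow(result) + n_censored(result)`
#' equals the input row count.
#'
#' @param data A data frame or matrix of events (rows) by dimensions
#'   (columns). Columns not named in `transforms`/`phenotyping` are dropped.
#' @param phenotyping Character vector of dimension names to flag as
#'   phenotyping dimensions, or a named logical vector. Default: all
#'   dimensions.
#' @param transforms Named list of [transform_spec()] objects, one per
#'   dimension to retain. Default: identity (`"none"`) for every column,
#'   i.e. the data are declared already transformed.
#' @param source Optional provenance string (file path).
#'
#' @return An `epp_events` tibble with attributes `phenotyping` (named
#'   logical), `n_censored`, `transforms`, and `provenance`.
#' @examples
#' ev <- as_event_matrix(data.frame(a = runif(10), b = runif(10)))
#' n_censored(ev)
#' @export
as_event_matrix <- function(data, phenotyping = NULL, transforms = NULL,
                            source = NULL) {
  data <- as.data.frame(data)
  if (is.null(transforms)) {
    dims <- colnames(data)
    transforms <- stats::setNames(
      replicate(length(dims), transform_spec("none"), simplify = FALSE), dims)
  } else {
    dims <- names(transforms)
    missing <- setdiff(dims, colnames(data))
    if (length(missing))
      stop("configured dimension(s) not present in data: ",
           paste(missing, collapse = ", "))
  }
  if (is.null(phenotyping)) {
    pheno <- stats::setNames(rep(TRUE, length(dims)), dims)
  } else if (is.logical(phenotyping)) {
    stopifnot(!is.null(names(phenotyping)))
    pheno <- stats::setNames(rep(FALSE, length(dims)), dims)
    pheno[names(phenotyping)] <- phenotyping
  } else {
    missing <- setdiff(phenotyping, dims)
    if (length(missing))
      stop("phenotyping dimension(s) not declared: ",
           paste(missing, collapse = ", "))
    pheno <- stats::setNames(dims %in% phenotyping, dims)
  }
  vals <- vapply(dims, function(d) transform_values(data[[d]], transforms[[d]]),
                 numeric(nrow(data)))
  if (nrow(data) == 1L) vals <- matrix(vals, nrow = 1,
                                       dimnames = list(NULL, dims))
  keep <- rowSums(!is.finite(vals) | vals < 0 | vals > 1) == 0
  out <- tibble::as_tibble(as.data.frame(vals[keep, , drop = FALSE]))
  structure(out,
            class = c("epp_events", class(out)),
            phenotyping = pheno,
            n_censored = sum(!keep),
            transforms = transforms,
            provenance = source %||% "in-memory")
}

#' @rdname as_event_matrix
#' @param events An `epp_events` object.
#' @export
n_censored <- function(events) attr(events, "n_censored") %||% 0L

#' @rdname as_event_matrix
#' @export
phenotyping_dims <- function(events) {
  ph <- attr(events, "phenotyping")
  if (is.null(ph)) colnames(events) else names(ph)[ph]
}

#' @export
print.epp_events <- function(x, ...) {
  cat(sprintf("<epp_events> %d events x %d dimensions (%d phenotyping), %d censored\n",
              nrow(x), ncol(x), length(phenotyping_dims(x)), n_censored(x)))
  NextMethod()
}

#' Read cytometry events from a file
#'
#' Reads an FCS 3.0/3.1 file or a delimited text file (CSV/TSV with a header
#' row), applies the configured display transforms and censoring, and
#' returns an `epp_events` matrix. Input is assumed already compensated or
#' unmixed and pre-gated to live single cells.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"fcs"`, or `"delimited"`.
#' @param dim_config A data frame (or path to a JSON/YAML file, see
#'   [read_dim_config()]) with one row per dimension to retain and columns
#'   `name`, `phenotyping` (logical), `kind` (`"logicle"`, `"mass_logicle"`,
#'   `"none"`), and optionally `decades`, `width`, `top`. If omitted, all
#'   columns are taken as already-transformed phenotyping dimensions.
#' @return An `epp_events` tibble; see [as_event_matrix()].
#' @export
read_events <- function(path, format = c("auto", "fcs", "delimited"),
                        dim_config = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read events: no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "delimited"
  raw <- if (format == "fcs") read_fcs(path)$data else {
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  }
  if (is.character(dim_config)) dim_config <- read_dim_config(dim_config)
  if (is.null(dim_config)) {
    return(as_event_matrix(raw, source = path))
  }
  dim_config <- as.data.frame(dim_config)
  tr <- lapply(seq_len(nrow(dim_config)), function(i) {
    row <- dim_config[i, ]
    kind <- row$kind %||% "none"
    if (kind %in% c("none", "none-precomputed")) transform_spec("none")
    else transform_spec(kind,
                        decades = if (!is.null(row$decades) && is.finite(row$decades)) row$decades else NULL,
                        width_w = if (!is.null(row$width) && is.finite(row$width)) row$width else NULL,
                        top_of_scale = if (!is.null(row$top) && is.finite(row$top)) row$top else 262144)
  })
  names(tr) <- dim_config$name
  pheno <- dim_config$name[as.logical(dim_config$phenotyping %||% TRUE)]
  as_event_matrix(raw, phenotyping = pheno, transforms = tr, source = path)
}

#' Read a dimension configuration file
#'
#' JSON (or YAML, if the `yaml` package is installed) file holding an array
#' of per-dimension records with keys `name`, `phenotyping`, `kind`,
#' `decades`, `width`, `top`. Missing optional keys fall back to the
#' transform defaults.
#'
#' @param path Path to the configuration file.
#' @return A data frame suitable for the `dim_config` argument of
#'   [read_events()].
#' @export
read_dim_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configuration requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.data.frame(cfg)) cfg <- dplyr::bind_rows(lapply(cfg, tibble::as_tibble))
  stopifnot("name" %in% names(cfg))
  if (is.null(cfg$phenotyping)) cfg$phenotyping <- TRUE
  if (is.null(cfg$kind)) cfg$kind <- "none"
  for (col in c("decades", "width", "top"))
    if (is.null(cfg[[col]])) cfg[[col]] <- NA_real_
  cfg
}

#' Minimal FCS 3.0/3.1 reader
#'
#' Parses the HEADER and TEXT segments and reads list-mode DATA in float
#' (`$DATATYPE F`), double (`D`), or unsigned integer (`I`) encoding. This
#' covers the standard output of current acquisition software for
#' compensated/unmixed exports; analysis segments and multi-dataset files
#' are ignored.
#'
#' @param path Path to an FCS file.
#' @return A list with `data` (numeric matrix, events x parameters, columns
#'   named from `$PnN`) and `keywords` (named character vector).
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version: ", version)
  off <- function(a, b) suppressWarnings(as.integer(trimws(substr(header, a, b))))
  text_beg <- off(11, 18); text_end <- off(19, 26)
  data_beg <- off(27, 34); data_end <- off(35, 42)
  seek(con, text_beg)
  txt <- rawToChar(readBin(con, "raw", text_end - text_beg + 1))
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        toupper(trimws(parts[seq(1, length(parts), 2)])))
  if (identical(kw[["$MODE"]], "C") || identical(kw[["$MODE"]], "U"))
    stop("only list-mode ($MODE L) FCS data is supported")
  npar <- as.integer(kw[["$PAR"]]); ntot <- as.integer(kw[["$TOT"]])
  dtype <- kw[["$DATATYPE"]]
  byteord <- kw[["$BYTEORD"]]
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  if (is.na(data_beg) || data_beg == 0) data_beg <- as.integer(kw[["$BEGINDATA"]])
  seek(con, data_beg)
  n_values <- npar * ntot
  vals <- switch(dtype,
    F = readBin(con, "numeric", n_values, size = 4, endian = endian),
    D = readBin(con, "numeric", n_values, size = 8, endian = endian),
    I = {
      bits <- as.integer(kw[[paste0("$P", 1, "B")]])
      stopifnot(all(vapply(seq_len(npar), function(i)
        as.integer(kw[[paste0("$P", i, "B")]]), 1L) == bits))
      readBin(con, "integer", n_values, size = bits / 8, endian = endian,
              signed = bits > 16)
    },
    stop("unsupported $DATATYPE: ", dtype))
  mat <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE)
  colnames(mat) <- vapply(seq_len(npar), function(i)
    kw[[paste0("$P", i, "N")]] %||% paste0("P", i), "")
  list(data = mat, keywords = kw)
}
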