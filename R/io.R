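#' Read unit-interval values from a text file
#'
#' Accepts either a plain list (one number per line, no header) or a TSV
#' with a header row, in which case `column` selects the column by name
#' or index.  Values exactly 0 and 1 are valid input -- handling them is
#' the point of the fitting algorithm.  Non-numeric cells and values
#' outside `[0, 1]` are reported with their line numbers.
#'
#' @param path File path.
#' @param column Optional column name or index for TSV input.  When
#'   omitted, the file is treated as a plain value list.
#' @return Numeric vector of values in `[0, 1]`.
#' @export
read_values <- function(path, column = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(column)) {
    lines <- readLines(path)
    keep <- nzchar(trimws(lines))
    idx <- which(keep)
    vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
    if (anyNA(vals)) {
      stop("non-numeric value on line(s): ",
           paste(idx[is.na(vals)], collapse = ", "), call. = FALSE)
    }
    line_no <- idx
  } else {
    tab <- utils::read.delim(path, check.names = FALSE)
    if (is.character(column) && !column %in% names(tab)) {
      stop("no column named '", column, "' in ", path, call. = FALSE)
    }
    raw <- tab[[column]]
    vals <- suppressWarnings(as.numeric(raw))
    if (anyNA(vals)) {
      stop("non-numeric value on line(s): ",
           paste(which(is.na(vals)) + 1L, collapse = ", "), call. = FALSE)
    }
    line_no <- seq_along(vals) + 1L
  }
  bad <- vals < 0 | vals > 1
  if (any(bad)) {
    stop("value(s) outside [0, 1] on line(s): ",
         paste(line_no[bad], collapse = ", "), call. = FALSE)
  }
  vals
}

MODEL_SCHEMA <- "betamix-model/1"
FMT <- "%.17g"  # lossless double round-trip

#' Write / read a mixture model file
#'
#' Models are serialized as human-readable structured text: a schema
#' line, one `component:` line per component holding (pi, alpha, beta)
#' with 17 significant digits (lossless for doubles), and optional
#' `meta.*` key-value lines for fit metadata (iterations, convergence,
#' KS distance/p-value, seed, initialization, dropped components...).
#' write -> read -> write is byte-identical.
#'
#' @param model A [beta_mixture()] object.
#' @param path File path.
#' @param meta Named list of scalar metadata values.
#' @return `read_model()`: a list with `model` (a [beta_mixture()]) and
#'   `meta` (named character list).  `write_model()`: `path`,
#'   invisibly.
#' @export
write_model <- function(model, path, meta = list()) {
  stopifnot(inherits(model, "beta_mixture"))
  lines <- c(
    paste0("schema: ", MODEL_SCHEMA),
    paste0("components: ", model$c),
    sprintf(paste("component:", FMT, FMT, FMT),
            model$weights, model$alpha, model$beta)
  )
  if (length(meta)) {
    keys <- names(meta)
    vals <- vapply(meta, function(v) {
      if (is.numeric(v)) sprintf(FMT, v) else as.character(v)
    }, character(1))
    lines <- c(lines, paste0("meta.", keys, ": ", vals))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "schema: ")) {
    stop("not a model file (missing schema line): ", path, call. = FALSE)
  }
  schema <- sub("^schema: ", "", lines[1L])
  if (schema != MODEL_SCHEMA) {
    stop("unsupported model schema '", schema, "' (expected ",
         MODEL_SCHEMA, ")", call. = FALSE)
  }
  comp_lines <- grep("^component: ", lines, value = TRUE)
  ncomp_line <- grep("^components: ", lines, value = TRUE)
  if (!length(comp_lines) || !length(ncomp_line)) {
    stop("truncated model file: ", path, call. = FALSE)
  }
  k <- as.integer(sub("^components: ", "", ncomp_line[1L]))
  if (length(comp_lines) != k) {
    stop("model file declares ", k, " components but lists ",
         length(comp_lines), call. = FALSE)
  }
  mat <- do.call(rbind, lapply(strsplit(sub("^component: ", "", comp_lines),
                                        " "), as.numeric))
  meta_lines <- grep("^meta\\.", lines, value = TRUE)
  meta <- list()
  if (length(meta_lines)) {
    keys <- sub("^meta\\.([^:]+): .*$", "\\1", meta_lines)
    vals <- sub("^meta\\.[^:]+: ", "", meta_lines)
    meta <- stats::setNames(as.list(vals), keys)
  }
  list(model = beta_mixture(mat[, 1L], mat[, 2L], mat[, 3L], sort = FALSE),
       meta = meta)
}

#' Write responsibility weights as TSV
#'
#' One row per observation: the value followed by one weight column per
#' component, so classification can be run decoupled from fitting.
#'
#' @param x Observed values.
#' @param W Responsibility matrix.
#' @param path Output path.
#' @export
write_weights <- function(x, W, path) {
  stopifnot(length(x) == nrow(W))
  tab <- data.frame(value = sprintf(FMT, x))
  for (j in seq_len(ncol(W))) {
    tab[[paste0("w", j)]] <- sprintf(FMT, W[, j])
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_weights <- function(path) {
  tab <- utils::read.delim(path)
  as.matrix(tab[, grep("^w[0-9]+$", names(tab)), drop = FALSE])
}
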