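# Delimited-text readers and writers for the objects the pipeline consumes.
# The delimiter (tab, comma or whitespace) is auto-detected from the first
# non-empty line.

detect_sep <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("empty file: ", path)
    if (nzchar(trimws(line))) break
  }
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

#' Read and write dense numeric matrices
#'
#' Whitespace-, tab- or comma-delimited dense text, auto-detected on read.
#' Ragged rows raise a parse error naming the first offending line.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  sep <- detect_sep(path)
  nf <- count.fields(path, sep = sep, blank.lines.skip = TRUE)
  if (length(unique(nf)) > 1L)
    stop("ragged rows in ", path, ": line ",
         which(nf != nf[1L])[1L], " has ", nf[which(nf != nf[1L])[1L]],
         " fields, expected ", nf[1L])
  m <- as.matrix(read.table(path, sep = sep, header = FALSE))
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  dimnames(m) <- NULL
  m
}

#' @rdname read_matrix
#' @param m numeric matrix.
#' @param sep field separator used on write (default tab).
#' @export
write_matrix <- function(m, path, sep = "\t") {
  write.table(as.matrix(m), path, sep = sep, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read and write parcellation tables
#'
#' Delimited table with header columns `name`, `hemi`, `x`, `y`, `z` and
#' optionally `network`.
#'
#' @param path file path.
#' @return a `"parcellation"`.
#' @export
read_parcellation <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  sep <- detect_sep(path)
  df <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  as_parcellation(df)
}

#' @rdname read_parcellation
#' @param parc a `"parcellation"`.
#' @param sep field separator (default tab).
#' @export
write_parcellation <- function(parc, path, sep = "\t") {
  write.table(as.data.frame(parc), path, sep = sep, row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read and write node time series
#'
#' An N x T delimited matrix; [write_series()] also writes a JSON sidecar
#' (`<path>.json`) recording TR, seed and any extra metadata so a run can be
#' reproduced from its files alone.
#'
#' @param path file path.
#' @return numeric N x T matrix; the sidecar metadata, when present, is
#'   attached as attribute `"meta"`.
#' @export
read_series <- function(path) {
  m <- read_matrix(path)
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(m, "meta") <- jsonlite::read_json(side, simplifyVector = TRUE)
  m
}

#' @rdname read_series
#' @param x N x T matrix or a `"hopf_sim"`.
#' @param meta named list of extra metadata for the sidecar.
#' @export
write_series <- function(x, path, meta = list()) {
  if (inherits(x, "hopf_sim")) {
    meta <- c(list(TR = x$TR, seed = x$seed,
                   n_volumes = ncol(x$x),
                   a = x$params$a, beta = x$params$beta, G = x$params$G,
                   nu = x$params$nu, forcing_on = x$forcing_on), meta)
    x <- x$x
  }
  write_matrix(x, path)
  if (length(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
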