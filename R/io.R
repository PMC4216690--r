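#' Read and write dual-GOS sample files
#'
#' The CSV dialect stores one replicate per row with columns `x1..xn`,
#' preceded by a single comment line recording the scheme and generation
#' metadata, e.g. `# n=4 m=-1 q=1 c=3 k=2 seed=42`. `read_dgos_csv`
#' validates every row (numeric, positive, strictly decreasing) and
#' reports the offending row and column on failure; scheme parameters are
#' taken from the header unless overridden.
#'
#' @param path file path.
#' @param samples for writing: a single `dgos_sample`, a list of them, or
#'   a numeric matrix (one replicate per row).
#' @param m,q scheme parameters (override the header on read; recorded on
#'   write).
#' @param meta named list of extra metadata to record (e.g. `c`, `k`,
#'   `seed`).
#' @return `read_dgos_csv`: a list of `dgos_sample` objects.
#'   `write_dgos_csv`: the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' s <- rdgos_records(4, 3, 2)
#' write_dgos_csv(s, f, meta = list(c = 3, k = 2))
#' read_dgos_csv(f)[[1]]
#' @name dgos_csv
NULL

#' @rdname dgos_csv
#' @export
write_dgos_csv <- function(samples, path, m = NULL, q = NULL, meta = list()) {
  if (inherits(samples, "dgos_sample")) samples <- list(samples)
  if (is.matrix(samples)) samples <- lapply(seq_len(nrow(samples)),
                                            function(i) samples[i, ])
  n <- length(samples[[1]])
  if (is.null(m) || is.null(q)) {
    sch <- attr(samples[[1]], "scheme")
    if (is.null(sch))
      stop("'m' and 'q' must be supplied when samples carry no scheme",
           call. = FALSE)
    m <- sch$m; q <- sch$q
  }
  fields <- c(list(n = n, m = m, q = q), meta)
  header <- paste0("# ", paste(names(fields), unlist(fields),
                               sep = "=", collapse = " "))
  mat <- do.call(rbind, lapply(samples, as.numeric))
  colnames(mat) <- paste0("x", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(as.data.frame(mat), con, row.names = FALSE)
  invisible(path)
}

#' @rdname dgos_csv
#' @export
read_dgos_csv <- function(path, m = NULL, q = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  meta <- list()
  if (startsWith(first, "#")) {
    kv <- strsplit(trimws(sub("^#", "", first)), "[[:space:]]+")[[1]]
    kv <- strsplit(kv, "=")
    meta <- stats::setNames(lapply(kv, function(p) as.numeric(p[2])),
                            vapply(kv, `[`, "", 1))
  }
  if (is.null(m)) m <- meta$m
  if (is.null(q)) q <- meta$q
  if (is.null(m) || is.null(q))
    stop("scheme parameters m and q found neither in header nor arguments",
         call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#")
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.numeric(df[i, ])
    if (any(is.na(row)))
      stop(sprintf("non-numeric value in row %d, column %s", i,
                   names(df)[which(is.na(row))[1]]), call. = FALSE)
    if (any(row <= 0))
      stop(sprintf("non-positive value in row %d, column %s", i,
                   names(df)[which(row <= 0)[1]]), call. = FALSE)
    if (length(row) > 1 && any(diff(row) >= 0))
      stop(sprintf("ordering violation in row %d at column %s: values must be strictly decreasing",
                   i, names(df)[which(diff(row) >= 0)[1] + 1L]), call. = FALSE)
    dgos_sample(row, dgos_scheme(length(row), m, q))
  })
}
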