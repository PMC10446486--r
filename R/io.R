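#' File input/output for analysis data
#'
#' Plain-text interchange: two-column xvg-dialect time series for umbrella
#' windows, key-value window manifests, tabular reduced-potential matrices
#' with a lambda manifest, and TSV/JSON result writers.
#'
#' @name file_io
NULL

#' Read a two-column xvg-dialect time series
#'
#' Whitespace-separated "time value" rows; lines starting with `#` or `@` are
#' ignored.
#'
#' @param path File path.
#' @return data.frame with columns `time`, `value`.
#' @export
read_xvg <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data rows in ", path)
  tab <- utils::read.table(text = lines)
  if (ncol(tab) < 2) stop("expected two columns in ", path)
  data.frame(time = tab[[1]], value = tab[[2]])
}

#' @rdname read_xvg
#' @param x data.frame with `time` and `value` columns (or an
#'   [umbrella_window]).
#' @param comment Optional header comment.
#' @export
write_xvg <- function(x, path, comment = NULL) {
  if (inherits(x, "umbrella_window"))
    x <- data.frame(time = x$times, value = x$samples)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines(sprintf("%.8g %.10g", x$time, x$value), con)
  invisible(path)
}

#' Read an umbrella-window manifest and its time series
#'
#' The manifest is whitespace-separated with a header line and columns
#' `file center force_constant temperature` (paths relative to the manifest's
#' directory). Optional column `equilibration_cutoff`.
#'
#' @param path Manifest path.
#' @return List of [umbrella_window] objects.
#' @export
read_window_manifest <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("file", "center", "force_constant", "temperature")
  if (!all(req %in% names(tab)))
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  dir <- dirname(path)
  lapply(seq_len(nrow(tab)), function(i) {
    f <- tab$file[i]
    if (!file.exists(f)) f <- file.path(dir, tab$file[i])
    if (!file.exists(f)) stop("window file not found: ", tab$file[i])
    ts <- read_xvg(f)
    umbrella_window(tab$center[i], tab$force_constant[i], tab$temperature[i],
                    ts$value, times = ts$time,
                    equilibration_cutoff =
                      if ("equilibration_cutoff" %in% names(tab))
                        tab$equilibration_cutoff[i] else 0)
  })
}

#' @rdname read_window_manifest
#' @param windows List of [umbrella_window] objects.
#' @param dir Output directory for the manifest and per-window xvg files.
#' @param prefix File-name prefix.
#' @return The manifest path, invisibly.
#' @export
write_window_manifest <- function(windows, dir, prefix = "window") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%03d.xvg", prefix, seq_along(windows))
  for (i in seq_along(windows))
    write_xvg(windows[[i]], file.path(dir, files[i]))
  tab <- data.frame(
    file = files,
    center = vapply(windows, `[[`, numeric(1), "center"),
    force_constant = vapply(windows, `[[`, numeric(1), "force_constant"),
    temperature = vapply(windows, `[[`, numeric(1), "temperature"),
    equilibration_cutoff = vapply(windows, `[[`, numeric(1),
                                  "equilibration_cutoff"))
  manifest <- file.path(dir, paste0(prefix, "_manifest.txt"))
  utils::write.table(tab, manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read/write a reduced-potential matrix
#'
#' The matrix file is whitespace-separated with samples as rows and evaluating
#' states as columns (so its transpose is `u[k, n]`); the manifest is a
#' two-line key-value file carrying `temperature` and the per-state counts
#' `n_k` plus optional `lambda` values.
#'
#' @param matrix_path,manifest_path File paths.
#' @return A [reduced_potential_matrix] (with attribute `"lambda"` when
#'   present in the manifest).
#' @export
read_reduced_potentials <- function(matrix_path, manifest_path) {
  u <- unname(t(as.matrix(utils::read.table(matrix_path))))
  man <- read_keyvalue(manifest_path)
  n_k <- as.numeric(strsplit(man$n_k, ",")[[1]])
  m <- reduced_potential_matrix(u, n_k, as.numeric(man$temperature))
  if (!is.null(man$lambda))
    attr(m, "lambda") <- as.numeric(strsplit(man$lambda, ",")[[1]])
  m
}

#' @rdname read_reduced_potentials
#' @param m A [reduced_potential_matrix].
#' @export
write_reduced_potentials <- function(m, matrix_path, manifest_path) {
  utils::write.table(t(m$u), matrix_path, row.names = FALSE,
                     col.names = FALSE)
  lines <- c(sprintf("temperature = %g", m$temperature),
             paste("n_k =", paste(m$n_k, collapse = ",")))
  if (!is.null(attr(m, "lambda")))
    lines <- c(lines, paste("lambda =",
                            paste(attr(m, "lambda"), collapse = ",")))
  writeLines(lines, manifest_path)
  invisible(matrix_path)
}

# flat "key = value" config reader; '#' comments allowed
read_keyvalue <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    out[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
  }
  out
}

#' Read transport legs from a JSON file
#'
#' Expects an array of records `{from, to, value, error, provenance}`.
#'
#' @param path JSON path.
#' @param sites Admissible site labels (`NULL` disables validation).
#' @return List of [transport_leg] objects.
#' @export
read_legs_json <- function(path, sites = NULL) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  lapply(seq_len(nrow(recs)), function(i)
    transport_leg(recs$from[i], recs$to[i], recs$value[i],
                  if ("error" %in% names(recs)) recs$error[i] else 0,
                  provenance = if ("provenance" %in% names(recs))
                    recs$provenance[i] else "",
                  sites = sites))
}

#' Write a PMF profile as TSV
#'
#' @param profile A [pmf_profile].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_json_result <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
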