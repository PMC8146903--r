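# Plain-text readers/writers for the 1-D signal types.  Files are
# two-column TSV (or CSV) with `# key: value` metadata header lines, so a
# dataset and its acquisition metadata round-trip through one file.

.write_signal <- function(df, path, meta, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, as.character(meta[[nm]])), con)
  writeLines(paste(names(df), collapse = sep), con)
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = sep, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.read_signal <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  body <- body[nzchar(trimws(body))]
  sep <- if (grepl("\t", body[1])) "\t" else if (grepl(",", body[1])) "," else ""
  tok <- strsplit(trimws(body[1]), if (sep == "") "\\s+" else sep)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(tok))))
  df <- read.table(text = body, header = has_header, sep = sep,
                   stringsAsFactors = FALSE)
  list(data = df, meta = meta)
}

#' Write / read a decay trace
#' @param trace a [decay_trace()].
#' @param path file path.
#' @param sep column separator ("\t" or ",").
#' @return the written path, or the re-read [decay_trace()].
#' @export
write_decay_trace <- function(trace, path, sep = "\t") {
  stopifnot(inherits(trace, "decay_trace"))
  .write_signal(trace, path,
                list(quencher_conc_M = attr(trace, "quencher_conc"),
                     label = attr(trace, "label")), sep)
}

#' @rdname write_decay_trace
#' @export
read_decay_trace <- function(path) {
  r <- .read_signal(path)
  decay_trace(r$data[[1]], r$data[[2]],
              quencher_conc = as.numeric(r$meta$quencher_conc_M %||% 0),
              label = r$meta$label %||% "")
}

#' Write / read an oxygen trace
#' @param trace an [o2_trace()].
#' @param path file path.
#' @param sep column separator.
#' @return the written path, or the re-read [o2_trace()].
#' @export
write_o2_trace <- function(trace, path, sep = "\t") {
  stopifnot(inherits(trace, "o2_trace"))
  .write_signal(trace, path,
                list(value_kind = attr(trace, "value_kind"),
                     sample_label = attr(trace, "sample_label")), sep)
}

#' @rdname write_o2_trace
#' @export
read_o2_trace <- function(path) {
  r <- .read_signal(path)
  o2_trace(r$data[[1]], r$data[[2]],
           value_kind = r$meta$value_kind %||% "concentration",
           sample_label = r$meta$sample_label %||% "")
}

#' Write / read an EPR spectrum
#'
#' Two-column field/amplitude text (Bruker-style exports without a header
#' are accepted on read; field unit may be declared as G or mT).
#' @param spec an [epr_spectrum()].
#' @param path file path.
#' @param sep column separator.
#' @return the written path, or the re-read [epr_spectrum()].
#' @export
write_epr_spectrum <- function(spec, path, sep = "\t") {
  stopifnot(inherits(spec, "epr_spectrum"))
  .write_signal(spec, path,
                list(temperature_K = attr(spec, "temperature_K"),
                     label_position = attr(spec, "label_position"),
                     field_unit = "G"), sep)
}

#' @rdname write_epr_spectrum
#' @export
read_epr_spectrum <- function(path) {
  r <- .read_signal(path)
  if (!is.numeric(r$data[[1]])) stop_param("non-numeric field column in %s", path)
  epr_spectrum(r$data[[1]], r$data[[2]],
               temperature_K = as.numeric(r$meta$temperature_K %||% 310),
               label_position = r$meta$label_position %||% "5-PC",
               unit = r$meta$field_unit %||% "G")
}

#' Write / read a Raman spectrum
#' @param spec a [raman_spectrum()].
#' @param path file path.
#' @param sep column separator.
#' @return the written path, or the re-read [raman_spectrum()].
#' @export
write_raman_spectrum <- function(spec, path, sep = "\t") {
  stopifnot(inherits(spec, "raman_spectrum"))
  .write_signal(spec, path,
                list(sample_label = attr(spec, "sample_label"),
                     replicate = attr(spec, "replicate")), sep)
}

#' @rdname write_raman_spectrum
#' @export
read_raman_spectrum <- function(path) {
  r <- .read_signal(path)
  raman_spectrum(r$data[[1]], r$data[[2]],
                 sample_label = r$meta$sample_label %||% "",
                 replicate = as.integer(r$meta$replicate %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
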