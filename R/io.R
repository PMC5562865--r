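# Plain-text force-curve dialect and table I/O.
#
# Curve files are TSV with a '#'-prefixed key=value metadata header. Units
# are fixed to nm (separation) and pN (force); the numeric payload is written
# at 9 significant digits so that write -> read round-trips bit-identically
# at that precision.

#' Write a force curve to the package TSV dialect
#'
#' @param curve A `force_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_file <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write curve file: ", path)
  on.exit(close(con))
  m <- curve$meta
  hdr <- c("# afmunfold force curve",
           "# separation_unit=nm",
           "# force_unit=pN",
           sprintf("# v_nm_s=%.9g", m$v_nm_s %||% NA),
           sprintf("# k_c_pN_nm=%.9g", m$k_c_pN_nm %||% NA),
           sprintf("# seed=%s", m$seed %||% ""),
           sprintf("# id=%s", m$id %||% ""))
  writeLines(hdr, con)
  writeLines("separation_nm\tforce_pN", con)
  writeLines(sprintf("%.9g\t%.9g", curve$separation, curve$force), con)
  invisible(path)
}

#' Read a force curve from the package TSV dialect
#'
#' Validates units, column layout and strict monotonicity of the separation
#' axis; parse failures report the offending line.
#'
#' @param path Path to a curve TSV.
#' @return A `force_curve`.
#' @export
read_curve_file <- function(path) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  hdr <- lines[hdr_idx]
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_]+)=(.*)$", h))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- kv[3]
  }
  if (!is.null(meta$separation_unit) && meta$separation_unit != "nm")
    stop("unit mismatch in ", path, ": separation_unit must be 'nm', got '",
         meta$separation_unit, "'")
  if (!is.null(meta$force_unit) && meta$force_unit != "pN")
    stop("unit mismatch in ", path, ": force_unit must be 'pN', got '",
         meta$force_unit, "'")
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  body <- body[nzchar(body)]
  if (length(body) < 2) stop("curve file has no data rows: ", path)
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 2 || cols[1] != "separation_nm" || cols[2] != "force_pN")
    stop("missing or misnamed columns in ", path,
         " (expected 'separation_nm<TAB>force_pN' at line ",
         which(lines == body[1]), ")")
  d <- utils::read.table(text = body[-1], sep = "\t", col.names = c("separation", "force"))
  if (any(!is.finite(d$separation)) || any(!is.finite(d$force)))
    stop("non-numeric payload in ", path)
  bad <- which(diff(d$separation) <= 0)
  if (length(bad))
    stop("separations not strictly increasing in ", path, " (first violation near data row ",
         bad[1] + 1L, ")")
  structure(list(separation = d$separation, force = d$force,
                 meta = list(v_nm_s = as.numeric(meta$v_nm_s %||% NA),
                             k_c_pN_nm = as.numeric(meta$k_c_pN_nm %||% NA),
                             seed = meta$seed %||% NA, id = meta$id %||% basename(path))),
            class = "force_curve")
}

#' Read every curve file in a directory
#'
#' @param dir Directory containing `*.tsv` curve files (the truth table, if
#'   present, is skipped).
#' @return Named list of `force_curve` objects.
#' @export
read_curve_dir <- function(dir) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  files <- files[basename(files) != "truth.tsv"]
  if (!length(files)) stop("no curve files (*.tsv) found in ", dir)
  out <- lapply(files, read_curve_file)
  names(out) <- vapply(out, function(cu) cu$meta$id, character(1))
  out
}

#' Write / read an events table
#'
#' Per-event results (curve id, peak ordinal, rupture force, fitted contour
#' length, increment, class label) as plain TSV.
#'
#' @param events Data frame of events.
#' @param path File path.
#' @return `path` / the data frame.
#' @export
write_events_table <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_table
#' @export
read_events_table <- function(path) {
  if (!file.exists(path)) stop("events table not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
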