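## QC reporting: a named list of metric results rendered both human-readable
## and machine-readable (JSON); the JSON re-parses to the same values.

#' Assemble a QC report
#'
#' @param qc_results named list; entries may be `resolution_estimate`,
#'   `fwhm_measurement`, `snr_map`, `artifact_scores` objects or plain
#'   numeric values/lists.
#' @return object of class `qc_report`.
#' @export
qc_report <- function(qc_results = list()) {
  flat <- lapply(qc_results, function(x) {
    if (inherits(x, "resolution_estimate"))
      list(resolution_nm = x$resolution_nm, cutoff = x$cutoff)
    else if (inherits(x, "fwhm_measurement")) list(fwhm_nm = x$fwhm_nm)
    else if (inherits(x, "snr_map"))
      list(median_snr = median(x$snr[is.finite(x$snr)]), n = x$n)
    else if (inherits(x, "artifact_scores"))
      list(rsp = x$rsp, rse = x$rse, rsf_fwhm_px = x$rsf_fwhm_px)
    else x
  })
  structure(list(results = flat), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n=========\n")
  if (!length(x$results)) {
    cat("(no metrics)\n")
    return(invisible(x))
  }
  for (nm in names(x$results)) {
    entry <- x$results[[nm]]
    if (is.list(entry)) {
      vals <- paste(sprintf("%s = %s", names(entry),
                            vapply(entry, function(v)
                              format(v, digits = 6), character(1))),
                    collapse = ", ")
    } else {
      vals <- format(entry, digits = 6)
    }
    cat(sprintf("  %-28s %s\n", nm, vals))
  }
  invisible(x)
}

#' Write a QC report as text and JSON
#'
#' @param report a `qc_report`.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return paths of the written files, invisibly.
#' @export
write_report <- function(report, dir, name = "qc_report") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, paste0(name, ".json"))
  txt_path <- file.path(dir, paste0(name, ".txt"))
  jsonlite::write_json(report$results, json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, txt_path)
  invisible(c(json = json_path, txt = txt_path))
}

#' Read back a JSON QC report
#' @param path JSON path written by [write_report()].
#' @return a `qc_report`.
#' @export
read_report <- function(path) {
  structure(list(results = jsonlite::read_json(path, simplifyVector = TRUE)),
            class = "qc_report")
}
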