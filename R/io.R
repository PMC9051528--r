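#' Read and write concentration curves as delimited text
#'
#' One row per pixel, one column per time point; the time vector and AIF
#' travel in a companion header block prefixed with `#`.
#'
#' @param curves pixels-by-timepoints matrix, mM.
#' @param t time vector, minutes.
#' @param aif AIF vector, mM.
#' @param file path to write to / read from.
#' @return `read_curves_csv` returns a list with `curves`, `t`, `aif`.
#' @export
write_curves_csv <- function(curves, t, aif, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste0("# t: ", paste(t, collapse = ",")),
               paste0("# aif: ", paste(aif, collapse = ","))), con)
  write.table(curves, con, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' @rdname write_curves_csv
#' @export
read_curves_csv <- function(file) {
  hdr <- readLines(file, n = 2)
  parse_num <- function(line)
    as.numeric(strsplit(sub("^# [a-z]+: ", "", line), ",")[[1]])
  curves <- as.matrix(read.csv(file, header = FALSE, comment.char = "#"))
  dimnames(curves) <- NULL
  list(curves = curves, t = parse_num(hdr[1]), aif = parse_num(hdr[2]))
}

#' Save or load a DRO (or any fit object) as an RDS container
#'
#' @param object object to save.
#' @param file path.
#' @export
write_container <- function(object, file) {
  saveRDS(object, file)
  invisible(file)
}

#' @rdname write_container
#' @export
read_container <- function(file) readRDS(file)

#' Export ground-truth or estimated parameter maps as CSV
#'
#' Writes one CSV per parameter, one row per x index, slices concatenated
#' column-blocks (`slice<z>_col<j>` headers).
#'
#' @param maps named list of parameter arrays (`Fp`, `vp`, `ve`, `PS`).
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @export
write_maps_csv <- function(maps, dir, prefix = "map") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in names(maps)) {
    a <- as.array(maps[[p]])
    if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1)
    flat <- do.call(cbind, lapply(seq_len(dim(a)[3]),
                                  function(z) a[, , z]))
    colnames(flat) <- unlist(lapply(seq_len(dim(a)[3]), function(z)
      sprintf("slice%d_col%d", z, seq_len(dim(a)[2]))))
    write.csv(flat, file.path(dir, sprintf("%s_%s.csv", prefix, p)),
              row.names = FALSE)
  }
  invisible(dir)
}
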