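#' Write one record as WFDB files (format 16)
#'
#' Writes `<name>.hea` and `<name>.dat` in WFDB format 16: interleaved
#' little-endian 16-bit ADC units with per-lead gain in ADU/mV. The gain
#' default of 4000 gives a quantization step of 0.00025 mV.
#'
#' @param signal 12 x N numeric matrix, mV.
#' @param fs sampling rate, Hz.
#' @param path file path without extension.
#' @param gain ADC gain, ADU per mV.
#' @return invisibly, the header path.
#' @export
write_wfdb <- function(signal, fs, path, gain = 4000) {
  stopifnot(is.matrix(signal), nrow(signal) == 12)
  n <- ncol(signal)
  adc <- round(signal * gain)
  if (any(abs(adc) > 32767)) stop("signal exceeds the int16 range at this gain")
  name <- basename(path)
  lead_names <- c("I", "II", "III", "AVR", "AVL", "AVF",
                  "V1", "V2", "V3", "V4", "V5", "V6")
  hea <- c(sprintf("%s 12 %g %d", name, fs, n),
           sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 %s",
                   name, gain, as.integer(adc[, 1]), lead_names))
  writeLines(hea, paste0(path, ".hea"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  # column-major = sample-interleaved lead order, the WFDB layout
  writeBin(as.integer(adc), con, size = 2, endian = "little")
  invisible(paste0(path, ".hea"))
}

#' Read one WFDB record (format 16)
#'
#' @param path path to the record without extension (or to the `.hea`).
#' @return list with `signal` (12 x N matrix, mV), `fs`, `n`, `id`.
#' @export
read_wfdb <- function(path) {
  path <- sub("\\.hea$", "", path)
  hea_path <- paste0(path, ".hea")
  if (!file.exists(hea_path)) stop("missing WFDB header: ", hea_path)
  hea <- readLines(hea_path)
  rec <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  nsig <- as.integer(rec[2]); fs <- as.numeric(rec[3]); n <- as.integer(rec[4])
  sig_lines <- strsplit(trimws(hea[1 + seq_len(nsig)]), "\\s+")
  fmt <- vapply(sig_lines, `[`, "", 2)
  if (!all(fmt == "16")) stop("only WFDB format 16 is supported: ", hea_path)
  gains <- vapply(sig_lines, function(f) as.numeric(sub("\\(.*$", "", sub("/.*$", "", f[3]))), 0)
  dat_path <- paste0(path, ".dat")
  if (!file.exists(dat_path)) stop("missing WFDB signal file: ", dat_path)
  con <- file(dat_path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, "integer", n = nsig * n, size = 2, endian = "little", signed = TRUE)
  if (length(raw_vals) < nsig * n) stop("truncated WFDB signal file: ", dat_path)
  adc <- matrix(raw_vals, nrow = nsig)
  list(signal = adc / gains, fs = fs, n = n, id = basename(path))
}

#' Write a synthetic dataset in the PTB-XL directory layout
#'
#' Produces `records500/<id>` WFDB files, a `ptbxl_database.csv` metadata
#' table (`ecg_id`, `scp_codes`, `age`, `sex`, `filename_hr`) and an
#' `scp_statements.csv` code map (`code`, `diagnostic`,
#' `diagnostic_class`, `diagnostic_subclass`), so the generated data
#' round-trips through [load_metadata()] / [filter_records()] /
#' [load_signals()].
#'
#' @param dataset list of `list(record, truth)` entries from
#'   [generate_dataset()].
#' @param specs the class specifications the dataset was generated from
#'   (used to emit the code-to-superclass map).
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_ptbxl_dataset <- function(dataset, specs, dir) {
  dir.create(file.path(dir, "records500"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset), function(i) {
    rec <- dataset[[i]]$record
    fname <- sprintf("records500/%s", rec$id)
    write_wfdb(rec$signal, rec$fs, file.path(dir, fname))
    code <- names(rec$labels)[1]
    data.frame(ecg_id = i,
               scp_codes = sprintf("{'%s': %.1f}", code, unname(rec$labels[1])),
               age = rec$age, sex = rec$sex, filename_hr = fname,
               stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, rows)
  utils::write.csv(meta, file.path(dir, "ptbxl_database.csv"), row.names = FALSE)
  scp <- do.call(rbind, lapply(specs, function(s) {
    data.frame(code = s$label, diagnostic = 1,
               diagnostic_class = s$class_label,
               diagnostic_subclass = s$label, stringsAsFactors = FALSE)
  }))
  utils::write.csv(scp, file.path(dir, "scp_statements.csv"), row.names = FALSE)
  invisible(dir)
}
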