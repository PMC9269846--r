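#' Load a PTB-XL-layout metadata table
#'
#' Reads `ptbxl_database.csv` (one row per record: `ecg_id`, `scp_codes`,
#' `age`, `sex`, `filename_hr`) and `scp_statements.csv` (SCP code to
#' diagnostic class/subclass map) from the dataset root. The `scp_codes`
#' column, a dictionary literal of code-to-likelihood pairs, is parsed
#' into list-columns `codes` and `likelihoods`.
#'
#' @param dataset_root directory containing the two CSV tables.
#' @return data.frame with one row per record; the parsed SCP statement
#'   map is attached as attribute `"scp_map"`.
#' @export
load_metadata <- function(dataset_root) {
  meta_path <- file.path(dataset_root, "ptbxl_database.csv")
  scp_path <- file.path(dataset_root, "scp_statements.csv")
  if (!file.exists(meta_path)) stop("missing metadata table: ", meta_path)
  if (!file.exists(scp_path)) stop("missing SCP statement table: ", scp_path)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  scp <- utils::read.csv(scp_path, stringsAsFactors = FALSE)
  # PTB-XL ships the code as the (unnamed) first column
  if (!"code" %in% names(scp)) names(scp)[1] <- "code"
  need <- c("ecg_id", "scp_codes", "age", "sex", "filename_hr")
  if (!all(need %in% names(meta)))
    stop("metadata table lacks required columns: ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  parsed <- parse_scp_codes(meta$scp_codes)
  meta$codes <- I(parsed$codes)
  meta$likelihoods <- I(parsed$likelihoods)
  attr(meta, "scp_map") <- scp
  meta
}

# "{'NORM': 100.0, 'SR': 0.0}" -> codes + likelihood vectors
parse_scp_codes <- function(x) {
  codes <- vector("list", length(x))
  liks <- vector("list", length(x))
  m <- gregexpr("'([^']+)'\\s*:\\s*([0-9.eE+-]+)", x)
  for (i in seq_along(x)) {
    hits <- regmatches(x[i], m[i])[[1]]
    if (length(hits) == 0) { codes[[i]] <- character(0); liks[[i]] <- numeric(0); next }
    codes[[i]] <- sub("'([^']+)'.*", "\\1", hits)
    liks[[i]] <- as.numeric(sub(".*:\\s*", "", hits))
  }
  list(codes = codes, likelihoods = liks)
}

#' Filter records to the single-class diagnostic subset
#'
#' Keeps only records that (a) carry at least one diagnostic label,
#' (b) carry it at likelihood 100, and (c) belong to a subclass whose
#' total record count (computed after step b) reaches
#' `min_subclass_size`. Records whose likelihood-100 diagnostic labels
#' map to more than one superclass or more than one subclass are dropped,
#' so each surviving record carries exactly one (binary, class, subclass)
#' label triple. The filter is idempotent.
#'
#' @param metadata table from [load_metadata()].
#' @param min_subclass_size minimum subclass population (default 100).
#' @param scp_map SCP statement map; defaults to the attribute attached
#'   by [load_metadata()].
#' @return data.frame with columns `ecg_id`, `class`, `subclass`,
#'   `binary`, `age`, `sex`, `filename_hr`.
#' @export
filter_records <- function(metadata, min_subclass_size = 100,
                           scp_map = attr(metadata, "scp_map")) {
  if (is.null(scp_map)) stop("no SCP statement map supplied")
  diag_map <- scp_map[!is.na(scp_map$diagnostic_class) & scp_map$diagnostic_class != "", ]
  rows <- lapply(seq_len(nrow(metadata)), function(i) {
    codes <- metadata$codes[[i]]
    liks <- metadata$likelihoods[[i]]
    keep <- codes %in% diag_map$code             # (a) diagnostic labels only
    codes <- codes[keep]; liks <- liks[keep]
    if (length(codes) == 0) return(NULL)
    codes <- codes[liks == 100]                  # (b) full-confidence only
    if (length(codes) == 0) return(NULL)
    j <- match(codes, diag_map$code)
    cls <- unique(diag_map$diagnostic_class[j])
    sub <- unique(diag_map$diagnostic_subclass[j])
    if (length(cls) != 1 || length(sub) != 1) return(NULL)  # one-class rule
    data.frame(ecg_id = metadata$ecg_id[i], class = cls, subclass = sub,
               binary = if (cls == "NORM") "NORM" else "OTHER",
               age = metadata$age[i], sex = metadata$sex[i],
               filename_hr = metadata$filename_hr[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(ecg_id = integer(0), class = character(0),
                      subclass = character(0), binary = character(0),
                      age = numeric(0), sex = integer(0),
                      filename_hr = character(0), stringsAsFactors = FALSE))
  }
  counts <- table(out$subclass)                  # (c) subclass population
  out <- out[counts[out$subclass] >= min_subclass_size, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load WFDB signals for a filtered record table
#'
#' @param filtered table from [filter_records()].
#' @param dataset_root dataset root containing the WFDB files.
#' @param expect_fs required sampling rate (Hz, default 500).
#' @return list of `ecg_record` objects (12 x N signal in mV, fs, age,
#'   sex, label annotations).
#' @export
load_signals <- function(filtered, dataset_root, expect_fs = 500) {
  lapply(seq_len(nrow(filtered)), function(i) {
    path <- file.path(dataset_root, filtered$filename_hr[i])
    w <- tryCatch(read_wfdb(path), error = function(e)
      stop("record ", filtered$ecg_id[i], ": ", conditionMessage(e), call. = FALSE))
    if (w$fs != expect_fs)
      stop("record ", filtered$ecg_id[i], ": sampling rate ", w$fs,
           " Hz, expected ", expect_fs)
    if (nrow(w$signal) != 12)
      stop("record ", filtered$ecg_id[i], ": expected 12 leads")
    structure(list(id = as.character(filtered$ecg_id[i]), signal = w$signal,
                   fs = w$fs, age = filtered$age[i], sex = filtered$sex[i],
                   labels = stats::setNames(100, filtered$subclass[i]),
                   class = filtered$class[i], subclass = filtered$subclass[i],
                   binary = filtered$binary[i]),
              class = "ecg_record")
  })
}
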