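# Plate-table readers/writers. One canonical CSV dialect: comma-delimited,
# UTF-8, header row; column order free on input, fixed on output.

.NON_DETECT_TOKENS <- c("NA", "Undetermined", "")

.asRegistry <- function(assays) {
  if (is(assays, "PcrAssay")) assays <- list(assays)
  if (!is.list(assays) || !all(vapply(assays, is, TRUE, "PcrAssay")))
    stop("'assays' must be a PcrAssay or a list of PcrAssay objects")
  nm <- vapply(assays, assayId, character(1))
  names(assays) <- nm
  assays
}

.checkColumns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " table is missing required column(s): ",
         paste(missing, collapse = ", "))
}

.parseCommon <- function(df, assays) {
  df$assay_id <- as.character(df$assay_id)
  df$sample_id <- as.character(df$sample_id)
  df$sample_type <- as.character(df$sample_type)
  bad <- !df$sample_type %in% c("standard", "unknown", "negative_control")
  if (any(bad))
    stop("unknown sample_type in row(s) ", paste(which(bad), collapse = ", "),
         ": ", paste(unique(df$sample_type[bad]), collapse = ", "))
  df$nominal_conc <- suppressWarnings(as.numeric(df$nominal_conc))
  df$replicate <- as.integer(df$replicate)
  std <- df$sample_type == "standard"
  lacks <- std & (is.na(df$nominal_conc) | df$nominal_conc <= 0)
  if (any(lacks))
    stop("standard row(s) without a positive nominal_conc: row ",
         paste(which(lacks), collapse = ", "))
  unreg <- !df$assay_id %in% names(assays)
  if (any(unreg))
    stop("assay_id not in registry: ",
         paste(unique(df$assay_id[unreg]), collapse = ", "))
  df
}

#' Read a qPCR plate table
#'
#' Reads a delimited plate export with columns `assay_id`, `sample_id`,
#' `sample_type` (standard / unknown / negative_control), `nominal_conc`
#' (copies/uL, required for standards), `replicate` and `ct`. The `ct`
#' column accepts a numeric cycle threshold or any of the non-detect tokens
#' `"NA"`, `"Undetermined"` or an empty field. The binary detection outcome
#' is derived: detected exactly when `ct` parses as a finite number.
#'
#' @param source path (or connection) to a CSV file.
#' @param assays a [PcrAssay-class] or named list of them covering every
#'   `assay_id` in the table; used to check `ct <= maxCycles`.
#' @return data.frame of reaction records with columns `assay_id`,
#'   `sample_id`, `sample_type`, `nominal_conc`, `replicate`, `ct`
#'   (NA for non-detect) and logical `detected`.
#' @seealso [readDdpcrTable()], [simulateQpcr()]
#' @export
readQpcrTable <- function(source, assays) {
  assays <- .asRegistry(assays)
  df <- utils::read.csv(source, colClasses = "character",
                        stringsAsFactors = FALSE, encoding = "UTF-8")
  .checkColumns(df, c("assay_id", "sample_id", "sample_type",
                      "nominal_conc", "replicate", "ct"), "qPCR")
  df <- .parseCommon(df, assays)
  raw <- trimws(df$ct)
  nd <- raw %in% .NON_DETECT_TOKENS | is.na(raw)
  ct <- suppressWarnings(as.numeric(raw))
  unparsable <- !nd & is.na(ct)
  if (any(unparsable))
    stop("unparsable ct value in row(s) ",
         paste(which(unparsable), collapse = ", "))
  if (any(!nd & ct <= 0))
    stop("ct must be positive; offending row(s): ",
         paste(which(!nd & ct <= 0), collapse = ", "))
  cap <- vapply(assays, function(a) a@maxCycles, 1L)[df$assay_id]
  over <- !nd & ct > cap
  if (any(over))
    stop("ct exceeds maxCycles of its assay in row(s) ",
         paste(which(over), collapse = ", "))
  out <- df[c("assay_id", "sample_id", "sample_type", "nominal_conc",
              "replicate")]
  out$ct <- ifelse(nd, NA_real_, ct)
  out$detected <- !nd
  out
}

#' Read a ddPCR plate table
#'
#' Reads a delimited droplet-count export with columns `assay_id`,
#' `sample_id`, `sample_type`, `nominal_conc`, `replicate`,
#' `positive_droplets` (W) and `total_droplets` (U). Enforces
#' `0 <= W <= U` and `U > 0`.
#'
#' @inheritParams readQpcrTable
#' @return data.frame of droplet records with integer columns
#'   `positive_droplets` and `total_droplets`.
#' @export
readDdpcrTable <- function(source, assays) {
  assays <- .asRegistry(assays)
  df <- utils::read.csv(source, colClasses = "character",
                        stringsAsFactors = FALSE, encoding = "UTF-8")
  .checkColumns(df, c("assay_id", "sample_id", "sample_type",
                      "nominal_conc", "replicate", "positive_droplets",
                      "total_droplets"), "ddPCR")
  df <- .parseCommon(df, assays)
  w <- suppressWarnings(as.integer(df$positive_droplets))
  u <- suppressWarnings(as.integer(df$total_droplets))
  if (anyNA(w) || anyNA(u))
    stop("droplet counts must be integers; offending row(s): ",
         paste(which(is.na(w) | is.na(u)), collapse = ", "))
  if (any(u <= 0L))
    stop("total_droplets must be positive; offending row(s): ",
         paste(which(u <= 0L), collapse = ", "))
  if (any(w < 0L | w > u))
    stop("positive_droplets must satisfy 0 <= W <= U; offending row(s): ",
         paste(which(w < 0L | w > u), collapse = ", "))
  out <- df[c("assay_id", "sample_id", "sample_type", "nominal_conc",
              "replicate")]
  out$positive_droplets <- w
  out$total_droplets <- u
  out
}

.ESTIMATE_COLUMNS <- c("sample_id", "assay_id", "method", "log10_c_median",
                       "log10_c_mean", "ci_low", "ci_high", "ci_width",
                       "is_detect")

#' Write a concentration-estimate table
#'
#' Writes per-sample posterior summaries (as returned by [estimates()]) to
#' CSV with the fixed column order `sample_id, assay_id, method,
#' log10_c_median, log10_c_mean, ci_low, ci_high, ci_width, is_detect`.
#' Numeric fields are written with enough digits that
#' `readEstimates(writeEstimates(x))` reproduces `x` beyond 6 decimals.
#'
#' @param est data.frame of estimates; must be non-empty and contain the
#'   columns above; duplicate `(sample_id, method)` pairs are an error.
#' @param sink output path or connection.
#' @return `sink`, invisibly.
#' @export
writeEstimates <- function(est, sink) {
  if (!is.data.frame(est) || nrow(est) == 0L)
    stop("'est' must be a non-empty data.frame of estimates")
  .checkColumns(est, .ESTIMATE_COLUMNS, "estimate")
  key <- paste(est$sample_id, est$method, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample_id, method) pair(s): ",
         paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "))
  out <- est[.ESTIMATE_COLUMNS]
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 15,
                                                   format = "g"))
  out$is_detect <- as.logical(est$is_detect)
  utils::write.csv(out, sink, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(sink)
}

#' @rdname writeEstimates
#' @param source path to a CSV previously written by `writeEstimates()`.
#' @export
readEstimates <- function(source) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE)
  .checkColumns(df, .ESTIMATE_COLUMNS, "estimate")
  df$is_detect <- as.logical(df$is_detect)
  df[.ESTIMATE_COLUMNS]
}

#' Write simulated plate records back to the canonical CSV schema
#'
#' Inverse of the plate readers: emits the same columns the readers accept,
#' with non-detect Ct written as the canonical token `"NA"`.
#'
#' @param records data.frame from [simulateQpcr()]/[readQpcrTable()] or
#'   [simulateDdpcr()]/[readDdpcrTable()].
#' @param sink output path or connection.
#' @return `sink`, invisibly.
#' @export
writePlateTable <- function(records, sink) {
  if ("ct" %in% names(records)) {
    out <- records[c("assay_id", "sample_id", "sample_type", "nominal_conc",
                     "replicate")]
    out$ct <- ifelse(is.na(records$ct), "NA",
                     formatC(records$ct, digits = 15, format = "g"))
  } else {
    out <- records[c("assay_id", "sample_id", "sample_type", "nominal_conc",
                     "replicate", "positive_droplets", "total_droplets")]
  }
  if ("nominal_conc" %in% names(out))
    out$nominal_conc <- ifelse(is.na(records$nominal_conc), "",
                               formatC(records$nominal_conc, digits = 15,
                                       format = "g"))
  utils::write.csv(out, sink, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(sink)
}
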