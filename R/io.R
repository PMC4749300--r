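# Standard-format I/O: minimal WFDB (format-16) reader/writer, rdann-style
# text beat annotations, the documented TSV feature-series dialect, basis
# export, and the YAML run configuration.

#' Read a WFDB record (signal format 16)
#'
#' Parses the `.hea` header and the interleaved 16-bit little-endian `.dat`
#' signal file, converting ADC units to microvolts using each signal's gain,
#' baseline and units fields.  Beat annotations, when present, are read from
#' `<record>.ann` — a plain-text table with columns `sample` and `symbol`
#' (rdann-style); symbol `N` maps to a normal beat, everything else to
#' abnormal.  Absent annotation files simply leave the beat list empty.
#'
#' @param path record path without extension (e.g. `"dir/rec"`).
#' @return an [ecg_record()].
#' @export
read_wfdb <- function(path) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop("header not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec_tok) < 4)
    stop("malformed header ", hea, " line 1: need record name, n_sig, fs, ",
         "n_samples")
  n_sig <- as.integer(rec_tok[2])
  fs <- as.numeric(rec_tok[3])
  n_samp <- as.integer(rec_tok[4])
  sig_lines <- lines[2:(1 + n_sig)]
  gains <- baselines <- numeric(n_sig)
  units <- character(n_sig)
  dat_file <- NA_character_
  for (k in seq_len(n_sig)) {
    tok <- strsplit(trimws(sig_lines[k]), "\\s+")[[1]]
    if (length(tok) < 3 || tok[2] != "16")
      stop("malformed header ", hea, " line ", k + 1,
           ": only signal format 16 is supported")
    dat_file <- tok[1]
    gain_tok <- tok[3]                       # gain(baseline)/units
    units[k] <- if (grepl("/", gain_tok)) sub(".*/", "", gain_tok) else "mV"
    gb <- sub("/.*", "", gain_tok)
    baselines[k] <- if (grepl("\\(", gb))
      as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gb)) else 0
    gains[k] <- as.numeric(sub("\\(.*", "", gb))
    if (is.na(gains[k]) || gains[k] == 0) gains[k] <- 200
  }
  dat <- file.path(dirname(hea), dat_file)
  raw_vals <- readBin(dat, "integer", n = n_samp * n_sig, size = 2,
                      signed = TRUE, endian = "little")
  m <- matrix(raw_vals, ncol = n_sig, byrow = TRUE)
  to_uv <- vapply(units, function(u)
    switch(tolower(u), "uv" = 1, "mv" = 1000, "v" = 1e6, 1000), numeric(1))
  for (k in seq_len(n_sig))
    m[, k] <- (m[, k] - baselines[k]) / gains[k] * to_uv[k]
  beats <- NULL
  ann <- paste0(path, ".ann")
  if (file.exists(ann)) {
    at <- utils::read.table(ann, header = TRUE, stringsAsFactors = FALSE)
    beats <- data.frame(fiducial = as.integer(at$sample),
                        label = ifelse(at$symbol == "N", "normal",
                                       "abnormal"))
  }
  ecg_record(m, fs, beats)
}

#' Write a record in WFDB format 16
#'
#' Signals are quantized at the given gain (ADC units per mV); beats, when
#' present, go to an rdann-style `<record>.ann` text table.
#'
#' @param record an [ecg_record()].
#' @param path record path without extension.
#' @param gain ADC units per mV (default 200, i.e. 5 uV per ADC unit).
#' @return `path`, invisibly.
#' @export
write_wfdb <- function(record, path, gain = 200) {
  n_sig <- ncol(record$signals)
  n <- nrow(record$signals)
  base <- basename(path)
  hea <- c(sprintf("%s %d %g %d", base, n_sig, record$fs, n),
           vapply(seq_len(n_sig), function(k)
             sprintf("%s.dat 16 %g(0)/mV 16 0 0 0 0 lead%d",
                     base, gain, k), character(1)))
  writeLines(hea, paste0(path, ".hea"))
  adc <- round(record$signals / 1000 * gain)
  adc <- pmin(pmax(adc, -32768), 32767)
  writeBin(as.integer(t(adc)), paste0(path, ".dat"), size = 2,
           endian = "little")
  if (nrow(record$beats)) {
    ann <- data.frame(sample = record$beats$fiducial,
                      symbol = ifelse(record$beats$label == "normal",
                                      "N", "V"))
    utils::write.table(ann, paste0(path, ".ann"), row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Write / read a feature-series TSV
#'
#' The on-disk dialect is a TSV whose leading `#` lines carry a JSON header
#' (units convention, number of coefficients, Mahalanobis dimensionality,
#' window and provenance); all numeric columns are written with 9
#' significant digits, which round-trips the series losslessly at the
#' resolution the pipeline produces.
#'
#' @param series a `feature_series`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_series <- function(series, path) {
  hdr <- list(format = "stmorph-feature-series/1",
              units = "uV; normalized coefficients unitless (unit std)",
              n_coeffs = attr(series, "n_coeffs"),
              n_d = attr(series, "n_d"),
              window = unclass(attr(series, "window")),
              provenance = attr(series, "provenance"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", jsonlite::toJSON(hdr, auto_unbox = TRUE)), con)
  df <- as.data.frame(series)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 9)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_series
#' @export
read_feature_series <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#"))
    stop("not a stmorph feature-series file (missing JSON header): ", path)
  hdr <- jsonlite::fromJSON(sub("^#", "", first))
  if (!identical(hdr$format, "stmorph-feature-series/1"))
    stop("unsupported feature-series format version in ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  w <- hdr$window
  structure(df, class = c("feature_series", "data.frame"),
            n_coeffs = hdr$n_coeffs, n_d = hdr$n_d,
            window = st_window_spec(w$start_offset_ms, w$end_offset_ms,
                                    w$n_samples),
            provenance = hdr$provenance)
}

#' Export a basis matrix as TSV with a JSON sidecar
#'
#' Rows are window samples, columns basis functions, 12 significant digits;
#' the sidecar (`<path>.json`) records the kind, window specification and
#' the orthonormality errors of the first 10 columns.
#'
#' @param basis a `basis_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_basis <- function(basis, path) {
  e <- signif(entries_of(basis), 12)
  colnames(e) <- paste0("phi_", seq_len(ncol(e)))
  utils::write.table(e, path, sep = "\t", row.names = FALSE, quote = FALSE)
  err <- orthonormality_error(basis, min(10, ncol(e)))
  side <- list(kind = basis$kind, window = unclass(basis$window),
               max_diag_error = err$max_diag_error,
               max_offdiag_error = err$max_offdiag_error)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Save / load a trained KLT model as JSON
#'
#' @param model list with `klt`, `lpt`, `norm` as returned by
#'   [train_klt()].
#' @param path JSON file path.
#' @return `path` invisibly / the reconstructed model list.
#' @export
write_klt_model <- function(model, path) {
  obj <- list(format = "stmorph-klt-model/1",
              window = unclass(model$klt$basis$window),
              basis = model$klt$basis$entries,
              eigenvalues = model$klt$eigenvalues,
              grand_mean = model$klt$grand_mean,
              rho = model$norm$rho, theta = model$norm$theta,
              provenance = model$norm$provenance)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_klt_model
#' @export
read_klt_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  w <- as.list(obj$window)
  window <- st_window_spec(w$start_offset_ms, w$end_offset_ms, w$n_samples)
  M <- nrow(obj$basis)
  klt <- structure(list(basis = new_basis_matrix(obj$basis, "KLT", window,
                                                 rep(1, M)),
                        eigenvalues = as.numeric(obj$eigenvalues),
                        grand_mean = as.numeric(obj$grand_mean)),
                   class = "klt_model")
  list(klt = klt, lpt = lpt_basis(M, window = window),
       norm = normalization_model(as.numeric(obj$rho),
                                  as.numeric(obj$theta),
                                  as.character(obj$provenance)))
}

#' Run configuration
#'
#' Bundles the tunable pipeline constants; round-trips losslessly through
#' YAML.
#'
#' @param ... overrides of the defaults.
#' @return named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(window = unclass(st_window_spec()), n_coeffs = 9L, n_d = 5L,
              lowpass_cutoff_hz = 55, lowpass_order = 6L,
              pq_search_ms = c(120, 20), pq_window_ms = 20,
              cv_folds = 10L, cv_repetitions = 10L, seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}
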