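#' Read an impedance spectrum from CSV
#'
#' Two header dialects are auto-detected:
#' `frequency_hz,z_real_ohm,z_imag_ohm` (Cartesian) and
#' `frequency_hz,z_mod_ohm,z_phase_deg` (Bode, with the phase stored in
#' the positive-degrees convention and converted back to a true complex
#' argument on read). Frequencies must be strictly increasing and all
#' values finite.
#'
#' @param path CSV file path.
#' @param ... replicate / tooth / label fields passed to
#'   [impedance_spectrum].
#' @return An [impedance_spectrum].
#' @export
read_spectrum <- function(path, ...) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  cart <- c("frequency_hz", "z_real_ohm", "z_imag_ohm")
  polar <- c("frequency_hz", "z_mod_ohm", "z_phase_deg")
  if (all(cart %in% names(df))) {
    z <- complex(real = df$z_real_ohm, imaginary = df$z_imag_ohm)
  } else if (all(polar %in% names(df))) {
    z <- complex(modulus = df$z_mod_ohm,
                 argument = -deg2rad(df$z_phase_deg))
  } else {
    stop(sprintf("unrecognized spectrum CSV header in %s", path),
         call. = FALSE)
  }
  if (any(is.na(df$frequency_hz)) || any(is.na(z)))
    stop(sprintf("NaN/missing values in %s", path), call. = FALSE)
  impedance_spectrum(df$frequency_hz, z, ...)
}

#' Write an impedance spectrum to CSV
#'
#' @param s an [impedance_spectrum].
#' @param path output path.
#' @param dialect `"cartesian"` (real/imaginary columns) or `"polar"`
#'   (magnitude and positive-convention phase).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, dialect = c("cartesian", "polar")) {
  stopifnot(inherits(s, "impedance_spectrum"))
  dialect <- match.arg(dialect)
  df <- if (dialect == "cartesian")
    data.frame(frequency_hz = s$frequency, z_real_ohm = Re(s$z),
               z_imag_ohm = Im(s$z))
  else
    data.frame(frequency_hz = s$frequency, z_mod_ohm = Mod(s$z),
               z_phase_deg = phase_positive(s$z))
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write circuit parameters as JSON
#'
#' JSON keys: `r1_ohm`, `r2_ohm`, `q_s^n_per_ohm`, `n`.
#'
#' @param path JSON file path.
#' @return [read_circuit_params]: a [circuit_params];
#'   [write_circuit_params]: `path`, invisibly.
#' @export
read_circuit_params <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  j <- jsonlite::read_json(path)
  circuit_params(r1 = j[["r1_ohm"]], r2 = j[["r2_ohm"]],
                 q = j[["q_s^n_per_ohm"]], n = j[["n"]])
}

#' @rdname read_circuit_params
#' @param p a [circuit_params].
#' @export
write_circuit_params <- function(p, path) {
  stopifnot(inherits(p, "circuit_params"))
  jsonlite::write_json(
    list(r1_ohm = p$r1, r2_ohm = p$r2, `q_s^n_per_ohm` = p$q, n = p$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a dataset manifest
#'
#' The manifest is a CSV with columns `file,label,tooth_id,replicate`
#' listing one spectrum file per row; `(tooth_id, replicate)` pairs
#' must be unique and labels must be `"ND"`/`"DM"`.
#'
#' @param d a [labeled_dataset].
#' @param dir output directory (created if needed); spectra are written
#'   as `tooth<id>_rep<k>.csv` alongside `manifest.csv`.
#' @return [write_dataset]: the manifest path, invisibly;
#'   [read_dataset]: a [labeled_dataset] (without provenance).
#' @export
write_dataset <- function(d, dir) {
  stopifnot(inherits(d, "labeled_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(d$spectra, function(s) {
    fn <- sprintf("tooth%03d_rep%d.csv", s$tooth_id, s$replicate_id)
    write_spectrum(s, file.path(dir, fn))
    data.frame(file = fn, label = s$label, tooth_id = s$tooth_id,
               replicate = s$replicate_id)
  })
  man <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' @rdname write_dataset
#' @param manifest path to a `manifest.csv`; spectrum files are
#'   resolved relative to its directory.
#' @export
read_dataset <- function(manifest) {
  if (!file.exists(manifest)) stop(sprintf("file not found: %s", manifest),
                                   call. = FALSE)
  man <- utils::read.csv(manifest)
  need <- c("file", "label", "tooth_id", "replicate")
  if (!all(need %in% names(man)))
    stop("manifest must have columns file,label,tooth_id,replicate",
         call. = FALSE)
  if (anyDuplicated(man[, c("tooth_id", "replicate")]))
    stop("duplicate (tooth_id, replicate) in manifest", call. = FALSE)
  base <- dirname(manifest)
  spectra <- lapply(seq_len(nrow(man)), function(i) {
    read_spectrum(file.path(base, man$file[i]),
                  replicate_id = man$replicate[i],
                  tooth_id = man$tooth_id[i], label = man$label[i])
  })
  structure(list(spectra = spectra, provenance = NULL,
                 model = NULL, noise = NULL),
            class = "labeled_dataset")
}
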