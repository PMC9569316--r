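# File dialects.
#
# Profiles: long TSV with header
#   molecule_id  molecule_class  phase  replicate  fraction  intensity
# iTSA: long TSV with header
#   protein_id  phase  temperature  replicate  intensity
#   (temperature "RT" is accepted and encoded as 22 C internally)
# Abundance: wide TSV (rows = proteins, columns = sample ids) plus a
#   sample-sheet CSV with columns sample_id, phase, replicate.
# MW standards: two-column CSV (fraction, mass_kDa).

validate_profiles <- function(profiles) {
  need <- c("molecule_id", "molecule_class", "phase", "replicate",
            "fraction", "intensity")
  if (!is.data.frame(profiles) || !all(need %in% names(profiles)))
    stop_secshift(paste("profiles need columns:",
                        paste(need, collapse = ", ")),
                  "secshift_format_error")
  if (any(profiles$intensity < 0, na.rm = TRUE))
    stop_secshift("negative intensity in profiles", "secshift_format_error")
  invisible(profiles)
}

#' Extract the replicate-by-fraction matrix for one molecule and phase
#'
#' @param profiles an `elution_profiles` data.frame.
#' @param molecule,phase selection labels.
#' @return numeric matrix (replicates x fractions), or NULL when the
#'   molecule was not measured in that phase.
#' @export
profile_matrix <- function(profiles, molecule, phase) {
  sub <- profiles[profiles$molecule_id == molecule &
                    profiles$phase == phase, ]
  if (!nrow(sub)) return(NULL)
  reps <- sort(unique(sub$replicate))
  frs <- sort(unique(profiles$fraction))
  m <- matrix(0, length(reps), length(frs),
              dimnames = list(reps, frs))
  m[cbind(match(sub$replicate, reps), match(sub$fraction, frs))] <-
    sub$intensity
  m
}

#' Read elution profiles from the long TSV dialect
#'
#' @param path TSV file with columns molecule_id, molecule_class, phase,
#'   replicate, fraction, intensity.
#' @return validated `elution_profiles` data.frame.
#' @export
read_profiles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_profiles(df)
  if (!is.numeric(df$fraction) || any(df$fraction < 1) ||
      any(df$fraction != as.integer(df$fraction)))
    stop_secshift("fractions must be 1-based integers",
                  "secshift_format_error")
  key <- paste(df$molecule_id, df$phase, df$replicate, df$fraction)
  if (anyDuplicated(key)) {
    lines <- which(duplicated(key)) + 1L  # +1 for the header line
    stop_secshift(sprintf("duplicate (molecule, phase, replicate, fraction) rows at line(s) %s",
                          paste(utils::head(lines, 5), collapse = ", ")),
                  "secshift_format_error")
  }
  class(df) <- c("elution_profiles", "data.frame")
  df
}

#' Write elution profiles to the long TSV dialect
#'
#' @param profiles an `elution_profiles` data.frame.
#' @param path output path.
#' @export
write_profiles <- function(profiles, path) {
  validate_profiles(profiles)
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read iTSA records from the long TSV dialect
#'
#' @param path TSV with columns protein_id, phase, temperature, replicate,
#'   intensity; temperature may be numeric or the label "RT".
#' @param rt_celsius numeric encoding for "RT" (default 22).
#' @return validated `itsa_records` data.frame with numeric temperatures.
#' @export
read_itsa <- function(path, rt_celsius = 22) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(temperature = "character"))
  df$temperature[toupper(df$temperature) == "RT"] <- as.character(rt_celsius)
  tnum <- suppressWarnings(as.numeric(df$temperature))
  if (anyNA(tnum))
    stop_secshift(sprintf("unparseable temperature at line(s) %s",
                          paste(utils::head(which(is.na(tnum)) + 1L, 5),
                                collapse = ", ")),
                  "secshift_format_error")
  df$temperature <- tnum
  validate_itsa_records(df)
  key <- paste(df$protein_id, df$phase, df$temperature, df$replicate)
  if (anyDuplicated(key))
    stop_secshift("duplicate (protein, phase, temperature, replicate) rows",
                  "secshift_format_error")
  class(df) <- c("itsa_records", "data.frame")
  df
}

#' Write iTSA records to the long TSV dialect
#'
#' @param records an `itsa_records` data.frame.
#' @param path output path.
#' @param rt_celsius temperatures equal to this value are written as "RT".
#' @export
write_itsa <- function(records, path, rt_celsius = 22) {
  validate_itsa_records(records)
  out <- records
  out$temperature <- ifelse(out$temperature == rt_celsius, "RT",
                            as.character(out$temperature))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a wide abundance table plus sample sheet
#'
#' @param path wide TSV: first column protein ids, remaining columns sample
#'   intensities.
#' @param samples_path CSV with columns sample_id, phase, replicate.
#' @return an [abundance_matrix()].
#' @export
read_abundance <- function(path, samples_path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "phase", "replicate") %in% names(samples)))
    stop_secshift("sample sheet needs sample_id, phase, replicate",
                  "secshift_format_error")
  if (!setequal(samples$sample_id, colnames(m)))
    stop_secshift("sample sheet does not match abundance columns",
                  "secshift_format_error")
  samples <- samples[match(colnames(m), samples$sample_id), ]
  abundance_matrix(m, samples)
}

#' Write an abundance matrix and its sample sheet
#'
#' @param am an `abundance_matrix`.
#' @param path wide TSV output path.
#' @param samples_path sample-sheet CSV output path.
#' @export
write_abundance <- function(am, path, samples_path) {
  stopifnot(inherits(am, "abundance_matrix"))
  df <- data.frame(protein_id = rownames(am$intensities),
                   am$intensities, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(am$samples, samples_path, row.names = FALSE)
  invisible(path)
}

#' Read molecular-weight calibration standards
#'
#' @param path two-column CSV (fraction, mass_kDa).
#' @return data.frame usable by [fit_mw_calibration()].
#' @export
read_mw_standards <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("fraction", "mass_kDa") %in% names(df)))
    stop_secshift("standards CSV needs columns fraction, mass_kDa",
                  "secshift_format_error")
  df
}
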