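# Model JSON, titration CSV and report writers.
#
# Model JSON schema:
#   {components, pKw, temperature, ionic_strength, species:
#     [{p, q, r, logbeta, sigma, refine}], description}
# Titration CSV: header `point,v_cm3,emf_mV,pH,T_M,T_L,T_H`, preceded by
# '#' provenance comment lines (package version, seed, electrode, v0).

model_json_keys <- c("components", "pKw", "temperature", "ionic_strength",
                     "species", "description")
species_json_keys <- c("p", "q", "r", "logbeta", "sigma", "refine")

#' Read an equilibrium model from JSON
#'
#' Validates the schema strictly: unknown keys are rejected with the
#' offending field named, duplicate (p,q,r) species are an error, and a
#' missing `pKw` falls back to the default 13.73 with a message.
#'
#' @param path Path to a model JSON file.
#' @param quiet Suppress the missing-pKw message.
#' @return An [eq_model()].
#' @export
read_model <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("No such model file: ", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  extra <- setdiff(names(raw), model_json_keys)
  if (length(extra)) {
    abort(paste0("Unknown key(s) in model file: ",
                 paste(extra, collapse = ", ")))
  }
  if (is.null(raw$species)) abort("Model file has no 'species' field.")
  spdf <- as.data.frame(raw$species)
  extra <- setdiff(names(spdf), species_json_keys)
  if (length(extra)) {
    abort(paste0("Unknown key(s) in species entries: ",
                 paste(extra, collapse = ", ")))
  }
  for (k in c("p", "q", "r", "logbeta")) {
    if (is.null(spdf[[k]])) abort(paste0("Species entries lack '", k, "'."))
  }
  pKw <- raw$pKw
  if (is.null(pKw)) {
    pKw <- 13.73
    if (!quiet) inform("Model file has no pKw; using default 13.73.")
  }
  sp <- eq_species(spdf$p, spdf$q, spdf$r, spdf$logbeta,
                   sigma = spdf$sigma %||% NA_real_,
                   refine = spdf$refine %||% FALSE)
  eq_model(sp,
           components = raw$components %||% c("M", "L", "H"),
           pKw = pKw,
           temperature = raw$temperature %||% 25,
           ionic_strength = raw$ionic_strength %||% 0.15)
}

#' Write an equilibrium model to JSON
#'
#' Inverse of [read_model()]; the hydroxide bookkeeping species (0,0,-1) is
#' serialized too, so files round-trip losslessly.
#'
#' @param model An [eq_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "eq_model"))
  sp <- model$species
  out <- list(components = model$components, pKw = model$pKw,
              temperature = model$temperature,
              ionic_strength = model$ionic_strength,
              species = data.frame(p = sp$p, q = sp$q, r = sp$r,
                                   logbeta = sp$log_beta, sigma = sp$sigma,
                                   refine = sp$refine))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

titration_cols <- c("point", "v_cm3", "emf_mV", "pH", "T_M", "T_L", "T_H")

provenance_header <- function(seed = NULL, inputs = character(), extra = list()) {
  lines <- c(
    sprintf("# eqspec %s", as.character(packageVersion("eqspec"))),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else format(seed)))
  for (f in inputs) {
    if (file.exists(f)) {
      lines <- c(lines, sprintf("# input: %s md5:%s", basename(f),
                                unname(tools::md5sum(f))))
    }
  }
  for (nm in names(extra)) {
    lines <- c(lines, sprintf("# %s: %s", nm, format(extra[[nm]])))
  }
  lines
}

#' Write a titration curve to CSV
#'
#' Emits the column layout `point,v_cm3,emf_mV,pH,T_M,T_L,T_H` preceded by
#' '#' comment lines carrying provenance (package version, seed, electrode
#' parameters, initial volume, input-file hashes).
#'
#' @param curve A `titration_curve` tibble.
#' @param path Output path.
#' @param inputs Optional character vector of input files to hash into the
#'   header.
#' @return `path`, invisibly.
#' @export
write_titration <- function(curve, path, inputs = character()) {
  stopifnot(all(titration_cols %in% names(curve)))
  meta <- list(E0_mV = attr(curve, "E0") %||% NA,
               slope_mV = attr(curve, "slope") %||% NA,
               v0_cm3 = attr(curve, "v0") %||% NA)
  hdr <- provenance_header(seed = attr(curve, "seed"), inputs = inputs,
                           extra = meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    format(as.data.frame(curve)[titration_cols], digits = 15, trim = TRUE,
           scientific = NA),
    con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a titration curve from CSV
#'
#' Validates required columns and strictly increasing volumes. When both
#' emf and pH columns are present together with electrode parameters in the
#' provenance header, the pH implied by the emf is cross-checked; a mismatch
#' worse than 0.02 pH units raises a warning naming the worst point.
#'
#' @param path Path to a titration CSV written by [write_titration()] (or
#'   following the same layout).
#' @return A `titration_curve` tibble.
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) abort(paste0("No such titration file: ", path))
  hdr <- character()
  con <- file(path, "r")
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  close(con)
  df <- tryCatch(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE),
    error = function(e) abort(paste0("Cannot parse titration CSV: ",
                                     conditionMessage(e))))
  if (!nrow(df)) abort("Titration file contains no data points.")
  missing <- setdiff(setdiff(titration_cols, "emf_mV"), names(df))
  if (length(missing)) {
    abort(paste0("Titration CSV lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(diff(df$v_cm3) <= 0)) abort("Titrant volumes must be strictly increasing.")
  grab <- function(key) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(m)) suppressWarnings(as.numeric(sub(paste0("^# ", key, ": "), "", m[1]))) else NA_real_
  }
  E0 <- grab("E0_mV"); s <- grab("slope_mV")
  out <- as_tibble(df)
  if ("emf_mV" %in% names(df) && is.finite(E0) && is.finite(s) && s != 0) {
    ph_from_emf <- (E0 - df$emf_mV) / s
    dev <- abs(ph_from_emf - df$pH)
    if (max(dev) > 0.02) {
      warn(sprintf(
        "emf/pH inconsistency: worst point %d deviates by %.3f pH units.",
        df$point[which.max(dev)], max(dev)))
    }
  }
  attr(out, "E0") <- E0
  attr(out, "slope") <- s
  attr(out, "v0") <- grab("v0_cm3")
  attr(out, "seed") <- grab("seed")
  class(out) <- c("titration_curve", class(out))
  out
}

#' Write a result object to machine- and human-readable files
#'
#' Dispatches on the result type: a refinement is written as JSON plus a
#' text block laid out like a formation-constant table (p, q, r,
#' log beta (sigma), R-factor and its limit); a pmi curve as JSON plus CSV
#' `metal,log_c,log_pmi`; a speciation distribution as JSON plus CSV.
#'
#' @param result A `beta_refinement`, `pmi_curve` or
#'   `speciation_distribution` object.
#' @param path Output path stem; `.json` and `.txt`/`.csv` are appended.
#' @param seed Optional seed to record in the provenance header.
#' @param inputs Optional input files to hash into the provenance header.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(result, path, seed = NULL, inputs = character()) {
  UseMethod("write_report")
}

#' @export
write_report.beta_refinement <- function(result, path, seed = NULL,
                                         inputs = character()) {
  jpath <- paste0(path, ".json")
  tpath <- paste0(path, ".txt")
  est <- result$estimates
  payload <- list(
    provenance = provenance_header(seed, inputs),
    estimates = as.data.frame(est),
    R_H = result$R_H, R_lim = result$R_lim,
    iterations = result$iterations, converged = result$converged,
    n_points = result$n_points, observable = result$observable)
  jsonlite::write_json(payload, jpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  lines <- c(provenance_header(seed, inputs),
             sprintf("%3s %3s %3s  %-14s %-10s", "p", "q", "r",
                     "log beta(sigma)", "flag"),
             sprintf("%3d %3d %3d  %8.4f (%.4f) %s",
                     est$p, est$q, est$r, est$log_beta, est$sigma,
                     ifelse(est$detectable, "", "not supported by data")),
             sprintf("R_H = %.4f  R_lim = %.4f  (%d points, %d iterations, converged: %s)",
                     result$R_H, result$R_lim, result$n_points,
                     result$iterations, result$converged))
  writeLines(lines, tpath)
  invisible(c(jpath, tpath))
}

#' @export
write_report.pmi_curve <- function(result, path, seed = NULL,
                                   inputs = character()) {
  jpath <- paste0(path, ".json")
  cpath <- paste0(path, ".csv")
  df <- data.frame(metal = result$metal, log_c = result$log10_drug,
                   log_pmi = result$log10_pmi)
  jsonlite::write_json(list(provenance = provenance_header(seed, inputs),
                            pmi = df),
                       jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(cpath, "w"); on.exit(close(con))
  writeLines(provenance_header(seed, inputs), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(c(jpath, cpath))
}

#' @export
write_report.speciation_distribution <- function(result, path, seed = NULL,
                                                 inputs = character()) {
  jpath <- paste0(path, ".json")
  cpath <- paste0(path, ".csv")
  df <- as.data.frame(result)
  jsonlite::write_json(list(provenance = provenance_header(seed, inputs),
                            basis = attr(result, "basis"),
                            T_M = attr(result, "T_M"),
                            T_L = attr(result, "T_L"),
                            distribution = df),
                       jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(cpath, "w"); on.exit(close(con))
  writeLines(provenance_header(seed, inputs), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(c(jpath, cpath))
}
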