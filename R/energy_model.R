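# Data model for static energy records and dynamic gap ensembles.
# Both containers are canonicalised to eV on construction; file readers
# accept hartree / eV / kcal_per_mol and convert on ingest.

.charge_states <- c("neutral", "cation")
.phases <- c("gas", "solvent")
.geometries <- c("gas_optimized", "solvent_optimized", "as_sampled")
.quantities <- c("E_e", "G_T")
.gap_kinds <- c("VIE", "VAE", "total_potential_energy")
.solvent_models <- c("implicit", "explicit")

.record_key_cols <- c("species", "charge_state", "phase", "geometry",
                      "quantity", "method_tag")

.check_enum <- function(x, allowed, what) {
  bad <- which(!x %in% allowed)
  if (length(bad) > 0) {
    stop("unknown ", what, " token '", x[bad[1]], "' in row ", bad[1],
         " (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
  }
}

#' Build a validated set of species energy records
#'
#' A species energy record holds one scalar quantity -- the electronic
#' energy E_e or the thermal correction to the Gibbs free energy G_T --
#' for one (species, charge state, phase, geometry, method) combination.
#' Long format: one quantity per row, so records without a thermal
#' correction are representable.
#'
#' @param df data frame with columns `species`, `charge_state`
#'   (neutral/cation), `phase` (gas/solvent), `geometry`
#'   (gas_optimized/solvent_optimized/as_sampled), `quantity` (E_e/G_T),
#'   `value`, `unit`, `method_tag`.
#' @return a `species_energy_records` data frame with values converted
#'   to eV in column `value_eV`. Duplicate keys are rejected, citing the
#'   offending rows.
#' @export
species_energy_records <- function(df) {
  required <- c("species", "charge_state", "phase", "geometry",
                "quantity", "value", "unit", "method_tag")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  .check_enum(df$charge_state, .charge_states, "charge_state")
  .check_enum(df$phase, .phases, "phase")
  .check_enum(df$geometry, .geometries, "geometry")
  .check_enum(df$quantity, .quantities, "quantity")
  if (!is.numeric(df$value) || anyNA(df$value)) {
    stop("'value' must be numeric and complete", call. = FALSE)
  }
  key <- do.call(paste, c(df[.record_key_cols], sep = "\r"))
  if (anyDuplicated(key)) {
    d <- which(key %in% key[duplicated(key)])
    stop("duplicate record key in rows ", paste(d, collapse = ", "),
         " (species=", df$species[d[1]], ", charge_state=",
         df$charge_state[d[1]], ", phase=", df$phase[d[1]],
         ", geometry=", df$geometry[d[1]], ", quantity=",
         df$quantity[d[1]], ")", call. = FALSE)
  }
  out <- df[c(.record_key_cols[1:5], "method_tag")]
  out$value_eV <- convert_energy(df$value, df$unit, "eV")
  class(out) <- c("species_energy_records", "data.frame")
  out
}

#' Read a species energy table from CSV or JSON
#'
#' @param path CSV file (comma separated, header required, '.' decimal)
#'   or JSON file (array of objects) with the
#'   [species_energy_records()] schema.
#' @return a `species_energy_records` data frame (values in eV).
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (NROW(df) == 0) stop("empty species table: ", path, call. = FALSE)
  species_energy_records(df)
}

#' Write a species energy table
#'
#' Emits the canonical long-format schema with values in eV, either as
#' CSV or as a JSON array of objects. Values are written with 17
#' significant digits so that a read/write/read round trip is
#' bit-exact.
#'
#' @param records a `species_energy_records` object.
#' @param path output file; format chosen from the extension
#'   (`.json` vs anything else = CSV).
#' @export
write_species_table <- function(records, path) {
  stopifnot(inherits(records, "species_energy_records"))
  df <- as.data.frame(records)
  df$unit <- "eV"
  df$value <- sprintf("%.17g", df$value_eV)
  df <- df[c("species", "charge_state", "phase", "geometry", "quantity",
             "value", "unit", "method_tag")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df$value <- as.numeric(df$value)
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Construct an ensemble of vertical energy gaps or total energies
#'
#' A gap ensemble is an ordered collection of per-snapshot energies for
#' one species: vertical ionization energies (VIE, sampled on the
#' neutral-state trajectory), vertical attachment energies (VAE, sampled
#' on the cation trajectory), or total potential energies (for the
#' dynamic direct protocol).
#'
#' @param values numeric vector of energies (at least one value).
#' @param species species identifier.
#' @param gap_kind `"VIE"`, `"VAE"` or `"total_potential_energy"`.
#' @param sampled_state `"neutral"` or `"cation"`; defaults to the state
#'   implied by `gap_kind` (VIE: neutral, VAE: cation) and is checked
#'   for consistency.
#' @param solvent_model `"implicit"` or `"explicit"`.
#' @param method_tag free-text label (functional / solvent model).
#' @param unit unit of `values`; converted to eV internally.
#' @return an object of class `gap_ensemble`.
#' @export
gap_ensemble <- function(values, species, gap_kind,
                         sampled_state = NULL,
                         solvent_model = "implicit",
                         method_tag = "",
                         unit = "eV") {
  gap_kind <- match.arg(gap_kind, .gap_kinds)
  solvent_model <- match.arg(solvent_model, .solvent_models)
  if (length(values) < 1 || !is.numeric(values) || anyNA(values)) {
    stop("ensemble values must be a non-empty numeric vector without NA",
         call. = FALSE)
  }
  implied <- switch(gap_kind, VIE = "neutral", VAE = "cation", NULL)
  if (is.null(sampled_state)) {
    sampled_state <- if (is.null(implied)) "neutral" else implied
  }
  sampled_state <- match.arg(sampled_state, .charge_states)
  if (!is.null(implied) && sampled_state != implied) {
    stop(gap_kind, " ensembles must be sampled on the ", implied,
         " state, got sampled_state = '", sampled_state, "'", call. = FALSE)
  }
  out <- list(
    species = as.character(species),
    gap_kind = gap_kind,
    sampled_state = sampled_state,
    values = convert_energy(as.numeric(values), unit, "eV"),
    solvent_model = solvent_model,
    method_tag = as.character(method_tag)
  )
  class(out) <- "gap_ensemble"
  out
}

#' @export
print.gap_ensemble <- function(x, ...) {
  cat(sprintf("Gap ensemble: %s %s (%s solvent, sampled on %s)\n",
              x$species, x$gap_kind, x$solvent_model, x$sampled_state))
  cat(sprintf("  n = %d snapshots", length(x$values)))
  if (length(x$values) >= 2) {
    cat(sprintf(", mean = %.4f eV, sd = %.4f eV",
                mean(x$values), stats::sd(x$values)))
  }
  cat("\n")
  if (nzchar(x$method_tag)) cat("  method:", x$method_tag, "\n")
  invisible(x)
}

#' @export
length.gap_ensemble <- function(x) length(x$values)

#' Read a gap ensemble from CSV or JSON
#'
#' Columns: `species`, `gap_kind`, `sampled_state`, `snapshot_id`,
#' `value`, `unit`, `solvent_model`, `method_tag`. Metadata must be
#' uniform across rows (a file mixing gap kinds or solvent models is
#' rejected); values are ordered by `snapshot_id`, an opaque sort key.
#'
#' @param path CSV or JSON file.
#' @return a [gap_ensemble()].
#' @export
read_gap_ensemble <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (NROW(df) == 0) stop("empty gap ensemble file: ", path, call. = FALSE)
  required <- c("species", "gap_kind", "sampled_state", "snapshot_id",
                "value", "unit", "solvent_model", "method_tag")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("species", "gap_kind", "sampled_state", "solvent_model",
                "method_tag", "unit")) {
    if (length(unique(df[[col]])) > 1) {
      stop("mixed '", col, "' values within one ensemble file: ",
           paste(unique(df[[col]]), collapse = " vs "), call. = FALSE)
    }
  }
  df <- df[order(df$snapshot_id), ]
  gap_ensemble(df$value, species = df$species[1], gap_kind = df$gap_kind[1],
               sampled_state = df$sampled_state[1],
               solvent_model = df$solvent_model[1],
               method_tag = df$method_tag[1], unit = df$unit[1])
}

#' Write a gap ensemble
#'
#' @param ens a [gap_ensemble()].
#' @param path output CSV or JSON file.
#' @export
write_gap_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "gap_ensemble"))
  df <- data.frame(
    species = ens$species, gap_kind = ens$gap_kind,
    sampled_state = ens$sampled_state,
    snapshot_id = seq_along(ens$values),
    value = sprintf("%.17g", ens$values), unit = "eV",
    solvent_model = ens$solvent_model, method_tag = ens$method_tag,
    stringsAsFactors = FALSE
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df$value <- as.numeric(df$value)
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Ensemble mean and standard deviation
#'
#' Arithmetic mean and sample (N-1 denominator) standard deviation of a
#' gap ensemble, both in eV.
#'
#' @param ens a [gap_ensemble()] with at least two values.
#' @return named list with elements `mean` and `sd`.
#' @export
ensemble_mean_sd <- function(ens) {
  stopifnot(inherits(ens, "gap_ensemble"))
  if (length(ens$values) < 2) {
    stop("ensemble statistics need at least 2 snapshots, got ",
         length(ens$values), call. = FALSE)
  }
  list(mean = mean(ens$values), sd = stats::sd(ens$values))
}

# Internal: check that two ensembles are statistically compatible for a
# paired estimator (same species and solvent model).
.check_pair <- function(a, b, kinds = NULL) {
  stopifnot(inherits(a, "gap_ensemble"), inherits(b, "gap_ensemble"))
  if (!is.null(kinds)) {
    if (a$gap_kind != kinds[1] || b$gap_kind != kinds[2]) {
      stop("expected a (", kinds[1], ", ", kinds[2], ") ensemble pair, got (",
           a$gap_kind, ", ", b$gap_kind, ")", call. = FALSE)
    }
  }
  if (a$solvent_model != b$solvent_model) {
    stop("mismatched solvent models: ", a$solvent_model, " vs ",
         b$solvent_model, call. = FALSE)
  }
  if (a$species != b$species) {
    stop("mismatched species: ", a$species, " vs ", b$species, call. = FALSE)
  }
  invisible(TRUE)
}
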