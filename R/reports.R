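# Report assembly: run every requested protocol over a set of inputs,
# collect potentials, diagnostics and benchmark tables, and persist
# them (TSV for reading, JSON for full precision) together with the
# configuration so a run can be replayed exactly.

.write_tsv <- function(df, path, digits = 2) {
  rounded <- df
  for (nm in names(rounded)) {
    if (is.numeric(rounded[[nm]])) rounded[[nm]] <- round(rounded[[nm]], digits)
  }
  utils::write.table(rounded, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.as_ensemble <- function(x) {
  if (inherits(x, "gap_ensemble")) x else read_gap_ensemble(x)
}

#' Run the full static/dynamic comparison workflow
#'
#' Drives every stage over one configuration: static potentials from an
#' energy-record table, dynamic potentials and linear-response
#' diagnostics from VIE/VAE and total-energy ensembles (with the
#' nonlinear correction applied automatically when requested and the
#' diagnostics flag a non-Marcus regime), tautomer-weighted potentials,
#' and a benchmark of everything against experimental ranges.
#'
#' @param config a named list (or path to a YAML/JSON file encoding
#'   one) with any of the entries:
#'   \describe{
#'     \item{species_table}{path to a [read_species_table()] file (or a
#'       records object); static protocols are run for each species in
#'       it.}
#'     \item{static_protocols}{subset of `c("static_direct", "cycle1",
#'       "cycle2")`; default all three.}
#'     \item{ensembles}{list of entries, each a list with optional
#'       `vie`/`vae` (Marcus + diagnostics) and/or `neutral`/`cation`
#'       (dynamic direct) ensemble paths or objects.}
#'     \item{auto_correct}{logical (default `TRUE`): apply
#'       [matyushov_voth_corrected()] to pairs whose diagnostics report
#'       a non-Marcus regime. `"always"` corrects every pair.}
#'     \item{tautomer_sets}{list of [read_tautomer_set()] paths or
#'       `tautomer_set` objects.}
#'     \item{ranges}{path to an [experimental_ranges()] file; default
#'       the packaged table. `NA` skips benchmarking.}
#'     \item{constants}{named list of [energy_constants()] overrides.}
#'     \item{out_dir}{directory for report files; created if absent.
#'       `NULL` (default) writes nothing.}
#'   }
#' @return invisibly, a list with `potentials`, `diagnostics`,
#'   `benchmark`, `tautomers` tables and the resolved `config`. When
#'   `out_dir` is set, writes `potentials.tsv`, `diagnostics.tsv`,
#'   `benchmark.tsv`, `tautomers.tsv` (two-decimal display tables),
#'   `results.json` (full precision) and `config.json`.
#' @export
run_full_comparison <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
    }
  }
  stopifnot(is.list(config))
  constants <- do.call(energy_constants,
                       if (is.null(config$constants)) list() else
                         config$constants)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  potentials <- list()
  add_pot <- function(species, protocol, solvent_model, method_tag,
                      potential, spread = NA_real_) {
    potentials[[length(potentials) + 1]] <<- data.frame(
      species = species, protocol = protocol,
      solvent_model = solvent_model, method_tag = method_tag,
      potential_V = potential, spread_V = spread,
      stringsAsFactors = FALSE)
  }

  # --- static stage -------------------------------------------------
  if (!is.null(config$species_table)) {
    records <- stage("static", {
      if (inherits(config$species_table, "species_energy_records")) {
        config$species_table
      } else {
        read_species_table(config$species_table)
      }
    })
    protos <- config$static_protocols
    if (is.null(protos)) protos <- c("static_direct", "cycle1", "cycle2")
    for (sp in unique(records$species)) {
      for (tag in unique(records$method_tag[records$species == sp])) {
        for (proto in protos) {
          res <- stage(paste0("static/", sp, "/", proto), {
            if (proto == "static_direct") {
              static_direct(records, sp, constants, method_tag = tag)
            } else {
              cycle_potential(records, sp, proto, constants, method_tag = tag)
            }
          })
          add_pot(sp, proto, "implicit", tag, res$potential_V)
        }
      }
    }
  }

  # --- dynamic stage ------------------------------------------------
  diagnostics <- list()
  for (entry in config$ensembles) {
    if (!is.null(entry$vie) && !is.null(entry$vae)) {
      vie <- stage("dynamic/read", .as_ensemble(entry$vie))
      vae <- stage("dynamic/read", .as_ensemble(entry$vae))
      res <- stage("dynamic/marcus", marcus_free_energy(vie, vae, constants))
      add_pot(res$species, res$protocol, res$solvent_model, vie$method_tag,
              res$potential_V, res$spread_V)
      diag <- stage("dynamic/diagnose",
                    linear_response_report(vie, vae, constants))
      diagnostics[[length(diagnostics) + 1]] <- data.frame(
        species = diag$species, solvent_model = diag$solvent_model,
        method_tag = vie$method_tag,
        sigma_vie_eV = diag$sigma_vie_eV, sigma_vae_eV = diag$sigma_vae_eV,
        lambda_gap_eV = diag$lambda_gap_eV,
        lambda_neutral_eV = diag$lambda_neutral_eV,
        lambda_cation_eV = diag$lambda_cation_eV,
        gaussian_vie = diag$gaussian_vie, gaussian_vae = diag$gaussian_vae,
        sigma_equal = diag$sigma_equal,
        lambda_consistent = diag$lambda_consistent,
        regime = diag$regime, stringsAsFactors = FALSE)
      auto <- if (is.null(config$auto_correct)) TRUE else config$auto_correct
      correct <- identical(auto, "always") ||
        (isTRUE(auto) && diag$regime == "non_marcus")
      if (correct) {
        cres <- stage("dynamic/correct",
                      matyushov_voth_corrected(vie, vae, constants))
        add_pot(cres$species, cres$protocol, cres$solvent_model,
                vie$method_tag, cres$potential_V, cres$spread_V)
      }
    }
    if (!is.null(entry$neutral) && !is.null(entry$cation)) {
      en <- stage("dynamic/read", .as_ensemble(entry$neutral))
      ec <- stage("dynamic/read", .as_ensemble(entry$cation))
      res <- stage("dynamic/direct", dynamic_direct(en, ec, constants))
      add_pot(res$species, res$protocol, res$solvent_model, en$method_tag,
              res$potential_V, res$spread_V)
    }
  }

  # --- tautomer stage -----------------------------------------------
  tautomers <- list()
  for (ts in config$tautomer_sets) {
    set <- stage("tautomer", {
      if (inherits(ts, "tautomer_set")) ts else read_tautomer_set(ts)
    })
    tautomers[[length(tautomers) + 1]] <- data.frame(
      species = set$parent_species, n_tautomers = nrow(set$members),
      potential_V = ensemble_potential(set, constants),
      stringsAsFactors = FALSE)
  }

  pot_df <- if (length(potentials) > 0) do.call(rbind, potentials) else
    data.frame()
  diag_df <- if (length(diagnostics) > 0) do.call(rbind, diagnostics) else
    data.frame()
  taut_df <- if (length(tautomers) > 0) do.call(rbind, tautomers) else
    data.frame()

  # --- benchmark stage ----------------------------------------------
  bench <- NULL
  skip_bench <- length(config$ranges) == 1 && is.na(config$ranges)
  if (nrow(pot_df) > 0 && !skip_bench) {
    ranges <- stage("benchmark", {
      if (is.null(config$ranges)) experimental_ranges() else
        experimental_ranges(config$ranges)
    })
    covered <- pot_df$species %in% ranges$species
    if (any(covered)) {
      bench <- stage("benchmark",
                     mue(pot_df[covered, , drop = FALSE], ranges,
                         group_by = c("method_tag", "protocol")))
    }
  }

  out <- list(potentials = pot_df, diagnostics = diag_df,
              tautomers = taut_df, benchmark = bench, config = config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    .write_tsv(pot_df, p("potentials.tsv"))
    if (nrow(diag_df) > 0) .write_tsv(diag_df, p("diagnostics.tsv"), 4)
    if (nrow(taut_df) > 0) .write_tsv(taut_df, p("tautomers.tsv"))
    if (!is.null(bench)) {
      .write_tsv(bench$mue, p("benchmark.tsv"))
      .write_tsv(bench$errors, p("benchmark_errors.tsv"))
    }
    jsonlite::write_json(
      list(potentials = pot_df, diagnostics = diag_df, tautomers = taut_df,
           benchmark = if (is.null(bench)) NULL else
             list(errors = bench$errors, mue = bench$mue)),
      p("results.json"), auto_unbox = TRUE, digits = NA, na = "null")
    serialisable <- config[!vapply(config, is.object, logical(1))]
    jsonlite::write_json(serialisable, p("config.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
  }
  invisible(out)
}
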