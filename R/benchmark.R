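# Benchmarking of computed potentials against experimental ranges:
# per-species unsigned errors relative to a reference point of each
# range (the midpoint by convention) and their mean (MUE).

#' Experimental oxidation-potential ranges
#'
#' Loads a table of experimental one-electron oxidation potential ranges
#' (volts vs SHE). The packaged default covers the five nucleobases in
#' aqueous solution, compiled from the electrochemical literature
#' (cyclic voltammetry, pulse radiolysis, kinetic and fluorescence
#' measurements), whose spread per species is substantial -- hence
#' ranges, not single values.
#'
#' @param path CSV with columns `species`, `low_V`, `high_V` and
#'   optionally `source_tag`; `NULL` loads the packaged table.
#' @return an `experimental_ranges` data frame.
#' @export
experimental_ranges <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "experimental_ranges.csv",
                        package = "oxpot", mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "low_V", "high_V")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("ranges file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(df$low_V > df$high_V)) {
    stop("invalid range (low > high) for species ",
         df$species[which(df$low_V > df$high_V)[1]], call. = FALSE)
  }
  if (is.null(df$source_tag)) df$source_tag <- "user"
  class(df) <- c("experimental_ranges", "data.frame")
  df
}

#' Reference one-electron oxidation potentials at the DFT level
#'
#' Packaged reference dataset: potentials of the five nucleobases
#' computed with three density functionals (PBEOP, M06-2X, B3LYP;
#' 6-311G(d) basis) under seven protocols -- static direct, two
#' thermodynamic cycles, and the dynamic direct / Marcus estimators in
#' implicit (COSMO) and explicit (TIP3P) solvent. Dynamic entries carry
#' the ensemble standard deviation. Useful as `computed` input for
#' [mue()] and as a worked benchmarking example.
#'
#' @return data frame with columns `species`, `method_tag`, `protocol`,
#'   `potential_V`, `sd_V`.
#' @export
reference_potentials <- function() {
  path <- system.file("extdata", "reference_dft_potentials.csv",
                      package = "oxpot", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference point of an experimental range
#'
#' @param ranges an [experimental_ranges()] data frame (or any data
#'   frame with `low_V`/`high_V`).
#' @param reference `"mid"` (the canonical choice), `"low"` or `"high"`.
#' @return numeric vector of reference potentials in volts.
#' @examples
#' reference_midpoint(data.frame(species = "A", low_V = 1.20, high_V = 1.63))
#' @export
reference_midpoint <- function(ranges, reference = c("mid", "low", "high")) {
  reference <- match.arg(reference)
  stopifnot(all(c("low_V", "high_V") %in% names(ranges)))
  if (any(ranges$low_V > ranges$high_V)) {
    stop("invalid range: low > high", call. = FALSE)
  }
  switch(reference,
         mid = (ranges$low_V + ranges$high_V) / 2,
         low = ranges$low_V,
         high = ranges$high_V)
}

#' Mean unsigned error of computed potentials
#'
#' For each computed species, the unsigned error is the absolute
#' difference between the computed potential and the reference point of
#' its experimental range (the range midpoint by default); the MUE is
#' their mean within each group.
#'
#' @param computed data frame with columns `species`, `potential_V` and
#'   optionally grouping columns (e.g. `method_tag`, `protocol`) and
#'   `sd_V` (propagated into a spread on the MUE).
#' @param ranges an [experimental_ranges()] table covering every
#'   computed species.
#' @param reference which point of the range to compare against
#'   (`"mid"`, `"low"`, `"high"`).
#' @param group_by character vector of grouping columns present in
#'   `computed`; by default any of `method_tag`, `protocol` found.
#' @return a `benchmark_report`: `errors` (per-species unsigned errors)
#'   and `mue` (one row per group, with `mue_V` and, when `sd_V` was
#'   supplied, `mue_spread_V`, the quadrature-mean spread).
#' @export
mue <- function(computed, ranges = experimental_ranges(),
                reference = c("mid", "low", "high"), group_by = NULL) {
  reference <- match.arg(reference)
  stopifnot(all(c("species", "potential_V") %in% names(computed)))
  if (is.null(group_by)) {
    group_by <- intersect(c("method_tag", "protocol"), names(computed))
  } else if (!all(group_by %in% names(computed))) {
    stop("group_by column(s) absent from computed: ",
         paste(setdiff(group_by, names(computed)), collapse = ", "),
         call. = FALSE)
  }
  missing_ref <- setdiff(unique(computed$species), ranges$species)
  if (length(missing_ref) > 0) {
    stop("no experimental range for species: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  ref <- data.frame(species = ranges$species,
                    reference_V = reference_midpoint(ranges, reference))
  errors <- merge(computed, ref, by = "species", sort = TRUE)
  errors$abs_error_V <- abs(errors$potential_V - errors$reference_V)

  grp <- if (length(group_by) > 0) {
    interaction(errors[group_by], drop = TRUE, lex.order = TRUE)
  } else {
    factor(rep("all", nrow(errors)))
  }
  mue_df <- do.call(rbind, lapply(levels(grp), function(g) {
    e <- errors[grp == g, , drop = FALSE]
    row <- if (length(group_by) > 0) {
      e[1, group_by, drop = FALSE]
    } else {
      data.frame(group = "all")
    }
    row$n_species <- nrow(e)
    row$mue_V <- mean(e$abs_error_V)
    row$mue_spread_V <- if ("sd_V" %in% names(e) && !anyNA(e$sd_V)) {
      sqrt(mean(e$sd_V^2))
    } else {
      NA_real_
    }
    row
  }))
  rownames(mue_df) <- NULL
  out <- list(errors = errors, mue = mue_df, reference = reference)
  class(out) <- "benchmark_report"
  out
}

#' @export
print.benchmark_report <- function(x, digits = 2, ...) {
  cat("Benchmark vs experimental ranges (reference:", x$reference, "point)\n")
  m <- x$mue
  m$mue_V <- round(m$mue_V, digits)
  if (all(is.na(m$mue_spread_V))) m$mue_spread_V <- NULL else
    m$mue_spread_V <- round(m$mue_spread_V, digits)
  print(m, row.names = FALSE)
  invisible(x)
}
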