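#' Species-level field summaries from raw perimeter records
#'
#' Runs the full measurement pipeline: infinity correction, per-individual
#' profile assembly, interpolation of blocked elevations, per-individual
#' summary statistics, then arithmetic averaging of the summaries across the
#' 1-3 individuals of each species.
#'
#' @param records Perimeter record tibble (see [profiles_from_records()]).
#' @param bill_tips Optional tibble `species`, `bill_tip_elevation_deg`
#'   giving the eye-bill-tip projection direction per species (default 0).
#' @return A tibble with one row per species: `n_individuals`,
#'   `max_overlap_deg`, `elevation_of_max_deg`, `vertical_extent_deg`,
#'   `offset_deg`.
#' @export
species_field_summaries <- function(records, bill_tips = NULL) {
  profiles <- profiles_from_records(records)
  per_ind <- profiles |>
    dplyr::group_by(.data$species, .data$individual) |>
    dplyr::group_modify(function(df, key) {
      bt <- 0
      if (!is.null(bill_tips)) {
        hit <- bill_tips$bill_tip_elevation_deg[
          bill_tips$species == key$species]
        if (length(hit)) bt <- hit[1]
      }
      df |> interpolate_blocked() |> summarize_field(bill_tip_elevation = bt)
    }) |>
    dplyr::ungroup()
  per_ind |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_individuals = dplyr::n(),
      max_overlap_deg = mean(.data$max_binocular_overlap),
      elevation_of_max_deg = mean(.data$elevation_of_max),
      vertical_extent_deg = mean(.data$vertical_extent),
      offset_deg = mean(.data$max_overlap_offset),
      .groups = "drop"
    )
}

#' Species-mean binocular-field outlines from perimeter records
#'
#' Averages the corrected per-individual widths at each elevation within a
#' species and converts the species-mean profile into a closed outline.
#'
#' @inheritParams species_field_summaries
#' @return A named list of closed outline tibbles, one per species.
#' @export
species_outlines <- function(records) {
  profiles <- profiles_from_records(records)
  filled <- profiles |>
    dplyr::group_by(.data$species, .data$individual) |>
    dplyr::group_modify(function(df, key) interpolate_blocked(df)) |>
    dplyr::ungroup()
  means <- filled |>
    dplyr::group_by(.data$species, .data$elevation) |>
    dplyr::summarise(binocular_width = mean(.data$binocular_width),
                     .groups = "drop")
  sp <- unique(means$species)
  out <- purrr::map(sp, function(s) {
    means |>
      dplyr::filter(.data$species == s) |>
      dplyr::arrange(.data$elevation) |>
      outline_from_profile()
  })
  setNames(out, sp)
}

#' Group means with standard errors
#'
#' Descriptive species-level means by an ecological class, with
#' `s.e. = s.d. / sqrt(n)`.
#'
#' @param traits Species trait tibble.
#' @param value Name of the trait column.
#' @param by Name of the grouping column.
#' @return A tibble `group`, `n`, `mean`, `se`.
#' @export
group_means <- function(traits, value, by) {
  traits |>
    dplyr::group_by(group = .data[[by]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[value]]),
      se = sd(.data[[value]]) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Set the reference levels used for ecological factors
#'
#' Diet is coded with `invertebrate` as baseline and habitat with `dense`
#' as baseline, so regression terms read as `diet [vertebrate]`,
#' `habitat [semi-open]`, `habitat [open]`.
#'
#' @param traits Species trait tibble with `diet` and/or `habitat` columns.
#' @return The tibble with factor levels fixed.
#' @export
prepare_traits <- function(traits) {
  traits <- tibble::as_tibble(traits)
  if ("diet" %in% names(traits)) {
    traits$diet <- factor(traits$diet,
                          levels = c("invertebrate", "vertebrate"))
  }
  if ("habitat" %in% names(traits)) {
    traits$habitat <- factor(traits$habitat,
                             levels = c("dense", "semi-open", "open"))
  }
  traits
}

#' Unidimensional comparative analysis of visual-field traits
#'
#' For each response trait: Pagel's-lambda phylogenetic signal, stepwise AIC
#' selection of ecological and allometric predictors, and the final PGLS
#' coefficient table. When habitat is selected for a response, the whole
#' factor is additionally tested with a simulation-based phylogenetic ANOVA.
#' If `dual_diet_species` names a species with an ambiguous diet, every diet
#' analysis is run twice, once with that species coded as a vertebrate eater
#' and once as an invertebrate eater.
#'
#' @param traits Species trait tibble (see [prepare_traits()]).
#' @param tree An `ape::phylo` tree.
#' @param responses Response columns to analyse.
#' @param candidates Candidate predictor columns.
#' @param dual_diet_species Species name to re-code, or `NULL`.
#' @param n_sims,seed Phylogenetic-ANOVA simulation settings.
#' @return An `analysis_report` list: `table` (per-term PGLS estimates),
#'   `signal`, `selection` traces, `anova`, and `provenance`.
#' @export
run_unidimensional <- function(traits, tree,
                               responses = c("max_overlap_deg",
                                             "vertical_extent_deg",
                                             "offset_deg"),
                               candidates = c("diet", "habitat",
                                              "body_mass_g",
                                              "eye_axial_length_mm"),
                               dual_diet_species = NULL,
                               n_sims = 1000, seed = 1) {
  traits <- prepare_traits(traits)
  codings <- list(default = traits)
  if (!is.null(dual_diet_species)) {
    stopifnot(dual_diet_species %in% traits$species)
    as_vert <- as_invert <- traits
    as_vert$diet[as_vert$species == dual_diet_species] <- "vertebrate"
    as_invert$diet[as_invert$species == dual_diet_species] <- "invertebrate"
    codings <- list(`dual-as-vertebrate` = as_vert,
                    `dual-as-invertebrate` = as_invert)
  }
  table <- signal <- selection <- anova_tb <- NULL
  for (coding in names(codings)) {
    tr <- codings[[coding]]
    for (resp in responses) {
      sig <- phylo_signal_lambda(tr, resp, tree)
      signal <- dplyr::bind_rows(signal, dplyr::mutate(
        sig, coding = coding, .before = 1))
      st <- phylostep(tr, resp, candidates, tree)
      selection <- dplyr::bind_rows(selection, dplyr::mutate(
        st$trace, coding = coding, response = resp, .before = 1))
      table <- dplyr::bind_rows(table, dplyr::mutate(
        tidy(st$model), coding = coding, response = resp, .before = 1))
      if ("habitat" %in% st$selected) {
        pa <- phylo_anova(tr, resp, "habitat", tree,
                          n_sims = n_sims, seed = seed)
        anova_tb <- dplyr::bind_rows(anova_tb, dplyr::mutate(
          tidy(pa), coding = coding, response = resp, factor = "habitat",
          .before = 1))
      }
    }
  }
  structure(
    list(table = table, signal = signal, selection = selection,
         anova = anova_tb,
         provenance = list(n_species = nrow(traits), responses = responses,
                           candidates = candidates, n_sims = n_sims,
                           seed = seed)),
    class = "analysis_report"
  )
}

#' Multidimensional (shape) comparative analysis
#'
#' Elliptic Fourier transform of each species outline, harmonic-count
#' selection by cumulative power, PCA of the coefficients, then Pagel's
#' lambda and stepwise PGLS of the leading principal-component scores on the
#' ecological covariates. Degenerate shape spaces (identical outlines) are
#' reported with the PGLS stage skipped.
#'
#' @param outlines Named list of closed outline tibbles, one per species.
#' @param covariates Species trait tibble with the candidate predictors.
#' @param tree An `ape::phylo` tree.
#' @param candidates Candidate predictor columns for the PC regressions.
#' @param n_harmonics_max Harmonics computed before selection.
#' @param power_threshold Cumulative power fraction for harmonic selection.
#' @param n_points Resampled points per outline.
#' @param n_pcs Number of leading PCs to analyse.
#' @return An `analysis_report` list: `pca` (variance table), `scores`,
#'   `table`, `signal`, `selection`, `n_harmonics`, `provenance`.
#' @export
run_multidimensional <- function(outlines, covariates, tree,
                                 candidates = c("diet", "habitat",
                                                "body_mass_g"),
                                 n_harmonics_max = 16,
                                 power_threshold = 0.99,
                                 n_points = 256, n_pcs = 2) {
  covariates <- prepare_traits(covariates)
  coeffs <- purrr::map(outlines, function(o) {
    o |> resample_outline(n_points) |> eft_forward(n_harmonics_max)
  })
  n_sel <- max(purrr::map_int(coeffs, function(cf) {
    harmonic_power(cf, power_threshold)$n_selected
  }))
  coeffs <- purrr::map(coeffs, truncate_harmonics, n_sel)
  space <- tryCatch(pca_shapes(coeffs), owlfield_degenerate_pca = identity)
  if (inherits(space, "condition")) {
    return(structure(
      list(pca = NULL, scores = NULL, table = NULL, signal = NULL,
           selection = NULL, n_harmonics = n_sel, degenerate = TRUE,
           provenance = list(n_outlines = length(outlines))),
      class = "analysis_report"
    ))
  }
  candidates <- intersect(candidates, names(covariates))
  pcs <- paste0("PC", seq_len(min(n_pcs, ncol(space$scores) - 1)))
  dat <- dplyr::left_join(
    dplyr::rename(space$scores, species = "outline"),
    covariates, by = "species"
  )
  table <- signal <- selection <- NULL
  for (pc in pcs) {
    sig <- phylo_signal_lambda(dat, pc, tree)
    signal <- dplyr::bind_rows(signal, sig)
    st <- phylostep(dat, pc, candidates, tree)
    selection <- dplyr::bind_rows(selection, dplyr::mutate(
      st$trace, response = pc, .before = 1))
    table <- dplyr::bind_rows(table, dplyr::mutate(
      tidy(st$model), response = pc, .before = 1))
  }
  structure(
    list(pca = tidy(space), scores = space$scores, space = space,
         table = table, signal = signal, selection = selection,
         n_harmonics = n_sel, degenerate = FALSE,
         provenance = list(n_outlines = length(outlines),
                           n_points = n_points,
                           power_threshold = power_threshold)),
    class = "analysis_report"
  )
}

# Truncate stored harmonics (coefficients are independent across harmonics,
# so truncation equals recomputation at the smaller count).
truncate_harmonics <- function(coeffs, n) {
  stopifnot(inherits(coeffs, "eft_coefficients"), n <= coeffs$n_harmonics)
  coeffs$a <- coeffs$a[1:n]; coeffs$b <- coeffs$b[1:n]
  coeffs$c <- coeffs$c[1:n]; coeffs$d <- coeffs$d[1:n]
  coeffs$n_harmonics <- as.integer(n)
  coeffs
}

#' Two-taxon comparison (e.g. owls versus diurnal raptors)
#'
#' Binds two species trait tables with a `group` indicator and fits a
#' group-term PGLS for each visual-field trait on the combined tree, plus an
#' optional combined shape analysis (PCA of outlines and group PGLS on the
#' leading PC scores).
#'
#' @param traits_a,traits_b Trait tibbles of the two taxa.
#' @param labels Length-2 character: group labels for `traits_a`, `traits_b`
#'   (first label is the regression baseline).
#' @param tree Combined tree covering both groups.
#' @param responses Trait columns to compare.
#' @param outlines Optional named outline list covering both groups.
#' @return An `analysis_report` with `table`, `signal`, `group_means`, and
#'   (when outlines are given) `pca` and `shape_table`.
#' @export
run_group_comparison <- function(traits_a, traits_b,
                                 labels = c("owl", "raptor"), tree,
                                 responses = c("max_overlap_deg",
                                               "vertical_extent_deg",
                                               "offset_deg"),
                                 outlines = NULL) {
  traits_a$group <- labels[1]
  traits_b$group <- labels[2]
  comb <- dplyr::bind_rows(tibble::as_tibble(traits_a),
                           tibble::as_tibble(traits_b))
  comb$group <- factor(comb$group, levels = labels)
  missing_grp <- setdiff(labels, unique(comb$group))
  if (length(missing_grp)) abort("a group has no species.")
  table <- signal <- gm <- NULL
  for (resp in responses) {
    sig <- phylo_signal_lambda(comb, resp, tree)
    signal <- dplyr::bind_rows(signal, sig)
    f <- stats::as.formula(paste0("`", resp, "` ~ group"))
    fit <- pgls_fit(comb, f, tree)
    table <- dplyr::bind_rows(table, dplyr::mutate(
      tidy(fit), response = resp, lambda = fit$lambda, .before = 1))
    gm <- dplyr::bind_rows(gm, dplyr::mutate(
      group_means(comb, resp, "group"), response = resp, .before = 1))
  }
  out <- list(table = table, signal = signal, group_means = gm,
              provenance = list(labels = labels, n_species = nrow(comb)))
  if (!is.null(outlines)) {
    shape <- run_multidimensional(outlines, comb, tree,
                                  candidates = "group")
    out$pca <- shape$pca
    out$shape_table <- shape$table
    out$shape_signal <- shape$signal
    out$n_harmonics <- shape$n_harmonics
  }
  structure(out, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Comparative analysis report\n")
  for (nm in c("signal", "selection", "table", "anova", "pca",
               "group_means")) {
    if (!is.null(x[[nm]])) {
      cat("\n--", nm, "--\n")
      print(as.data.frame(x[[nm]]), digits = 4)
    }
  }
  invisible(x)
}
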