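#' Configuration for the synthetic owl-field study generator
#'
#' Bundles every knob of the synthetic data generator with defaults chosen
#' to emulate the study design the analyses assume: 23 species measured with
#' 1-3 individuals each, a Yule tree, and three species-level traits
#' (maximum binocular overlap, vertical extent of the binocular field, and
#' the elevation offset of the maximum relative to the bill-tip projection)
#' generated as lambda-scaled Brownian motion around additive diet and
#' habitat effects. Default intercepts and effect magnitudes mirror the
#' group differences reported for owls (overlap intercept ~52.6 deg with
#' vertebrate diet -3.6, semi-open -5.0 and open -9.8; extent intercept
#' ~97 deg with diet -9.7 and open -9.1; offset ~34.3 deg with no ecological
#' effects), so synthetic runs resemble the study.
#'
#' @param n_species Number of species (>= 3).
#' @param birth_rate Yule speciation rate.
#' @param individuals Allowed individuals per species (sampled uniformly).
#' @param noise_sd Individual-level measurement noise s.d. (degrees) on
#'   overlap and extent.
#' @param p_vertebrate Probability a species is a vertebrate eater.
#' @param p_habitat Probabilities of dense/semi-open/open habitat.
#' @param traits Per-trait generative parameters: `intercept`,
#'   `diet_vertebrate`, `habitat_semi_open`, `habitat_open` (degrees),
#'   `lambda` in [0,1], and `sd` (Brownian tip standard deviation, degrees).
#' @param apparatus_radius Perimeter radius (m).
#' @param eye_separation_base Eye separation (m) of a 500 g owl; scales with
#'   the cube root of body mass.
#' @param frac_below Fraction of the vertical extent lying below the
#'   elevation of maximum overlap.
#' @param blocked Mark one grid elevation per individual as blocked by the
#'   bill holder, to exercise interpolation.
#' @param seed Master seed (mandatory); per-stage streams are derived from
#'   it so stages can be regenerated independently.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 23,
                       birth_rate = 1,
                       individuals = 1:3,
                       noise_sd = 2,
                       p_vertebrate = 0.65,
                       p_habitat = c(dense = 0.35, `semi-open` = 0.40,
                                     open = 0.25),
                       traits = list(
                         max_overlap = list(intercept = 52.6,
                                            diet_vertebrate = -3.6,
                                            habitat_semi_open = -5.0,
                                            habitat_open = -9.8,
                                            lambda = 1e-7, sd = 2.5),
                         vertical_extent = list(intercept = 97,
                                                diet_vertebrate = -9.7,
                                                habitat_semi_open = -3.0,
                                                habitat_open = -9.1,
                                                lambda = 0.97, sd = 8),
                         offset = list(intercept = 34.3,
                                       diet_vertebrate = 0,
                                       habitat_semi_open = 0,
                                       habitat_open = 0,
                                       lambda = 1e-7, sd = 6)
                       ),
                       apparatus_radius = 0.5,
                       eye_separation_base = 0.024,
                       frac_below = 0.55,
                       blocked = TRUE,
                       seed) {
  if (missing(seed)) abort("`seed` is mandatory in sim_config().")
  if (n_species < 3) abort("`n_species` must be >= 3.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  for (tr in traits) {
    if (tr$lambda < 0 || tr$lambda > 1 || tr$sd < 0) {
      abort("trait lambda must lie in [0,1] and sd must be >= 0.")
    }
  }
  structure(
    list(n_species = n_species, birth_rate = birth_rate,
         individuals = individuals, noise_sd = noise_sd,
         p_vertebrate = p_vertebrate, p_habitat = p_habitat,
         traits = traits, apparatus_radius = apparatus_radius,
         eye_separation_base = eye_separation_base,
         frac_below = frac_below, blocked = blocked,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Derived per-stage seeds, kept below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(tree = 101L, traits = 202L, profiles = 303L)
  (as.integer(seed) * 7919L + offsets[[stage]]) %% 2147483562L
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree conditioned on the number of tips, deterministic for a
#' given seed.
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed RNG seed.
#' @return An `ape::phylo` tree with tips `sp01, sp02, ...`.
#' @export
simulate_yule <- function(n_species, birth_rate = 1, seed) {
  if (n_species < 2) abort("`n_species` must be >= 2.")
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree
}

#' Simulate correlated traits under lambda-scaled Brownian motion
#'
#' Draws one or more trait vectors `y = X beta + eps` with
#' `eps ~ MVN(0, sigma2 * C_lambda)`, where `C` is the tree's Brownian
#' covariance scaled to unit height (so `sd` is the tip-level standard
#' deviation in trait units).
#'
#' @param tree An `ape::phylo` tree.
#' @param n_reps Number of independent replicate vectors.
#' @param sd Tip-level Brownian standard deviation.
#' @param lambda Pagel's lambda of the generating process.
#' @param mean Mean vector (scalar or per tip).
#' @return A matrix (tips x `n_reps`) with tip labels as rownames.
#' @export
simulate_bm <- function(tree, n_reps = 1, sd = 1, lambda = 1, mean = 0) {
  C <- phylo_vcv(tree)
  C <- C / max(diag(C))
  V <- lambda_transform(C, lambda) * sd^2 + diag(1e-12, nrow(C))
  mu <- rep_len(mean, nrow(C))
  Y <- rmvn_chol(n_reps, mu, V)
  rownames(Y) <- rownames(C)
  Y
}

#' Simulate a species trait table
#'
#' Generates ecological covariates (diet, habitat, body mass, eye axial
#' length) and the three visual-field traits with additive diet/habitat
#' effects plus lambda-scaled Brownian residuals, in the schema consumed by
#' the comparative analyses. Body mass and axial length carry no effect on
#' the visual-field traits: they are the allometric candidates the model
#' selection should reject.
#'
#' @param tree Tree from [simulate_yule()].
#' @param config A [sim_config()].
#' @return A tibble: `species`, `diet`, `habitat`, `body_mass_g`,
#'   `eye_axial_length_mm`, `max_overlap_deg`, `vertical_extent_deg`,
#'   `offset_deg`, `elevation_of_max_deg` (on the 10-degree grid) and
#'   `bill_tip_elevation_deg`.
#' @export
simulate_traits <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "traits"))
  sp <- tree$tip.label
  n <- length(sp)
  diet <- factor(
    ifelse(runif(n) < config$p_vertebrate, "vertebrate", "invertebrate"),
    levels = c("invertebrate", "vertebrate")
  )
  habitat <- factor(
    sample(names(config$p_habitat), n, replace = TRUE,
           prob = config$p_habitat),
    levels = c("dense", "semi-open", "open")
  )
  mass <- exp(rnorm(n, log(500), 0.8))
  axial <- 12 * (mass / 500)^0.2 * exp(rnorm(n, 0, 0.05))
  draw_trait <- function(par) {
    mu <- par$intercept +
      par$diet_vertebrate * (diet == "vertebrate") +
      par$habitat_semi_open * (habitat == "semi-open") +
      par$habitat_open * (habitat == "open")
    unname(drop(simulate_bm(tree, 1, sd = par$sd, lambda = par$lambda,
                            mean = mu)))
  }
  overlap <- pmin(pmax(draw_trait(config$traits$max_overlap), 5), 175)
  extent <- pmin(pmax(draw_trait(config$traits$vertical_extent), 25), 175)
  offset <- pmax(draw_trait(config$traits$offset), 0)
  e_max <- sample(c(0, 10, 20), n, replace = TRUE)
  tibble::tibble(
    species = sp,
    diet = diet,
    habitat = habitat,
    body_mass_g = mass,
    eye_axial_length_mm = axial,
    max_overlap_deg = overlap,
    vertical_extent_deg = extent,
    offset_deg = offset,
    elevation_of_max_deg = e_max,
    bill_tip_elevation_deg = e_max - offset
  )
}

#' Simulate perimeter measurement records for a trait table
#'
#' Inverse construction: for each species and individual, builds symmetric
#' left/right medial margins on the 10-degree elevation grid whose derived
#' summary statistics (maximum overlap, its elevation, vertical extent)
#' equal the table's trait values plus seeded individual noise, then maps
#' the eye-frame margins back to the apparatus frame (finite radius, finite
#' eye separation), so the full correction pipeline is exercised. The
#' signed width rises linearly from the lower field limit to its maximum at
#' `elevation_of_max_deg` and falls linearly to the upper limit; the limits
#' generally fall between grid rows.
#'
#' @param trait_table Output of [simulate_traits()].
#' @param config The same [sim_config()].
#' @return A tibble of perimeter records (`species`, `individual`, `eye`,
#'   `eye_state`, `elevation`, `margin_azimuth`, `apparatus_radius`,
#'   `eye_separation`, `blocked`).
#' @export
simulate_field_profiles <- function(trait_table, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(trait_table$max_overlap_deg > 180) ||
      any(trait_table$vertical_extent_deg > 180)) {
    abort("traits outside physical range (overlap/extent must be <= 180).")
  }
  if (any(trait_table$vertical_extent_deg <= 0 &
          trait_table$max_overlap_deg > 0)) {
    abort("infeasible trait combination: zero extent with positive overlap.")
  }
  set.seed(stage_seed(config$seed, "profiles"))
  rows <- purrr::pmap_dfr(
    trait_table[, c("species", "max_overlap_deg", "vertical_extent_deg",
                    "elevation_of_max_deg", "body_mass_g")],
    function(species, max_overlap_deg, vertical_extent_deg,
             elevation_of_max_deg, body_mass_g) {
      n_ind <- if (length(config$individuals) == 1) config$individuals
               else sample(config$individuals, 1)
      eye_sep <- config$eye_separation_base * (body_mass_g / 500)^(1 / 3)
      purrr::map_dfr(seq_len(n_ind), function(ind) {
        W <- max(5, max_overlap_deg + rnorm(1, 0, config$noise_sd))
        E <- max(25, vertical_extent_deg + rnorm(1, 0, config$noise_sd))
        one_individual_records(
          species, sprintf("%s_i%d", species, ind), W, E,
          elevation_of_max_deg, config$frac_below,
          config$apparatus_radius, eye_sep, config$blocked
        )
      })
    }
  )
  rows
}

# Build the per-elevation records of one individual. The signed binocular
# width is a tent function peaking at e_max; margins are symmetric about the
# median plane.
one_individual_records <- function(species, individual, W, E, e_max,
                                   frac_below, radius, eye_sep, blocked) {
  lo <- e_max - frac_below * E
  up <- lo + E
  grid <- seq(10 * floor(lo / 10), 10 * ceiling(up / 10), by = 10)
  s <- ifelse(grid <= e_max,
              W * (grid - lo) / (e_max - lo),
              W * (up - grid) / (up - e_max))
  blocked_rows <- rep(FALSE, length(grid))
  if (blocked) {
    # one interior row away from the peak and the field limits
    cand <- which(grid > lo + 10 & grid < up - 10 & grid != e_max &
                    abs(grid - e_max) > 10)
    if (length(cand)) {
      pick <- if (length(cand) == 1) cand else sample(cand, 1)
      blocked_rows[pick] <- TRUE
    }
  }
  left_eye <- uncorrect_from_infinity(s / 2, "left", radius, eye_sep)
  right_eye <- uncorrect_from_infinity(-s / 2, "right", radius, eye_sep)
  tibble::tibble(
    species = species,
    individual = individual,
    eye = rep(c("left", "right"), each = length(grid)),
    eye_state = "converged",
    elevation = rep(grid, 2),
    margin_azimuth = ifelse(rep(blocked_rows, 2), NA_real_,
                            c(left_eye, right_eye)),
    apparatus_radius = radius,
    eye_separation = eye_sep,
    blocked = rep(blocked_rows, 2)
  )
}

#' Simulate a complete synthetic study
#'
#' Tree, trait table and perimeter records in one call, each stage on its
#' own seed stream derived from the master seed.
#'
#' @param config A [sim_config()].
#' @return A list with `tree`, `traits`, `records` and the `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_yule(config$n_species, config$birth_rate,
                        stage_seed(config$seed, "tree"))
  traits <- simulate_traits(tree, config)
  records <- simulate_field_profiles(traits, config)
  list(tree = tree, traits = traits, records = records, config = config)
}
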