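#' Recipe for a synthetic saturation binding dataset
#'
#' Bound concentrations follow the Langmuir isotherm
#' `B = Bmax * F / (Kd + F)` with multiplicative Gaussian noise per
#' replicate. Defaults mirror the measured system: an apparent affinity of
#' order 1-3 nM, a capacity near 2 nM, and a mass-concentration ladder
#' spanning 10-5000 ng/mL of a 688 bp fragment.
#'
#' @param Kd Dissociation constant, nM (> 0; default 1.3).
#' @param Bmax Maximum binding concentration, nM (> 0; default 1.9).
#' @param free_ng_ml Free-DNA concentration ladder, ng/mL.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0.05).
#' @param replicates Replicates per concentration (default 3).
#' @param dna_length_bp Fragment length for the mass-molar conversion
#'   (default 688).
#' @param specific_activity Scintillation response, cpm per ng/mL
#'   (arbitrary instrument scale; default 100).
#' @param elapsed_days Days between labelling and counting (default 0).
#' @param seed Default seed for [gen_binding_data()].
#' @return A `binding_recipe` list.
#' @export
binding_recipe <- function(Kd = 1.3, Bmax = 1.9,
                           free_ng_ml = c(10, 25, 50, 100, 250, 500,
                                          1000, 2500, 5000),
                           noise_cv = 0.05, replicates = 3L,
                           dna_length_bp = 688L, specific_activity = 100,
                           elapsed_days = 0, seed = 1L) {
  stopifnot(Kd > 0, Bmax > 0, all(free_ng_ml >= 0), noise_cv >= 0,
            replicates >= 1L, dna_length_bp >= 1L)
  structure(as.list(environment()), class = "binding_recipe")
}

#' Generate a synthetic binding dataset with known truth
#'
#' @param recipe A [binding_recipe()].
#' @param seed Seed (defaults to `recipe$seed`).
#' @return List with `data` (a data.frame in assay units: `free_ng_ml`,
#'   `replicate`, `free_nM`, `bound_nM`, `supernatant_cpm`, `pellet_cpm`,
#'   `elapsed_days`) and `truth` (`list(Kd, Bmax)` in nM). Convert to a
#'   fitting-ready [binding_dataset()] with
#'   `binding_dataset(data$free_nM, data$bound_nM, data$replicate)`.
#' @export
gen_binding_data <- function(recipe, seed = recipe$seed) {
  stopifnot(inherits(recipe, "binding_recipe"))
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(recipe$replicates),
                        free_ng_ml = recipe$free_ng_ml)
    Fnm <- mass_to_molar(grid$free_ng_ml, recipe$dna_length_bp)
    B <- recipe$Bmax * Fnm / (recipe$Kd + Fnm)
    if (recipe$noise_cv > 0) {
      B <- B * pmax(1 + stats::rnorm(length(B), 0, recipe$noise_cv), 0)
    }
    decay <- 2^(-recipe$elapsed_days / P33_HALF_LIFE_DAYS)
    data <- data.frame(
      free_ng_ml = grid$free_ng_ml,
      replicate = grid$replicate,
      free_nM = Fnm,
      bound_nM = B,
      supernatant_cpm = grid$free_ng_ml * recipe$specific_activity * decay,
      pellet_cpm = molar_to_mass(B, recipe$dna_length_bp) *
        recipe$specific_activity * decay,
      elapsed_days = recipe$elapsed_days
    )
    list(data = data, truth = list(Kd = recipe$Kd, Bmax = recipe$Bmax))
  })
}
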